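## Readers and writers for materials and body configurations.
##
## Material CSV dialect: header `frequency_hz, eps_rel_real, sigma_s_per_m`,
## UTF-8, '.' decimal, optional leading '#' metadata lines.
## Parametric material JSON: {name, eps_inf, terms: [{delta_eps, tau_s,
## alpha}, ...], sigma_static}; a file may carry a top-level "materials"
## array instead of a single object.

#' Write and read tabulated materials as CSV
#'
#' @param material a tabulated `dispersive_material` (convert a parametric
#'   one first with [tabulate_material()]).
#' @param path file path.
#' @param name material name to attach on read; defaults to the file stem.
#' @return `read_material_csv` returns a `dispersive_material`;
#'   `write_material_csv` returns `path` invisibly.
#' @export
write_material_csv <- function(material, path) {
  stopifnot(inherits(material, "dispersive_material"))
  if (material$source != "tabulated")
    stop("only tabulated materials have a CSV form; use tabulate_material() first",
         call. = FALSE)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# tpbecm material '%s'", material$name), con)
  utils::write.csv(material$table, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_material_csv
#' @export
read_material_csv <- function(path, name = NULL) {
  d <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                       fileEncoding = "UTF-8")
  need <- c("frequency_hz", "eps_rel_real", "sigma_s_per_m")
  if (!all(need %in% names(d)))
    stop("material CSV must have header columns ", paste(need, collapse = ", "),
         " (got: ", paste(names(d), collapse = ", "), ")", call. = FALSE)
  tabulated_material(name %||% sub("\\.[^.]*$", "", basename(path)),
                     d$frequency_hz, d$eps_rel_real, d$sigma_s_per_m,
                     check_physical = FALSE)
}

#' Evaluate a material onto a fixed grid as a tabulated material
#'
#' @param material any `dispersive_material`.
#' @param frequencies target grid, Hz.
#' @return a tabulated `dispersive_material`.
#' @export
tabulate_material <- function(material, frequencies = default_frequency_grid()) {
  eps <- evaluate_permittivity(material, frequencies, relative = TRUE)
  tabulated_material(material$name, frequencies, Re(eps),
                     -Im(eps) * 2 * pi * frequencies * EPS0,
                     check_physical = FALSE)
}

.parse_parametric_json <- function(x) {
  for (f in c("name", "eps_inf"))
    if (is.null(x[[f]]))
      stop("parametric material JSON missing field '", f, "'", call. = FALSE)
  terms <- x$terms %||% list()
  if (is.data.frame(terms)) terms <- split(terms, seq_len(nrow(terms)))
  parametric_material(x$name, x$eps_inf, terms = terms,
                      sigma_static = x$sigma_static %||% 0,
                      f_max_hz = x$f_max_hz %||% Inf)
}

#' Read parametric materials from JSON
#'
#' @param path file path; either one material object or a file with a
#'   top-level `materials` array.
#' @return one `dispersive_material`, or a named list of them.
#' @export
read_material_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE,
                           simplifyDataFrame = TRUE)
  if (!is.null(x$materials)) {
    mats <- x$materials
    if (is.data.frame(mats)) {
      out <- lapply(seq_len(nrow(mats)), function(i) {
        row <- as.list(mats[i, ])
        row$terms <- mats$terms[[i]]
        .parse_parametric_json(row)
      })
    } else {
      out <- lapply(mats, .parse_parametric_json)
    }
    names(out) <- vapply(out, `[[`, character(1), "name")
    return(out)
  }
  .parse_parametric_json(x)
}

#' Read a layered-body configuration (YAML or JSON)
#'
#' Expected fields: `layers` (list of `{material, thickness_mm}` entries,
#' the last one `{material, infinite: true}`), optional `materials` (path to
#' a material JSON/CSV, relative to the config file, or a named inline
#' list), `geometry` (`width_m`, `length_m`, `separation_m`), `gel_ohms`,
#' `g2` (number or `"estimate"`), `if_scale`, `name`.  Schema violations are
#' reported with the offending path and field.
#'
#' @param path config file path (`.yaml`/`.yml` or `.json`).
#' @param materials optional named list of `dispersive_material` objects
#'   overriding the config's `materials` entry.
#' @return a [layered_body()].
#' @export
read_body_config <- function(path, materials = NULL) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path) else jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(cfg$layers) || !length(cfg$layers))
    stop(path, ": field 'layers' is missing or empty", call. = FALSE)
  if (is.null(materials)) {
    m <- cfg$materials
    if (is.character(m)) {
      mpath <- if (file.exists(m)) m else file.path(dirname(path), m)
      if (!file.exists(mpath))
        stop(path, ": materials file not found: ", m, call. = FALSE)
      materials <- if (grepl("\\.json$", mpath, ignore.case = TRUE))
        read_material_json(mpath) else list(read_material_csv(mpath))
      if (inherits(materials, "dispersive_material"))
        materials <- stats::setNames(list(materials), materials$name)
    } else if (is.list(m)) {
      materials <- lapply(m, .parse_parametric_json)
      names(materials) <- vapply(materials, `[[`, character(1), "name")
    } else {
      stop(path, ": field 'materials' must be a path or an inline list",
           call. = FALSE)
    }
  }
  layers <- lapply(seq_along(cfg$layers), function(i) {
    l <- cfg$layers[[i]]
    if (is.null(l$material))
      stop(path, ": layers[", i, "] missing field 'material'", call. = FALSE)
    mat <- materials[[l$material]]
    if (is.null(mat))
      stop(path, ": layers[", i, "]: unknown material '", l$material, "'",
           call. = FALSE)
    inf <- isTRUE(l$infinite)
    if (!inf && is.null(l$thickness_mm))
      stop(path, ": layers[", i, "] missing field 'thickness_mm'", call. = FALSE)
    tissue_layer(mat, thickness_mm = l$thickness_mm, infinite = inf)
  })
  geo <- cfg$geometry %||% list()
  geometry <- electrode_geometry(geo$width_m %||% 0.01,
                                 geo$length_m %||% 0.01,
                                 geo$separation_m %||% 0.01)
  layered_body(layers, geometry = geometry,
               gel_ohms = cfg$gel_ohms %||% 0,
               g2 = cfg$g2 %||% "estimate",
               if_scale = cfg$if_scale %||% 1,
               name = cfg$name %||% sub("\\.[^.]*$", "", basename(path)))
}

#' Write an impedance spectrum as CSV
#'
#' Long format `frequency_hz, layer, z_real, z_imag` with a metadata
#' comment header.
#'
#' @param spectrum an `impedance_spectrum`.
#' @param path file path.
#' @param seed optional seed to record in the header.
#' @return `path`, invisibly.
#' @export
write_spectrum_csv <- function(spectrum, path, seed = NA) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# tpbecm impedance_spectrum body=%s seed=%s version=%s",
                     spectrum$body_name, as.character(seed),
                     as.character(utils::packageVersion("tpbecm"))), con)
  utils::write.csv(as.data.frame(spectrum), con, row.names = FALSE)
  invisible(path)
}
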