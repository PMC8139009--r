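## Refitting interdimensional factors from (h1, eps1, eps2, C_tot) data.
##
## The IF models are linear in their coefficients once the capacitance rows
## are transformed to observed Layer-1 geometric factors, so the fit is plain
## OLS on the exact parameterization:
##   PPC: I = a0 + a1 ln(eps1-eps2) + a2 ln(h1)      regressors 1, ln(de), ln(h)
##   SPC: I = (b0 + b1 ln(eps2/eps1))/h1 + c0        regressors 1/h, ln(r)/h, 1
## (no nonlinear minimization, hence no initialization question).

.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Relative-permittivity pairs of the in-silico simulation design
#'
#' The ten (eps1, eps2) pairs per kind used by the 3D simulation campaign
#' behind the shipped coefficients: all ordered pairs drawn from
#' \{10, 20, 30, 40, 50\} with eps1 > eps2 for PPC and eps1 < eps2 for SPC.
#'
#' @param kind `"PPC"` or `"SPC"`.
#' @return data.frame with columns `eps1_rel`, `eps2_rel` (10 rows).
#' @export
design_permittivity_pairs <- function(kind = c("PPC", "SPC")) {
  kind <- match.arg(kind)
  g <- expand.grid(eps1_rel = c(10, 20, 30, 40, 50),
                   eps2_rel = c(10, 20, 30, 40, 50))
  keep <- if (kind == "PPC") g$eps1_rel > g$eps2_rel else g$eps1_rel < g$eps2_rel
  out <- g[keep, ]
  out <- out[order(out$eps1_rel, out$eps2_rel), ]
  rownames(out) <- NULL
  out
}

#' Generate a surrogate simulation dataset on the standard design
#'
#' Stands in for the 3D FEM campaign: evaluates the forward PC + IF model on
#' the full factorial of the ten design permittivity pairs and the
#' thicknesses `h1_mm` (default 2/4/6 mm, 30 rows), optionally perturbing
#' the capacitance response with multiplicative Gaussian noise.
#' Permittivities are treated as real and relative (the regression harness
#' units); the response `c_total` carries GF-units x relative-permittivity.
#'
#' @param kind `"PPC"` or `"SPC"`.
#' @param coeffs [if_coefficients()] driving the forward model; defaults to
#'   the shipped triple for `kind`.
#' @param noise_sd multiplicative noise standard deviation (e.g. 0.01 for
#'   1\%); 0 for a noise-free dataset.
#' @param noise_on where the noise enters: `"capacitance"` perturbs the
#'   total-capacitance response; `"gf"` perturbs the interdimensional factor
#'   before composing (the GF term is where the 2D-to-3D fluctuation error
#'   the regression absorbs actually lives, and it is the regression's
#'   response after the transform).
#' @param seed optional RNG seed for reproducible noise (the global RNG
#'   state is restored afterwards).
#' @param g2 bottom geometric factor, in the same unit system as the
#'   coefficients.  The default keeps the two composed terms commensurate
#'   (a design in which the bottom term swamps the Layer-1 term could not
#'   identify the IF): the coplanar half-space estimate for the standard
#'   1 cm geometry for PPC, and that estimate scaled by 1e5 -- the ratio
#'   between the shipped SPC and PPC coefficient scales -- for SPC.
#' @param h1_mm Layer-1 thickness levels, mm.
#' @return object of class `if_dataset`: a data.frame with columns `kind`,
#'   `h1_mm`, `eps1_rel`, `eps2_rel`, `c_total` and attributes `kind`, `g2`,
#'   `noise_sd`, `seed`.
#' @export
generate_fem_surrogate <- function(kind = c("PPC", "SPC"), coeffs = NULL,
                                   noise_sd = 0, seed = NULL, g2 = NULL,
                                   h1_mm = c(2, 4, 6),
                                   noise_on = c("capacitance", "gf")) {
  kind <- match.arg(kind)
  noise_on <- match.arg(noise_on)
  coeffs <- coeffs %||% default_if_coefficients(kind)
  if (coeffs$kind != kind) stop("coefficient kind does not match 'kind'", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  g2 <- g2 %||% (gf_halfspace(electrode_geometry()) *
                   if (kind == "SPC") 1e5 else 1)
  des <- merge(design_permittivity_pairs(kind), data.frame(h1_mm = h1_mm))
  e1 <- des$eps1_rel; e2 <- des$eps2_rel; h <- des$h1_mm
  I <- if (kind == "PPC") .if_ppc(e1 - e2, h, coeffs$values)
       else .if_spc(e2 / e1, h, coeffs$values)
  if (noise_sd > 0 && noise_on == "gf")
    I <- .with_seed(seed, I * (1 + stats::rnorm(length(I), 0, noise_sd)))
  ct <- if (kind == "PPC") (e1 - e2) * I + e2 * g2
        else 1 / ((1 / e1 - 1 / e2) / I + 1 / (e2 * g2))
  if (noise_sd > 0 && noise_on == "capacitance")
    ct <- .with_seed(seed, ct * (1 + stats::rnorm(length(ct), 0, noise_sd)))
  out <- data.frame(kind = kind, h1_mm = h, eps1_rel = e1, eps2_rel = e2,
                    c_total = ct)
  structure(out, kind = kind, g2 = g2, noise_sd = noise_sd, seed = seed,
            class = c("if_dataset", "data.frame"))
}

#' Observed Layer-1 geometric factor from a capacitance row
#'
#' Inverts the pairwise composition to the quantity the IF regression is fit
#' on: for PPC \eqn{(C - \varepsilon_2 g_2)/(\varepsilon_1 - \varepsilon_2)},
#' for SPC the algebraic inverse of the reciprocal-sum model,
#' \eqn{(1/\varepsilon_1 - 1/\varepsilon_2)\big/(1/C - 1/(\varepsilon_2 g_2))}.
#' Rows with a vanishing denominator (homogeneous pairs, or a capacitance
#' equal to the bottom term) are rejected: returned as `NA` with a warning
#' naming the reason.
#'
#' @param c_total total capacitance response (GF-units x relative
#'   permittivity).
#' @param eps1_rel,eps2_rel relative permittivities of upper/lower layer.
#' @param g2 bottom geometric factor used when generating the data.
#' @param kind `"PPC"` or `"SPC"`.
#' @return numeric vector of observed GF values (`NA` for rejected rows).
#' @export
gf1_from_capacitance <- function(c_total, eps1_rel, eps2_rel, g2,
                                 kind = c("PPC", "SPC")) {
  kind <- match.arg(kind)
  .tpb_stopifnot_scalar(g2, "g2")
  if (kind == "PPC") {
    den <- eps1_rel - eps2_rel
    bad <- den == 0
    out <- ifelse(bad, NA_real_, (c_total - eps2_rel * g2) / den)
    reason <- "eps1 == eps2"
  } else {
    den <- 1 / c_total - 1 / (eps2_rel * g2)
    num <- 1 / eps1_rel - 1 / eps2_rel
    bad <- den == 0 | num == 0 | c_total == 0
    out <- ifelse(bad, NA_real_, num / den)
    reason <- "zero reciprocal denominator"
  }
  if (any(bad))
    warning(sprintf("%d row(s) rejected (%s)", sum(bad), reason), call. = FALSE)
  out
}

#' Fit interdimensional-factor coefficients by least squares
#'
#' Transforms each (h1, eps1, eps2, C_tot) row to its observed Layer-1
#' geometric factor via [gf1_from_capacitance()], then fits the IF model of
#' the dataset's kind by ordinary least squares on its exact
#' linear-in-coefficients form (unweighted, deterministic given the data).
#'
#' @param data an `if_dataset` from [generate_fem_surrogate()] /
#'   [read_if_dataset()], or any data.frame with columns `h1_mm`,
#'   `eps1_rel`, `eps2_rel`, `c_total`.
#' @param kind `"PPC"` or `"SPC"`; taken from the dataset attribute when
#'   omitted.
#' @param g2 bottom geometric factor used to generate the responses; taken
#'   from the dataset attribute when omitted.
#' @return object of class `if_fit` with methods `print`, `summary`, `coef`,
#'   `predict`, `residuals`, `fitted`, `simulate` and `plot`.  The fitted
#'   triple is exposed as an [if_coefficients()] object in `$coefficients`.
#' @export
#' @examples
#' d <- generate_fem_surrogate("SPC")
#' fit <- fit_if(d)
#' coef(fit) / 1e3
fit_if <- function(data, kind = NULL, g2 = NULL) {
  kind <- kind %||% attr(data, "kind") %||% unique(as.character(data$kind))
  if (length(kind) != 1L || !kind %in% c("PPC", "SPC"))
    stop("dataset kind must be exactly one of 'PPC' or 'SPC'", call. = FALSE)
  g2 <- g2 %||% attr(data, "g2")
  if (is.null(g2)) stop("'g2' (bottom geometric factor) is required", call. = FALSE)
  need <- c("h1_mm", "eps1_rel", "eps2_rel", "c_total")
  if (!all(need %in% names(data)))
    stop("data must have columns ", paste(need, collapse = ", "), call. = FALSE)
  ok_order <- if (kind == "PPC") data$eps1_rel > data$eps2_rel else
    data$eps1_rel < data$eps2_rel
  if (!all(ok_order))
    stop(sprintf("%d row(s) violate the %s permittivity ordering", sum(!ok_order), kind),
         call. = FALSE)
  y <- gf1_from_capacitance(data$c_total, data$eps1_rel, data$eps2_rel, g2, kind)
  keep <- is.finite(y)
  d <- data[keep, , drop = FALSE]; y <- y[keep]
  if (length(y) < 3L) stop("need at least 3 usable rows", call. = FALSE)
  if (length(unique(d$h1_mm)) < 2L ||
      nrow(unique(d[c("eps1_rel", "eps2_rel")])) < 2L)
    stop("design must span at least 2 thickness values and 2 permittivity pairs",
         call. = FALSE)
  if (kind == "PPC") {
    df <- data.frame(y = y, x1 = log(d$eps1_rel - d$eps2_rel), x2 = log(d$h1_mm))
    labels <- c("a0", "a1", "a2")
    reg_names <- c("1", "ln(eps1-eps2)", "ln(h1)")
  } else {
    df <- data.frame(y = y, x1 = 1 / d$h1_mm,
                     x2 = log(d$eps2_rel / d$eps1_rel) / d$h1_mm)
    labels <- c("c0", "b0", "b1")  # lm order: (Intercept)=c0, x1=b0, x2=b1
    reg_names <- c("1", "1/h1", "ln(eps2/eps1)/h1")
  }
  fit <- stats::lm(y ~ x1 + x2, data = df)
  if (fit$rank < 3L) {
    alias <- reg_names[is.na(stats::coef(fit))]
    stop("rank-deficient IF design; collinear regressors: ",
         paste(alias, collapse = ", "), call. = FALSE)
  }
  cf <- stats::coef(fit)
  names(cf) <- labels
  values <- if (kind == "PPC") cf[c("a0", "a1", "a2")] else cf[c("b0", "b1", "c0")]
  ## noise-free recovery datasets fit exactly; summary.lm warns about that
  sm <- suppressWarnings(summary(fit))
  se <- sm$coefficients[, "Std. Error"]
  names(se) <- labels
  structure(list(
    coefficients = if_coefficients(kind, values,
                                   provenance = sprintf("fit on %d rows", length(y))),
    kind = kind, g2 = g2, n_rows = length(y),
    rss = sum(stats::residuals(fit)^2),
    std_errors = se[names(values)],
    lm = fit, data = d, gf_observed = y),
    class = "if_fit")
}

#' @export
coef.if_fit <- function(object, ...) object$coefficients$values

#' @export
residuals.if_fit <- function(object, ...) stats::residuals(object$lm)

#' @export
fitted.if_fit <- function(object, ...) stats::fitted(object$lm)

#' @export
print.if_fit <- function(x, ...) {
  cat(sprintf("Interdimensional-factor fit (%s), %d rows, g2 = %.6g (GF units)\n",
              x$kind, x$n_rows, x$g2))
  print(round(rbind(estimate = coef(x), std.error = x$std_errors), 8))
  cat(sprintf("residual sum of squares: %.4g\n", x$rss))
  invisible(x)
}

#' @export
summary.if_fit <- function(object, ...) {
  structure(list(fit = object, lm_summary = summary(object$lm)),
            class = "summary.if_fit")
}

#' @export
print.summary.if_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("R-squared: %.6f on GF observations\n", x$lm_summary$r.squared))
  invisible(x)
}

#' Predict interdimensional factors or capacitances from a fit
#'
#' @param object an `if_fit`.
#' @param newdata data.frame with columns `h1_mm`, `eps1_rel`, `eps2_rel`;
#'   defaults to the training design.
#' @param type `"if"` for the interdimensional factor, `"capacitance"` for
#'   the composed total capacitance (uses the fit's `g2`).
#' @param ... unused.
#' @return numeric vector.
#' @export
predict.if_fit <- function(object, newdata = NULL,
                           type = c("if", "capacitance"), ...) {
  type <- match.arg(type)
  d <- newdata %||% object$data
  v <- coef(object)
  if (object$kind == "PPC") {
    I <- .if_ppc(d$eps1_rel - d$eps2_rel, d$h1_mm, v)
    if (type == "if") I else (d$eps1_rel - d$eps2_rel) * I + d$eps2_rel * object$g2
  } else {
    I <- .if_spc(d$eps2_rel / d$eps1_rel, d$h1_mm, v)
    if (type == "if") I else
      1 / ((1 / d$eps1_rel - 1 / d$eps2_rel) / I + 1 / (d$eps2_rel * object$g2))
  }
}

#' Simulate surrogate datasets from a fitted IF model
#'
#' @param object an `if_fit`.
#' @param nsim number of datasets.
#' @param seed optional seed.
#' @param noise_sd multiplicative response noise per dataset.
#' @param ... unused.
#' @return list of `if_dataset` objects (length `nsim`).
#' @export
simulate.if_fit <- function(object, nsim = 1, seed = NULL, noise_sd = 0.01, ...) {
  .with_seed(seed, lapply(seq_len(nsim), function(i)
    generate_fem_surrogate(object$kind, object$coefficients,
                           noise_sd = noise_sd, g2 = object$g2)))
}

#' @export
plot.if_fit <- function(x, ...) {
  graphics::plot(x$gf_observed, fitted(x),
                 xlab = "observed Layer-1 GF", ylab = "fitted IF",
                 main = sprintf("%s interdimensional-factor fit", x$kind), ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

## ---------------------------------------------------------------------------
## Dataset / fit-report IO

#' Read and write IF datasets as CSV
#'
#' Column dialect: `kind, h1_mm, eps1_rel, eps2_rel, c_total`.  Comment
#' lines starting with `#` carry metadata (g2, seed) and are restored as
#' attributes on read when present.
#'
#' @param data an `if_dataset` or compatible data.frame.
#' @param path file path.
#' @return `read_if_dataset` returns an `if_dataset`;
#'   `write_if_dataset` returns `path` invisibly.
#' @export
write_if_dataset <- function(data, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# tpbecm if_dataset kind=%s g2=%.17g seed=%s",
                     attr(data, "kind") %||% unique(data$kind),
                     attr(data, "g2") %||% NA_real_,
                     as.character(attr(data, "seed") %||% "NA")), con)
  utils::write.csv(as.data.frame(data), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_if_dataset
#' @export
read_if_dataset <- function(path) {
  first <- readLines(path, n = 1L)
  d <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  kind <- unique(d$kind); g2 <- NULL
  if (startsWith(first, "#")) {
    m <- regmatches(first, regexec("g2=([0-9.eE+-]+)", first))[[1]]
    if (length(m) == 2L) g2 <- as.numeric(m[2])
    k <- regmatches(first, regexec("kind=([A-Z]+)", first))[[1]]
    if (length(k) == 2L) kind <- k[2]
  }
  structure(d, kind = kind, g2 = g2, class = c("if_dataset", "data.frame"))
}

#' Write an IF fit report as JSON
#'
#' @param fit an `if_fit`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_if_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "if_fit"))
  rep <- list(kind = fit$kind,
              values = unname(coef(fit)),
              coef_names = names(coef(fit)),
              std_errors = unname(fit$std_errors),
              rss = fit$rss, n_rows = fit$n_rows, g2 = fit$g2,
              units_note = fit$coefficients$units_note,
              provenance = fit$coefficients$provenance)
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read IF coefficients from JSON
#'
#' Accepts both fit reports written by [write_if_fit_json()] and plain
#' coefficient files of the form
#' `{kind, values, units_note, provenance}`.
#'
#' @param path file path.
#' @return an [if_coefficients()] object.
#' @export
read_if_coefficients <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(x$PPC) || !is.null(x$SPC))
    return(lapply(x, function(e)
      if_coefficients(e$kind, unlist(e$values),
                      units_note = e$units_note %||% "h1 in mm; relative permittivity",
                      provenance = e$provenance %||% "file")))
  if_coefficients(x$kind, unlist(x$values),
                  units_note = x$units_note %||% "h1 in mm; relative permittivity",
                  provenance = x$provenance %||% "file")
}
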