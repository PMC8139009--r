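test_that("the simulation design carries ten ordered pairs per kind", {
  ppc <- design_permittivity_pairs("PPC")
  spc <- design_permittivity_pairs("SPC")
  expect_equal(nrow(ppc), 10)
  expect_equal(nrow(spc), 10)
  expect_true(all(ppc$eps1_rel > ppc$eps2_rel))
  # the SPC panel is exactly the upper-triangle tuples (10,20) ... (40,50)
  expect_equal(spc$eps1_rel, c(10, 10, 10, 10, 20, 20, 20, 30, 30, 40))
  expect_equal(spc$eps2_rel, c(20, 30, 40, 50, 30, 40, 50, 40, 50, 50))
})

test_that("the surrogate generator is a seeded forward model on the full design", {
  d <- generate_fem_surrogate("PPC")
  expect_s3_class(d, "if_dataset")
  expect_equal(nrow(d), 30)                      # 10 pairs x {2,4,6} mm
  expect_true(all(d$eps1_rel > d$eps2_rel))
  expect_setequal(unique(d$h1_mm), c(2, 4, 6))
  # determinism: same seed, same noise
  d1 <- generate_fem_surrogate("SPC", noise_sd = 0.01, seed = 7)
  d2 <- generate_fem_surrogate("SPC", noise_sd = 0.01, seed = 7)
  expect_identical(d1$c_total, d2$c_total)
  d3 <- generate_fem_surrogate("SPC", noise_sd = 0.01, seed = 8)
  expect_false(identical(d1$c_total, d3$c_total))
  expect_error(generate_fem_surrogate("XYZ"), "arg")
  expect_error(generate_fem_surrogate("PPC", noise_sd = -1), "noise_sd")
})

test_that("the capacitance-to-GF transform inverts the forward composition", {
  g2 <- 0.02
  # PPC row built with a known IF comes straight back
  I <- 0.0123
  ct <- (40 - 10) * I + 10 * g2
  expect_equal(gf1_from_capacitance(ct, 40, 10, g2, "PPC"), I, tolerance = 1e-14)
  # SPC forward-inverse round trip at the worked IF value 3215
  Is <- 3215
  cs <- 1 / ((1 / 10 - 1 / 20) / Is + 1 / (20 * g2))
  expect_equal(gf1_from_capacitance(cs, 10, 20, g2, "SPC"), Is, tolerance = 1e-10 * Is)
  # homogeneous rows are rejected, not silently kept
  expect_warning(out <- gf1_from_capacitance(1, 10, 10, g2, "PPC"), "rejected")
  expect_true(is.na(out))
})

test_that("least-squares refit recovers the generating coefficients exactly", {
  for (kind in c("PPC", "SPC")) {
    truth <- default_if_coefficients(kind)$values
    fit <- fit_if(generate_fem_surrogate(kind))
    expect_lt(max(abs(coef(fit) - truth) / abs(truth)), 1e-8)
    expect_equal(fit$n_rows, 30)
    expect_lt(fit$rss, 1e-12 * sum(fit$gf_observed^2))
  }
  # arbitrary (non-default) triples recover too: the central
  # forward-fit consistency property
  th <- if_coefficients("SPC", c(1234, -56, 7.8))
  fit2 <- fit_if(generate_fem_surrogate("SPC", th))
  expect_lt(max(abs(coef(fit2) - th$values) / abs(th$values)), 1e-8)
})

test_that("degenerate designs are refused with informative errors", {
  d <- generate_fem_surrogate("PPC")
  # constant-GF response: slopes vanish, intercept is the constant
  dconst <- d
  dconst$c_total <- (dconst$eps1_rel - dconst$eps2_rel) * 0.02 +
    dconst$eps2_rel * attr(d, "g2")
  fc <- fit_if(dconst)
  expect_equal(unname(coef(fc)), c(0.02, 0, 0), tolerance = 1e-10)
  # single thickness level: the design no longer identifies a2
  expect_error(fit_if(d[d$h1_mm == 2, ], kind = "PPC", g2 = attr(d, "g2")),
               "2 thickness")
  # collinear regressors: constant permittivity difference makes ln(de)
  # indistinguishable from the intercept
  dc <- d[d$eps1_rel - d$eps2_rel == 10, ]
  expect_error(fit_if(dc, kind = "PPC", g2 = attr(d, "g2")), "collinear")
  # ordering violations are caught before transforming
  dbad <- d; dbad$eps1_rel[1] <- 5
  expect_error(fit_if(dbad), "ordering")
})

test_that("coefficient estimates are robust to 1% noise on the GF response", {
  # single seeded fit lands within 3 standard errors of truth
  truth <- default_if_coefficients("SPC")$values
  f1 <- fit_if(generate_fem_surrogate("SPC", noise_sd = 0.01, seed = 11,
                                      noise_on = "gf"))
  expect_true(all(abs(coef(f1) - truth) <= 3 * f1$std_errors))
  # relative RMSE over 200 seeded replicates stays below 5% per coefficient,
  # for both model kinds
  for (kind in c("PPC", "SPC")) {
    truth <- default_if_coefficients(kind)$values
    est <- sapply(1:200, function(s)
      coef(fit_if(generate_fem_surrogate(kind, noise_sd = 0.01, seed = s,
                                         noise_on = "gf"))))
    rmse <- sqrt(rowMeans((est - truth)^2)) / abs(truth)
    expect_true(all(rmse <= 0.05))
  }
})

test_that("if_fit behaves like a standard fitted-model object", {
  d <- generate_fem_surrogate("PPC", noise_sd = 0.005, seed = 3)
  fit <- fit_if(d)
  expect_named(coef(fit), c("a0", "a1", "a2"))
  expect_length(residuals(fit), 30)
  expect_equal(fitted(fit) + residuals(fit), fit$gf_observed,
               ignore_attr = TRUE)
  expect_output(print(fit), "Interdimensional-factor fit")
  expect_output(print(summary(fit)), "R-squared")
  # noise-free predictions reproduce the training capacitances
  d0 <- generate_fem_surrogate("PPC")
  f0 <- fit_if(d0)
  expect_equal(predict(f0, d0, type = "capacitance"), d0$c_total,
               tolerance = 1e-10)
  # simulate() is reproducible under a seed
  s1 <- simulate(fit, nsim = 2, seed = 5)
  s2 <- simulate(fit, nsim = 2, seed = 5)
  expect_identical(s1[[1]]$c_total, s2[[1]]$c_total)
  expect_false(identical(s1[[1]]$c_total, s1[[2]]$c_total))
})

test_that("datasets and fit reports survive the CSV/JSON round trip", {
  d <- generate_fem_surrogate("SPC", noise_sd = 0.01, seed = 9)
  p <- withr::local_tempfile(fileext = ".csv")
  write_if_dataset(d, p)
  d2 <- read_if_dataset(p)
  expect_equal(attr(d2, "kind"), "SPC")
  expect_equal(attr(d2, "g2"), attr(d, "g2"), tolerance = 1e-15)
  expect_equal(d2$c_total, d$c_total, tolerance = 1e-15)
  fit <- fit_if(d2)
  pj <- withr::local_tempfile(fileext = ".json")
  write_if_fit_json(fit, pj)
  cf <- read_if_coefficients(pj)
  expect_s3_class(cf, "if_coefficients")
  expect_equal(unname(cf$values), unname(coef(fit)), tolerance = 1e-12)
  # the shipped default-coefficients file matches the in-code defaults
  shipped <- read_if_coefficients(system.file("extdata", "if_defaults.json",
                                              package = "tpbecm"))
  expect_equal(shipped$PPC$values, default_if_coefficients("PPC")$values)
  expect_equal(shipped$SPC$values, default_if_coefficients("SPC")$values)
})
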