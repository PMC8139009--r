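test_that("layer pairs classify by complex-permittivity magnitude", {
  expect_identical(classify_pair(2 + 0i, 1 + 0i), "PPC")
  expect_identical(classify_pair(1 + 0i, 2 + 0i), "SPC")
  expect_identical(classify_pair(3 + 4i, 5 + 0i), "HOMOGENEOUS")  # equal magnitude
  expect_identical(classify_pair(1, 1 * (1 + 1e-12)), "HOMOGENEOUS")
  expect_error(classify_pair(Inf + 0i, 1), "finite")
  # the synthetic forearm stack is SPC at every analysis frequency
  tp <- synthetic_tissue_pack()
  f <- default_frequency_grid()
  es <- evaluate_permittivity(tp$skin, f)
  ef <- evaluate_permittivity(tp$fat, f)
  em <- evaluate_permittivity(tp$muscle, f)
  expect_true(all(classify_pair(es, ef) == "SPC"))
  expect_true(all(classify_pair(ef, em) == "SPC"))
  # salted-over-pure agar is PPC everywhere (NaCl raises |eps*|)
  pair <- gen_agar_pair()
  expect_true(all(classify_pair(evaluate_permittivity(pair$salted, f),
                                evaluate_permittivity(pair$pure, f)) == "PPC"))
})

test_that("interdimensional factors evaluate their closed forms", {
  ppc <- default_if_coefficients("PPC")
  spc <- default_if_coefficients("SPC")
  e0 <- EPS0_T
  # both logs vanish: I = a0
  p <- layer_pair(2 * e0, 1 * e0, h1_mm = 1, g2 = 0.1)
  expect_equal(eval_ppc_if(p, ppc), 4.69e-3)
  # delta = e, h1 = e: I = (a0 + a1 + a2)
  p2 <- layer_pair((1 + exp(1)) * e0, 1 * e0, h1_mm = exp(1), g2 = 0.1)
  expect_equal(eval_ppc_if(p2, ppc), (4.69 + 1.12 + 4.40) * 1e-3, tolerance = 1e-12)
  # constant coefficients give a constant IF
  cc <- if_coefficients("PPC", c(0.37, 0, 0))
  expect_equal(eval_ppc_if(p2, cc), 0.37)
  # SPC: ratio = e, h1 = 2 -> (2830 + 1000)/2 + 1300
  s <- layer_pair(1 * e0, exp(1) * e0, h1_mm = 2, g2 = 0.1)
  expect_equal(eval_spc_if(s, spc), 3215, tolerance = 1e-12)
  # ratio = 1 (homogeneous in magnitude but distinct complex values)
  s2 <- layer_pair(complex(real = 0, imaginary = -e0), e0, h1_mm = 2, g2 = 0.1)
  expect_equal(eval_spc_if(s2, spc), 2830 / 2 + 1300)
  # inverse-linear term vanishes for thick layers
  s3 <- layer_pair(1 * e0, exp(1) * e0, h1_mm = 1e9, g2 = 0.1)
  expect_equal(eval_spc_if(s3, spc), 1300, tolerance = 1e-5)
  # errors: homogeneous pair, mismatched coefficient kind
  ph <- layer_pair(e0, e0, 1, 0.1)
  expect_error(eval_ppc_if(ph, ppc), "homogeneous")
  expect_error(eval_ppc_if(p, spc), "not PPC")
  expect_error(eval_spc_if(s, ppc), "not SPC")
})

test_that("pairwise composition reproduces hand arithmetic and its limits", {
  e0 <- EPS0_T
  # PPC harness in relative units: eps1=2, eps2=1, I=0.01, g2=0.1
  p <- layer_pair(2 * e0, 1 * e0, h1_mm = 1, g2 = 0.1)
  cc <- if_coefficients("PPC", c(0.01, 0, 0))
  expect_equal(Re(compose_ppc(p, cc)) / e0, 1 * 0.01 + 1 * 0.1, tolerance = 1e-12)
  # SPC harness: eps1=1, eps2=2, I=0.5, g2=1 -> 1/C = (1-0.5)/0.5 + 0.5
  s <- layer_pair(1 * e0, 2 * e0, h1_mm = 1, g2 = 1)
  sc <- if_coefficients("SPC", c(0, 0, 0.5))
  expect_equal(Re(compose_spc(s, sc)) / e0, 2 / 3, tolerance = 1e-12)
  # homogeneous pairs short-circuit to eps2*g2 on both paths
  ph <- layer_pair(3 * e0, 3 * e0, 1, 0.1)
  expect_equal(compose_ppc(ph, cc), as.complex(3 * e0 * 0.1))
  expect_equal(compose_spc(ph, sc), as.complex(3 * e0 * 0.1))
  # class preconditions are enforced
  expect_error(compose_ppc(s, cc), "PPC condition")
  expect_error(compose_spc(p, sc), "SPC condition")
  # monotonicity: with I > 0 fixed, raising eps1 raises |C| (PPC)
  cs <- sapply(seq(2, 5, by = 0.5), function(e1)
    Mod(compose_ppc(layer_pair(e1 * e0, 1 * e0, 1, 0.1), cc)))
  expect_true(all(diff(cs) > 0))
  # SPC: adding a series layer cannot increase the capacitance
  expect_lt(Mod(compose_spc(s, sc)), Mod(2 * e0 * 1))
})

test_that("both composition paths approach the homogeneous limit smoothly", {
  e0 <- EPS0_T
  g2 <- 0.05
  for (kind in c("PPC", "SPC")) {
    d <- 1e-8 * ifelse(kind == "PPC", 1, -1)
    pr <- layer_pair((10 + d) * e0, 10 * e0, h1_mm = 2, g2 = g2)
    cmp <- suppressWarnings(
      if (kind == "PPC") compose_ppc(pr) else compose_spc(pr))
    expect_lt(Mod(cmp - 10 * e0 * g2) / Mod(10 * e0 * g2), 1e-6)
  }
})

test_that("recurrent stack reduction matches the hand-stepped composition", {
  f <- c(1, 10, 100)
  m1 <- const_material("a", 10, 1e-4)
  m2 <- const_material("b", 100, 1e-3)
  m3 <- const_material("c", 1000, 1e-2)
  layers <- list(list(material = m1, thickness_mm = 2),
                 list(material = m2, thickness_mm = 3),
                 list(material = m3, thickness_mm = 50))
  g2 <- 0.0123
  red <- reduce_stack(layers, f, g2 = g2)
  # hand-stepped oracle: fold bottom pair first, then the top layer against
  # its immediate neighbour with the reduced structure as the bottom term
  e1 <- evaluate_permittivity(m1, f)
  e2 <- evaluate_permittivity(m2, f)
  e3 <- evaluate_permittivity(m3, f)
  c23 <- compose_spc(layer_pair(e2, e3, 3, g2))
  c123 <- compose_spc(layer_pair(e1, e2, 2, g2), c_below = c23)
  expect_equal(red$c_total, c123, tolerance = 1e-14)
  expect_true(all(red$classes == "SPC"))
  # single layer: exactly eps* g2
  red1 <- reduce_stack(layers[3], f, g2 = g2)
  expect_equal(red1$c_total, e3 * g2)
  # two identical layers collapse to the homogeneous value (the equal
  # thicknesses also trip the thin-bottom advisory)
  expect_warning(red2 <- reduce_stack(list(layers[[3]], layers[[3]]), f, g2 = g2),
                 "10x")
  expect_equal(red2$c_total, e3 * g2)
  # empty stack and thin-bottom warnings
  expect_error(reduce_stack(list(), f), "empty")
  expect_warning(reduce_stack(list(list(material = m1, thickness_mm = 10),
                                   list(material = m3, thickness_mm = 20)),
                              f, g2 = g2), "10x")
})

test_that("reduction is pointwise in frequency and flags class crossovers", {
  f <- default_frequency_grid(51)
  tp <- synthetic_tissue_pack()
  layers <- list(list(material = tp$skin, thickness_mm = 1.5),
                 list(material = tp$fat, thickness_mm = 2.5),
                 list(material = tp$muscle, thickness_mm = 100))
  red <- reduce_stack(layers, f, g2 = 0.0078)
  # no cross-frequency leakage: evaluating one frequency at a time agrees
  one <- vapply(f, function(ff) reduce_stack(layers, ff, g2 = 0.0078)$c_total,
                complex(1))
  expect_equal(red$c_total, one, tolerance = 1e-14)
  # passive inputs keep Re(C*) >= 0 across the grid
  expect_true(all(Re(red$c_total) >= 0))
  expect_true(all(Re(red$partials[is.finite(red$partials)]) >= 0))
  # a pair whose ordering flips across the grid raises a crossover warning
  flip <- tabulated_material("flip", c(0.1, 1e4), c(1000, 1000), c(0, 0.5))
  anchor <- const_material("anchor", 1500, 0.01)
  expect_warning(
    reduce_stack(list(list(material = flip, thickness_mm = 2),
                      list(material = anchor, thickness_mm = 50)),
                 default_frequency_grid(41), g2 = 0.01),
    "class")
})
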