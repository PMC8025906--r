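# Typical-path deposition model: discretization, kernel behaviour, regional
# transport, mass conservation and the shape of the deposition-size curve.

diskus_breath <- breathing_pattern(4520, 2.8, 10.3, 9.7)

test_that("log-normal discretization is normalized and centred", {
  a <- discretize_lognormal(2, 1, 64L)
  expect_equal(a$mass_frac, 1)
  expect_equal(a$d_ae, 2)

  for (gsd in c(1.3, 2, 3.6)) for (nb in c(16L, 128L)) {
    a <- discretize_lognormal(1.83, gsd, nb)
    expect_equal(sum(a$mass_frac), 1, tolerance = 1e-12)
    expect_true(all(diff(a$d_ae) > 0))
  }
  # discretized median converges to the MMAD
  a <- discretize_lognormal(3.2, 2.5, 256L)
  med <- exp(stats::approx(cumsum(a$mass_frac) - a$mass_frac / 2,
                           log(a$d_ae), xout = 0.5)$y)
  expect_lt(abs(med - 3.2) / 3.2, 0.005)
  expect_error(discretize_lognormal(2, 0.9), "gsd")
})

test_that("deposition kernels have the expected limits and monotonicity", {
  tree <- airway_tree()
  gen <- tree[5, ]
  q <- 100  # mL/s through one tube
  tiny <- deposition_probabilities(1e-3, gen, q, 1e-6)
  expect_lt(tiny[["pI"]], 1e-5)
  expect_lt(tiny[["pS"]], 1e-6)
  p1 <- deposition_probabilities(2, gen, q, 0.01)
  p2 <- deposition_probabilities(2, gen, q, 0.02)
  expect_gte(p2[["pS"]], p1[["pS"]])
  big <- deposition_probabilities(10, gen, q, 0.01)
  sml <- deposition_probabilities(1, gen, q, 0.01)
  expect_gt(big[["pI"]], sml[["pI"]])
  expect_true(all(unlist(p1) >= 0 & unlist(p1) <= 1))
})

test_that("regional fractions conserve mass and respect physical limits", {
  tree <- airway_tree()
  # coarse aerosol is captured in the throat
  coarse <- regional_deposition(discretize_lognormal(100, 1.2, 32L, 1.33),
                                diskus_breath, tree)
  expect_gte(coarse$ET, 0.99)

  # breath-hold increases the lung fraction
  no_hold <- breathing_pattern(4520, 2.8, 0, 9.7)
  a <- discretize_lognormal(1.83, 3.6, 64L, 1.33)
  expect_gt(regional_deposition(a, diskus_breath, tree)$lung,
            regional_deposition(a, no_hold, tree)$lung)

  # exact mass conservation over a grid of conditions
  for (mmad in c(0.7, 1.83, 5)) for (gsd in c(1.2, 3.6)) {
    r <- regional_deposition(discretize_lognormal(mmad, gsd, 32L, 1.33),
                             diskus_breath, tree)
    expect_equal(r$ET + r$TB + r$AL + r$exhaled, 1, tolerance = 1e-9)
    expect_true(all(unlist(r) >= 0 & unlist(r) <= 1))
  }
})

test_that("reference aerosol lands in the product lower-airway band", {
  r <- regional_deposition(discretize_lognormal(1.83, 3.60, 128L, 1.33),
                           diskus_breath)
  expect_gte(100 * r$lung, 10)
  expect_lte(100 * r$lung, 20)
})

test_that("results are bin-stable and deterministic", {
  b <- diskus_breath
  r128 <- regional_deposition(discretize_lognormal(1.83, 3.6, 128L, 1.33), b)
  r256 <- regional_deposition(discretize_lognormal(1.83, 3.6, 256L, 1.33), b)
  expect_lt(abs(r128$lung - r256$lung) / r256$lung, 0.01)
  again <- regional_deposition(discretize_lognormal(1.83, 3.6, 128L, 1.33), b)
  expect_identical(r128, again)
})

test_that("lung fraction is unimodal in MMAD under tidal breathing", {
  # resting tidal pattern (no breath-hold), the canonical condition for the
  # deposition-size curve; under long breath-holds the fine-side decline
  # moves below the tested range (see vignette)
  tidal <- breathing_pattern(750, 2, 0, 2)
  tree <- airway_tree()
  mm <- exp(seq(log(0.5), log(10), length.out = 20))
  lung <- vapply(mm, function(m)
    regional_deposition(discretize_lognormal(m, 1.5, 48L, 1.33),
                        tidal, tree)$lung, numeric(1))
  peak <- which.max(lung)
  expect_gt(peak, 1)
  expect_lt(peak, 20)
  # rises to the peak, falls after: exactly one sign change
  expect_true(all(diff(lung[1:peak]) > 0))
  expect_true(all(diff(lung[peak:20]) < 0))
})
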