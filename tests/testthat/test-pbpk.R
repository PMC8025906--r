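# PBPK core: partition coefficients, mass balance, linearity, solver
# convergence, elimination bookkeeping and descriptor extraction.

test_that("partition coefficients match a straight-line reimplementation", {
  drug <- drug_params()
  kp <- kp_perfusion_limited(drug)
  # independent recomputation for muscle, term by term
  P <- 10^0.74
  z <- function(ph) 10^(10.61 - ph) + 10^(10.61 + 9.35 - 2 * ph)
  xp <- 1 + z(7.4)
  kpu_bc <- (0.96 - 0.55) / (0.45 * 0.92)
  ka_ap <- max(0, (kpu_bc - (1 + z(7.22)) / xp * 0.63 -
                     (P * 0.0017 + (0.3 * P + 0.7) * 0.0029) / xp) *
                 xp / (0.5 * z(7.22)))
  kpu_muscle <- 0.118 + (1 + z(7.0)) / xp * 0.630 +
    (P * 0.010 + (0.3 * P + 0.7) * 0.0072) / xp +
    ka_ap * 1.53 * z(7.0) / xp
  expect_equal(kp[["muscle"]], kpu_muscle * 0.92, tolerance = 1e-12)
  expect_true(all(kp > 0))
})

test_that("partitioning collapses to tissue water without lipophilicity or charge", {
  neutral <- drug_params(logP = -30, pKa = c(-20, -30), Fup = 1, B2P = 0.55)
  kp <- kp_perfusion_limited(neutral)
  comp <- utils::read.csv(system.file("extdata", "tissue_composition.csv",
                                      package = "dpipk"), comment.char = "#")
  # closed-form limit: tissue water plus the residual neutral-phospholipid
  # water partition (0.7 f_NP as P -> 0)
  expect_equal(as.numeric(kp[comp$tissue]),
               comp$f_ew + comp$f_iw + 0.7 * comp$f_np, tolerance = 1e-6)
  # Kp increases with logP at fixed ionization
  k1 <- kp_perfusion_limited(drug_params(logP = 1))
  k2 <- kp_perfusion_limited(drug_params(logP = 2))
  expect_true(all(k2 >= k1))
})

test_that("simulated profiles conserve mass and scale linearly with dose", {
  dep <- list(ET = 0.792, TB = 0.0102, AL = 0.1158)
  p1 <- simulate_pbpk(build_model(dep, 600))
  expect_lt(max(abs(mass_balance(p1))), 1e-6)
  expect_true(all(diff(p1$urine_ug) >= 0))
  expect_true(all(p1$Cp_ug_ml >= 0))

  p2 <- simulate_pbpk(build_model(dep, 1200))
  d1 <- pk_descriptors(p1); d2 <- pk_descriptors(p2)
  expect_equal(d2$Cmax_ug_ml / d1$Cmax_ug_ml, 2, tolerance = 1e-6)
  expect_equal(d2$AUC_0_12_ug_h_ml / d1$AUC_0_12_ug_h_ml, 2, tolerance = 1e-6)
  expect_equal(d2$ConcU_30min_ug / d1$ConcU_30min_ug, 2, tolerance = 1e-6)

  # zero dose: identically zero plasma concentration
  p0 <- simulate_pbpk(build_model(dep, 0), times = c(0, 1, 6, 12))
  expect_true(all(p0$Cp_ug_ml == 0))
})

test_that("urinary output is bounded by the renal share of elimination", {
  dep <- list(ET = 0.792, TB = 0.0102, AL = 0.1158)
  share <- 4.2 / (4.2 + 5.44)
  p <- simulate_pbpk(build_model(dep, 600))
  expect_lte(max(p$urine_ug), share * 600)
  # at exhaustion the renal share is exact
  pl <- simulate_pbpk(build_model(dep, 600), duration = 600,
                      times = c(0, 300, 600))
  fin <- pl[nrow(pl), ]
  expect_equal(fin$urine / (fin$urine + fin$metabolized), share,
               tolerance = 1e-4)
})

test_that("solution is converged with respect to solver tolerances", {
  model <- build_model(list(ET = 0.792, TB = 0.0102, AL = 0.1158), 600)
  a <- pk_descriptors(simulate_pbpk(model))
  b <- pk_descriptors(simulate_pbpk(model, rtol = 5e-9, atol = 5e-13))
  expect_equal(a$Cmax_ug_ml, b$Cmax_ug_ml, tolerance = 1e-6)
})

test_that("complete first pass makes exposure depend only on the ET remainder", {
  dep <- list(ET = 0.792, TB = 0.0102, AL = 0.1158)
  lp1 <- lung_disposition_params(swallowed_frac_ET = 0.65,
                                 expectorated_frac_ET = 0.30)
  lp2 <- lung_disposition_params(swallowed_frac_ET = 0.30,
                                 expectorated_frac_ET = 0.65)
  d1 <- pk_descriptors(simulate_pbpk(build_model(dep, 600, lungp = lp1)))
  d2 <- pk_descriptors(simulate_pbpk(build_model(dep, 600, lungp = lp2)))
  # identical up to solver step-size noise (the sink states differ)
  expect_equal(d1$Cmax_ug_ml, d2$Cmax_ug_ml, tolerance = 1e-8)
  expect_equal(d1$AUC_0_12_ug_h_ml, d2$AUC_0_12_ug_h_ml, tolerance = 1e-8)
})

test_that("descriptors read off simple synthetic profiles", {
  fake <- function(t, cp, urine = 0 * t) {
    df <- data.frame(time_h = t, Cp_ug_ml = cp, urine_ug = urine)
    attr(df, "model") <- list(sysp = list(plasma_volume = 3.78))
    df
  }
  t <- seq(0, 12, by = 0.01)
  tri <- pmax(0, 1 - abs(t - 2))          # triangular peak of height 1 at 2 h
  d <- pk_descriptors(fake(t, tri))
  expect_equal(d$Cmax_ug_ml, 1, tolerance = 1e-9)
  expect_equal(d$tmax_h, 2, tolerance = 0.011)
  d2 <- pk_descriptors(fake(t, rep(3, length(t))))
  expect_equal(d2$AUC_0_12_ug_h_ml, 36, tolerance = 1e-9)
})

test_that("the bundled configuration reproduces the constructor defaults", {
  cfg <- read_pbpk_config()
  expect_equal(cfg$dose_ug, 600)
  expect_equal(cfg$drug$pKa, c(10.61, 9.35))
  expect_equal(cfg$lung$sa_AL, lung_disposition_params()$sa_AL)
  expect_equal(cfg$systemic$CL_renal, 4.2)
})
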