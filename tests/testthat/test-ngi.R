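# Impactor reduction: cut-off scaling, emitted dose, cumulative undersize,
# probit/log-normal fit and the fine-particle quantities.

make_table <- function(masses, flow = 60, id = "t") {
  m <- stats::setNames(numeric(11), ngi_locations)
  m[names(masses)] <- masses
  stage_mass_table(id, "capsule", flow, m)
}

test_that("stage cut-offs scale with flow by the archival power law", {
  ref <- ngi_cutoffs(60)
  expect_equal(as.numeric(ref$d50),
               c(8.06, 4.46, 2.82, 1.66, 0.94, 0.55, 0.34), tolerance = 1e-12)

  lo <- ngi_cutoffs(30)
  hi <- suppressWarnings(ngi_cutoffs(120))
  expect_true(all(lo$d50 > hi$d50))

  # hand evaluation of d50_ref * (60/100)^x per stage
  d100 <- ngi_cutoffs(100)
  by_hand <- c(8.06, 4.46, 2.82, 1.66, 0.94, 0.55, 0.34) *
    0.6^c(0.54, 0.52, 0.50, 0.47, 0.53, 0.60, 0.67)
  expect_equal(as.numeric(d100$d50), by_hand, tolerance = 1e-12)

  expect_error(ngi_cutoffs(0), "positive")
  expect_warning(ngi_cutoffs(10), "calibration window")
})

test_that("emitted dose is the recovered mass leaving the device", {
  expect_equal(emitted_dose(make_table(c())), 0)
  expect_equal(emitted_dose(make_table(c(induction_port = 1, pre_separator = 1,
                                         stage3 = 0.5))), 2.5)
  # generator round-trip at zero noise
  run <- gen_ngi_run(2.6, 1.9, ed_mg = 3.10, residue_mg = 0.6, cv = 0)[[1]]
  expect_equal(emitted_dose(run), 3.10, tolerance = 1e-12)
  # bookkeeping: residue + ED = total recovered mass, exactly
  expect_identical(run$masses[["device_residue"]] + emitted_dose(run),
                   sum(run$masses))
})

test_that("cumulative undersize counts sized mass below each cut-off", {
  moc_only <- cumulative_undersize(make_table(c(moc = 2)))
  expect_equal(moc_only$fraction, rep(1, 7))

  equal <- make_table(stats::setNames(rep(1, 8), c(paste0("stage", 1:7), "moc")))
  cum <- cumulative_undersize(equal)
  expect_equal(cum$fraction[7], 7 / 8)   # below stage 1 cut-off
  expect_equal(cum$fraction[1], 1 / 8)   # below stage 7 cut-off
  expect_true(all(diff(cum$fraction) >= 0))
  expect_true(all(diff(cum$diameter_um) > 0))

  # synthetic log-normal run: fractions equal the log-normal CDF at each
  # cut-off; invariant under uniform rescaling of all masses
  run <- gen_ngi_run(3.1, 2.2, ed_mg = 2, cv = 0)[[1]]
  cum <- cumulative_undersize(run)
  expect_equal(cum$fraction,
               pnorm(log(cum$diameter_um), log(3.1), log(2.2)),
               tolerance = 1e-12)
  scaled <- run
  scaled$masses <- run$masses * 7.3
  expect_equal(cumulative_undersize(scaled)$fraction, cum$fraction,
               tolerance = 1e-12)

  expect_error(cumulative_undersize(make_table(c(induction_port = 1))),
               "zero sized mass")
})

test_that("probit fit recovers log-normal parameters", {
  pts <- function(mmad, gsd, d = c(0.4, 0.8, 1.5, 3, 6, 10))
    data.frame(diameter_um = d, fraction = pnorm(log(d), log(mmad), log(gsd)))
  fit <- fit_lognormal(pts(3.0, 2.0))
  expect_equal(fit$mmad, 3.0, tolerance = 1e-9)
  expect_equal(fit$gsd, 2.0, tolerance = 1e-9)
  expect_equal(fit$fit_r2, 1, tolerance = 1e-9)

  # near-monodisperse limit
  fit1 <- fit_lognormal(pts(2, 1.001, d = c(1.995, 1.999, 2.001, 2.005)))
  expect_equal(fit1$gsd, 1.001, tolerance = 1e-6)

  expect_error(fit_lognormal(data.frame(diameter_um = c(1, 2),
                                        fraction = c(0.3, 0.7))),
               "insufficient")
  expect_error(fit_lognormal(data.frame(diameter_um = c(1, 2, 3),
                                        fraction = c(0.7, 0.5, 0.3))),
               "slope")
})

test_that("fit recovers generator parameters across the parameter box", {
  # noise-free synthetic runs over (MMAD, GSD) in [0.5, 10] x [1.1, 4]
  set.seed(11)
  for (i in 1:25) {
    mmad <- exp(runif(1, log(0.5), log(10)))
    gsd <- runif(1, 1.1, 4)
    run <- gen_ngi_run(mmad, gsd, ed_mg = 3, cv = 0)[[1]]
    cum <- cumulative_undersize(run)
    usable <- sum(cum$fraction > 1e-7 & cum$fraction < 1 - 1e-7)
    if (usable >= 3) {
      fit <- fit_lognormal(cum)
      expect_equal(fit$mmad, mmad, tolerance = 1e-9)
      expect_equal(fit$gsd, gsd, tolerance = 1e-9)
    } else {
      expect_error(fit_lognormal(cum), "insufficient")
    }
  }
})

test_that("fitted MMAD is unbiased under replicate stage noise", {
  runs <- gen_ngi_run(2.6, 1.9, ed_mg = 3.1, cv = 0.02, n_rep = 50, seed = 42)
  mmads <- vapply(runs, function(r) fit_lognormal(cumulative_undersize(r))$mmad,
                  numeric(1))
  expect_lt(abs(mean(mmads) - 2.6) / 2.6, 0.02)
})

test_that("fine particle mass equals the closed-form band probability", {
  # symmetric band: ln-sd chosen so 1 and 5 um sit at -/+1.645 sigma around
  # the median sqrt(5) = 2.236
  gsd <- exp(log(5) / (2 * 1.645))
  run <- gen_ngi_run(sqrt(5), gsd, ed_mg = 2, sized_frac = 1, cv = 0)[[1]]
  fpm <- fine_particle_mass(run)
  expect_equal(fpm / 2, pnorm(1.645) - pnorm(-1.645), tolerance = 1e-6)

  # closed form on an asymmetric case
  run2 <- gen_ngi_run(2.8, 1.7, ed_mg = 3, sized_frac = 0.4, cv = 0)[[1]]
  sized <- sum(run2$masses[paste0("stage", 1:7)]) + run2$masses[["moc"]]
  band <- pnorm(log(5), log(2.8), log(1.7)) - pnorm(log(1), log(2.8), log(1.7))
  expect_equal(fine_particle_mass(run2), sized * band, tolerance = 1e-6)
  expect_lte(fine_particle_mass(run2), sized)
  expect_lte(sized, emitted_dose(run2))

  # distribution far above the band: negligible fine mass
  coarse <- gen_ngi_run(20, 1.5, ed_mg = 2, sized_frac = 1, cv = 0,
                        flow = 60)[[1]]
  expect_lt(fine_particle_mass(coarse), 1e-3 * 2)
  # and a fully coarse aerosol leaves the fit undefined
  all_coarse <- gen_ngi_run(40, 1.2, ed_mg = 2, sized_frac = 1, cv = 0)[[1]]
  expect_error(fit_lognormal(cumulative_undersize(all_coarse)), "insufficient")
})

test_that("fine particle fraction is FPM over ED in percent", {
  expect_equal(fine_particle_fraction(0, 3), 0)
  expect_error(fine_particle_fraction(1, 0), "emitted dose")
  # observed mean FPM/ED pairs reproduce the reported FPF within 0.5%
  expect_lt(abs(fine_particle_fraction(0.74, 3.10) - 23.85) / 23.85, 0.005)
  expect_lt(abs(fine_particle_fraction(0.62, 2.95) - 21.04) / 21.04, 0.005)
})

test_that("replicate averaging is local to each formulation", {
  a <- gen_ngi_run(2.6, 1.9, 3.1, cv = 0.05, n_rep = 3, seed = 7, label = "A")
  b <- gen_ngi_run(3.4, 2.1, 2.8, cv = 0.05, n_rep = 3, seed = 7, label = "B")
  full <- reduce_ngi_runs(c(a, b), c("A", "A", "A", "B", "B", "B"))
  dropped <- reduce_ngi_runs(c(a[-2], b), c("A", "A", "B", "B", "B"))
  expect_equal(dropped[dropped$group == "B", ],
               full[full$group == "B", ], ignore_attr = TRUE)
  expect_false(isTRUE(all.equal(dropped[dropped$group == "A", "ED_mg"],
                                full[full$group == "A", "ED_mg"])))
})

test_that("run tables round-trip through the CSV dialect", {
  runs <- gen_ngi_run(2.6, 1.9, 3.1, cv = 0.05, n_rep = 2, seed = 3)
  path <- tempfile(fileext = ".csv")
  write_ngi_runs(runs, path)
  back <- read_ngi_runs(path)
  expect_equal(back[[1]]$masses, runs[[1]]$masses, tolerance = 1e-12)
  expect_equal(back[[2]]$flow, runs[[2]]$flow)
})
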