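test_that("one-site fit recovers noiseless parameters exactly", {
  conc <- 10^seq(0, 4, length.out = 12)
  resp <- 0.9 * conc / (100 + conc) + 0.05
  fit <- fit_one_site(conc, resp)
  expect_true(fit$converged)
  expect_equal(unname(fit$parameters[["kd"]]), 100, tolerance = 1e-6)
  expect_equal(unname(fit$parameters[["bmax"]]), 0.9, tolerance = 1e-6)
  expect_equal(unname(fit$parameters[["baseline"]]), 0.05,
               tolerance = 1e-6)

  flat <- fit_one_site(conc, rep(0.5, 12))
  expect_true(!flat$converged || "no_dynamic_range" %in% flat$flags)

  expect_error(fit_one_site(conc[1:3], resp[1:3]), "at least 5")
  expect_error(fit_one_site(c(1, 2, 3, 4, 5), rep(0.1, 5)),
               "orders of magnitude")
})

test_that("one-site fit matches a profile grid-search oracle", {
  set.seed(3)
  for (i in 1:5) {
    iso <- sim_isotherm(kd = 10^runif(1, 1, 4), noise_cv = 0.05,
                        seed = 100 + i)
    fit <- fit_one_site(iso$concentration, iso$response)
    kd_grid <- grid_one_site(iso$concentration, iso$response)
    expect_equal(unname(fit$parameters[["kd"]]), kd_grid,
                 tolerance = 0.01)
  }
})

test_that("constrained 4PL recovers IC50 and flags degenerate data", {
  conc <- 10^seq(1, 5, length.out = 10)
  resp <- 0 + (100 - 0) / (1 + (conc / 1000)^1)
  fit <- fit_competitive_4pl(conc, resp, top_fixed = 100,
                             bottom_fixed = 0)
  expect_true(fit$converged)
  expect_equal(unname(fit$parameters[["ic50"]]), 1000, tolerance = 1e-6)
  expect_equal(unname(fit$parameters[["h"]]), 1, tolerance = 1e-6)

  stuck <- fit_competitive_4pl(conc, rep(100, 10), top_fixed = 100,
                               bottom_fixed = 0)
  expect_false(stuck$converged)
  expect_true("ic50_unidentifiable" %in% stuck$flags)
})

test_that("4PL fit agrees with an independent grid-search minimizer", {
  set.seed(4)
  for (i in 1:3) {
    conc <- 10^seq(1, 5, length.out = 12)
    ic50 <- 10^runif(1, 2.5, 3.5)
    resp <- (100 / (1 + (conc / ic50)^1.2)) * (1 + rnorm(12, 0, 0.02))
    fit <- fit_competitive_4pl(conc, resp, 100, 0)
    oracle <- grid_ic50(conc, resp, 100, 0)
    expect_equal(unname(fit$parameters[["ic50"]]), oracle,
                 tolerance = 0.01)
  }
})

test_that("melt normalization anchors 25C at 100% and 74C at 0%", {
  temps <- c(25, 50, 52.1, 55.4, 59.4, 64.9, 69.2, 72.1, 74)
  sig <- 100 / (1 + exp((temps - 62) / 2))
  norm <- normalize_melt_curve(temps, sig)
  expect_equal(norm$percent[1], 100)
  expect_equal(norm$percent[length(temps)], 0)
  expect_error(normalize_melt_curve(temps[-1], sig[-1]),
               "anchor temperature")
})

test_that("Boltzmann melt fit recovers Tm and delta-Tm", {
  mc <- sim_melt_curves(tm_control = 62, delta_tm = 4.5, noise_cv = 0,
                        seed = 1)
  fc <- fit_melt(mc$control$temperature, mc$control$signal)
  ft <- fit_melt(mc$treated$temperature, mc$treated$signal)
  expect_equal(unname(fc$parameters[["tm"]]), 62, tolerance = 1e-6)
  expect_equal(unname(ft$parameters[["tm"]]), 57.5, tolerance = 1e-6)
  expect_equal(delta_tm(fc, ft), 4.5, tolerance = 1e-5)
  expect_equal(delta_tm(fc, fc), 0)
})

test_that("Bliss scores are observed minus independence expectation", {
  eff <- matrix(c(0, 0.4, 0.5, 0.7), 2, 2)
  dm <- dose_matrix(c(0, 10), c(0, 20), eff)
  syn <- bliss_synergy(dm)
  expect_equal(syn$expected[2, 2], 0.5 + 0.4 - 0.5 * 0.4)
  expect_equal(syn$score[2, 2], 0)
  expect_equal(syn$score[1, 1], 0)
  expect_equal(syn$score[2, 1], 0)
  expect_equal(syn$score[1, 2], 0)

  eff2 <- eff; eff2[2, 2] <- 0.8
  syn2 <- bliss_synergy(dose_matrix(c(0, 10), c(0, 20), eff2))
  expect_equal(syn2$score[2, 2], 0.1)
  expect_equal(syn2$summary_score, 0.1)

  expect_error(dose_matrix(c(0, 10), c(0, 20),
                           matrix(c(0, 0.4, 0.5, 1.2), 2, 2)), "\\[0, 1\\]")
  expect_error(dose_matrix(c(10, 20), c(0, 20), eff), "include 0")
})

test_that("SEC window quantification follows the printed formulas", {
  base <- setNames(rep(0, 11), c("B1", "B2", paste0("C", 1:9)))
  p <- base; p["C4"] <- 10
  q <- sec_quantify(p)
  expect_equal(unname(q["dimer"]), 100)
  expect_equal(unname(q["monomer"]), 0)

  p <- base; p["C6"] <- 8
  q <- sec_quantify(p)
  expect_equal(unname(q["dimer"]), 50)
  expect_equal(unname(q["monomer"]), 50)

  p <- base; p["C3"] <- 1; p["C6"] <- 2; p["C7"] <- 1
  q <- sec_quantify(p)
  expect_equal(unname(q["dimer"]), 50)
  expect_equal(unname(q["monomer"]), 50)

  # all mass inside the three windows -> percentages sum to exactly 100
  p <- base; p[c("C3", "C5", "C6", "C8", "B1")] <- c(3, 2, 4, 1, 2)
  q <- sec_quantify(p)
  expect_equal(sum(q), 100)
  # mass outside every window caps the sum below 100
  p2 <- p; p2 <- c(p2, D1 = 5)
  expect_lt(sum(sec_quantify(p2)), 100)

  expect_error(sec_quantify(base), "zero total")
  expect_error(sec_quantify(p[names(p) != "C7"]), "missing fractions")
})

test_that("SEC molecular-weight calibration is log-linear in volume", {
  cal <- sec_mw_calibrate(c(14.0, 16.0), c(44, 29))  # ovalbumin, CA
  expect_equal(predict_mw(cal, 14.0)$mw_kda, 44, tolerance = 1e-9)
  expect_equal(predict_mw(cal, 16.0)$mw_kda, 29, tolerance = 1e-9)
  expect_equal(predict_mw(cal, 15.0)$mw_kda, sqrt(44 * 29),
               tolerance = 1e-9)
  out <- predict_mw(cal, c(13.0, 15.0, 17.0))
  expect_equal(out$extrapolated, c(TRUE, FALSE, TRUE))
  expect_error(sec_mw_calibrate(c(14, 14), c(44, 29)), "duplicate")
})

test_that("depolarization normalization maps the controls to 0% and 100%", {
  dep <- sim_depolarization(true_percent = c(0, 50, 100), noise_cv = 0,
                            seed = 1)
  pct <- depolarization_percent(dep$time, dep$sample, dep$dmso, dep$cccp)
  expect_equal(as.numeric(pct), c(0, 50, 100), tolerance = 1e-9)
  # the DMSO and CCCP traces themselves anchor the scale exactly
  both <- rbind(dep$dmso, dep$cccp)
  expect_equal(as.numeric(depolarization_percent(dep$time, both,
                                                 dep$dmso, dep$cccp)),
               c(0, 100))
  # affine invariance: common gain and offset cancel
  g <- 3.7; o <- 250
  pct2 <- depolarization_percent(dep$time, g * dep$sample + o,
                                 g * dep$dmso + o, g * dep$cccp + o)
  expect_equal(pct2, pct, tolerance = 1e-9)
  expect_error(depolarization_percent(dep$time, dep$sample, dep$dmso,
                                      dep$dmso), "no dynamic range")
  # values outside [0,100] are flagged, not clipped
  hot <- 2 * dep$cccp - dep$dmso
  p3 <- depolarization_percent(dep$time, hot, dep$dmso, dep$cccp)
  expect_gt(as.numeric(p3), 100)
  expect_true(attr(p3, "out_of_range"))
})
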