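# Creatinine-clearance bridge and Monte Carlo exposure.

test_that("regression recovers exact linear input and rejects degenerate data", {
  cr <- c(0.3, 0.6, 1.0, 1.8, 2.4)
  cl <- 2.6235 - 0.9019 * cr
  reg <- fit_cr_cl_regression(data.frame(cl_posthoc = cl, CR = cr))
  expect_equal(reg$intercept, 2.6235, tolerance = 1e-12)
  expect_equal(reg$slope, -0.9019, tolerance = 1e-12)
  expect_equal(reg$r2, 1)
  # two points define the interpolating line
  reg2 <- fit_cr_cl_regression(data.frame(cl_posthoc = c(2, 1), CR = c(0.5, 1.5)))
  expect_equal(reg2$slope, -1)
  expect_equal(reg2$intercept, 2.5)
  expect_error(fit_cr_cl_regression(data.frame(cl_posthoc = c(1, 2, 3),
                                               CR = c(1, 1, 1))),
               "constant")
})

test_that("anchor line reproduces the reported exposure extremes", {
  reg <- anchor_regression()
  expect_equal(predict(reg, 0.3), 8 / 3.4, tolerance = 1e-12)
  expect_equal(predict(reg, 2.5), 8 / 21.7, tolerance = 1e-12)
  expect_equal(reg$intercept, 2.6235, tolerance = 1e-4)
  expect_equal(reg$slope, -0.9019, tolerance = 1e-4)
  # severe-group mean creatinine lands near the observed total clearance
  expect_equal(predict(reg, 0.95), 1.7667, tolerance = 1e-4)
  # extrapolation is refused
  expect_error(predict(reg, 3.0), "range")
  expect_error(predict(reg, 0.1), "range")
})

test_that("Monte Carlo exposure matches its analytic limits", {
  reg <- anchor_regression()
  pop <- pop_model_oxaliplatin()
  # omega = 0: AUC is deterministic dose/CL_typ(Cr)
  pop0 <- pop_model(pop$theta, c(v1 = 0, cl = 0, cl2 = 0), sigma = 0.149)
  mc0 <- monte_carlo_exposure(pop0, reg, cr_levels = c(0.5, 1.5), n = 50,
                              seed = 1)
  expect_equal(mc0$auc$median, 8 / predict(reg, c(0.5, 1.5)), tolerance = 1e-10)
  expect_equal(mc0$auc$p5, mc0$auc$p95)
  # residual error does not enter the analytic AUC
  pop_a <- pop_model(pop$theta, pop$omega2, sigma = 0.05)
  pop_b <- pop_model(pop$theta, pop$omega2, sigma = 0.30)
  mc_a <- monte_carlo_exposure(pop_a, reg, 1.0, n = 500, seed = 7)
  mc_b <- monte_carlo_exposure(pop_b, reg, 1.0, n = 500, seed = 7)
  expect_equal(mc_a$auc, mc_b$auc)
  # lognormal quantile structure: log(p95/median) ~ 1.645 * omega_CL
  mc <- monte_carlo_exposure(pop, reg, 1.0, n = 4000, seed = 3)
  expect_equal(log(mc$auc$p95 / mc$auc$median), 1.645 * 0.305,
               tolerance = 0.08)
  expect_equal(log(mc$auc$median / mc$auc$p5), 1.645 * 0.305,
               tolerance = 0.08)
  # medians increase with creatinine; percentile order is respected
  mc3 <- monte_carlo_exposure(pop, reg, c(0.3, 1.0, 2.0), n = 500, seed = 5)
  expect_true(all(diff(mc3$auc$median) > 0))
  expect_true(all(mc3$auc$p5 <= mc3$auc$median & mc3$auc$median <= mc3$auc$p95))
  # concentration percentile table covers every level and time
  expect_equal(nrow(mc3$conc), 3 * length(unique(mc3$conc$time)))
})

test_that("marker correlations have the built-in sign pattern", {
  # perfectly linear relation gives |r| = 1
  fake <- data.frame(ID = 1:5, BUN = c(10, 20, 30, 40, 50),
                     CR = c(0.2, 0.4, 0.6, 0.8, 1.0),
                     CCR = c(5, 4, 3, 2, 1),
                     cl_tot = c(2.5, 2.0, 1.5, 1.0, 0.5), ok = TRUE)
  ct <- correlate_markers(fake)
  expect_equal(ct$r[ct$marker == "CR"], -1)
  expect_equal(ct$r[ct$marker == "CCR"], 1)
  # constant marker errors out
  fake2 <- transform(fake, BUN = 20)
  expect_error(correlate_markers(fake2), "constant")
  # generated study with an active renal effect: creatinine anti-correlates
  # with clearance, creatinine clearance correlates positively
  design <- study_design(n_per_arm = 25)
  study <- generate_study(design, seed = 31,
                          renal_effect = renal_effect_model())
  ct2 <- correlate_markers(nca(study), urine_summary(study))
  r_of <- function(m, o) ct2$r[ct2$marker == m & ct2$outcome == o]
  expect_lt(r_of("CR", "cl_tot"), 0)
  expect_gt(r_of("CCR", "cl_tot"), 0)
  expect_lt(r_of("CR", "ae_total"), 0)
  expect_gt(r_of("CCR", "ae_total"), 0)
})

test_that("regression on an anchor-generated study recovers the line", {
  design <- study_design(n_per_arm = 15)
  study <- generate_study(design, seed = 41,
                          renal_effect = renal_effect_model())
  fit <- fit_foce(study, se = "none")
  reg <- fit_cr_cl_regression(posthoc_table(fit))
  expect_lt(reg$slope, -0.2)
  expect_gt(reg$slope, -2.0)
  expect_gt(reg$intercept, 1.8)
  expect_lt(reg$intercept, 3.5)
})
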