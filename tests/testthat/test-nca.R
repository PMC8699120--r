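# Non-compartmental analysis.

test_that("terminal slope and summaries are exact on a monoexponential", {
  tt <- seq(0.1, 6, by = 0.1)
  conc <- 10 * exp(-0.693 * tt)
  ts <- terminal_slope(tt, conc, n_terminal = 3)
  expect_equal(ts$ke, 0.693, tolerance = 1e-8)
  res <- nca_analyze(data.frame(time = tt, conc = conc), dose = 10 * 0.5)
  # dose chosen so V1 = dose / C0 = 0.5: CLtot = ke * V1, Vd = V1
  expect_equal(res$t_half, log(2) / 0.693, tolerance = 1e-6)
  expect_equal(res$cl_tot, 0.693 * 0.5, tolerance = 0.01)
  expect_equal(res$vd, 0.5, tolerance = 0.01)
  # rising profile has no terminal decline
  flat <- terminal_slope(c(1, 2, 3), c(1, 2, 3))
  expect_false(flat$ok)
  expect_true(is.na(flat$ke))
})

test_that("trapezoid handles elementary segments exactly", {
  # two points (0 h, 10) and (1 h, 6): segment area 8
  a <- auc_0_inf(c(0, 1), c(10, 6), ke = 1)
  expect_equal(a$auc_last, 8)
  # constant concentration over [0, T]
  a2 <- auc_0_inf(c(0, 2, 4), c(3, 3, 3), ke = 1)
  expect_equal(a2$auc_last, 12)
  expect_equal(a2$auc_inf, 12 + 3)
})

test_that("dense noise-free profiles converge to the closed-form values", {
  p <- reference_params()
  prof <- dense_profile(p, 8, t_end = 24, n = 2000)
  m <- macro_constants(p, 8)
  ts <- terminal_slope(prof$time, prof$conc, n_terminal = 5)
  expect_equal(ts$ke, m$beta, tolerance = 0.01)
  res <- nca_analyze(prof, dose = 8, n_terminal = 5)
  expect_equal(res$auc_inf, 8 / 1.76, tolerance = 0.01)
  expect_equal(res$cl_tot, 1.76, tolerance = 0.01)
  expect_equal(res$vd, res$cl_tot / res$ke, tolerance = 1e-9)
  expect_false(res$flag_extrap)
})

test_that("the short 2-hour schedule biases clearance high at 8 mg/kg", {
  p <- reference_params()
  tt <- c(c(3, 5, 10, 20, 30, 45) / 60, 1, 1.5, 2)
  res <- nca_analyze(data.frame(time = tt, conc = predict_conc(p, 8, tt)),
                     dose = 8)
  expect_gt(res$cl_tot, 1.76) # truncation: AUC undercounted, CL inflated
})

test_that("results are invariant to row order and redundant points", {
  p <- reference_params()
  tt <- c(c(3, 5, 10, 20, 30, 45) / 60, 1, 1.5, 2)
  prof <- data.frame(time = tt, conc = predict_conc(p, 8, tt))
  set.seed(8)
  shuf <- prof[sample(nrow(prof)), ]
  expect_equal(nca_analyze(shuf, 8), nca_analyze(prof, 8))
  # inserting linearly interpolated points leaves the trapezoid AUC unchanged
  # (profiles anchored at t = 0 so no back-extrapolation is involved)
  prof0 <- rbind(data.frame(time = 0, conc = predict_conc(p, 8, 0)), prof)
  mid_t <- (prof0$time[-1] + prof0$time[-nrow(prof0)]) / 2
  mid_c <- (prof0$conc[-1] + prof0$conc[-nrow(prof0)]) / 2
  aug <- rbind(prof0, data.frame(time = mid_t, conc = mid_c))
  aug <- aug[order(aug$time), ]
  a1 <- auc_0_inf(prof0$time, prof0$conc, ke = 1)
  a2 <- auc_0_inf(aug$time, aug$conc, ke = 1)
  expect_equal(a2$auc_last, a1$auc_last, tolerance = 1e-10)
})

test_that("median terminal slope stays near beta under proportional noise", {
  p <- reference_params()
  m <- macro_constants(p, 8)
  tt <- seq(1, 6, by = 0.5) # beta-dominated window
  f <- predict_conc(p, 8, tt)
  set.seed(12)
  kes <- replicate(500, {
    y <- f * (1 + rnorm(length(f), 0, 0.149))
    y[y <= 0] <- f[y <= 0]
    terminal_slope(tt, y, n_terminal = 5)$ke
  })
  expect_equal(median(kes, na.rm = TRUE), m$beta, tolerance = 0.05)
})

test_that("study-level NCA returns one row per subject with flags", {
  study <- generate_study(seed = 6)
  res <- nca(study)
  expect_equal(nrow(res), 30)
  expect_true(all(c("ke", "t_half", "auc_inf", "cl_tot", "vd",
                    "flag_extrap", "ok") %in% names(res)))
  expect_true(all(res$auc_inf >= res$auc_last, na.rm = TRUE))
  expect_true(all(res$t_half[res$ok] > 0))
  # automatic terminal-window selection also runs
  res_auto <- nca(study, n_terminal = "auto")
  expect_equal(nrow(res_auto), 30)
})
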