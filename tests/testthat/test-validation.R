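# Bootstrap and prediction-corrected VPC.

small_fit <- function(seed = 2, n_per_arm = 2) {
  design <- study_design(n_per_arm = n_per_arm, doses = 8)
  study <- generate_study(design, seed = seed)
  fit_foce(study, se = "none")
}

test_that("bootstrap resampling is reproducible and stratified", {
  fit <- small_fit()
  b1 <- pk_bootstrap(fit, n = 3, seed = 42)
  b2 <- pk_bootstrap(fit, n = 3, seed = 42)
  expect_identical(b1$indices, b2$indices)
  expect_equal(b1$summary$median, b2$summary$median)
  # stratification: each replicate keeps the per-arm sample sizes
  subjects <- unique(fit$data[, c("ID", "RENGRP")])
  for (ids in b1$indices) {
    tab <- table(subjects$RENGRP[match(ids, subjects$ID)])
    expect_true(all(tab == 2))
  }
})

test_that("a cohort of identical subjects gives zero-width intervals", {
  base <- generate_study(study_design(n_per_arm = 1, doses = 8,
                                      renal_groups = "normal"), seed = 5)
  clones <- do.call(rbind, lapply(1:6, function(i) {
    d <- base
    d$ID <- i
    d
  }))
  fit <- fit_foce(clones, se = "none")
  b <- pk_bootstrap(fit, n = 4, seed = 1)
  expect_equal(b$n_converged, 4)
  width <- b$summary$p97.5 - b$summary$p2.5
  expect_true(all(width[!is.na(width)] < 1e-6))
})

test_that("pcVPC percentiles and envelopes are internally ordered", {
  fit <- small_fit(seed = 7, n_per_arm = 3)
  v <- pk_pcvpc(fit, n_sim = 60, seed = 3)
  b <- v$bins
  expect_true(all(b$obs_p5 <= b$obs_p50 & b$obs_p50 <= b$obs_p95))
  expect_true(all(b$lo_p5 <= b$hi_p5 & b$lo_p50 <= b$hi_p50 &
                    b$lo_p95 <= b$hi_p95))
  expect_true(all(b$n_obs >= 2))
  # reproducibility
  v2 <- pk_pcvpc(fit, n_sim = 60, seed = 3)
  expect_equal(v$bins, v2$bins)
  # degenerate n_sim = 1: the envelope collapses onto one simulated value
  v1 <- pk_pcvpc(fit, n_sim = 1, seed = 3)
  expect_equal(v1$bins$lo_p50, v1$bins$hi_p50)
})

test_that("with homogeneous covariates the correction cancels", {
  # single dose, single group: PRED is identical within each bin, so the
  # prediction-corrected observed percentiles equal the raw ones
  design <- study_design(n_per_arm = 6, doses = 8, renal_groups = "normal")
  study <- generate_study(design, seed = 9)
  fit <- fit_foce(study, se = "none")
  v <- pk_pcvpc(fit, n_sim = 5, seed = 1)
  obs <- subset(fit$data, EVID == 0 & CMT == "plasma")
  raw_med <- tapply(obs$DV, obs$TIME, median)
  expect_equal(v$bins$obs_p50, as.numeric(raw_med), tolerance = 1e-10)
})

test_that("pcVPC flags a deliberately misspecified model", {
  design <- study_design(n_per_arm = 5, doses = 8, renal_groups = "normal")
  study <- generate_study(design, seed = 23)
  fit <- fit_foce(study, se = "none")
  # halve the clearance and recompute the population predictions coherently
  th <- fit$pop$theta
  bad_pop <- pop_model(pk_params(th$v1, th$v2, th$cl / 2, th$cl2),
                       fit$pop$omega2, fit$pop$sigma)
  bad_fit <- fit
  bad_fit$pop <- bad_pop
  obs <- subset(fit$data, EVID == 0 & CMT == "plasma" & MDV == 0)
  obs <- obs[order(obs$ID, obs$TIME), ]
  bad_fit$gof$PRED <- unlist(lapply(split(obs, obs$ID), function(d) {
    predict_conc(bad_pop$theta, d$DOSEGRP[1], d$TIME)
  }), use.names = FALSE)
  v <- pk_pcvpc(bad_fit, n_sim = 200, seed = 4)
  outside <- with(v$bins, obs_p50 < lo_p50 | obs_p50 > hi_p50)
  expect_gt(sum(outside), nrow(v$bins) / 2)
})
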