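# Synthetic study generator: design counts, stochastic components, markers,
# urine model, determinism.

test_that("default study reproduces the design arithmetic", {
  study <- generate_study(seed = 11)
  plasma_obs <- subset(study, EVID == 0 & CMT == "plasma")
  expect_equal(length(unique(study$ID)), 30) # 3 groups x 2 doses x 5
  expect_equal(nrow(plasma_obs), 270)        # 30 subjects x 9 samples
  expect_equal(sum(study$EVID == 1), 30)     # one dose row each, at time 0
  expect_true(all(study$TIME[study$EVID == 1] == 0))
  # urine only in the 8 mg/kg arms
  urine <- subset(study, CMT == "urine")
  expect_true(all(urine$DOSEGRP == 8))
  expect_equal(length(unique(urine$ID)), 15)
  # truth attribute carries the simulated individual parameters
  truth <- attr(study, "truth")
  expect_equal(nrow(truth), 30)
  expect_true(all(truth$cl > 0))
})

test_that("same seed regenerates the identical dataset", {
  a <- generate_study(seed = 3)
  b <- generate_study(seed = 3)
  expect_identical(as.data.frame(a), as.data.frame(b))
  c <- generate_study(seed = 4)
  expect_false(identical(a$DV, c$DV))
})

test_that("individual parameters follow the lognormal exponential-error model", {
  pop <- pop_model_oxaliplatin()
  # omega = 0 returns the typical values exactly
  pop0 <- pop_model(pop$theta, c(v1 = 0, cl = 0, cl2 = 0), sigma = 0.149)
  set.seed(1)
  d <- draw_individual_params(pop0)
  expect_equal(d$params$cl, 1.76)
  expect_equal(d$params$v1, 0.44)
  expect_equal(unname(d$eta), c(0, 0, 0))
  # large-sample spread of log CL recovers omega_CL = 0.305
  set.seed(2)
  draws <- vapply(seq_len(2e4), function(i) draw_individual_params(pop)$params$cl,
                  numeric(1))
  expect_equal(sd(log(draws)), 0.305, tolerance = 0.02)
  expect_equal(median(draws), 1.76, tolerance = 0.02)
  # V2 carries no random effect
  expect_true(all(vapply(seq_len(20), function(i) draw_individual_params(pop)$params$v2,
                         numeric(1)) == 2.26))
})

test_that("proportional residual error has the stated CV and stays positive", {
  p <- reference_params()
  # sigma = 0 reproduces the model prediction exactly
  prof0 <- simulate_profile(p, 8, c(0.05, 0.5, 2), sigma = 0)
  expect_equal(prof0$conc, predict_conc(p, 8, c(0.05, 0.5, 2)))
  # replicate observations at one time: sd/mean recovers sigma = 0.149
  set.seed(5)
  y <- replicate(1e4, simulate_profile(p, 8, 0.5, sigma = 0.149)$conc)
  expect_equal(sd(y) / mean(y), 0.149, tolerance = 0.03)
  expect_true(all(y > 0))
  # below-LLOQ values are flagged, not dropped
  prof <- simulate_profile(p, 8, c(0.05, 2), sigma = 0, lloq = 1)
  expect_equal(nrow(prof), 2)
  expect_identical(prof$blq, c(FALSE, TRUE))
})

test_that("urine model reproduces the printed excretion and is monotone", {
  p <- reference_params()
  ends <- c(0.5, 1, 1.5, 2, 3, 4)
  # fe = 5e-4 of a 2400 µg dose -> 1.2 µg by 4 h, noise off
  ur <- simulate_urine(p, 8, ends, fe = 5e-4, cv = 0)
  expect_equal(ur$amount[length(ends)], 1.2, tolerance = 1e-12)
  expect_true(all(diff(ur$amount) >= 0))
  # fe = 0 -> all zeros
  expect_true(all(simulate_urine(p, 8, ends, fe = 0)$amount == 0))
  # noise preserves monotonicity
  set.seed(9)
  urn <- simulate_urine(p, 8, ends, fe = 5e-4)
  expect_true(all(diff(urn$amount) >= 0))
  expect_error(simulate_urine(p, 8, ends, fe = 1.2), "fe")
})

test_that("marker draws match the group summaries and stay positive", {
  mk <- marker_model()
  # zero-SD model returns the group means exactly
  mk0 <- marker_model(sds = data.frame(bun = c(0, 0, 0), cr = c(0, 0, 0),
                                       ccr = c(0, 0, 0)))
  set.seed(1)
  m <- generate_markers("normal", mk0)
  expect_equal(unname(m), c(18.3, 0.27, 4.2))
  # severe-group mean BUN converges to 62.0
  set.seed(2)
  bun <- vapply(seq_len(1e4), function(i) generate_markers("severe", mk)[["bun"]],
                numeric(1))
  expect_equal(mean(bun), 62.0, tolerance = 0.5)
  # truncation: all draws positive even for the tight Cr distributions
  set.seed(3)
  for (g in c("normal", "mild", "severe")) {
    draws <- t(vapply(seq_len(500), function(i) generate_markers(g, mk),
                      numeric(3)))
    expect_true(all(draws > 0))
  }
})

test_that("an active renal effect couples creatinine to the true clearance", {
  big <- study_design(n_per_arm = 30)
  study <- generate_study(big, seed = 21, renal_effect = renal_effect_model())
  truth <- attr(study, "truth")
  covs <- unique(study[, c("ID", "CR")])
  d <- merge(truth, covs, by = "ID")
  r <- cor(d$CR, d$cl + d$cl2)
  expect_lt(r, -0.15)
  # without the effect the correlation is null
  study0 <- generate_study(big, seed = 21)
  d0 <- merge(attr(study0, "truth"), unique(study0[, c("ID", "CR")]), by = "ID")
  expect_lt(abs(cor(d0$CR, d0$cl + d0$cl2)), 0.15)
})
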