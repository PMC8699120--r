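# FOCE-ELS estimator: inner problem, objective, outer fit.

test_that("empirical Bayes modes honour the limits of the inner problem", {
  pop <- pop_model_oxaliplatin()
  tt <- c(c(3, 5, 10, 20, 30, 45) / 60, 1, 1.5, 2)

  # all variances zero: eta is structurally fixed at zero
  pop0 <- pop_model(pop$theta, c(v1 = 0, cl = 0, cl2 = 0), sigma = 0.149)
  y <- predict_conc(pop$theta, 8, tt)
  e0 <- estimate_eta(tt, y, 8, pop0)
  expect_equal(unname(e0$eta), c(0, 0, 0))

  # near-zero prior variance pins eta near zero whatever the data say
  pop_tiny <- pop_model(pop$theta, c(v1 = 1e-8, cl = 1e-8, cl2 = 1e-8),
                        sigma = 0.149)
  y_shift <- predict_conc(pk_params(0.44, 2.26, 2.5, 1.0), 8, tt)
  e1 <- estimate_eta(tt, y_shift, 8, pop_tiny)
  expect_lt(max(abs(e1$eta)), 1e-3)

  # rich noise-free data from a known eta is recovered
  eta_true <- c(v1 = 0.25, cl = -0.3, cl2 = 0.15)
  ind <- pk_params(0.44 * exp(eta_true[["v1"]]), 2.26,
                   1.76 * exp(eta_true[["cl"]]), 1.0 * exp(eta_true[["cl2"]]))
  tt_rich <- seq(0.05, 4, by = 0.05)
  y_rich <- predict_conc(ind, 8, tt_rich)
  pop_wide <- pop_model(pop$theta, c(v1 = 1, cl = 1, cl2 = 1), sigma = 0.02)
  e2 <- estimate_eta(tt_rich, y_rich, 8, pop_wide)
  expect_true(e2$converged)
  expect_equal(unname(e2$eta), unname(eta_true), tolerance = 0.02)
})

test_that("with no random effects the objective is the analytic ELS value", {
  toy <- make_toy_single_eta(31, sigma = 0.12)
  pop0 <- pop_model(toy$pop$theta, c(v1 = 0, cl = 0, cl2 = 0), sigma = 0.12)
  got <- foce_objective(pop0, toy$data)
  # extended least squares computed directly in R
  els <- sum(vapply(toy$subs, function(s) {
    f <- predict_conc(pop0$theta, s$dose, s$t)
    v <- 0.12^2 * f^2
    sum((s$y - f)^2 / v + log(v) + log(2 * pi))
  }, numeric(1)))
  expect_equal(as.numeric(got), els, tolerance = 1e-8)
})

test_that("objective agrees with the adaptive quadrature oracle on single-eta toys", {
  diffs <- vapply(1:20, function(i) {
    toy <- make_toy_single_eta(100 + i, sigma = 0.08)
    as.numeric(foce_objective(toy$pop, toy$data)) - agh_m2ll(toy$pop, toy$subs)
  }, numeric(1))
  expect_lt(max(abs(diffs)), 0.5)
  # linearization error shrinks quadratically with the residual noise: halving
  # sigma must shrink the mean gap by far more than half
  diffs_small <- vapply(1:20, function(i) {
    toy <- make_toy_single_eta(100 + i, sigma = 0.04)
    as.numeric(foce_objective(toy$pop, toy$data)) - agh_m2ll(toy$pop, toy$subs)
  }, numeric(1))
  expect_lt(mean(abs(diffs_small)), mean(abs(diffs)) / 2.5)
})

test_that("objective is invariant to subject relabeling and row permutation", {
  study <- generate_study(seed = 17)
  pop <- pop_model_oxaliplatin()
  base <- as.numeric(foce_objective(pop, study))
  set.seed(1)
  perm <- study[sample(nrow(study)), ]
  expect_equal(as.numeric(foce_objective(pop, perm)), base, tolerance = 1e-10)
  relab <- study
  map <- sample(30)
  relab$ID <- map[relab$ID]
  expect_equal(as.numeric(foce_objective(pop, relab)), base, tolerance = 1e-10)
})

test_that("fixed-effects fit recovers the truth on low-noise data", {
  pop_gen <- pop_model(reference_params(), c(v1 = 0, cl = 0, cl2 = 0),
                       sigma = 0.01)
  study <- generate_study(pop = pop_gen, seed = 13)
  init <- pop_model(pk_params(0.6, 1.5, 1.2, 0.6), c(v1 = 0, cl = 0, cl2 = 0),
                    sigma = 0.05)
  fit <- fit_foce(study, init = init, se = "none")
  expect_equal(fit$pop$theta$cl, 1.76, tolerance = 0.02)
  expect_equal(fit$pop$theta$v1, 0.44, tolerance = 0.02)
  expect_equal(fit$pop$theta$v2, 2.26, tolerance = 0.02)
  expect_equal(fit$pop$theta$cl2, 1.0, tolerance = 0.02)
})

test_that("the fitted point is a fixed point of refitting", {
  study <- generate_study(seed = 2)
  fit <- fit_foce(study, se = "none")
  refit <- fit_foce(study, init = fit$pop, se = "none")
  expect_lt(abs(refit$minus2LL - fit$minus2LL), 0.01)
})

test_that("typical values are recovered without material bias across seeds", {
  fits <- lapply(1:5, function(s) {
    fit_foce(generate_study(seed = s), se = "none")
  })
  rel_bias <- function(get, truth) {
    median(vapply(fits, get, numeric(1))) / truth - 1
  }
  expect_lt(abs(rel_bias(function(f) f$pop$theta$cl, 1.76)), 0.10)
  expect_lt(abs(rel_bias(function(f) f$pop$theta$v1, 0.44)), 0.10)
  expect_lt(abs(rel_bias(function(f) f$pop$theta$cl2, 1.0)), 0.10)
  # omega_CL estimates bracket the generating 0.305
  om <- vapply(fits, function(f) sqrt(f$pop$omega2[["cl"]]), numeric(1))
  expect_gt(max(om), 0.2)
  expect_lt(min(om), 0.4)
})

test_that("fit output carries coherent report, EBE and GOF tables", {
  study <- generate_study(seed = 2)
  fit <- fit_foce(study)
  tid <- tidy(fit)
  expect_equal(tid$estimate[tid$term == "CLtot"],
               fit$pop$theta$cl + fit$pop$theta$cl2)
  expect_true(all(is.finite(tid$cv_percent[tid$block %in%
                                             c("theta", "omega", "sigma")])))
  g <- glance(fit)
  expect_equal(g$n_obs, 270L)
  expect_true(g$converged)
  expect_equal(nrow(fit$eta), 30)
  expect_equal(fit$eta$cl_posthoc, fit$pop$theta$cl * exp(fit$eta$eta_cl))
  a <- augment(fit)
  expect_equal(nrow(a), 270)
  expect_identical(compute_cwres(fit), a$CWRES)
  # recomputation from the stored data matches
  expect_equal(compute_cwres(fit, fit$data), a$CWRES, tolerance = 1e-6)
  # sandwich standard errors are available as an option
  fit_sw <- fit_foce(study, init = fit$pop, se = "sandwich")
  tid_sw <- tidy(fit_sw)
  expect_true(all(is.finite(tid_sw$cv_percent[tid_sw$block == "theta"])))
})
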