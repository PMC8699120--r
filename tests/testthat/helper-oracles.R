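# Shared fixtures and independent oracles, all built in code.

reference_params <- function() pk_params(v1 = 0.44, v2 = 2.26, cl = 1.76, cl2 = 1.0)

# Minimal event-table rows for one subject (dose row + plasma observations).
subject_rows <- function(id, dose, times, y, group = "normal",
                         cr = 0.3, bun = 18, ccr = 4) {
  data.frame(
    ID = id, TIME = c(0, times), EVID = c(1L, rep(0L, length(times))),
    AMT = c(dose, rep(NA_real_, length(times))), DV = c(NA_real_, y),
    CMT = "plasma", MDV = c(1L, rep(0L, length(times))), BLQ = FALSE,
    DOSEGRP = dose, RENGRP = group, CR = cr, BUN = bun, CCR = ccr, WT = 0.3
  )
}

# Single-random-effect toy (one-compartment limit, eta on CL only) for the
# marginal-likelihood oracle comparison.
make_toy_single_eta <- function(seed, n_sub = 6, sigma = 0.08,
                                omega_cl = 0.305,
                                times = c(0.25, 0.5, 1, 1.5, 2, 3, 4),
                                dose = 8) {
  set.seed(seed)
  th <- pk_params(v1 = runif(1, 1.5, 2.5), v2 = 2,
                  cl = runif(1, 1, 2), cl2 = 1e-6)
  pop <- pop_model(th, c(v1 = 0, cl = omega_cl^2, cl2 = 0), sigma = sigma)
  subs <- vector("list", n_sub)
  rows <- vector("list", n_sub)
  for (i in seq_len(n_sub)) {
    eta <- rnorm(1, 0, omega_cl)
    f <- predict_conc(pk_params(th$v1, th$v2, th$cl * exp(eta), th$cl2),
                      dose, times)
    y <- f * (1 + rnorm(length(f), 0, sigma))
    while (any(y <= 0)) {
      y[y <= 0] <- f[y <= 0] * (1 + rnorm(sum(y <= 0), 0, sigma))
    }
    subs[[i]] <- list(t = times, y = y, dose = dose)
    rows[[i]] <- subject_rows(i, dose, times, y)
  }
  list(pop = pop, subs = subs, data = do.call(rbind, rows))
}

# Independent oracle: exact marginal -2LL for one random effect on CL by
# adaptive Gauss-Hermite quadrature (centered and scaled at the conditional
# mode), fully separate from the FOCE code path.
agh_m2ll <- function(pop, subs, n_nodes = 40) {
  th <- pop$theta
  s2 <- pop$sigma^2
  w2 <- pop$omega2[["cl"]]
  gh <- pracma::gaussHermite(n_nodes)
  tot <- 0
  for (s in subs) {
    lg <- function(e) {
      f <- predict_conc(pk_params(th$v1, th$v2, th$cl * exp(e), th$cl2),
                        s$dose, s$t)
      sum(dnorm(s$y, f, sqrt(s2) * f, log = TRUE)) +
        dnorm(e, 0, sqrt(w2), log = TRUE)
    }
    o <- optimize(function(e) -lg(e), c(-4, 4), tol = 1e-10)
    m <- o$minimum
    h <- 1e-4
    H <- (-lg(m + h) + 2 * lg(m) - lg(m - h)) / h^2
    sd_l <- 1 / sqrt(max(H, 1e-8))
    z <- m + sqrt(2) * sd_l * gh$x
    lw <- log(gh$w) + gh$x^2 + vapply(z, lg, numeric(1)) +
      log(sqrt(2) * sd_l)
    mx <- max(lw)
    tot <- tot - 2 * (mx + log(sum(exp(lw - mx))))
  }
  tot
}

# Dense noise-free two-compartment profile for NCA convergence checks.
dense_profile <- function(params, dose, t_end = 12, n = 400) {
  tt <- seq(0.01, t_end, length.out = n)
  data.frame(time = tt, conc = predict_conc(params, dose, tt))
}
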