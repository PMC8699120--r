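# Model qualification: nonparametric bootstrap of the FOCE fit and the
# prediction-corrected visual predictive check.

#' Nonparametric bootstrap of a population fit
#'
#' Resamples subjects with replacement (stratified by renal group x dose arm
#' by default, preserving the six-arm design) and refits the population model
#' on each replicate, starting from the original estimates. Non-converged
#' replicates are excluded from the summaries and counted.
#'
#' @param fit A `foce_fit` of the original dataset.
#' @param n Number of bootstrap replicates (the reference analysis uses 1000;
#'   scaled-down runs are routine).
#' @param seed Integer seed driving the resampling.
#' @param stratified Stratify resampling by `RENGRP` x `DOSEGRP` (default) or
#'   resample subjects freely.
#' @return An object of class `pk_bootstrap`: `summary` (per-parameter
#'   median and 2.5th/97.5th percentiles over converged replicates, alongside
#'   the original estimates), `replicates` (tidy estimates per replicate),
#'   `indices` (the resampled subject ids per replicate), `n_requested`,
#'   `n_converged`.
#' @export
pk_bootstrap <- function(fit, n = 1000, seed = 1, stratified = TRUE) {
  stopifnot(inherits(fit, "foce_fit"), n >= 1)
  data <- fit$data
  subjects <- data |>
    dplyr::distinct(.data$ID, .data$RENGRP, .data$DOSEGRP)
  set.seed(seed)
  strata <- if (stratified) {
    split(subjects$ID, interaction(subjects$RENGRP, subjects$DOSEGRP, drop = TRUE))
  } else {
    list(subjects$ID)
  }
  indices <- purrr::map(seq_len(n), function(b) {
    unlist(purrr::map(strata, ~ sample(.x, length(.x), replace = TRUE)),
           use.names = FALSE)
  })

  split_data <- split(data, data$ID)
  reps <- purrr::imap(indices, function(ids, b) {
    boot_data <- dplyr::bind_rows(
      purrr::imap(ids, function(id, new_id) {
        dplyr::mutate(split_data[[as.character(id)]], ID = new_id)
      })
    )
    rep_fit <- try(fit_foce(boot_data, init = fit$pop, se = "none"),
                   silent = TRUE)
    if (inherits(rep_fit, "try-error") || !rep_fit$convergence) return(NULL)
    dplyr::mutate(tidy.foce_fit(rep_fit)[, c("term", "estimate")], replicate = b)
  })
  converged <- !purrr::map_lgl(reps, is.null)
  replicates <- dplyr::bind_rows(reps[converged])
  if (mean(converged) < 0.8) {
    warning(sprintf("bootstrap: only %d of %d replicates converged",
                    sum(converged), n), call. = FALSE)
  }

  orig <- tidy.foce_fit(fit)[, c("block", "term", "unit", "estimate")]
  summ <- replicates |>
    dplyr::group_by(.data$term) |>
    dplyr::summarise(
      median = stats::median(.data$estimate),
      p2.5 = stats::quantile(.data$estimate, 0.025, names = FALSE),
      p97.5 = stats::quantile(.data$estimate, 0.975, names = FALSE),
      .groups = "drop"
    )
  summ <- dplyr::left_join(orig, summ, by = "term")

  structure(list(summary = summ, replicates = replicates, indices = indices,
                 n_requested = n, n_converged = sum(converged), seed = seed),
            class = "pk_bootstrap")
}

#' @export
print.pk_bootstrap <- function(x, ...) {
  cat(sprintf("Nonparametric bootstrap: %d/%d replicates converged\n",
              x$n_converged, x$n_requested))
  print(as.data.frame(x$summary), digits = 3)
  invisible(x)
}

#' @export
tidy.pk_bootstrap <- function(x, ...) {
  x$summary
}

# Simulate one replicate of the observation vector from a fitted model,
# reusing the original design (per-subject times and doses, in the original
# row order).
simulate_obs_vector <- function(pop, design_list) {
  unlist(purrr::map(design_list, function(d) {
    ind <- draw_individual_params(pop)
    simulate_profile(ind$params, d$dose, d$times, sigma = pop$sigma)$conc
  }), use.names = FALSE)
}

#' Prediction-corrected visual predictive check
#'
#' Simulates `n_sim` replicate studies from the fitted model on the original
#' design, prediction-corrects both observed and simulated concentrations by
#' the bin-median population prediction
#' (`pcY = Y * median(PRED in bin) / PRED`), and summarizes the observed
#' 5th/50th/95th percentiles per time bin against the 2.5th-97.5th percentile
#' envelopes of the corresponding simulated percentiles. Bins are the nominal
#' sampling times; bins with fewer than two observations are merged with
#' their left neighbor.
#'
#' @param fit A `foce_fit`.
#' @param n_sim Number of simulated replicate studies (reference: 1000).
#' @param seed Integer seed.
#' @return An object of class `pk_vpc` whose `bins` element is a tibble with,
#'   per bin: `time` (bin median time), `n_obs`, observed percentiles
#'   `obs_p5`, `obs_p50`, `obs_p95`, and simulated confidence bounds
#'   `lo_p5`, `hi_p5`, `lo_p50`, `hi_p50`, `lo_p95`, `hi_p95`.
#' @export
pk_pcvpc <- function(fit, n_sim = 1000, seed = 1) {
  stopifnot(inherits(fit, "foce_fit"), n_sim >= 1)
  a <- obs_arrays(fit$data)
  obs <- a$obs
  gof <- fit$gof
  stopifnot(nrow(obs) == nrow(gof))

  # nominal-time bins (exact double match, no character round-trip), merging
  # sparse bins leftward
  lvls <- sort(unique(obs$TIME))
  code <- match(obs$TIME, lvls)
  counts <- tabulate(code, nbins = length(lvls))
  merged <- seq_along(lvls)
  for (i in seq_along(lvls)) {
    if (counts[i] < 2 && i > 1) merged[i] <- merged[i - 1]
  }
  bin_of <- merged[code]
  bin_levels <- sort(unique(bin_of))
  bin_idx <- match(bin_of, bin_levels)
  n_bins <- length(bin_levels)

  pred <- gof$PRED
  bin_med_pred <- vapply(split(pred, bin_idx), stats::median, numeric(1))
  corr <- bin_med_pred[bin_idx] / pred
  pc_obs <- obs$DV * corr

  pctl <- function(x) stats::quantile(x, c(0.05, 0.5, 0.95), names = FALSE)
  obs_pct <- t(vapply(split(pc_obs, bin_idx), pctl, numeric(3)))
  dimnames(obs_pct) <- NULL

  design_list <- purrr::map(split(obs, match(obs$ID, unique(obs$ID))),
                            ~ list(times = .x$TIME, dose = .x$DOSEGRP[1]))
  set.seed(seed)
  sim_pct <- array(NA_real_, dim = c(n_sim, n_bins, 3))
  for (r in seq_len(n_sim)) {
    pc_sim <- simulate_obs_vector(fit$pop, design_list) * corr
    sim_pct[r, , ] <- t(vapply(split(pc_sim, bin_idx), pctl, numeric(3)))
  }
  ci <- apply(sim_pct, c(2, 3), stats::quantile, probs = c(0.025, 0.975))

  bins <- tibble::tibble(
    time = unname(vapply(split(obs$TIME, bin_idx), stats::median, numeric(1))),
    n_obs = tabulate(bin_idx, nbins = n_bins),
    obs_p5 = obs_pct[, 1], obs_p50 = obs_pct[, 2], obs_p95 = obs_pct[, 3],
    lo_p5 = ci[1, , 1], hi_p5 = ci[2, , 1],
    lo_p50 = ci[1, , 2], hi_p50 = ci[2, , 2],
    lo_p95 = ci[1, , 3], hi_p95 = ci[2, , 3]
  )
  structure(list(bins = bins, n_sim = n_sim, seed = seed), class = "pk_vpc")
}

#' @export
print.pk_vpc <- function(x, ...) {
  cat(sprintf("Prediction-corrected VPC (%d simulated studies)\n", x$n_sim))
  inside <- with(x$bins, obs_p50 >= lo_p50 & obs_p50 <= hi_p50)
  cat(sprintf("  observed medians inside simulated 95%% CI: %d/%d bins\n",
              sum(inside), nrow(x$bins)))
  print(as.data.frame(x$bins), digits = 3)
  invisible(x)
}

#' @export
tidy.pk_vpc <- function(x, ...) {
  x$bins
}

#' Plot a prediction-corrected visual predictive check
#'
#' Observed percentiles (lines/points) overlaid on the simulated
#' 95% confidence bands of each percentile.
#'
#' @param object A `pk_vpc`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pk_vpc <- function(object, ...) {
  b <- object$bins
  long_obs <- tidyr::pivot_longer(
    b[, c("time", "obs_p5", "obs_p50", "obs_p95")],
    -"time", names_to = "pctl", values_to = "observed",
    names_prefix = "obs_"
  )
  bands <- dplyr::bind_rows(
    tibble::tibble(time = b$time, pctl = "p5", lo = b$lo_p5, hi = b$hi_p5),
    tibble::tibble(time = b$time, pctl = "p50", lo = b$lo_p50, hi = b$hi_p50),
    tibble::tibble(time = b$time, pctl = "p95", lo = b$lo_p95, hi = b$hi_p95)
  )
  ggplot2::ggplot(bands, ggplot2::aes(x = .data$time)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi,
                                      fill = .data$pctl), alpha = 0.3) +
    ggplot2::geom_line(data = long_obs,
                       ggplot2::aes(y = .data$observed, colour = .data$pctl)) +
    ggplot2::geom_point(data = long_obs,
                        ggplot2::aes(y = .data$observed, colour = .data$pctl)) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Time after dose (h)",
                  y = "Prediction-corrected concentration (µg/mL)",
                  colour = "Observed", fill = "Simulated 95% CI",
                  title = "Prediction-corrected visual predictive check") +
    ggplot2::theme_bw()
}
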