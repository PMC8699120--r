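# Synthetic study generation: individual parameters, plasma profiles with
# proportional error, cumulative urine amounts, renal markers, and the full
# event-table assembly.

# Deterministic per-subject substream: master seed + subject counter mapped
# into the 32-bit integer range. Allows regenerating any one subject without
# replaying the whole study.
subject_seed <- function(master_seed, i) {
  as.integer((as.numeric(master_seed) * 1009 + i * 7919) %% 2147483647)
}

#' Draw individual pharmacokinetic parameters
#'
#' Individual parameters follow the exponential (lognormal) inter-individual
#' model `P_i = theta_P * exp(eta_P)` with `eta_P ~ N(0, omega2_P)`
#' independently for V1, CL and CL2; V2 carries no random effect. When a
#' [renal_effect_model()] is supplied, the typical clearance is replaced by
#' `cr_to_cl(cr)` before the random effect is applied.
#'
#' @param pop A [pop_model()].
#' @param cr Plasma creatinine of the subject (mg/dL); used only when
#'   `renal_effect` is supplied.
#' @param renal_effect Optional [renal_effect_model()].
#' @return A list with `params` (a [pk_params()]) and `eta`
#'   (named vector `v1`, `cl`, `cl2`).
#' @examples
#' set.seed(1)
#' draw_individual_params(pop_model_oxaliplatin())
#' @export
draw_individual_params <- function(pop, cr = NULL, renal_effect = NULL) {
  stopifnot(inherits(pop, "pop_model"))
  eta <- stats::rnorm(3, 0, sqrt(pop$omega2))
  names(eta) <- c("v1", "cl", "cl2")
  th <- pop$theta
  cl_typ <- th$cl
  if (!is.null(renal_effect)) {
    stopifnot(inherits(renal_effect, "renal_effect_model"), !is.null(cr))
    cl_typ <- renal_effect$cr_to_cl(cr)
    if (cl_typ <= 0) stop("renal effect maps Cr to a non-positive clearance", call. = FALSE)
  }
  list(
    params = pk_params(v1 = th$v1 * exp(eta[["v1"]]),
                       v2 = th$v2,
                       cl = cl_typ * exp(eta[["cl"]]),
                       cl2 = th$cl2 * exp(eta[["cl2"]])),
    eta = eta
  )
}

#' Simulate an observed concentration profile
#'
#' Applies proportional residual error `y = f(t) * (1 + e)`,
#' `e ~ N(0, sigma^2)`, to the closed-form individual prediction. Draws that
#' would produce a non-positive observation are redrawn (truncation would bias
#' the mean). Observations below the lower limit of quantification are
#' flagged, not dropped.
#'
#' @param ind Individual [pk_params()].
#' @param dose Dose (mg/kg).
#' @param times Sampling times (h).
#' @param sigma Proportional error SD (>= 0); 0 returns the noise-free curve.
#' @param lloq Lower limit of quantification (µg/mL) used for the `blq` flag.
#' @return A tibble with columns `time`, `conc`, `ipred`, `blq`.
#' @export
simulate_profile <- function(ind, dose, times, sigma, lloq = 0.01) {
  stopifnot(sigma >= 0)
  f <- predict_conc(ind, dose, times)
  y <- f
  if (sigma > 0) {
    y <- f * (1 + stats::rnorm(length(f), 0, sigma))
    bad <- which(y <= 0)
    while (length(bad)) {
      y[bad] <- f[bad] * (1 + stats::rnorm(length(bad), 0, sigma))
      bad <- bad[y[bad] <= 0]
    }
  }
  tibble::tibble(time = times, conc = y, ipred = f, blq = y < lloq)
}

#' Simulate cumulative urinary excretion of intact drug
#'
#' The cumulative amount excreted intact by the end of each collection
#' interval follows the plasma exposure profile:
#' `Ae(t) = fe * dose_total * AUC(0..t) / AUC(0..t_last)`, where `dose_total`
#' is the absolute dose for a reference 0.3 kg rat (per-kg dose x 0.3 kg,
#' in µg). A single multiplicative lognormal factor (CV `cv`) scales the whole
#' curve, preserving monotonicity while matching the observed variability of
#' the terminal amount.
#'
#' @param ind Individual [pk_params()].
#' @param dose Dose (mg/kg).
#' @param interval_ends Ends of the cumulative collection intervals (h).
#' @param fe Fraction of the dose excreted intact by the final interval end;
#'   in (0, 1). `fe = 0` is allowed and returns zeros.
#' @param cv Coefficient of variation of the multiplicative noise; 0 disables
#'   noise. Default 0.2/1.2 (observed 1.2 ± 0.2 µg terminal amount).
#' @param ref_weight Reference body weight (kg) converting per-kg dose to an
#'   absolute amount; default 0.3.
#' @return A tibble with columns `time` (interval end, h) and `amount`
#'   (cumulative µg), non-decreasing.
#' @examples
#' p <- pk_params(0.44, 2.26, 1.76, 1.0)
#' simulate_urine(p, dose = 8, interval_ends = c(0.5, 1, 1.5, 2, 3, 4),
#'                fe = 5e-4, cv = 0) # terminal amount 1.2 µg
#' @export
simulate_urine <- function(ind, dose, interval_ends, fe, cv = 0.2 / 1.2,
                           ref_weight = 0.3) {
  if (fe < 0 || fe >= 1) stop("fe must lie in [0, 1)", call. = FALSE)
  if (fe == 0) {
    return(tibble::tibble(time = interval_ends, amount = 0))
  }
  dose_total_ug <- dose * ref_weight * 1000 # mg/kg -> µg absolute
  shape <- auc_partial(ind, dose, interval_ends) /
    auc_partial(ind, dose, max(interval_ends))
  noise <- 1
  if (cv > 0) {
    sdlog <- sqrt(log(1 + cv^2))
    noise <- stats::rlnorm(1, meanlog = -sdlog^2 / 2, sdlog = sdlog)
  }
  tibble::tibble(time = interval_ends,
                 amount = fe * dose_total_ug * shape * noise)
}

#' Draw renal biochemical markers for one subject
#'
#' Truncated-normal draws (at zero) from the group's marker means/SDs. A
#' one-factor Gaussian copula ties BUN (positively) and CCr (negatively) to
#' the creatinine draw, so that all marker-PK correlations are non-trivial
#' when creatinine drives the true clearance.
#'
#' @param group Renal group label present in `markers`.
#' @param markers A [marker_model()].
#' @return Named vector `c(bun, cr, ccr)`.
#' @export
generate_markers <- function(group, markers) {
  stopifnot(inherits(markers, "marker_model"), group %in% markers$groups)
  mu <- unlist(markers$means[group, c("bun", "cr", "ccr")])
  sd <- unlist(markers$sds[group, c("bun", "cr", "ccr")])
  r <- markers$copula_r
  resid <- sqrt(1 - r^2)
  draw_one <- function() {
    z_cr <- stats::rnorm(1)
    z_bun <- r * z_cr + resid * stats::rnorm(1)
    z_ccr <- -r * z_cr + resid * stats::rnorm(1)
    c(bun = mu[["bun"]] + sd[["bun"]] * z_bun,
      cr = mu[["cr"]] + sd[["cr"]] * z_cr,
      ccr = mu[["ccr"]] + sd[["ccr"]] * z_ccr)
  }
  x <- draw_one()
  tries <- 0L
  while (any(x <= 0) && all(sd > 0) && tries < 1000L) {
    x <- draw_one()
    tries <- tries + 1L
  }
  x[x <= 0] <- .Machine$double.eps # degenerate SD = 0 with zero mean guard
  x
}

#' Generate a complete synthetic pharmacokinetic study
#'
#' Assembles a full event table for the rat study design: one dose row per
#' subject at time zero, nine plasma observation rows per subject, and
#' cumulative urine rows for the 8 mg/kg arms. Deterministic for a fixed
#' seed; per-subject random substreams allow stable partial regeneration.
#'
#' @param design A [study_design()].
#' @param pop A [pop_model()] holding the true typical values, variances and
#'   residual error used as simulation truth.
#' @param markers A [marker_model()].
#' @param renal_effect Optional [renal_effect_model()]; when supplied, each
#'   subject's typical clearance is driven by their creatinine draw and the
#'   urinary excretion fraction is scaled per group. When `NULL` (default) the
#'   truth has no covariate effect on clearance, matching a final population
#'   model without covariates, and the normal-function excretion fraction
#'   applies to every group.
#' @param seed Master seed (integer).
#' @param lloq Lower limit of quantification for the plasma `BLQ` flag.
#' @param urine_cv CV of the urine noise factor (see [simulate_urine()]).
#' @param fe Urinary excretion fraction used when `renal_effect` is `NULL`.
#' @return A tibble in NONMEM-style event-table layout with columns
#'   `ID`, `TIME` (h), `EVID` (1 dose, 0 observation), `AMT` (mg/kg),
#'   `DV` (µg/mL plasma or cumulative µg urine), `CMT`
#'   (`"plasma"`/`"urine"`), `MDV`, `BLQ`, and covariates `DOSEGRP` (mg/kg),
#'   `RENGRP`, `CR`, `BUN`, `CCR`, `WT` (kg). The per-subject simulation
#'   truth (individual parameters and random effects) is attached as the
#'   `"truth"` attribute, a tibble.
#' @examples
#' study <- generate_study(seed = 42)
#' dplyr::count(study, EVID, CMT)
#' @export
generate_study <- function(design = study_design(),
                           pop = pop_model_oxaliplatin(),
                           markers = marker_model(),
                           renal_effect = NULL,
                           seed = 1,
                           lloq = 0.01,
                           urine_cv = 0.2 / 1.2,
                           fe = 5e-4) {
  stopifnot(inherits(design, "study_design"), inherits(pop, "pop_model"))
  if (!all(design$renal_groups %in% markers$groups)) {
    stop("marker model lacks some renal groups of the design", call. = FALSE)
  }
  arms <- tidyr::expand_grid(group = design$renal_groups, dose = design$doses,
                             rep = seq_len(design$n_per_arm))
  arms$id <- seq_len(nrow(arms))

  rows <- purrr::pmap(arms, function(group, dose, rep, id) {
    set.seed(subject_seed(seed, id))
    mk <- generate_markers(group, markers)
    ind <- draw_individual_params(pop, cr = mk[["cr"]], renal_effect = renal_effect)
    obs <- simulate_profile(ind$params, dose, design$plasma_times,
                            sigma = pop$sigma, lloq = lloq)
    base <- tibble::tibble(
      ID = id, DOSEGRP = dose, RENGRP = group,
      CR = mk[["cr"]], BUN = mk[["bun"]], CCR = mk[["ccr"]], WT = 0.3
    )
    dose_row <- dplyr::mutate(base, TIME = 0, EVID = 1L, AMT = dose,
                              DV = NA_real_, CMT = "plasma", MDV = 1L, BLQ = FALSE)
    obs_rows <- dplyr::mutate(base[rep(1, nrow(obs)), ], TIME = obs$time,
                              EVID = 0L, AMT = NA_real_, DV = obs$conc,
                              CMT = "plasma", MDV = 0L, BLQ = obs$blq)
    out <- dplyr::bind_rows(dose_row, obs_rows)
    if (dose %in% design$urine_doses) {
      fe_i <- if (is.null(renal_effect)) fe else
        renal_effect$fe_normal * renal_effect$urine_scaling[[group]]
      ur <- simulate_urine(ind$params, dose, design$urine_interval_ends,
                           fe = fe_i, cv = urine_cv)
      ur_rows <- dplyr::mutate(base[rep(1, nrow(ur)), ], TIME = ur$time,
                               EVID = 0L, AMT = NA_real_, DV = ur$amount,
                               CMT = "urine", MDV = 0L, BLQ = FALSE)
      out <- dplyr::bind_rows(out, ur_rows)
    }
    truth <- tibble::tibble(
      ID = id, v1 = ind$params$v1, v2 = ind$params$v2, cl = ind$params$cl,
      cl2 = ind$params$cl2, eta_v1 = ind$eta[["v1"]], eta_cl = ind$eta[["cl"]],
      eta_cl2 = ind$eta[["cl2"]]
    )
    list(rows = out, truth = truth)
  })

  dataset <- dplyr::bind_rows(purrr::map(rows, "rows"))
  dataset <- dplyr::select(dataset, "ID", "TIME", "EVID", "AMT", "DV", "CMT",
                           "MDV", "BLQ", "DOSEGRP", "RENGRP", "CR", "BUN",
                           "CCR", "WT")
  attr(dataset, "truth") <- dplyr::bind_rows(purrr::map(rows, "truth"))
  dataset
}
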