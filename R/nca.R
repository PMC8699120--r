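# Non-compartmental analysis: terminal slope by log-linear regression,
# linear-trapezoid AUC with back-extrapolated C(0) for an IV bolus, and the
# derived clearance / volume / half-life summaries.

#' Terminal elimination rate constant
#'
#' Ordinary least-squares regression of `log(C)` on `t` over the last
#' `n_terminal` positive concentrations; `ke` is minus the slope.
#' `n_terminal = "auto"` picks the window (last 3 to 5 points) with the best
#' adjusted R-squared.
#'
#' @param time,conc Numeric vectors of the profile, sorted by time.
#' @param n_terminal Number of terminal points (>= 3), or `"auto"`.
#' @return A list with `ke` (1/h), `n_used`, `adj_r2` and `ok` (FALSE when
#'   the fitted slope is non-negative, i.e. no terminal decline — the profile
#'   is then unusable for extrapolation and `ke` is `NA`).
#' @export
terminal_slope <- function(time, conc, n_terminal = 3) {
  keep <- which(conc > 0)
  time <- time[keep]; conc <- conc[keep]
  fit_window <- function(n) {
    if (length(time) < n) return(NULL)
    idx <- seq(length(time) - n + 1, length(time))
    fit <- stats::lm(log(conc[idx]) ~ time[idx])
    ly <- log(conc[idx])
    r2 <- 1 - sum(stats::resid(fit)^2) / sum((ly - mean(ly))^2)
    list(ke = -unname(stats::coef(fit)[2]),
         adj_r2 = 1 - (1 - r2) * (n - 1) / (n - 2), n_used = n)
  }
  if (identical(n_terminal, "auto")) {
    cand <- purrr::compact(purrr::map(3:5, fit_window))
    if (!length(cand)) stop("need at least 3 positive concentrations", call. = FALSE)
    res <- cand[[which.max(purrr::map_dbl(cand, "adj_r2"))]]
  } else {
    if (n_terminal < 3) stop("n_terminal must be >= 3", call. = FALSE)
    res <- fit_window(n_terminal)
    if (is.null(res)) stop("need at least ", n_terminal, " positive concentrations",
                           call. = FALSE)
  }
  res$ok <- is.finite(res$ke) && res$ke > 0
  if (!res$ok) res$ke <- NA_real_
  res
}

# Back-extrapolated C(0) for an IV bolus: exp of the intercept of a
# log-linear fit through the first two positive points. Falls back to the
# first observed concentration when the early profile is not declining.
extrapolate_c0 <- function(time, conc) {
  pos <- which(conc > 0)
  if (length(pos) < 2) return(conc[pos][1])
  i <- pos[1:2]
  slope <- (log(conc[i[2]]) - log(conc[i[1]])) / (time[i[2]] - time[i[1]])
  if (slope >= 0) return(conc[i[1]])
  exp(log(conc[i[1]]) - slope * time[i[1]])
}

#' Trapezoidal AUC to the last observation and to infinity
#'
#' Linear trapezoidal rule over the observed profile, with a leading segment
#' from `(0, C0)` where `C0` is back-extrapolated for the IV bolus (log-linear
#' through the first two points), plus the standard extrapolation
#' `C_last / ke` beyond the last observation.
#'
#' @inheritParams terminal_slope
#' @param ke Terminal rate constant (1/h), positive.
#' @return A list with `auc_last`, `auc_inf` (µg·h/mL) and `extrap_frac`, the
#'   extrapolated fraction of `auc_inf`.
#' @export
auc_0_inf <- function(time, conc, ke) {
  stopifnot(length(time) == length(conc), ke > 0)
  if (time[1] > 0) {
    c0 <- extrapolate_c0(time, conc)
    time <- c(0, time); conc <- c(c0, conc)
  }
  auc_last <- pracma::trapz(time, conc)
  tail_area <- conc[length(conc)] / ke
  list(auc_last = auc_last, auc_inf = auc_last + tail_area,
       extrap_frac = tail_area / (auc_last + tail_area))
}

#' Non-compartmental analysis of one profile
#'
#' Computes the standard IV-bolus NCA summaries: terminal `ke` and half-life,
#' `AUC` to the last point and to infinity (linear trapezoid), total clearance
#' `CLtot = dose / AUC0-inf` and distribution volume `Vd = CLtot / ke`.
#' Profiles whose extrapolated AUC fraction exceeds `extrap_warn` are flagged
#' (not rejected); profiles without a declining terminal phase return `NA`
#' summaries with `ok = FALSE`.
#'
#' @param profile A data frame with columns `time` (h) and `conc` (µg/mL);
#'   rows are sorted by time internally.
#' @param dose Dose (mg/kg).
#' @param n_terminal Passed to [terminal_slope()].
#' @param extrap_warn Extrapolated-fraction threshold for the flag.
#' @return A one-row tibble: `ke`, `t_half`, `auc_last`, `auc_inf`, `cl_tot`,
#'   `vd`, `extrap_frac`, `flag_extrap`, `ok`.
#' @export
nca_analyze <- function(profile, dose, n_terminal = 3, extrap_warn = 0.2) {
  stopifnot(all(c("time", "conc") %in% names(profile)), dose > 0)
  profile <- dplyr::arrange(dplyr::as_tibble(profile), .data$time)
  if (any(profile$time < 0) || anyDuplicated(profile$time)) {
    stop("times must be non-negative and unique", call. = FALSE)
  }
  if (any(profile$conc < 0)) stop("concentrations must be non-negative", call. = FALSE)
  ts <- terminal_slope(profile$time, profile$conc, n_terminal)
  if (!ts$ok) {
    return(tibble::tibble(ke = NA_real_, t_half = NA_real_, auc_last = NA_real_,
                          auc_inf = NA_real_, cl_tot = NA_real_, vd = NA_real_,
                          extrap_frac = NA_real_, flag_extrap = FALSE, ok = FALSE))
  }
  a <- auc_0_inf(profile$time, profile$conc, ts$ke)
  cl_tot <- dose / a$auc_inf
  tibble::tibble(ke = ts$ke, t_half = log(2) / ts$ke, auc_last = a$auc_last,
                 auc_inf = a$auc_inf, cl_tot = cl_tot, vd = cl_tot / ts$ke,
                 extrap_frac = a$extrap_frac,
                 flag_extrap = a$extrap_frac > extrap_warn, ok = TRUE)
}

#' Non-compartmental analysis of a whole study
#'
#' Runs [nca_analyze()] on the plasma observations of every subject of a
#' study event table.
#'
#' @param data A study event table as produced by [generate_study()] or
#'   [read_pk_dataset()].
#' @inheritParams nca_analyze
#' @return A tibble with one row per subject: `ID`, covariates (`DOSEGRP`,
#'   `RENGRP`, `CR`, `BUN`, `CCR`) and the NCA summary columns.
#' @examples
#' study <- generate_study(seed = 7)
#' nca(study)
#' @export
nca <- function(data, n_terminal = 3, extrap_warn = 0.2) {
  obs <- dplyr::filter(data, .data$EVID == 0L, .data$CMT == "plasma",
                       .data$MDV == 0L)
  obs |>
    dplyr::group_by(.data$ID, .data$DOSEGRP, .data$RENGRP, .data$CR,
                    .data$BUN, .data$CCR) |>
    dplyr::group_modify(function(d, key) {
      nca_analyze(tibble::tibble(time = d$TIME, conc = d$DV),
                  dose = key$DOSEGRP, n_terminal = n_terminal,
                  extrap_warn = extrap_warn)
    }) |>
    dplyr::ungroup()
}

#' Summarize urinary excretion of intact drug
#'
#' Per-subject cumulative amount excreted by the end of urine collection and
#' the corresponding fraction of the administered dose, as a percentage.
#' A 1.2 µg cumulative amount of a 2400 µg dose gives 0.05%.
#'
#' @param data A study event table containing urine rows (`CMT == "urine"`,
#'   `DV` cumulative µg).
#' @param ref_weight Reference body weight (kg) converting the per-kg dose to
#'   an absolute amount; per-row `WT` is used when present.
#' @return A tibble with `ID`, `DOSEGRP`, `RENGRP`, `ae_total` (µg),
#'   `dose_total` (µg) and `fe_percent`.
#' @export
urine_summary <- function(data, ref_weight = 0.3) {
  ur <- dplyr::filter(data, .data$EVID == 0L, .data$CMT == "urine")
  if (!nrow(ur)) stop("dataset has no urine rows", call. = FALSE)
  wt <- if ("WT" %in% names(ur)) ur$WT else ref_weight
  ur |>
    dplyr::mutate(.wt = wt) |>
    dplyr::group_by(.data$ID, .data$DOSEGRP, .data$RENGRP) |>
    dplyr::summarise(
      ae_total = max(.data$DV),
      dose_total = .data$DOSEGRP[1] * .data$.wt[1] * 1000,
      .groups = "drop"
    ) |>
    dplyr::mutate(fe_percent = 100 * .data$ae_total / .data$dose_total)
}
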