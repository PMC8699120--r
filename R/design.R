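#' Study design of the rat pharmacokinetic experiment
#'
#' Defaults reproduce the acute-kidney-injury rat study: three renal-function
#' groups (normal, mild, severe), IV bolus doses of 3 or 8 mg/kg with five
#' rats per dose per group, plasma sampling at 3, 5, 10, 20, 30, 45 min and
#' 1, 1.5, 2 h, and urine collection windows ending at 0.5, 1, 1.5, 2, 3, 4 h
#' in the 8 mg/kg arms only (urinary drug levels are quantifiable only at the
#' high dose).
#'
#' @param renal_groups Character vector of renal-function group labels.
#' @param doses Numeric vector of bolus doses (mg/kg).
#' @param n_per_arm Rats per renal group per dose arm.
#' @param plasma_times Plasma sampling times in hours, strictly increasing.
#' @param urine_interval_ends Ends of the cumulative urine collection
#'   intervals in hours (applied to `urine_doses` arms only).
#' @param urine_doses Doses (mg/kg) whose arms have urine collection.
#' @return An object of class `study_design`.
#' @export
study_design <- function(renal_groups = c("normal", "mild", "severe"),
                         doses = c(3, 8),
                         n_per_arm = 5,
                         plasma_times = c(c(3, 5, 10, 20, 30, 45) / 60, 1, 1.5, 2),
                         urine_interval_ends = c(0.5, 1, 1.5, 2, 3, 4),
                         urine_doses = 8) {
  stopifnot(length(renal_groups) >= 1, length(doses) >= 1)
  if (n_per_arm < 1) stop("n_per_arm must be >= 1", call. = FALSE)
  for (tm in list(plasma_times, urine_interval_ends)) {
    if (any(tm <= 0) || is.unsorted(tm, strictly = TRUE)) {
      stop("sampling times must be positive and strictly increasing", call. = FALSE)
    }
  }
  structure(
    list(renal_groups = renal_groups, doses = doses, n_per_arm = n_per_arm,
         plasma_times = plasma_times, urine_interval_ends = urine_interval_ends,
         urine_doses = urine_doses),
    class = "study_design"
  )
}

#' Renal biochemical marker distributions
#'
#' Group-wise means and SDs of the renal-function markers: blood urea nitrogen
#' (BUN, mg/dL), plasma creatinine (Cr, mg/dL) and creatinine clearance
#' (CCr, mL/min/kg). Defaults are the observed group summaries of the rat
#' study (normal / mild / severe):
#' BUN 18.3±1.4 / 27.9±12.7 / 62.0±12.8; Cr 0.27±0.02 / 0.54±0.21 / 0.95±0.17;
#' CCr 4.2±1.3 / 2.2±0.7 / 1.6±0.7. Draws are truncated at zero.
#'
#' @param means,sds Data frames (or named lists of vectors) with one row per
#'   group and columns `bun`, `cr`, `ccr`; row order matches `groups`.
#' @param groups Group labels, same order as the rows.
#' @param copula_r Correlation (absolute value) tying BUN and CCr draws to the
#'   Cr draw through a one-factor Gaussian copula; BUN co-varies positively
#'   with Cr, CCr negatively.
#' @return An object of class `marker_model`.
#' @export
marker_model <- function(groups = c("normal", "mild", "severe"),
                         means = data.frame(bun = c(18.3, 27.9, 62.0),
                                            cr = c(0.27, 0.54, 0.95),
                                            ccr = c(4.2, 2.2, 1.6)),
                         sds = data.frame(bun = c(1.4, 12.7, 12.8),
                                          cr = c(0.02, 0.21, 0.17),
                                          ccr = c(1.3, 0.7, 0.7)),
                         copula_r = 0.8) {
  means <- as.data.frame(means); sds <- as.data.frame(sds)
  stopifnot(nrow(means) == length(groups), nrow(sds) == length(groups),
            all(c("bun", "cr", "ccr") %in% names(means)),
            all(c("bun", "cr", "ccr") %in% names(sds)))
  if (any(as.matrix(sds) < 0)) stop("marker SDs must be >= 0", call. = FALSE)
  if (copula_r < 0 || copula_r >= 1) stop("copula_r must be in [0, 1)", call. = FALSE)
  rownames(means) <- rownames(sds) <- groups
  structure(list(groups = groups, means = means, sds = sds, copula_r = copula_r),
            class = "marker_model")
}

#' Renal effect on clearance and urinary excretion
#'
#' Describes how renal function enters the generated truth: the typical
#' elimination clearance of a subject becomes `cl_fun(Cr)` (a linear map of
#' plasma creatinine by default, see [anchor_regression()]), and the fraction
#' of the dose excreted intact in urine by 4 h is `fe_normal` scaled per group
#' (mild and severe kidneys excrete 63.5% and 37.7% of the normal amount).
#'
#' @param cr_to_cl Function mapping Cr (mg/dL) to typical CL (L/h/kg), or a
#'   `cr_cl_regression` object. Default: the anchor regression line.
#' @param fe_normal Fraction of dose excreted intact in urine to 4 h for
#'   normal renal function. Default 5e-4 (the observed 1.2 µg of a 2400 µg
#'   dose, i.e. 0.05%, below the 0.1% bound).
#' @param urine_scaling Named multipliers of `fe_normal` per renal group.
#' @return An object of class `renal_effect_model`.
#' @export
renal_effect_model <- function(cr_to_cl = anchor_regression(),
                               fe_normal = 5e-4,
                               urine_scaling = c(normal = 1, mild = 0.635,
                                                 severe = 0.377)) {
  if (inherits(cr_to_cl, "cr_cl_regression")) {
    reg <- cr_to_cl
    cr_to_cl <- function(cr) reg$intercept + reg$slope * cr
  }
  stopifnot(is.function(cr_to_cl))
  if (fe_normal <= 0 || fe_normal >= 1) stop("fe_normal must be in (0, 1)", call. = FALSE)
  if (any(urine_scaling <= 0)) stop("urine_scaling must be positive", call. = FALSE)
  structure(list(cr_to_cl = cr_to_cl, fe_normal = fe_normal,
                 urine_scaling = urine_scaling),
            class = "renal_effect_model")
}
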