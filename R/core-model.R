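#' Structural two-compartment parameters
#'
#' Construct and validate the structural parameter set of the two-compartment
#' intravenous-bolus model with linear elimination. All volumes and clearances
#' are expressed per kilogram body weight, so that a dose in mg/kg yields
#' concentrations directly in µg/mL.
#'
#' @param v1 Central volume of distribution (L/kg).
#' @param v2 Peripheral volume of distribution (L/kg).
#' @param cl Elimination clearance from the central compartment (L/h/kg).
#' @param cl2 Inter-compartmental clearance (L/h/kg).
#'
#' @return An object of class `pk_params`: a named list with fields `v1`,
#'   `v2`, `cl`, `cl2` and the derived composites `cl_tot = cl + cl2`
#'   (total clearance) and `vd = v1 + v2` (distribution volume).
#' @examples
#' p <- pk_params(v1 = 0.44, v2 = 2.26, cl = 1.76, cl2 = 1.0)
#' p$cl_tot # 2.76 L/h/kg
#' p$vd     # 2.70 L/kg
#' @export
pk_params <- function(v1, v2, cl, cl2) {
  vals <- c(v1 = v1, v2 = v2, cl = cl, cl2 = cl2)
  if (!all(is.finite(vals)) || any(vals <= 0)) {
    stop("all structural parameters (v1, v2, cl, cl2) must be finite and strictly positive",
         call. = FALSE)
  }
  structure(
    list(v1 = v1, v2 = v2, cl = cl, cl2 = cl2,
         cl_tot = cl + cl2, vd = v1 + v2),
    class = "pk_params"
  )
}

#' @export
print.pk_params <- function(x, ...) {
  cat("Two-compartment IV-bolus parameters (per kg):\n")
  cat(sprintf("  V1  = %.4g L/kg    V2  = %.4g L/kg    (Vd    = %.4g L/kg)\n",
              x$v1, x$v2, x$vd))
  cat(sprintf("  CL  = %.4g L/h/kg  CL2 = %.4g L/h/kg  (CLtot = %.4g L/h/kg)\n",
              x$cl, x$cl2, x$cl_tot))
  invisible(x)
}

#' Micro rate constants of the two-compartment model
#'
#' Standard reparameterization of the volume/clearance parameterization into
#' first-order rate constants.
#'
#' @param params A [pk_params()] object.
#' @return A named numeric vector `c(k10, k12, k21)` in 1/h, where
#'   `k10 = CL/V1` (elimination), `k12 = CL2/V1` (central-to-peripheral) and
#'   `k21 = CL2/V2` (peripheral-to-central).
#' @examples
#' micro_constants(pk_params(0.44, 2.26, 1.76, 1.0))
#' @export
micro_constants <- function(params) {
  stopifnot(inherits(params, "pk_params"))
  c(k10 = params$cl / params$v1,
    k12 = params$cl2 / params$v1,
    k21 = params$cl2 / params$v2)
}

#' Macro (bi-exponential) constants for an IV bolus dose
#'
#' Solves the bi-exponential form `C(t) = A exp(-alpha t) + B exp(-beta t)`
#' of the two-compartment disposition after an instantaneous bolus.
#' `alpha` and `beta` are the roots of
#' `s^2 - (k10 + k12 + k21) s + k10 k21 = 0` with `alpha >= beta`.
#'
#' @param params A [pk_params()] object.
#' @param dose Dose per body weight (mg/kg); must be positive.
#' @return A named list with `A`, `B` (µg/mL), `alpha`, `beta` (1/h).
#'   Satisfies `A + B = dose/V1` (initial concentration) and
#'   `A/alpha + B/beta = dose/CL` (total exposure).
#' @examples
#' m <- macro_constants(pk_params(0.44, 2.26, 1.76, 1.0), dose = 8)
#' m$A / m$alpha + m$B / m$beta # 8 / 1.76
#' @export
macro_constants <- function(params, dose) {
  stopifnot(inherits(params, "pk_params"))
  if (!is.finite(dose) || dose <= 0) stop("dose must be positive", call. = FALSE)
  k <- micro_constants(params)
  s <- sum(k)
  disc <- s^2 - 4 * k[["k10"]] * k[["k21"]]
  if (disc <= .Machine$double.eps * s^2) {
    stop("degenerate kinetics: alpha == beta (repeated root) is not supported",
         call. = FALSE)
  }
  root <- sqrt(disc)
  alpha <- (s + root) / 2
  beta <- (s - root) / 2
  c0 <- dose / params$v1
  list(A = c0 * (alpha - k[["k21"]]) / (alpha - beta),
       B = c0 * (k[["k21"]] - beta) / (alpha - beta),
       alpha = unname(alpha), beta = unname(beta))
}

#' Predicted plasma concentration after an IV bolus
#'
#' Evaluates the closed-form two-compartment concentration-time curve.
#'
#' @inheritParams macro_constants
#' @param t Time after dose in hours; vectorized, all values `>= 0`.
#' @return Numeric vector of concentrations (µg/mL), same length as `t`.
#' @examples
#' predict_conc(pk_params(0.44, 2.26, 1.76, 1.0), dose = 8, t = c(0, 0.5, 2))
#' @export
predict_conc <- function(params, dose, t) {
  if (any(!is.finite(t)) || any(t < 0)) {
    stop("times must be finite and non-negative", call. = FALSE)
  }
  m <- macro_constants(params, dose)
  m$A * exp(-m$alpha * t) + m$B * exp(-m$beta * t)
}

#' Closed-form AUC from zero to infinity
#'
#' For a linear model the total area under the concentration-time curve is
#' exactly `dose / CL`, independent of the distribution parameters.
#'
#' @inheritParams macro_constants
#' @return AUC0-inf in µg·h/mL.
#' @examples
#' auc_closed_form(pk_params(0.44, 2.26, 1.76, 1.0), dose = 8) # 4.545
#' @export
auc_closed_form <- function(params, dose) {
  stopifnot(inherits(params, "pk_params"))
  if (!is.finite(dose) || dose <= 0) stop("dose must be positive", call. = FALSE)
  dose / params$cl
}

# Partial AUC 0..t of the closed-form curve; used by the urine model.
auc_partial <- function(params, dose, t) {
  m <- macro_constants(params, dose)
  m$A / m$alpha * (1 - exp(-m$alpha * t)) + m$B / m$beta * (1 - exp(-m$beta * t))
}
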