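#' Population pharmacokinetic model specification
#'
#' Bundles the typical structural parameters (theta), the diagonal
#' inter-individual variance components (omega^2, lognormal random effects on
#' V1, CL and CL2; V2 carries none) and the proportional residual error SD
#' (sigma, a fraction of the prediction).
#'
#' @param theta A [pk_params()] object of typical values.
#' @param omega2 Named numeric vector `c(v1 = , cl = , cl2 = )` of variances of
#'   the log-scale random effects; all `>= 0`. Reported inter-individual
#'   variability percentages correspond to `100 * sqrt(omega2)`.
#' @param sigma Proportional residual error SD (fraction, e.g. 0.149 = 14.9%).
#' @return An object of class `pop_model`.
#' @examples
#' pop_model_oxaliplatin()
#' @export
pop_model <- function(theta, omega2, sigma) {
  stopifnot(inherits(theta, "pk_params"))
  omega2 <- omega2[c("v1", "cl", "cl2")]
  if (anyNA(omega2) || any(omega2 < 0)) {
    stop("omega2 must supply non-negative variances named v1, cl, cl2", call. = FALSE)
  }
  if (!is.finite(sigma) || sigma <= 0) {
    stop("sigma must be a positive fraction", call. = FALSE)
  }
  structure(list(theta = theta, omega2 = omega2, sigma = sigma),
            class = "pop_model")
}

#' Final oxaliplatin population model estimates
#'
#' The fitted two-compartment population model for intact oxaliplatin in rats:
#' V1 0.44 L/kg, V2 2.26 L/kg, CL 1.76 L/h/kg, CL2 1.0 L/h/kg;
#' inter-individual variability 37.5% (V1), 30.5% (CL), 31.5% (CL2);
#' proportional residual error 14.9%. These are the default truth for the
#' synthetic study generator and the default initial values fallback.
#'
#' @return A [pop_model()] object.
#' @export
pop_model_oxaliplatin <- function() {
  pop_model(
    theta = pk_params(v1 = 0.44, v2 = 2.26, cl = 1.76, cl2 = 1.0),
    omega2 = c(v1 = 0.375^2, cl = 0.305^2, cl2 = 0.315^2),
    sigma = 0.149
  )
}

#' @export
print.pop_model <- function(x, ...) {
  cat("Population PK model (two-compartment IV bolus, lognormal IIV,\n")
  cat("proportional residual error)\n")
  print(x$theta)
  cat(sprintf("  IIV (%%): V1 %.1f, CL %.1f, CL2 %.1f;  sigma %.1f%%\n",
              100 * sqrt(x$omega2[["v1"]]), 100 * sqrt(x$omega2[["cl"]]),
              100 * sqrt(x$omega2[["cl2"]]), 100 * x$sigma))
  invisible(x)
}

#' Tidy a population model into a parameter table
#'
#' Mirrors the conventional population-PK report layout: fixed effects with
#' their composites (CLtot = CL + CL2, Vd = V1 + V2), inter-individual
#' variability as percentages, and the residual error percentage.
#'
#' @param x A `pop_model`.
#' @param ... Unused.
#' @return A tibble with columns `block`, `term`, `unit`, `estimate`.
#' @export
tidy.pop_model <- function(x, ...) {
  th <- x$theta
  tibble::tibble(
    block = c(rep("theta", 4), rep("composite", 2), rep("omega", 3), "sigma"),
    term = c("V1", "V2", "CL", "CL2", "CLtot", "Vd",
             "IIV_V1", "IIV_CL", "IIV_CL2", "sigma_prop"),
    unit = c("L/kg", "L/kg", "L/h/kg", "L/h/kg", "L/h/kg", "L/kg",
             "%", "%", "%", "%"),
    estimate = c(th$v1, th$v2, th$cl, th$cl2, th$cl_tot, th$vd,
                 100 * sqrt(x$omega2[["v1"]]), 100 * sqrt(x$omega2[["cl"]]),
                 100 * sqrt(x$omega2[["cl2"]]), 100 * x$sigma)
  )
}
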