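# broom-style and plotting methods for FOCE fits.

#' @export
print.foce_fit <- function(x, ...) {
  cat("FOCE-ELS population fit\n")
  cat(sprintf("  subjects: %d   observations: %d   -2LL: %.3f\n",
              x$counts[["n_subjects"]], x$counts[["n_obs"]], x$minus2LL))
  cat(sprintf("  converged: %s (%d outer iterations)\n",
              x$convergence, x$iterations))
  print(x$pop)
  invisible(x)
}

#' Tidy parameter table of a FOCE fit
#'
#' One row per reported parameter in the conventional report layout: fixed
#' effects with composites (CLtot, Vd), inter-individual variabilities as
#' percentages, and the proportional residual error percentage, each with its
#' estimation CV%.
#'
#' @param x A `foce_fit`.
#' @param ... Unused.
#' @return A tibble with columns `block`, `term`, `unit`, `estimate`,
#'   `cv_percent`.
#' @export
tidy.foce_fit <- function(x, ...) {
  x$estimates
}

#' One-row model summary of a FOCE fit
#'
#' @param x A `foce_fit`.
#' @param ... Unused.
#' @return A tibble with `minus2LL`, `n_subjects`, `n_obs`, `converged`,
#'   `iterations`.
#' @export
glance.foce_fit <- function(x, ...) {
  tibble::tibble(minus2LL = x$minus2LL,
                 n_subjects = x$counts[["n_subjects"]],
                 n_obs = x$counts[["n_obs"]],
                 converged = x$convergence,
                 iterations = x$iterations)
}

#' Per-observation diagnostics of a FOCE fit
#'
#' @param x A `foce_fit`.
#' @param ... Unused.
#' @return The goodness-of-fit tibble: `ID`, `TAD` (time after dose, h),
#'   `OBS`, `PRED` (population prediction, random effects at zero), `IPRED`
#'   (individual prediction at the empirical Bayes modes), `CWRES`.
#' @export
augment.foce_fit <- function(x, ...) {
  x$gof
}

#' Goodness-of-fit panels for a FOCE fit
#'
#' Standard four-panel display: OBS vs PRED, OBS vs IPRED (identity line),
#' CWRES vs PRED and CWRES vs time after dose (zero line).
#'
#' @param object A `foce_fit`.
#' @param ... Unused.
#' @return A ggplot object (facetted panels).
#' @export
autoplot.foce_fit <- function(object, ...) {
  g <- object$gof
  long <- dplyr::bind_rows(
    tibble::tibble(panel = "OBS vs PRED", x = g$PRED, y = g$OBS, ref = "identity"),
    tibble::tibble(panel = "OBS vs IPRED", x = g$IPRED, y = g$OBS, ref = "identity"),
    tibble::tibble(panel = "CWRES vs PRED", x = g$PRED, y = g$CWRES, ref = "zero"),
    tibble::tibble(panel = "CWRES vs TAD", x = g$TAD, y = g$CWRES, ref = "zero")
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.5, size = 1) +
    ggplot2::geom_abline(
      data = dplyr::filter(dplyr::distinct(long, .data$panel, .data$ref),
                           .data$ref == "identity"),
      ggplot2::aes(slope = 1, intercept = 0), linetype = 2, colour = "grey40"
    ) +
    ggplot2::geom_hline(
      data = dplyr::filter(dplyr::distinct(long, .data$panel, .data$ref),
                           .data$ref == "zero"),
      ggplot2::aes(yintercept = 0), linetype = 2, colour = "grey40"
    ) +
    ggplot2::facet_wrap(~panel, scales = "free") +
    ggplot2::labs(x = NULL, y = NULL, title = "Goodness of fit") +
    ggplot2::theme_bw()
}
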