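# User-tunable bounds of the series definition.

#' Detection parameters for homologue-series search
#'
#' Bundles every bound of the series definition. Defaults are sized for
#' surfactant-type screening in sewage effluent: an m/z difference window
#' wide enough for alkyl (14.016 Th) through propylene-oxide-sized
#' (58.042 Th) units, retention times in seconds, and a minimum series
#' length of 5 members.
#'
#' @param dmz_min,dmz_max Allowed adjacent m/z difference (Th); both
#'   positive, \code{dmz_min <= dmz_max}.
#' @param drt_min,drt_max Allowed adjacent RT difference, in the RT units of
#'   the input (negative \code{drt_min} admits series eluting earlier with
#'   growing mass, as arises in cross-meshed subtraction series).
#' @param ddrt_max Maximum absolute change of the RT difference between
#'   consecutive adjacent pairs (same RT units).
#' @param n_min Minimum reported series length, at least 3.
#' @param epsilon An \code{\link{epsilon_model}}; the maximum +/- m/z
#'   measurement error.
#' @param lambda Smoothing-spline roughness penalty for the RT-vs-m/z fit;
#'   \code{0} means an interpolating fit (check always passes on distinct
#'   m/z). Larger values enforce smoother RT trends.
#' @param r2_min Minimum coefficient of determination of the spline fit, in
#'   \code{[0, 1]}; applied to tuples of length >= 4.
#' @param elements Element symbols assumed possible in the homologue unit;
#'   sets the mass-defect slope bounds (see \code{\link{gamma_bounds}}).
#' @return An object of class \code{detection_params}.
#' @examples
#' detection_params(dmz_min = 14, dmz_max = 60)
#' @export
detection_params <- function(dmz_min = 14, dmz_max = 60,
                             drt_min = -60, drt_max = 180,
                             ddrt_max = 30, n_min = 5L,
                             epsilon = epsilon_model(0.002),
                             lambda = 1e-4, r2_min = 0.9,
                             elements = c("C", "H", "N", "O", "S",
                                          "Cl", "Br")) {
  stopifnot(inherits(epsilon, "epsilon_model"))
  if (!(dmz_min > 0 && dmz_min <= dmz_max)) {
    stop("need 0 < dmz_min <= dmz_max", call. = FALSE)
  }
  if (drt_min > drt_max) stop("need drt_min <= drt_max", call. = FALSE)
  if (ddrt_max < 0) stop("'ddrt_max' must be non-negative", call. = FALSE)
  if (n_min < 3) stop("'n_min' must be at least 3", call. = FALSE)
  if (lambda < 0) stop("'lambda' must be non-negative", call. = FALSE)
  if (r2_min < 0 || r2_min > 1) stop("'r2_min' must lie in [0, 1]",
                                     call. = FALSE)
  structure(list(dmz_min = dmz_min, dmz_max = dmz_max,
                 drt_min = drt_min, drt_max = drt_max,
                 ddrt_max = ddrt_max, n_min = as.integer(n_min),
                 epsilon = epsilon, lambda = lambda, r2_min = r2_min,
                 elements = elements),
            class = "detection_params")
}

#' @export
print.detection_params <- function(x, ...) {
  cat("homologue-series detection parameters\n")
  cat(sprintf("  dmz:   [%g; %g] Th\n", x$dmz_min, x$dmz_max))
  cat(sprintf("  drt:   [%g; %g], |ddrt| <= %g\n",
              x$drt_min, x$drt_max, x$ddrt_max))
  cat(sprintf("  n_min: %d, lambda: %g, r2_min: %g\n",
              x$n_min, x$lambda, x$r2_min))
  cat(sprintf("  epsilon: %g (%s); elements: %s\n", x$epsilon$value,
              x$epsilon$mode, paste(x$elements, collapse = ",")))
  invisible(x)
}
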