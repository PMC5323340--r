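# The series-definition predicates, shared by the k-d-tree search path, the
# recombination stage and the independent output validator.

#' Adjacent-pair feasibility under the series definition
#'
#' Vectorized check whether peak 2 can directly follow peak 1 in a homologue
#' series: the m/z difference lies in \code{[dmz_min, dmz_max]}, the RT
#' difference in \code{[drt_min, drt_max]}, and the mass-defect difference in
#' \code{[gamma_min*d - 2*eps, gamma_max*d + 2*eps]} for some wrap shift in
#' \code{{-1, 0, +1}} (defects are stored in \code{[-0.5, 0.5)}, so a true
#' defect change can appear shifted by one full unit). \code{eps} is
#' evaluated at the lower-m/z peak of the pair.
#'
#' @param mz1,rt1 m/z and RT of the lower-m/z peak (vectors recycle).
#' @param mz2,rt2 m/z and RT of the candidate successor.
#' @param params A \code{\link{detection_params}}.
#' @param gamma A \code{\link{gamma_bounds}}; defaults to the bounds of
#'   \code{params$elements}.
#' @return Logical vector.
#' @export
pair_feasible <- function(mz1, rt1, mz2, rt2, params, gamma = NULL) {
  if (is.null(gamma)) gamma <- gamma_bounds(params$elements)
  d <- mz2 - mz1
  ok <- d >= params$dmz_min & d <= params$dmz_max
  drt <- rt2 - rt1
  ok <- ok & drt >= params$drt_min & drt <= params$drt_max
  eps <- epsilon_at(params$epsilon, mz1)
  dd <- mass_defect(mz2) - mass_defect(mz1)
  lo <- gamma$gamma_min * d - 2 * eps
  hi <- gamma$gamma_max * d + 2 * eps
  wrap_ok <- (dd >= lo & dd <= hi) |
    (dd - 1 >= lo & dd - 1 <= hi) |
    (dd + 1 >= lo & dd + 1 <= hi)
  ok & wrap_ok
}

#' Consecutive-pair (triplet-level) feasibility
#'
#' Vectorized check of the two constraints linking consecutive adjacent
#' pairs (p1,p2) and (p2,p3): the change of the m/z difference must stay
#' within \code{[-4*eps, 4*eps]} with \code{eps} evaluated at the middle
#' peak's m/z, and the change of the RT difference must not exceed
#' \code{ddrt_max} in absolute value.
#'
#' @param mz1,rt1,mz2,rt2,mz3,rt3 Coordinates of the three m/z-ordered peaks.
#' @inheritParams pair_feasible
#' @return Logical vector.
#' @export
step_feasible <- function(mz1, rt1, mz2, rt2, mz3, rt3, params) {
  eps <- epsilon_at(params$epsilon, mz2)
  d12 <- mz2 - mz1
  d23 <- mz3 - mz2
  ok <- abs(d23 - d12) <= 4 * eps
  ok & abs((rt3 - rt2) - (rt2 - rt1)) <= params$ddrt_max
}

#' Validate a candidate series tuple against the full series definition
#'
#' Walks the tuple and re-checks every constraint independently of how the
#' tuple was assembled: distinct ids, strictly increasing m/z, every adjacent
#' pair feasible, every consecutive pair of pairs feasible, and (for length
#' >= 4) the smoothing-spline RT model fit.
#'
#' @param ids Integer vector of peak ids, ordered by increasing m/z.
#' @param peaks The \code{peaklist} the ids refer to.
#' @param params A \code{\link{detection_params}}.
#' @param gamma Optional precomputed \code{\link{gamma_bounds}}.
#' @param check_spline Whether to include the spline fit check.
#' @return \code{TRUE} or \code{FALSE}.
#' @export
validate_tuple <- function(ids, peaks, params, gamma = NULL,
                           check_spline = TRUE) {
  if (length(ids) < 3L || anyDuplicated(ids)) return(FALSE)
  if (is.null(gamma)) gamma <- gamma_bounds(params$elements)
  i <- match(ids, peaks$peak_id)
  if (anyNA(i)) return(FALSE)
  mz <- peaks$mz[i]; rt <- peaks$rt[i]
  if (any(diff(mz) <= 0)) return(FALSE)
  n <- length(ids)
  if (!all(pair_feasible(mz[-n], rt[-n], mz[-1], rt[-1], params, gamma))) {
    return(FALSE)
  }
  if (n >= 3L) {
    j <- seq_len(n - 2L)
    if (!all(step_feasible(mz[j], rt[j], mz[j + 1], rt[j + 1],
                           mz[j + 2], rt[j + 2], params))) {
      return(FALSE)
    }
  }
  if (check_spline && n >= 4L) {
    sc <- spline_check(mz, rt, params$lambda, params$r2_min)
    if (!sc$pass) return(FALSE)
  }
  TRUE
}
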