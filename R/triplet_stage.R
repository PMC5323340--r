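# Stage 1: enumerate all feasible peak triplets.
#
# For every peak taken as the middle member of a candidate triplet, two
# axis-aligned boxes are queried in the 4-d embedding: H (possible
# successors at higher m/z) and L (possible predecessors at lower m/z).
# Because stored mass defects live in [-0.5, 0.5), a true defect change can
# appear shifted by a whole unit; where the center's defect is close enough
# to the boundary for that to happen, additional boxes shifted by +/-1 on
# the two defect dimensions are queried. All candidates are then re-checked
# with the exact predicates in unwrapped arithmetic, so the boxes only need
# to be supersets and are padded by a tiny margin against floating-point
# boundary effects.

.BOX_PAD <- 1e-9

# Which wrap shifts w of the pair predicate can be active for a center with
# this defect? `change_rng` is the widest possible unwrapped defect change.
.wrap_shifts <- function(defect, change_rng, side) {
  w <- 0L
  if (side == "H") {
    if (defect + change_rng[2] >= 0.5 - .BOX_PAD) w <- c(w, 1L)
    if (defect + change_rng[1] < -0.5 + .BOX_PAD) w <- c(w, -1L)
  } else {
    if (defect - change_rng[2] < -0.5 + .BOX_PAD) w <- c(w, 1L)
    if (defect - change_rng[1] >= 0.5 - .BOX_PAD) w <- c(w, -1L)
  }
  w
}

#' Subspace query boxes for one center peak
#'
#' Builds the closed 4-d boxes defining the successor subspace H and the
#' predecessor subspace L of a center peak: dimension 1 is the m/z window
#' \code{[dmz_min, dmz_max]} away from the center, dimensions 2 and 3 bound
#' the feasible mass-defect change (one-sided, widened by \code{2*eps} with
#' \code{eps} at the center m/z), and dimension 4 is the RT window. Where
#' the mass-defect wrap can apply, each side carries up to three boxes whose
#' defect dimensions are shifted by whole units.
#'
#' @param center_vec Length-4 embedded vector of the center peak.
#' @param center_defect Stored mass defect of the center peak.
#' @param params A \code{\link{detection_params}}.
#' @param gamma A \code{\link{gamma_bounds}}.
#' @return List with elements \code{H} and \code{L}, each a list of
#'   \code{list(lo, hi)} boxes.
#' @export
subspace_boxes <- function(center_vec, center_defect, params, gamma) {
  center_vec <- unname(center_vec)
  eps <- epsilon_at(params$epsilon, center_vec[1])
  dmz <- c(params$dmz_min, params$dmz_max)
  change_rng <- c(min(gamma$gamma_min * dmz) - 2 * eps,
                  max(gamma$gamma_max * dmz) + 2 * eps)
  pad <- .BOX_PAD
  mk_H <- function(w) {
    list(lo = c(center_vec[1] + params$dmz_min - pad,
                center_vec[2] - 2 * eps - w - pad,
                -Inf,
                center_vec[4] + params$drt_min - pad),
         hi = c(center_vec[1] + params$dmz_max + pad,
                Inf,
                center_vec[3] + 2 * eps - w + pad,
                center_vec[4] + params$drt_max + pad))
  }
  mk_L <- function(w) {
    list(lo = c(center_vec[1] - params$dmz_max - pad,
                -Inf,
                center_vec[3] - 2 * eps + w - pad,
                center_vec[4] - params$drt_max - pad),
         hi = c(center_vec[1] - params$dmz_min + pad,
                center_vec[2] + 2 * eps + w + pad,
                Inf,
                center_vec[4] - params$drt_min + pad))
  }
  list(H = lapply(.wrap_shifts(center_defect, change_rng, "H"), mk_H),
       L = lapply(.wrap_shifts(center_defect, change_rng, "L"), mk_L))
}

#' Stage 1: find all feasible triplets
#'
#' Enumerates every ordered triplet (l, c, h) of peaks with strictly
#' increasing m/z such that both adjacent pairs satisfy the series
#' definition and the triplet-level constraints hold (m/z difference change
#' within \code{[-4*eps, 4*eps]} at the middle peak, RT difference change at
#' most \code{ddrt_max}). Each peak acts once as the center c; candidate
#' predecessors/successors come from k-d tree range queries.
#'
#' @param peaks A \code{peaklist}.
#' @param params A \code{\link{detection_params}}.
#' @param gamma Optional precomputed \code{\link{gamma_bounds}}.
#' @return Integer matrix with columns \code{p1}, \code{p2}, \code{p3}
#'   (peak ids by increasing m/z), rows sorted lexicographically;
#'   zero rows when no triplet exists.
#' @export
find_triplets <- function(peaks, params, gamma = NULL) {
  stopifnot(inherits(params, "detection_params"))
  empty <- matrix(integer(0), ncol = 3L,
                  dimnames = list(NULL, c("p1", "p2", "p3")))
  if (nrow(peaks) < 3L) return(empty)
  if (is.null(gamma)) gamma <- gamma_bounds(params$elements)
  vec <- embed_peaks(peaks, gamma)
  defect <- mass_defect(peaks$mz)
  tree <- kdtree_build(vec)
  res <- vector("list", nrow(peaks))
  for (ci in seq_len(nrow(peaks))) {
    boxes <- subspace_boxes(vec[ci, ], defect[ci], params, gamma)
    hs <- unique(unlist(lapply(boxes$H, function(b)
      kdtree_query(tree, b$lo, b$hi))))
    hs <- hs[hs != ci]
    if (length(hs) > 0L) {
      hs <- hs[pair_feasible(peaks$mz[ci], peaks$rt[ci],
                             peaks$mz[hs], peaks$rt[hs], params, gamma)]
    }
    if (length(hs) == 0L) next
    ls <- unique(unlist(lapply(boxes$L, function(b)
      kdtree_query(tree, b$lo, b$hi))))
    ls <- ls[ls != ci]
    if (length(ls) > 0L) {
      ls <- ls[pair_feasible(peaks$mz[ls], peaks$rt[ls],
                             peaks$mz[ci], peaks$rt[ci], params, gamma)]
    }
    if (length(ls) == 0L) next
    grid <- expand.grid(l = ls, h = hs, KEEP.OUT.ATTRS = FALSE)
    keep <- step_feasible(peaks$mz[grid$l], peaks$rt[grid$l],
                          peaks$mz[ci], peaks$rt[ci],
                          peaks$mz[grid$h], peaks$rt[grid$h], params)
    if (!any(keep)) next
    res[[ci]] <- cbind(p1 = peaks$peak_id[grid$l[keep]],
                       p2 = peaks$peak_id[ci],
                       p3 = peaks$peak_id[grid$h[keep]])
  }
  res <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
  if (is.null(res)) return(empty)
  res <- res[order(res[, 1], res[, 2], res[, 3]), , drop = FALSE]
  res
}
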