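# Shared fixtures and independent oracles.
#
# The triplet oracle enumerates candidate triples directly from the series-
# definition predicates (no embedding, no k-d tree, no box queries), so it
# is an independent check of the stage-1 search path.

random_peaklist <- function(n, mz_range = c(100, 500), rt_range = c(0, 600)) {
  as_peaklist(data.frame(mz = runif(n, mz_range[1], mz_range[2]),
                         rt = runif(n, rt_range[1], rt_range[2]),
                         intensity = 10^runif(n, 3, 7)))
}

# Exhaustive stage-1 oracle: all ordered (l, c, h) triples with increasing
# m/z, checked pair by pair and step by step.
brute_triplets <- function(peaks, params, gamma = NULL) {
  if (is.null(gamma)) gamma <- gamma_bounds(params$elements)
  n <- nrow(peaks)
  idx <- which(outer(peaks$mz, peaks$mz, FUN = function(a, b) b > a),
               arr.ind = TRUE)
  ok <- pair_feasible(peaks$mz[idx[, 1]], peaks$rt[idx[, 1]],
                      peaks$mz[idx[, 2]], peaks$rt[idx[, 2]], params, gamma)
  idx <- idx[ok, , drop = FALSE]
  out <- list()
  for (ci in seq_len(n)) {
    ls <- idx[idx[, 2] == ci, 1]
    hs <- idx[idx[, 1] == ci, 2]
    if (length(ls) == 0L || length(hs) == 0L) next
    g <- expand.grid(l = ls, h = hs, KEEP.OUT.ATTRS = FALSE)
    keep <- step_feasible(peaks$mz[g$l], peaks$rt[g$l],
                          peaks$mz[ci], peaks$rt[ci],
                          peaks$mz[g$h], peaks$rt[g$h], params)
    if (any(keep)) {
      out[[length(out) + 1L]] <- cbind(peaks$peak_id[g$l[keep]],
                                       peaks$peak_id[ci],
                                       peaks$peak_id[g$h[keep]])
    }
  }
  m <- if (length(out) > 0L) do.call(rbind, out)
  else matrix(integer(0), ncol = 3L)
  m <- m[order(m[, 1], m[, 2], m[, 3]), , drop = FALSE]
  dimnames(m) <- list(NULL, c("p1", "p2", "p3"))
  m
}

# A hand-sized peak list forming one exact CH2 series with linear RT.
ch2_series_peaks <- function(n = 5, mz0 = 200, rt0 = 100, rt_step = 30) {
  dmz <- unit_mass("CH2")
  as_peaklist(data.frame(mz = mz0 + (seq_len(n) - 1) * dmz,
                         rt = rt0 + (seq_len(n) - 1) * rt_step,
                         intensity = 1e5))
}

default_test_params <- function(...) {
  args <- list(dmz_min = 10, dmz_max = 60, drt_min = -60, drt_max = 150,
               ddrt_max = 30, n_min = 3, epsilon = epsilon_model(0.002),
               lambda = 1e-4, r2_min = 0.9)
  args[names(list(...))] <- list(...)
  do.call(detection_params, args)
}
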