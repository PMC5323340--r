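# Peak-sharing series pairs: intersection angles, SOM-ready property
# vectors, and cross-sample mass-difference prevalence.

#' Extract all peak-sharing series pairs
#'
#' Every unordered pair of series sharing at least one peak id appears
#' exactly once. Within a pair, series x is the one with the larger mean
#' m/z difference (ties by smaller series index), so downstream property
#' vectors are order-normalized.
#'
#' @param series A \code{homol_series_list} (see \code{\link{detect_series}}).
#' @return Data frame with columns \code{series_x}, \code{series_y}
#'   (indices into \code{series}), \code{n_shared}, \code{mean_dmz_x},
#'   \code{mean_drt_x}, \code{mean_dmz_y}, \code{mean_drt_y}.
#' @export
find_pairs <- function(series) {
  empty <- data.frame(series_x = integer(), series_y = integer(),
                      n_shared = integer(), mean_dmz_x = numeric(),
                      mean_drt_x = numeric(), mean_dmz_y = numeric(),
                      mean_drt_y = numeric())
  if (length(series) < 2L) return(empty)
  # invert peak -> series membership, then enumerate co-membership
  ids <- lapply(series, function(s) s$peaks)
  memb <- data.frame(peak = unlist(ids),
                     ser = rep(seq_along(ids), lengths(ids)))
  pairs <- new.env(parent = emptyenv())
  for (g in split(memb$ser, memb$peak)) {
    g <- sort(unique(g))
    if (length(g) < 2L) next
    cmb <- utils::combn(g, 2L)
    for (j in seq_len(ncol(cmb))) {
      key <- paste(cmb[1L, j], cmb[2L, j], sep = "_")
      prev <- pairs[[key]]
      pairs[[key]] <- if (is.null(prev)) 1L else prev + 1L
    }
  }
  keys <- sort(ls(pairs))
  if (length(keys) == 0L) return(empty)
  ab <- do.call(rbind, strsplit(keys, "_", fixed = TRUE))
  a <- as.integer(ab[, 1L]); b <- as.integer(ab[, 2L])
  n_shared <- vapply(keys, function(k) pairs[[k]], integer(1))
  dmz_a <- vapply(series, function(s) s$mean_dmz, numeric(1))[a]
  dmz_b <- vapply(series, function(s) s$mean_dmz, numeric(1))[b]
  drt_a <- vapply(series, function(s) s$mean_drt, numeric(1))[a]
  drt_b <- vapply(series, function(s) s$mean_drt, numeric(1))[b]
  swap <- dmz_b > dmz_a
  out <- data.frame(
    series_x = ifelse(swap, b, a), series_y = ifelse(swap, a, b),
    n_shared = unname(n_shared),
    mean_dmz_x = ifelse(swap, dmz_b, dmz_a),
    mean_drt_x = ifelse(swap, drt_b, drt_a),
    mean_dmz_y = ifelse(swap, dmz_a, dmz_b),
    mean_drt_y = ifelse(swap, drt_a, drt_b))
  rownames(out) <- NULL
  out[order(out$series_x, out$series_y), , drop = FALSE]
}

#' Intersection angle of a series pair
#'
#' Each series is represented by the vector of its mean RT difference and
#' mean m/z difference, scaled by the ranges of those means over all series
#' of the sample; theta is the angle between the two vectors (cosine
#' clamped to [-1, 1]). theta = 0 means the two series run fully
#' superjacent in the RT-vs-m/z plane.
#'
#' @param drt_x,dmz_x,drt_y,dmz_y Mean adjacent RT and m/z differences of
#'   the two series (vectors recycle).
#' @param c_drt,c_dmz Positive scale constants: the ranges (max - min) of
#'   the mean RT and m/z differences over all series.
#' @return Numeric vector of angles in radians, in \code{[0, pi]}.
#' @export
intersection_angle <- function(drt_x, dmz_x, drt_y, dmz_y, c_drt, c_dmz) {
  stopifnot(c_drt > 0, c_dmz > 0)
  ux1 <- drt_x / c_drt; ux2 <- dmz_x / c_dmz
  uy1 <- drt_y / c_drt; uy2 <- dmz_y / c_dmz
  dot <- ux1 * uy1 + ux2 * uy2
  nx <- sqrt(ux1^2 + ux2^2); ny <- sqrt(uy1^2 + uy2^2)
  if (any(nx == 0 | ny == 0)) {
    stop("zero-norm series vector: mean dmz must be positive", call. = FALSE)
  }
  acos(pmin(1, pmax(-1, dot / (nx * ny))))
}

#' Angles and superjacency classification for all pairs
#'
#' Convenience wrapper: computes the scale constants from the series list
#' (ranges of mean RT and m/z differences; a degenerate zero range falls
#' back to 1 so single-unit samples remain well-defined), the intersection
#' angle of each pair, and the superjacent/meshed label using a histogram-
#' derived default threshold of 0.08*pi.
#'
#' @param series A \code{homol_series_list}.
#' @param pairs Optionally a precomputed \code{\link{find_pairs}} table.
#' @param theta_threshold Pairs with \code{theta < theta_threshold} are
#'   labeled superjacent.
#' @return The pair table with added columns \code{theta} and
#'   \code{superjacent}.
#' @export
pair_angles <- function(series, pairs = find_pairs(series),
                        theta_threshold = 0.08 * pi) {
  if (nrow(pairs) == 0L) {
    pairs$theta <- numeric(0)
    pairs$superjacent <- logical(0)
    return(pairs)
  }
  dmz <- vapply(series, function(s) s$mean_dmz, numeric(1))
  drt <- vapply(series, function(s) s$mean_drt, numeric(1))
  c_dmz <- diff(range(dmz)); c_drt <- diff(range(drt))
  if (c_dmz <= 0) c_dmz <- 1
  if (c_drt <= 0) c_drt <- 1
  pairs$theta <- intersection_angle(pairs$mean_drt_x, pairs$mean_dmz_x,
                                    pairs$mean_drt_y, pairs$mean_dmz_y,
                                    c_drt, c_dmz)
  pairs$superjacent <- pairs$theta < theta_threshold
  pairs
}

#' SOM-ready property vectors of series pairs
#'
#' Builds the 4-dimensional property vector of each pair: the mean RT and
#' m/z differences of both series, each scaled by the expected measurement
#' uncertainty of that quantity, with series x the larger-mean-dmz member.
#' The vectors are intended as input to external clustering tools such as a
#' self-organizing map; no clustering is performed here.
#'
#' @param pairs A \code{\link{find_pairs}} table.
#' @param c_hat_drt,c_hat_dmz Positive scale constants: expected mean
#'   uncertainties of the RT and m/z differences.
#' @return Numeric matrix with columns \code{drt_x}, \code{dmz_x},
#'   \code{drt_y}, \code{dmz_y}; one row per pair.
#' @export
pair_vectors <- function(pairs, c_hat_drt, c_hat_dmz) {
  stopifnot(c_hat_drt > 0, c_hat_dmz > 0)
  cbind(drt_x = pairs$mean_drt_x / c_hat_drt,
        dmz_x = pairs$mean_dmz_x / c_hat_dmz,
        drt_y = pairs$mean_drt_y / c_hat_drt,
        dmz_y = pairs$mean_dmz_y / c_hat_dmz)
}

#' Cross-sample prevalence of series mass differences
#'
#' For every observed series mean m/z difference, counts in how many samples
#' at least one series has a mean m/z difference within a moving window of
#' \code{+/- window} Th, emulating a stacked cross-site comparison of
#' mass-difference distributions.
#'
#' @param per_sample_series Named list: one \code{homol_series_list} (or a
#'   numeric vector of mean m/z differences) per sample.
#' @param window Half-width of the moving window in Th (default 0.005,
#'   i.e. +/- 5 mu).
#' @return Data frame with columns \code{dmz} (sorted unique observed
#'   values) and \code{n_samples}.
#' @export
delta_mz_prevalence <- function(per_sample_series, window = 5e-3) {
  stopifnot(length(per_sample_series) >= 1L, window > 0)
  vals <- lapply(per_sample_series, function(s) {
    if (is.numeric(s)) s
    else vapply(s, function(x) x$mean_dmz, numeric(1))
  })
  dmz <- sort(unique(unlist(vals)))
  if (length(dmz) == 0L) {
    return(data.frame(dmz = numeric(), n_samples = integer()))
  }
  counts <- vapply(dmz, function(v) {
    sum(vapply(vals, function(sv) any(abs(sv - v) <= window), logical(1)))
  }, numeric(1))
  data.frame(dmz = dmz, n_samples = as.integer(counts))
}
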