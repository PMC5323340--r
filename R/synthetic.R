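# Synthetic peak lists with planted homologue series and known ground
# truth, plus a randomization-based false-series rate estimate.

#' Specification of one planted homologue series
#'
#' Describes a synthetic series to plant into a peak list: its repeating
#' unit (formula or direct m/z spacing), charge, start coordinates, length,
#' retention-time increment model, noise levels, optional gaps (omitted
#' members) and optional isobaric twins (a close-m/z duplicate next to a
#' member, the classic source of 2^n combinatorial series).
#'
#' @param unit Molecular formula of the repeating unit (e.g. \code{"CH2"},
#'   \code{"C2H4O"}) or a numeric m/z spacing in Th.
#' @param z Charge; formula-derived spacings are divided by \code{z}.
#' @param mz_start m/z of the first member (Th).
#' @param length Number of members (>= 3) before gaps are applied.
#' @param rt_start RT of the first member.
#' @param rt_step Initial adjacent RT difference.
#' @param rt_model \code{"constant"} (equal steps), \code{"decaying"}
#'   (each step is \code{rt_decay} times the previous, the typical
#'   saturating elution trend of long homologue chains) or \code{"curved"}
#'   (smooth quadratic taper of the step).
#' @param rt_decay Step ratio for the decaying model.
#' @param intensity Member intensity (single value or per-member vector).
#' @param mz_noise_sd,rt_noise_sd Gaussian noise standard deviations applied
#'   to member m/z and RT.
#' @param gaps Integer member positions to delete (series gaps).
#' @param twins Integer member positions that receive an isobaric twin peak.
#' @param twin_mz_offset,twin_rt_offset Coordinate offsets of twin peaks.
#' @return An object of class \code{planted_series}.
#' @export
planted_series <- function(unit = "CH2", z = 1L, mz_start = 300,
                           length = 8L, rt_start = 300, rt_step = 30,
                           rt_model = c("constant", "decaying", "curved"),
                           rt_decay = 0.9, intensity = 1e5,
                           mz_noise_sd = 0, rt_noise_sd = 0,
                           gaps = integer(0), twins = integer(0),
                           twin_mz_offset = 5e-4, twin_rt_offset = 2) {
  rt_model <- match.arg(rt_model)
  if (length < 3L) stop("'length' must be at least 3", call. = FALSE)
  if (mz_noise_sd < 0 || rt_noise_sd < 0) {
    stop("noise standard deviations must be non-negative", call. = FALSE)
  }
  if (any(gaps < 1L | gaps > length) || any(twins < 1L | twins > length)) {
    stop("'gaps' and 'twins' must be member positions in 1..length",
         call. = FALSE)
  }
  dmz <- if (is.numeric(unit)) unit / z else unit_mass(unit, z)
  if (dmz <= 0) stop("unit spacing must be positive", call. = FALSE)
  structure(list(unit = unit, z = z, dmz = dmz, mz_start = mz_start,
                 length = as.integer(length), rt_start = rt_start,
                 rt_step = rt_step, rt_model = rt_model,
                 rt_decay = rt_decay, intensity = intensity,
                 mz_noise_sd = mz_noise_sd, rt_noise_sd = rt_noise_sd,
                 gaps = as.integer(gaps), twins = as.integer(twins),
                 twin_mz_offset = twin_mz_offset,
                 twin_rt_offset = twin_rt_offset),
            class = "planted_series")
}

.series_coords <- function(spec) {
  n <- spec$length
  steps <- switch(spec$rt_model,
    constant = rep(spec$rt_step, n - 1L),
    decaying = spec$rt_step * spec$rt_decay^(seq_len(n - 1L) - 1L),
    curved = spec$rt_step * (1 - 0.5 * ((seq_len(n - 1L) - 1L) /
                                          max(1L, n - 2L))^2))
  data.frame(position = seq_len(n),
             mz = spec$mz_start + (seq_len(n) - 1L) * spec$dmz,
             rt = spec$rt_start + c(0, cumsum(steps)))
}

#' Simulate a picked-peak list with planted series
#'
#' Generates a synthetic LC-HRMS peak list: every planted series member
#' (with noise, gaps and isobaric twins applied) plus uniformly distributed
#' background peaks with log-uniform intensities. Fully reproducible for a
#' given seed.
#'
#' @param specs List of \code{\link{planted_series}} objects (may be empty).
#' @param n_background Number of uniform background peaks.
#' @param mz_range,rt_range Background coordinate ranges.
#' @param intensity_range Background intensity range (log-uniform draw).
#' @param seed Integer random seed (mandatory for reproducibility).
#' @return List with \code{peaks} (a \code{peaklist}) and \code{truth}, a
#'   data frame mapping each peak id to its origin: \code{series} (index
#'   into \code{specs}, NA for background), \code{position} (member
#'   position) and \code{role} (\code{"member"}, \code{"twin"} or
#'   \code{"background"}).
#' @examples
#' sim <- simulate_peaklist(list(planted_series()), n_background = 100,
#'                          seed = 7)
#' table(sim$truth$role)
#' @export
simulate_peaklist <- function(specs = list(), n_background = 0L,
                              mz_range = c(100, 1000),
                              rt_range = c(60, 1500),
                              intensity_range = c(1e3, 1e7), seed) {
  if (missing(seed)) stop("'seed' is required", call. = FALSE)
  stopifnot(mz_range[1] > 0, mz_range[1] < mz_range[2],
            rt_range[1] < rt_range[2], n_background >= 0)
  set.seed(as.integer(seed))
  rows <- list()
  for (si in seq_along(specs)) {
    spec <- specs[[si]]
    stopifnot(inherits(spec, "planted_series"))
    co <- .series_coords(spec)
    co$mz <- co$mz + stats::rnorm(nrow(co), 0, spec$mz_noise_sd)
    co$rt <- co$rt + stats::rnorm(nrow(co), 0, spec$rt_noise_sd)
    inten <- rep_len(spec$intensity, nrow(co))
    keep <- !(co$position %in% spec$gaps)
    rows[[length(rows) + 1L]] <- data.frame(
      mz = co$mz[keep], rt = co$rt[keep], intensity = inten[keep],
      series = si, position = co$position[keep], role = "member")
    tw <- intersect(spec$twins, co$position[keep])
    if (length(tw) > 0L) {
      ti <- match(tw, co$position)
      rows[[length(rows) + 1L]] <- data.frame(
        mz = co$mz[ti] + spec$twin_mz_offset,
        rt = co$rt[ti] + spec$twin_rt_offset,
        intensity = inten[ti], series = si, position = tw, role = "twin")
    }
  }
  if (n_background > 0L) {
    rows[[length(rows) + 1L]] <- data.frame(
      mz = stats::runif(n_background, mz_range[1], mz_range[2]),
      rt = stats::runif(n_background, rt_range[1], rt_range[2]),
      intensity = exp(stats::runif(n_background, log(intensity_range[1]),
                                   log(intensity_range[2]))),
      series = NA_integer_, position = NA_integer_, role = "background")
  }
  df <- if (length(rows) > 0L) do.call(rbind, rows)
  else data.frame(mz = numeric(), rt = numeric(), intensity = numeric(),
                  series = integer(), position = integer(),
                  role = character())
  ord <- order(df$mz, df$rt, df$intensity)  # same sort as as_peaklist
  peaks <- as_peaklist(df[c("mz", "rt", "intensity")])
  truth <- data.frame(peak_id = seq_along(ord),
                      series = df$series[ord], position = df$position[ord],
                      role = df$role[ord])
  list(peaks = peaks, truth = truth)
}

#' Randomization estimate of the false-series rate
#'
#' Destroys real series structure by re-pairing the (m/z, mass-defect)
#' coordinates with the RT coordinates across peaks (a permutation of the
#' RT column), which preserves both marginal distributions exactly, then
#' re-runs \code{\link{detect_series}} and records the fraction of peaks
#' assigned to at least one series. The mean over permutations estimates
#' how much series assignment is expected by chance alone.
#'
#' @param peaks A \code{peaklist}.
#' @param params A \code{\link{detection_params}}.
#' @param n_permutations Number of RT permutations (>= 1).
#' @param seed Integer random seed.
#' @return List with \code{mean}, \code{sd} (NA for a single permutation)
#'   and the per-permutation \code{rates}.
#' @export
estimate_false_series_rate <- function(peaks, params, n_permutations = 10L,
                                       seed) {
  if (missing(seed)) stop("'seed' is required", call. = FALSE)
  stopifnot(n_permutations >= 1L)
  set.seed(as.integer(seed))
  rates <- vapply(seq_len(n_permutations), function(i) {
    perm <- as_peaklist(data.frame(mz = peaks$mz,
                                   rt = sample(peaks$rt),
                                   intensity = peaks$intensity))
    assigned_fraction(detect_series(perm, params), perm)
  }, numeric(1))
  list(mean = mean(rates),
       sd = if (n_permutations > 1L) stats::sd(rates) else NA_real_,
       rates = rates)
}

#' Fraction of peaks assigned to at least one series
#'
#' @param series A \code{homol_series_list}.
#' @param peaks The \code{peaklist} the series were detected in.
#' @return Numeric scalar in \code{[0, 1]}.
#' @export
assigned_fraction <- function(series, peaks) {
  if (nrow(peaks) == 0L) return(0)
  length(unique(unlist(lapply(series, function(s) s$peaks)))) / nrow(peaks)
}
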