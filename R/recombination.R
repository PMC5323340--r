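# Stage 2: recursive recombination of triplets into longer series tuples.
#
# Two n-tuples x and y merge into an (n+1)-tuple when the first n-1 peaks of
# one equal the last n-1 peaks of the other. Tuples that extend are removed
# from their set; the rest are retained. Redundant sub-tuples arising from a
# regular omission of peaks in tuples of length >= 5 are filtered at each
# recursion.

.tuple_key <- function(ids) paste(ids, collapse = "-")

#' Smoothing-spline retention-time model check
#'
#' Fits a cubic smoothing spline RT ~ m/z with roughness penalty
#' \code{lambda} and computes the coefficient of determination
#' R2 = 1 - SS_res/SS_tot at the data points. \code{lambda = 0} requests an
#' interpolating fit, which reproduces the points exactly (R2 = 1) whenever
#' the m/z values are distinct. A tuple with identical RT everywhere has
#' SS_tot = 0 and passes by convention (R2 reported as 1). Tuples with
#' fewer than 4 points are not checked (a cubic smoothing spline is
#' degenerate there; the RT-step constraint already restricts triplets).
#'
#' @param mz,rt Numeric vectors of the tuple's m/z and RT values, m/z
#'   strictly increasing.
#' @param lambda Non-negative roughness penalty (see
#'   \code{\link[stats]{smooth.spline}}; larger is smoother).
#' @param r2_min Pass threshold for R2.
#' @return List with \code{pass} (logical) and \code{r2} (NA for n < 4).
#' @export
spline_check <- function(mz, rt, lambda, r2_min) {
  n <- length(mz)
  if (n < 4L) return(list(pass = TRUE, r2 = NA_real_))
  sstot <- sum((rt - mean(rt))^2)
  if (sstot <= 0) return(list(pass = TRUE, r2 = 1))
  if (lambda <= 0) return(list(pass = TRUE, r2 = 1))  # interpolating fit
  fit <- tryCatch(
    stats::smooth.spline(mz, rt, lambda = lambda, all.knots = TRUE,
                         keep.data = FALSE),
    error = function(e) NULL)
  if (is.null(fit)) {
    # degenerate fit (e.g. numerically collapsed abscissa): fall back to the
    # interpolation limit
    return(list(pass = TRUE, r2 = 1))
  }
  fitted <- stats::predict(fit, mz)$y
  r2 <- 1 - sum((rt - fitted)^2) / sstot
  list(pass = r2 >= r2_min, r2 = r2)
}

#' One recombination step
#'
#' Merges every overlapping pair of equal-length tuples into a new tuple one
#' longer, keeping only merges whose result passes the full series
#' definition (including the spline check). Tuples that took part in at
#' least one merge are removed from the input set; the rest are retained.
#'
#' @param tuples List of integer id vectors, all the same length n >= 3,
#'   each ordered by increasing m/z.
#' @param peaks The \code{peaklist} the ids refer to.
#' @param params A \code{\link{detection_params}}.
#' @param gamma Optional precomputed \code{\link{gamma_bounds}}.
#' @return List with \code{extended} (the new (n+1)-tuples, deduplicated)
#'   and \code{retained} (input tuples that did not merge).
#' @export
merge_step <- function(tuples, peaks, params, gamma = NULL) {
  if (length(tuples) == 0L) return(list(extended = list(), retained = list()))
  if (is.null(gamma)) gamma <- gamma_bounds(params$elements)
  n <- length(tuples[[1L]])
  prefix <- vapply(tuples, function(t) .tuple_key(t[-n]), character(1))
  suffix <- vapply(tuples, function(t) .tuple_key(t[-1L]), character(1))
  by_suffix <- split(seq_along(tuples), suffix)
  extended <- logical(length(tuples))
  out <- new.env(parent = emptyenv())
  hit <- match(prefix, names(by_suffix))
  for (x in which(!is.na(hit))) {
    for (y in by_suffix[[hit[x]]]) {
      if (y == x) next
      cand <- c(tuples[[y]][1L], tuples[[x]])
      if (anyDuplicated(cand)) next
      if (validate_tuple(cand, peaks, params, gamma)) {
        assign(.tuple_key(cand), cand, envir = out)
        extended[x] <- TRUE
        extended[y] <- TRUE
      }
    }
  }
  new_tuples <- mget(sort(ls(out)), envir = out)
  names(new_tuples) <- NULL
  list(extended = new_tuples, retained = tuples[!extended])
}

# All dash-keys of arithmetic subsequences (step >= 2, length >= 3) of one
# parent tuple.
.arith_sub_keys <- function(ids) {
  n <- length(ids)
  if (n < 5L) return(character(0))
  keys <- character(0)
  for (k in 2:((n - 1L) %/% 2L)) {
    for (o in seq_len(n - 2L * k)) {
      idx <- seq(o, n, by = k)
      for (m in 3:length(idx)) {
        keys <- c(keys, .tuple_key(ids[idx[seq_len(m)]]))
      }
    }
  }
  keys
}

#' Filter redundant regular-omission sub-tuples
#'
#' Removes every tuple whose peak sequence equals an arithmetic index
#' subsequence (every k-th peak, k >= 2, any offset, length >= 3) of a
#' longer parent tuple. Irregular subsets are retained.
#'
#' @param tuples List of integer id vectors to filter.
#' @param parents List of integer id vectors acting as parents (only those
#'   of length >= 5 can produce length >= 3 regular omissions).
#' @return The filtered \code{tuples} list.
#' @export
filter_subtuples <- function(tuples, parents) {
  if (length(tuples) == 0L || length(parents) == 0L) return(tuples)
  bad <- unique(unlist(lapply(parents, .arith_sub_keys)))
  if (length(bad) == 0L) return(tuples)
  keys <- vapply(tuples, .tuple_key, character(1))
  tuples[!(keys %in% bad)]
}

#' Detect homologue series in a peak list
#'
#' Runs the full two-stage search: stage 1 enumerates all feasible triplets
#' via k-d tree range queries (\code{\link{find_triplets}}); stage 2
#' repeatedly merges overlapping tuples into longer ones until no merge
#' succeeds, filtering regular-omission sub-tuples at each recursion. A peak
#' may appear in several series, but never twice within one series.
#'
#' @param peaks A \code{peaklist} (see \code{\link{read_peaks}},
#'   \code{\link{as_peaklist}}).
#' @param params A \code{\link{detection_params}}.
#' @return A list of class \code{homol_series_list}; each element is a list
#'   with \code{peaks} (ordered ids), \code{mean_dmz}, \code{mean_drt} and
#'   \code{r2}. Sorted by first peak id, then length. The per-stage tuple
#'   counts are attached as attribute \code{funnel}.
#' @examples
#' sim <- simulate_peaklist(list(planted_series(length = 6)),
#'                          n_background = 50, seed = 1)
#' res <- detect_series(sim$peaks, detection_params(n_min = 5))
#' series_summary(res)
#' @export
detect_series <- function(peaks, params = detection_params()) {
  stopifnot(inherits(params, "detection_params"))
  gamma <- gamma_bounds(params$elements)
  trip <- find_triplets(peaks, params, gamma)
  live <- lapply(seq_len(nrow(trip)), function(i) unname(trip[i, ]))
  funnel <- c("3" = length(live))
  retained <- list()
  while (length(live) > 0L) {
    st <- merge_step(live, peaks, params, gamma)
    retained <- c(retained, st$retained)
    live <- st$extended
    if (length(live) > 0L) {
      funnel[as.character(length(live[[1L]]))] <- length(live)
      retained <- filter_subtuples(retained, live)
    }
  }
  retained <- retained[vapply(retained, length, integer(1)) >= params$n_min]
  if (length(retained) > 0L) {
    ord <- order(vapply(retained, `[`, integer(1), 1L),
                 vapply(retained, length, integer(1)),
                 vapply(retained, .tuple_key, character(1)))
    retained <- retained[ord]
  }
  out <- lapply(retained, function(ids) {
    i <- match(ids, peaks$peak_id)
    mz <- peaks$mz[i]; rt <- peaks$rt[i]
    sc <- spline_check(mz, rt, params$lambda, params$r2_min)
    list(peaks = ids, mean_dmz = mean(diff(mz)), mean_drt = mean(diff(rt)),
         r2 = sc$r2)
  })
  attr(out, "funnel") <- funnel
  class(out) <- "homol_series_list"
  out
}

#' @export
print.homol_series_list <- function(x, ...) {
  cat(sprintf("%d homologue series\n", length(x)))
  f <- attr(x, "funnel")
  if (!is.null(f) && length(f) > 0L) {
    cat("tuples per length before retention/filtering:\n")
    cat(paste(sprintf("  n=%s: %d", names(f), f), collapse = "\n"), "\n")
  }
  if (length(x) > 0L) {
    print(utils::head(series_summary(x), 10L))
    if (length(x) > 10L) cat("...\n")
  }
  invisible(x)
}
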