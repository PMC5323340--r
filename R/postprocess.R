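# Majority-vote blank flagging and monoisotopic flagging of detected series.

#' Blank voting for detected series
#'
#' A sample peak fails the blank check when any picked blank peak lies
#' within \code{+/- mz_tol} and \code{+/- rt_tol} of it and exceeds
#' \code{intensity_factor} times the sample peak's intensity. A series is
#' voted to be of blank origin when the fraction of failing member peaks
#' reaches \code{majority}. Note this operates on a picked blank peak list;
#' screening of raw blank profiles is upstream of this tool.
#'
#' @param series A \code{homol_series_list} (see \code{\link{detect_series}}).
#' @param sample_peaks The \code{peaklist} the series were detected in.
#' @param blank_peaks A \code{peaklist} from the blank measurement; an empty
#'   (0-row) list makes every peak pass.
#' @param mz_tol,rt_tol Half-widths of the peak-centered match window.
#' @param intensity_factor Blank peaks at or below this multiple of the
#'   sample peak intensity are ignored (default 0.1).
#' @param majority Minimum failing fraction for a blank verdict (default 0.5).
#' @return A list with \code{series_blank} (logical per series),
#'   \code{fail_fraction} (numeric per series) and \code{peak_fails}
#'   (logical per peak of \code{sample_peaks}, named by id).
#' @export
blank_flag <- function(series, sample_peaks, blank_peaks, mz_tol, rt_tol,
                       intensity_factor = 0.1, majority = 0.5) {
  stopifnot(mz_tol > 0, rt_tol > 0, intensity_factor >= 0,
            majority > 0, majority <= 1)
  fails <- vapply(seq_len(nrow(sample_peaks)), function(i) {
    if (nrow(blank_peaks) == 0L) return(FALSE)
    near <- abs(blank_peaks$mz - sample_peaks$mz[i]) <= mz_tol &
      abs(blank_peaks$rt - sample_peaks$rt[i]) <= rt_tol
    any(near & blank_peaks$intensity >
          intensity_factor * sample_peaks$intensity[i])
  }, logical(1))
  names(fails) <- sample_peaks$peak_id
  frac <- vapply(series, function(s) {
    mean(fails[match(s$peaks, sample_peaks$peak_id)])
  }, numeric(1))
  list(series_blank = frac >= majority, fail_fraction = frac,
       peak_fails = fails)
}

#' Monoisotopic voting for detected series
#'
#' Given per-peak isotopologue annotations (each annotated peak carries the
#' 1-based m/z rank it holds within its isotopologue group), a series is
#' voted monoisotopic when the most frequent rank over its annotated member
#' peaks equals 1. Unannotated peaks are excluded from the vote; a series
#' with no annotated peak is \code{NA} (undetermined). A tie between rank 1
#' and another rank resolves to monoisotopic and is reported in \code{tie}.
#'
#' @param series A \code{homol_series_list}.
#' @param annotations Data frame with columns \code{peak_id},
#'   \code{group_id}, \code{mz_rank} (rank >= 1).
#' @return A list with \code{monoisotopic} (logical per series, NA when
#'   undetermined), \code{modal_rank} and \code{tie} (logical).
#' @export
monoisotopic_flag <- function(series, annotations) {
  stopifnot(all(c("peak_id", "mz_rank") %in% names(annotations)))
  if (nrow(annotations) > 0 &&
      (any(annotations$mz_rank < 1) ||
       any(annotations$mz_rank != round(annotations$mz_rank)))) {
    stop("'mz_rank' must be positive integers", call. = FALSE)
  }
  verdict <- logical(length(series))
  modal <- integer(length(series))
  tie <- logical(length(series))
  for (i in seq_along(series)) {
    ranks <- annotations$mz_rank[match(series[[i]]$peaks,
                                       annotations$peak_id)]
    ranks <- ranks[!is.na(ranks)]
    if (length(ranks) == 0L) {
      verdict[i] <- NA; modal[i] <- NA_integer_
      next
    }
    counts <- table(ranks)
    top <- as.integer(names(counts)[counts == max(counts)])
    tie[i] <- length(top) > 1L
    # tie including rank 1 resolves to monoisotopic
    modal[i] <- if (1L %in% top) 1L else min(top)
    verdict[i] <- modal[i] == 1L
  }
  list(monoisotopic = verdict, modal_rank = modal, tie = tie)
}
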