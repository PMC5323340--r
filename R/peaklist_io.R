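# Reading/writing peak tables and the m/z measurement-uncertainty model.

#' Measurement-uncertainty model for m/z
#'
#' The maximum expected +/- m/z error of a picked peak, either a fixed
#' absolute value (Th) or proportional to m/z (ppm). Retention-time and
#' intensity dependence are not modelled.
#'
#' @param value Positive error magnitude: Th in \code{"absolute"} mode, parts
#'   per million in \code{"ppm"} mode.
#' @param mode \code{"absolute"} or \code{"ppm"}.
#' @return An object of class \code{epsilon_model}.
#' @examples
#' epsilon_at(epsilon_model(0.002), 500)        # 0.002
#' epsilon_at(epsilon_model(5, "ppm"), 200)     # 0.001
#' @export
epsilon_model <- function(value, mode = c("absolute", "ppm")) {
  mode <- match.arg(mode)
  if (length(value) != 1L || !is.finite(value) || value <= 0) {
    stop("'value' must be a single positive number", call. = FALSE)
  }
  structure(list(mode = mode, value = value), class = "epsilon_model")
}

#' @export
print.epsilon_model <- function(x, ...) {
  unit <- if (x$mode == "absolute") "Th" else "ppm"
  cat(sprintf("epsilon model: +/- %g %s\n", x$value, unit))
  invisible(x)
}

#' Evaluate the m/z uncertainty at given m/z values
#'
#' @param model An \code{\link{epsilon_model}}.
#' @param mz Numeric vector of positive m/z values (Th).
#' @return Numeric vector of +/- errors in Th.
#' @export
epsilon_at <- function(model, mz) {
  stopifnot(inherits(model, "epsilon_model"))
  if (any(!is.finite(mz)) || any(mz <= 0)) {
    stop("'mz' must be positive and finite", call. = FALSE)
  }
  if (model$mode == "absolute") rep(model$value, length(mz))
  else mz * model$value * 1e-6
}

.detect_sep <- function(line) {
  counts <- vapply(c(",", "\t", ";"), function(s)
    lengths(regmatches(line, gregexpr(s, line, fixed = TRUE))), integer(1))
  if (all(counts == 0L)) {
    stop("could not detect a delimiter (comma, tab or semicolon) in header",
         call. = FALSE)
  }
  c(",", "\t", ";")[which.max(counts)]
}

#' Read a picked-peak table
#'
#' Reads a delimited text file (comma, tab or semicolon; auto-detected from
#' the header unless \code{sep} is given) with one row per picked LC-HRMS
#' peak. Peaks are returned sorted by increasing m/z and given stable integer
#' ids 1..N in that order, so identical inputs always yield identical ids.
#'
#' @param path Path to the file; a header row is required.
#' @param column_map Named character vector mapping the required names
#'   \code{mz}, \code{rt}, \code{intensity} to the file's column names, e.g.
#'   \code{c(mz = "m.z", rt = "RT", intensity = "int")}.
#' @param sep Optional explicit field separator.
#' @return A \code{peaklist}: a data frame with columns \code{peak_id},
#'   \code{mz}, \code{rt}, \code{intensity}, sorted by \code{mz}.
#' @export
read_peaks <- function(path, column_map = NULL, sep = NULL) {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  header <- readLines(path, n = 1L)
  if (length(header) == 0L) stop("empty input file: ", path, call. = FALSE)
  if (is.null(sep)) sep <- .detect_sep(header)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           strip.white = TRUE, comment.char = "")
  wanted <- c(mz = "mz", rt = "rt", intensity = "intensity")
  if (!is.null(column_map)) wanted[names(column_map)] <- column_map
  miss <- setdiff(unname(wanted), names(raw))
  if (length(miss) > 0L) {
    stop("missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  num <- lapply(wanted, function(cn) suppressWarnings(as.numeric(raw[[cn]])))
  bad <- sort(unique(unlist(lapply(num, function(v) which(is.na(v))))))
  if (length(bad) > 0L) {
    stop("non-numeric value(s) in data line(s) ",
         paste(bad + 1L, collapse = ", "), " of ", path, call. = FALSE)
  }
  as_peaklist(data.frame(mz = num$mz, rt = num$rt, intensity = num$intensity))
}

#' Construct a peaklist from in-memory columns
#'
#' @param x A data frame with columns \code{mz}, \code{rt}, \code{intensity}.
#' @return A \code{peaklist} sorted by m/z with ids assigned 1..N.
#' @export
as_peaklist <- function(x) {
  stopifnot(is.data.frame(x), all(c("mz", "rt", "intensity") %in% names(x)))
  if (any(!is.finite(x$mz)) || any(x$mz <= 0)) {
    stop("all m/z values must be positive and finite", call. = FALSE)
  }
  if (any(!is.finite(x$rt))) stop("all RT values must be finite", call. = FALSE)
  if (any(!is.finite(x$intensity)) || any(x$intensity < 0)) {
    stop("intensities must be finite and non-negative", call. = FALSE)
  }
  ord <- order(x$mz, x$rt, x$intensity)
  out <- data.frame(peak_id = seq_along(ord),
                    mz = x$mz[ord], rt = x$rt[ord],
                    intensity = x$intensity[ord])
  class(out) <- c("peaklist", "data.frame")
  out
}

#' Write detected series tables
#'
#' Writes two tab-separated files: \code{<stem>_series.tsv}, one row per
#' series (id, length, mean adjacent m/z difference, mean adjacent RT
#' difference, spline R2, dash-separated peak-id list), and
#' \code{<stem>_assignments.tsv}, one row per (peak, series) membership. A
#' peak belonging to k series appears k times in the assignment table.
#'
#' @param series A list of series tuples as returned by
#'   \code{\link{detect_series}}.
#' @param stem Output path stem (directory must exist).
#' @param digits Number of decimals written for floating-point columns.
#' @return Invisibly, the two file paths.
#' @export
write_series <- function(series, stem, digits = 6L) {
  summ <- series_summary(series)
  fmt <- function(v) formatC(v, digits = digits, format = "f")
  out1 <- paste0(stem, "_series.tsv")
  out2 <- paste0(stem, "_assignments.tsv")
  s <- summ
  for (cn in c("mean_dmz", "mean_drt", "r2")) s[[cn]] <- fmt(s[[cn]])
  utils::write.table(s, out1, sep = "\t", quote = FALSE, row.names = FALSE)
  if (length(series) == 0L) {
    assign <- data.frame(peak_id = integer(), series_id = integer())
  } else {
    assign <- data.frame(
      peak_id = unlist(lapply(series, function(s) s$peaks)),
      series_id = rep(summ$series_id, vapply(series, function(s)
        length(s$peaks), integer(1))))
  }
  utils::write.table(assign, out2, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(out1, out2))
}

#' Summarize a list of series tuples
#'
#' @param series A list of series tuples (see \code{\link{detect_series}}).
#' @return A data frame with one row per series: \code{series_id},
#'   \code{length}, \code{mean_dmz}, \code{mean_drt}, \code{r2} and the
#'   dash-separated \code{peak_ids}.
#' @export
series_summary <- function(series) {
  if (length(series) == 0L) {
    return(data.frame(series_id = integer(), length = integer(),
                      mean_dmz = numeric(), mean_drt = numeric(),
                      r2 = numeric(), peak_ids = character()))
  }
  data.frame(
    series_id = seq_along(series),
    length = vapply(series, function(s) length(s$peaks), integer(1)),
    mean_dmz = vapply(series, function(s) s$mean_dmz, numeric(1)),
    mean_drt = vapply(series, function(s) s$mean_drt, numeric(1)),
    r2 = vapply(series, function(s) s$r2, numeric(1)),
    peak_ids = vapply(series, function(s)
      paste(s$peaks, collapse = "-"), character(1)))
}
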