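# Element/isotope constants and homologue-unit mass algebra.
#
# Everything downstream reasons about mass defects: the deviation of an exact
# ion m/z from its nearest integer. For a homologue unit made of a given
# element set, the feasible change of mass defect per Th of m/z difference is
# bounded by the extreme defect/mass ratios over the elements (gamma bounds).

.homol_env <- new.env(parent = emptyenv())

#' Table of lightest-isotope exact masses
#'
#' Returns the bundled table of exact masses (u) of the lowest-mass isotope
#' of each supported element, together with the signed mass defect of that
#' isotope. Values are fixed package constants so that results are
#' reproducible without any external database.
#'
#' @return A data frame with columns \code{symbol}, \code{isotope},
#'   \code{mass} (u) and \code{mass_defect} (u, in \code{[-0.5, 0.5)}).
#' @examples
#' element_table()[, c("symbol", "mass")]
#' @export
element_table <- function() {
  if (is.null(.homol_env$elements)) {
    path <- system.file("extdata", "lightest_isotopes.tsv",
                        package = "homolseries", mustWork = TRUE)
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    tab$mass_defect <- mass_defect(tab$mass)
    .homol_env$elements <- tab
  }
  .homol_env$elements
}

#' Signed mass defect of an exact mass
#'
#' The mass defect is the deviation of an exact mass (or ion m/z) from its
#' nearest integer. Halves round away from zero, so the result always lies in
#' \code{[-0.5, 0.5)}.
#'
#' @param mass Numeric vector of exact masses (u) or m/z values (Th); all
#'   values must be positive.
#' @return Numeric vector of signed defects in \code{[-0.5, 0.5)}.
#' @examples
#' mass_defect(1.00782503)   #  0.00782503 (1H)
#' mass_defect(78.9183376)   # -0.0816624  (79Br)
#' @export
mass_defect <- function(mass) {
  if (!is.numeric(mass) || any(!is.finite(mass)) || any(mass <= 0)) {
    stop("'mass' must be a positive finite numeric vector", call. = FALSE)
  }
  # round half away from zero; mass > 0 so this is floor(mass + 0.5)
  d <- mass - floor(mass + 0.5)
  # defect of exactly +0.5 wraps to -0.5 by the half-away rule above
  d
}

#' Mass-defect slope bounds for an element set
#'
#' For two peaks differing by a monoisotopic chemical unit of mass difference
#' \eqn{\Delta m/z}, the change in mass defect is bounded by the extreme
#' ratios of mass defect to isotope mass over the elements the unit may
#' contain. With the default organic/halogen set the lower bound comes from
#' 79Br and the upper bound from 1H.
#'
#' @param elements Character vector of element symbols, all present in
#'   \code{\link{element_table}}.
#' @return An object of class \code{gamma_bounds}: a list with numeric
#'   scalars \code{gamma_min} and \code{gamma_max} (defect change per Th).
#' @examples
#' g <- gamma_bounds(c("C", "H", "N", "O", "S", "Cl", "Br"))
#' round(c(g$gamma_min, g$gamma_max), 4)  # -0.0010  0.0078
#' @export
gamma_bounds <- function(elements) {
  if (length(elements) == 0L) {
    stop("'elements' must name at least one element", call. = FALSE)
  }
  tab <- element_table()
  idx <- match(elements, tab$symbol)
  if (anyNA(idx)) {
    stop("unknown element symbol(s): ",
         paste(elements[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  ratio <- tab$mass_defect[idx] / tab$mass[idx]
  structure(list(gamma_min = min(ratio), gamma_max = max(ratio)),
            class = "gamma_bounds")
}

#' @export
print.gamma_bounds <- function(x, ...) {
  cat(sprintf("gamma bounds: [%.6f; %.6f] (defect change per Th)\n",
              x$gamma_min, x$gamma_max))
  invisible(x)
}

.parse_formula <- function(formula) {
  if (is.numeric(formula)) {        # already a named count vector
    counts <- formula
    if (is.null(names(counts)) || any(!nzchar(names(counts)))) {
      stop("numeric formulas must be named by element symbol", call. = FALSE)
    }
  } else {
    formula <- as.character(formula)
    stopifnot(length(formula) == 1L)
    if (!grepl("^([A-Z][a-z]?[0-9]*)+$", formula)) {
      stop("cannot parse formula '", formula, "'", call. = FALSE)
    }
    m <- gregexpr("[A-Z][a-z]?[0-9]*", formula)[[1L]]
    parts <- regmatches(formula, list(m))[[1L]]
    sym <- sub("[0-9]*$", "", parts)
    num <- sub("^[A-Za-z]+", "", parts)
    counts <- ifelse(nzchar(num), as.numeric(num), 1)
    names(counts) <- sym
    counts <- tapply(counts, names(counts), sum)  # merge repeats like CH2CH2
  }
  counts
}

#' Mass difference of a homologue unit per charge
#'
#' Exact m/z spacing (Th) produced by repeated insertion of a chemical unit
#' into an ion of charge \code{z}, computed from lightest-isotope masses.
#' Typical surfactant units are CH2 (14.016 Th), C2H4O (44.026 Th), CH2O
#' (30.011 Th) and C3H6O (58.042 Th) at \code{z = 1}.
#'
#' @param formula A molecular formula string such as \code{"C2H4O1"} (counts
#'   default to 1) or a named numeric vector of element counts.
#' @param z Positive integer charge; the neutral unit mass is divided by
#'   \code{z}.
#' @return Numeric scalar, the unit's m/z difference in Th.
#' @examples
#' unit_mass("CH2")         # 14.01565
#' unit_mass("CH2", z = 2)  #  7.007825
#' @export
unit_mass <- function(formula, z = 1L) {
  if (length(z) != 1L || !is.finite(z) || z < 1 || z != round(z)) {
    stop("'z' must be a positive integer", call. = FALSE)
  }
  counts <- .parse_formula(formula)
  counts <- counts[counts > 0]
  if (length(counts) == 0L) {
    stop("formula contains no elements with positive counts", call. = FALSE)
  }
  tab <- element_table()
  idx <- match(names(counts), tab$symbol)
  if (anyNA(idx)) {
    stop("unknown element symbol(s): ",
         paste(names(counts)[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  sum(counts * tab$mass[idx]) / z
}
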