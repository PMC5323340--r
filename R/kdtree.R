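# 4-d peak embedding and k-d tree with axis-aligned range queries.
#
# Every peak is mapped to a_x = (m/z, defect - gamma_min*m/z,
# defect - gamma_max*m/z, RT). Dimensions 2 and 3 turn the feasible
# mass-defect change per Th into one-sided metric bounds, so that both
# subspaces of a triplet query become axis-aligned boxes.

#' Embed peaks into the 4-d search space
#'
#' @param peaks A \code{peaklist} (see \code{\link{as_peaklist}}).
#' @param gamma A \code{\link{gamma_bounds}} object.
#' @return A numeric matrix with one row per peak and columns \code{a1}
#'   (m/z), \code{a2} (defect minus \code{gamma_min}*m/z), \code{a3}
#'   (defect minus \code{gamma_max}*m/z), \code{a4} (RT); rownames are
#'   peak ids.
#' @export
embed_peaks <- function(peaks, gamma) {
  stopifnot(inherits(gamma, "gamma_bounds"))
  defect <- mass_defect(peaks$mz)
  m <- cbind(a1 = peaks$mz,
             a2 = defect - gamma$gamma_min * peaks$mz,
             a3 = defect - gamma$gamma_max * peaks$mz,
             a4 = peaks$rt)
  rownames(m) <- peaks$peak_id
  m
}

#' Build a balanced 4-d k-d tree
#'
#' The splitting dimension cycles 1 -> 2 -> 3 -> 4 starting from dimension 1
#' at the root. Each node holds the median point of its partition (ties by
#' lower row index; even-sized partitions take the lower middle element), so
#' equal inputs always produce the same tree.
#'
#' @param vectors Numeric matrix of embedded peaks (rows are points, 4
#'   columns), as from \code{\link{embed_peaks}}.
#' @return An object of class \code{kdtree}.
#' @export
kdtree_build <- function(vectors) {
  stopifnot(is.matrix(vectors), ncol(vectors) == 4L)
  n <- nrow(vectors)
  point <- integer(n)   # row index stored at node i
  left <- integer(n)    # child node indices, 0 = none
  right <- integer(n)
  nn <- 0L
  build <- function(rows, depth) {
    if (length(rows) == 0L) return(0L)
    d <- (depth %% 4L) + 1L
    rows <- rows[order(vectors[rows, d], rows)]
    mid <- (length(rows) + 1L) %/% 2L
    nn <<- nn + 1L
    node <- nn
    point[node] <<- rows[mid]
    l <- build(rows[seq_len(mid - 1L)], depth + 1L)
    r <- if (mid < length(rows))
      build(rows[(mid + 1L):length(rows)], depth + 1L) else 0L
    left[node] <<- l
    right[node] <<- r
    node
  }
  root <- build(seq_len(n), 0L)
  structure(list(vectors = vectors, point = point, left = left,
                 right = right, root = root, n = n),
            class = "kdtree")
}

#' @export
print.kdtree <- function(x, ...) {
  cat(sprintf("4-d k-d tree over %d points\n", x$n))
  invisible(x)
}

#' Orthogonal range query on a k-d tree
#'
#' Returns all points lying inside a closed axis-aligned box, by recursive
#' descent with subtree pruning on the splitting dimension. Boundaries are
#' inclusive, matching the +/- phrasing of all tolerance parameters.
#'
#' @param tree A \code{kdtree}.
#' @param lo,hi Numeric length-4 vectors of lower/upper bounds;
#'   \code{-Inf}/\code{Inf} allowed.
#' @return Sorted integer row indices (into the embedding matrix) of the
#'   points inside the box.
#' @export
kdtree_query <- function(tree, lo, hi) {
  stopifnot(inherits(tree, "kdtree"), length(lo) == 4L, length(hi) == 4L)
  if (any(lo > hi)) stop("box bounds must satisfy lo <= hi", call. = FALSE)
  if (tree$n == 0L) return(integer(0))
  v <- tree$vectors
  point <- tree$point; left <- tree$left; right <- tree$right
  out <- integer(0)
  recurse <- function(node, depth) {
    if (node == 0L) return(invisible())
    d <- (depth %% 4L) + 1L
    p <- point[node]
    val <- v[p, d]
    if (lo[1] <= v[p, 1] && v[p, 1] <= hi[1] &&
        lo[2] <= v[p, 2] && v[p, 2] <= hi[2] &&
        lo[3] <= v[p, 3] && v[p, 3] <= hi[3] &&
        lo[4] <= v[p, 4] && v[p, 4] <= hi[4]) {
      out[length(out) + 1L] <<- p
    }
    if (lo[d] <= val) recurse(left[node], depth + 1L)
    if (hi[d] >= val) recurse(right[node], depth + 1L)
    invisible()
  }
  recurse(tree$root, 0L)
  sort(out)
}
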