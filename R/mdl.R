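# MDL/MML code-length costs. Every log2 argument (segment length, weighted
# distance) is clamped below at 1 so each code-length term is non-negative;
# with data ranges in the hundreds-to-thousands the clamp is inactive except
# for near-coincident points.

check_ij <- function(n, i, j) {
  if (i < 1 || j > n || i >= j) {
    stop(sprintf("need 1 <= i < j <= %d (got i = %s, j = %s)", n, i, j))
  }
}

#' Hypothesis code length of one candidate segment
#'
#' Bits needed to describe the segment joining points `i` and `j`:
#' `log2(max(1, len))` where `len` is the Euclidean length of the segment in
#' the (index, value) plane.
#'
#' @param points stream points: a data.frame with `index`/`value` columns, a
#'   two-column matrix, or a numeric value vector (0-based serial indices).
#' @param i,j 1-based positions into `points`, with `i < j`.
#' @return Non-negative scalar (bits).
#' @examples
#' hypothesis_cost(data.frame(index = c(0, 8), value = c(0, 0)), 1, 2) # 3
#' @export
hypothesis_cost <- function(points, i, j) {
  p <- as_points(points)
  check_ij(length(p$x), i, j)
  log2_floor1(sqrt((p$x[j] - p$x[i])^2 + (p$y[j] - p$y[i])^2))
}

#' Data code length of the points covered by one candidate segment
#'
#' Bits needed to describe the original lines between points `i` and `j`
#' given the candidate segment joining them: for each original line, the sum
#' of `log2(max(1, wp * dp))` and `log2(max(1, wa * da))` with `dp` and `da`
#' the perpendicular and angle distances to the candidate. It is 0 when all
#' interior points are collinear with the candidate.
#'
#' @inheritParams hypothesis_cost
#' @param w a [distance_weights()] object.
#' @return Non-negative scalar (bits).
#' @export
data_cost <- function(points, i, j, w = distance_weights()) {
  p <- as_points(points)
  check_ij(length(p$x), i, j)
  if (j == i + 1) return(0)
  d <- line_candidate_dists(p$x, p$y, i, j, i:(j - 1))
  sum(log2_floor1(w$wp * d$dp)) + sum(log2_floor1(w$wa * d$da))
}

#' MDL cost of encoding a stretch as one segment
#'
#' `hypothesis_cost(points, i, j) + data_cost(points, i, j, w)`: the total
#' code length when `i` and `j` are taken as the only character points of the
#' stretch.
#'
#' @inheritParams data_cost
#' @return Non-negative scalar (bits).
#' @export
mdl_seg <- function(points, i, j, w = distance_weights()) {
  hypothesis_cost(points, i, j) + data_cost(points, i, j, w)
}

#' MDL cost of keeping every original line of a stretch
#'
#' The hypothesis cost of retaining all points between `i` and `j`: the sum
#' of `log2(max(1, len))` over the original lines of the stretch. There is no
#' data term because the encoding is exact.
#'
#' @inheritParams hypothesis_cost
#' @return Non-negative scalar (bits).
#' @export
mdl_noseg <- function(points, i, j) {
  p <- as_points(points)
  check_ij(length(p$x), i, j)
  ks <- i:(j - 1)
  sum(log2_floor1(sqrt((p$x[ks + 1] - p$x[ks])^2 + (p$y[ks + 1] - p$y[ks])^2)))
}

#' Greedy segmentation criterion
#'
#' `TRUE` when encoding the stretch from `i` to `j` as a single segment is
#' strictly cheaper than keeping every original line
#' (`mdl_seg < mdl_noseg`). Ties mean "do not segment"; in particular the
#' criterion is always `FALSE` for `j = i + 1`, where both costs coincide.
#'
#' @inheritParams data_cost
#' @return Logical scalar.
#' @export
prefer_segment <- function(points, i, j, w = distance_weights()) {
  mdl_seg(points, i, j, w) < mdl_noseg(points, i, j)
}
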