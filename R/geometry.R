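#' Line segment in the (index, value) plane
#'
#' A directed line between two observations of a stream. Original lines join
#' consecutive stream points; candidate segments join two character points.
#'
#' @param x0,y0 index and value of the start point.
#' @param x1,y1 index and value of the end point. For a candidate segment the
#'   end index must exceed the start index (non-vertical line); original lines
#'   may be degenerate.
#' @return An object of class `presee_segment`.
#' @examples
#' segment(0, 0, 2, 0)
#' @export
segment <- function(x0, y0, x1, y1) {
  v <- c(x0 = x0, y0 = y0, x1 = x1, y1 = y1)
  if (any(!is.finite(v))) stop("segment coordinates must be finite")
  if (x1 < x0) stop("segment end index must not precede its start index")
  structure(as.list(v), class = "presee_segment")
}

#' @export
print.presee_segment <- function(x, ...) {
  cat(sprintf("<segment (%g, %g) -> (%g, %g), length %g>\n",
              x$x0, x$y0, x$x1, x$y1, seg_length(x)))
  invisible(x)
}

seg_length <- function(s) sqrt((s$x1 - s$x0)^2 + (s$y1 - s$y0)^2)

check_candidate <- function(ls) {
  if (!inherits(ls, "presee_segment")) stop("`ls` must be a segment()")
  if (ls$x1 <= ls$x0) {
    stop("invalid candidate segment: start and end share the same index")
  }
  invisible(ls)
}

#' Distance weights for the segmenting distance
#'
#' Weights of the perpendicular and angle components of the segmenting
#' distance. They must be non-negative and sum to one; equal weights are the
#' default when no application-specific emphasis is wanted.
#'
#' @param wp weight of the perpendicular distance.
#' @param wa weight of the angle distance.
#' @return An object of class `presee_weights`.
#' @examples
#' distance_weights()        # wp = wa = 1/2
#' distance_weights(0.8, 0.2)
#' @export
distance_weights <- function(wp = 0.5, wa = 0.5) {
  if (wp < 0 || wa < 0) stop("distance weights must be non-negative")
  if (abs(wp + wa - 1) > 1e-8) stop("distance weights must sum to 1")
  structure(list(wp = wp, wa = wa), class = "presee_weights")
}

#' Perpendicular offsets of an original line from a candidate line
#'
#' Unsigned distances from the start and end point of the original line `lo`
#' to the infinite line through the candidate segment `ls`, computed in the
#' numerically stable cross-product form (identical to the slope/intercept
#' formula wherever the latter is defined).
#'
#' @param lo original line (a [segment()]).
#' @param ls candidate segment (a [segment()] with strictly increasing index).
#' @return Named numeric vector `c(lp1, lp2)`, both `>= 0`.
#' @examples
#' perpendicular_offsets(segment(0, 1, 2, 1), segment(0, 0, 2, 0)) # c(1, 1)
#' @export
perpendicular_offsets <- function(lo, ls) {
  check_candidate(ls)
  ex <- ls$x1 - ls$x0
  ey <- ls$y1 - ls$y0
  len <- sqrt(ex^2 + ey^2)
  lp1 <- abs(ex * (lo$y0 - ls$y0) - ey * (lo$x0 - ls$x0)) / len
  lp2 <- abs(ex * (lo$y1 - ls$y0) - ey * (lo$x1 - ls$x0)) / len
  c(lp1 = lp1, lp2 = lp2)
}

#' Perpendicular distance between an original line and a candidate segment
#'
#' Combines the two endpoint offsets as `(lp1^2 + lp2^2) / (lp1 + lp2)`, a
#' contraharmonic mean that lies between `min(lp1, lp2)` and `max(lp1, lp2)`.
#' The collinear 0/0 case is defined as 0.
#'
#' @inheritParams perpendicular_offsets
#' @return Non-negative scalar.
#' @examples
#' perpendicular_distance(segment(0, 0, 1, 1), segment(0, 0, 2, 0)) # 1
#' @export
perpendicular_distance <- function(lo, ls) {
  o <- perpendicular_offsets(lo, ls)
  s <- o[["lp1"]] + o[["lp2"]]
  if (s == 0) 0 else (o[["lp1"]]^2 + o[["lp2"]]^2) / s
}

#' Angle distance between an original line and a candidate segment
#'
#' The length of the original line scaled by the sine of the smaller
#' intersection angle between the two lines: `len(lo) * sin(theta)`, computed
#' as `|cross(lo, ls)| / len(ls)`. It is 0 for parallel lines and for
#' zero-length original lines, and never exceeds `len(lo)`.
#'
#' @inheritParams perpendicular_offsets
#' @return Scalar in `[0, len(lo)]`.
#' @examples
#' angle_distance(segment(0, 0, 1, 1), segment(0, 0, 2, 0)) # 1
#' @export
angle_distance <- function(lo, ls) {
  check_candidate(ls)
  ex <- ls$x1 - ls$x0
  ey <- ls$y1 - ls$y0
  abs((lo$x1 - lo$x0) * ey - (lo$y1 - lo$y0) * ex) / sqrt(ex^2 + ey^2)
}

#' Segmenting distance between an original line and a candidate segment
#'
#' Weighted sum of the perpendicular and angle distances. It is 0 exactly
#' when the original line lies on the candidate's line.
#'
#' @inheritParams perpendicular_offsets
#' @param w a [distance_weights()] object.
#' @return Non-negative scalar.
#' @examples
#' segmenting_distance(segment(0, 0, 1, 1), segment(0, 0, 2, 0)) # 1
#' @export
segmenting_distance <- function(lo, ls, w = distance_weights()) {
  w$wp * perpendicular_distance(lo, ls) + w$wa * angle_distance(lo, ls)
}

# Vectorized distances of original lines ks..ks+1 to the candidate through
# points i and j (1-based positions into x, y). Returns list(dp, da).
line_candidate_dists <- function(x, y, i, j, ks) {
  ax <- x[i]; ay <- y[i]
  ex <- x[j] - ax; ey <- y[j] - ay
  len <- sqrt(ex^2 + ey^2)
  d1 <- abs(ex * (y[ks] - ay) - ey * (x[ks] - ax)) / len
  d2 <- abs(ex * (y[ks + 1] - ay) - ey * (x[ks + 1] - ax)) / len
  s <- d1 + d2
  dp <- ifelse(s > 0, (d1^2 + d2^2) / s, 0)
  da <- abs((x[ks + 1] - x[ks]) * ey - (y[ks + 1] - y[ks]) * ex) / len
  list(dp = dp, da = da)
}
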