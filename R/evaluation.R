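#' Segmentation error rate
#'
#' For each segment (a consecutive pair of character points) the per-segment
#' error is the mean segmenting distance of the original lines it spans to
#' the segment; the error rate is the unweighted mean of the per-segment
#' errors. It is 0 when every point is a character point and invariant under
#' rigid motions of the data.
#'
#' @inheritParams segment_window
#' @param char_points the character points: a `presee_result`, a data.frame
#'   with a `projection` column (as returned by [segment_window()] or
#'   [bottom_up()]), or a vector of 1-based positions into `points`. The
#'   projections must be strictly increasing and start/end at the first/last
#'   point.
#' @return An object of class `presee_error_report`: list with `error_rate`,
#'   `n_segments`, `compress_rate` and `per_segment_errors`.
#' @examples
#' tri <- data.frame(index = c(0, 10, 20), value = c(0, 10, 0))
#' error_rate(tri, c(1, 3))$error_rate # 10
#' @export
error_rate <- function(points, char_points, w = distance_weights()) {
  p <- as_points(points)
  n <- length(p$x)
  proj <- char_projections(char_points, p)
  m <- length(proj)
  if (m < 2) stop("need at least 2 character points")
  if (any(diff(proj) <= 0)) stop("projections must be strictly increasing")
  if (proj[1] != 1 || proj[m] != n) {
    stop("character points must include the first and last stream point")
  }

  # each original line k (points k..k+1) belongs to exactly one segment
  ks <- seq_len(n - 1)
  seg_id <- findInterval(ks, proj[-m])
  d <- line_candidate_dists(p$x, p$y, proj[seg_id], proj[seg_id + 1], ks)
  dist <- w$wp * d$dp + w$wa * d$da
  n_lines <- tabulate(seg_id, nbins = m - 1)
  per_seg <- as.numeric(rowsum(dist, seg_id)) / n_lines

  structure(list(error_rate = mean(per_seg),
                 n_segments = m - 1L,
                 compress_rate = m / n,
                 per_segment_errors = per_seg),
            class = "presee_error_report")
}

#' @export
print.presee_error_report <- function(x, ...) {
  cat(sprintf("segmentation error rate %.5f over %d segments (compress rate %.5f)\n",
              x$error_rate, x$n_segments, x$compress_rate))
  invisible(x)
}

char_projections <- function(char_points, p) {
  if (inherits(char_points, "presee_result")) {
    char_points <- char_points$points
  }
  if (is.data.frame(char_points)) {
    if ("projection" %in% names(char_points)) {
      return(as.numeric(char_points$projection))
    }
    # fall back to matching character points to the stream by index
    proj <- match(char_points$index, p$x)
    if (anyNA(proj)) stop("character-point indices not found in the stream")
    return(as.numeric(proj))
  }
  as.numeric(char_points)
}

#' Compression rate of a segmentation
#'
#' Size of the result over the size of the original data:
#' `n_char / n_points`.
#'
#' @param n_char number of character points emitted.
#' @param n_points number of input stream points.
#' @return Scalar in `(0, 1]` for any valid segmentation.
#' @examples
#' compress_rate(2, 10) # 0.2
#' @export
compress_rate <- function(n_char, n_points) n_char / n_points

#' Segment counts of bottom-up segmentation across error thresholds
#'
#' Runs [bottom_up()] once per threshold and reports the resulting number of
#' segments, which is non-increasing in the threshold.
#'
#' @inheritParams segment_window
#' @param thresholds numeric vector of error thresholds.
#' @return A data.frame with columns `threshold` and `n_segments`.
#' @export
threshold_sweep <- function(points, thresholds, w = distance_weights()) {
  n_segments <- vapply(thresholds, function(th) {
    nrow(bottom_up(points, th, w)) - 1L
  }, integer(1))
  data.frame(threshold = thresholds, n_segments = n_segments)
}
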