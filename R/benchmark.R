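#' Configuration of the bottom-up benchmark segmenter
#'
#' @param error_threshold merging stops once the cheapest adjacent merge
#'   would cost at least this much (same units as [segmenting_distance()]).
#' @param window_size slide-window capacity for [swbu_stream()].
#' @param weights a [distance_weights()] object.
#' @return An object of class `presee_bu_config`.
#' @export
bu_config <- function(error_threshold, window_size = 1000,
                      weights = distance_weights()) {
  if (error_threshold < 0) stop("error_threshold must be non-negative")
  if (window_size < 3) stop("window_size must be at least 3")
  structure(list(error_threshold = error_threshold,
                 window_size = as.integer(window_size),
                 weights = weights),
            class = "presee_bu_config")
}

#' Bottom-up segmentation
#'
#' The classical bottom-up benchmark: start with one segment per original
#' line and repeatedly merge the adjacent pair whose merged segment is
#' cheapest, while that minimal cost is below `error_threshold`. The cost of
#' a merged segment is the mean segmenting distance of the original lines it
#' covers (so thresholds and [error_rate()] share one unit). Among equal-cost
#' candidates the leftmost pair is merged, making the output deterministic.
#'
#' @inheritParams segment_window
#' @param error_threshold see [bu_config()]; `0` retains every point,
#'   `Inf` merges down to a single segment (or to `min_segments`).
#' @param w a [distance_weights()] object.
#' @param min_segments stop merging once this many segments remain. Set it
#'   together with `error_threshold = Inf` to count-match another segmenter's
#'   output, which is equivalent to tuning the threshold (the merge order
#'   does not depend on the threshold).
#' @return A data.frame of surviving boundary points with columns `index`,
#'   `value`, `projection` (1-based positions into `points`).
#' @examples
#' tri <- data.frame(index = c(0, 10, 20), value = c(0, 10, 0))
#' nrow(bottom_up(tri, error_threshold = 11)) # 2: merged (cost 10 < 11)
#' nrow(bottom_up(tri, error_threshold = 9))  # 3: kept   (cost 10 >= 9)
#' @export
bottom_up <- function(points, error_threshold, w = distance_weights(),
                      min_segments = 1L) {
  p <- as_points(points)
  n <- length(p$x)
  if (n < 2) stop("need at least 2 points to segment")
  check_point_order(p$x)
  x <- p$x
  y <- p$y

  merge_cost <- function(i, j) {
    d <- line_candidate_dists(x, y, i, j, i:(j - 1))
    mean(w$wp * d$dp + w$wa * d$da)
  }

  bounds <- seq_len(n)
  if (n > 2) {
    # cost[k]: merging the two segments around interior boundary bounds[k + 1]
    cost <- vapply(2:(n - 1),
                   function(b) merge_cost(bounds[b - 1], bounds[b + 1]),
                   numeric(1))
    while (length(bounds) - 1 > min_segments) {
      k <- which.min(cost)
      if (!(cost[k] < error_threshold)) break
      bounds <- bounds[-(k + 1)]
      cost <- cost[-k]
      if (k <= length(cost)) cost[k] <- merge_cost(bounds[k], bounds[k + 2])
      if (k > 1) cost[k - 1] <- merge_cost(bounds[k - 1], bounds[k + 1])
    }
  }
  data.frame(index = x[bounds], value = y[bounds], projection = bounds)
}

#' Slide-window bottom-up segmentation of a stream
#'
#' Applies [bottom_up()] inside each full slide window; all character points
#' of a window are emitted except the last one, which seeds the next window.
#' The remaining buffer is flushed through a final bottom-up pass when the
#' source is exhausted. Equals [bottom_up()] whenever the input fits in one
#' window.
#'
#' @inheritParams presee_stream
#' @param config a [bu_config()].
#' @return A `presee_result` (see [presee_stream()]); `evals` is `NA`.
#' @export
swbu_stream <- function(source, config, sink = NULL) {
  if (!inherits(config, "presee_bu_config")) stop("config must be bu_config()")
  cap <- config$window_size
  acc <- if (is.null(sink)) new_accumulator()
  n_in <- 0
  n_out <- 0
  reads_at_first_emit <- NA_real_
  last_index <- -Inf
  last_emitted <- 0
  offset <- 0
  wx <- numeric(0)
  wy <- numeric(0)
  exhausted <- FALSE

  emit <- function(ix, vv, proj) {
    if (n_out == 0) reads_at_first_emit <<- n_in
    n_out <<- n_out + length(ix)
    if (is.null(sink)) acc$add(ix, vv, proj) else sink(ix, vv, proj)
    last_emitted <<- proj[length(proj)]
  }

  repeat {
    need <- cap - length(wx)
    if (need > 0 && !exhausted) {
      ch <- source(need)
      if (is.null(ch) || length(ch$index) == 0) {
        exhausted <- TRUE
      } else {
        ix <- as.numeric(ch$index)
        if (ix[1] <= last_index || (length(ix) > 1 && any(diff(ix) <= 0))) {
          stop("stream order violation: indices must be strictly increasing")
        }
        last_index <- ix[length(ix)]
        wx <- c(wx, ix)
        wy <- c(wy, as.numeric(ch$value))
        n_in <- n_in + length(ix)
        if (length(ix) < need) exhausted <- TRUE
      }
    }
    m <- length(wx)
    if (m == 0) break
    if (m == 1) {
      if (offset + 1 > last_emitted) emit(wx, wy, offset + 1)
      break
    }
    cp <- bottom_up(data.frame(index = wx, value = wy),
                    config$error_threshold, config$weights)$projection
    if (exhausted) {
      keep <- cp[offset + cp > last_emitted]
      if (length(keep)) emit(wx[keep], wy[keep], offset + keep)
      break
    }
    head_cp <- cp[-length(cp)]
    keep <- head_cp[offset + head_cp > last_emitted]
    if (length(keep)) emit(wx[keep], wy[keep], offset + keep)
    wx <- wx[m]
    wy <- wy[m]
    offset <- offset + m - 1
  }

  structure(list(points = if (is.null(sink)) acc$drain(),
                 n_in = n_in,
                 n_out = n_out,
                 compress_rate = if (n_in > 0) n_out / n_in else NA_real_,
                 evals = NA_real_,
                 reads_at_first_emit = reads_at_first_emit,
                 config = config),
            class = "presee_result")
}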