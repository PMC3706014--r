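#' Configuration of the streaming segmenter
#'
#' @param window_size capacity of the slide window (points held at once);
#'   at least 3. Affects throughput, not (materially) the result.
#' @param batch_size number of segments emitted per window pass (at least 1).
#'   An efficiency knob only: each pass releases at most `batch_size + 1`
#'   character points.
#' @param weights a [distance_weights()] object.
#' @return An object of class `presee_config`.
#' @examples
#' segmenter_config(window_size = 500)
#' @export
segmenter_config <- function(window_size = 1000, batch_size = 1,
                             weights = distance_weights()) {
  if (window_size < 3) stop("window_size must be at least 3")
  if (batch_size < 1) stop("batch_size must be at least 1")
  structure(list(window_size = as.integer(window_size),
                 batch_size = as.integer(batch_size),
                 weights = weights),
            class = "presee_config")
}

#' Greedy character-point extraction from one window of points
#'
#' Single left-to-right scan: a candidate segment anchored at the most recent
#' character point grows one point at a time while [prefer_segment()] holds;
#' at the first violation the previous point is emitted as a character point
#' and the candidate restarts there. The first and last points are always
#' character points (the last one is provisional when the window is an
#' interior slice of a longer stream).
#'
#' @inheritParams data_cost
#' @param points at least two stream points (see [hypothesis_cost()] for
#'   accepted forms).
#' @return A data.frame with columns `index`, `value` and `projection`
#'   (1-based position of each character point in `points`), with the number
#'   of criterion evaluations in `attr(, "evals")`.
#' @examples
#' segment_window(data.frame(index = c(0, 10, 20, 30), value = 0))
#' @export
segment_window <- function(points, w = distance_weights()) {
  p <- as_points(points)
  if (length(p$x) < 2) stop("need at least 2 points to segment")
  check_point_order(p$x)
  r <- .greedy_scan_cpp(p$x, p$y, w$wp, w$wa, 0L)
  cp <- r$cp
  out <- data.frame(index = p$x[cp], value = p$y[cp], projection = cp)
  attr(out, "evals") <- r$evals
  out
}

# Wrap an in-memory point set as a chunk source: function(n) returning up to
# n points as list(index, value), or NULL when drained.
points_source <- function(points) {
  p <- as_points(points)
  pos <- 0L
  total <- length(p$x)
  function(n) {
    if (pos >= total) return(NULL)
    take <- seq.int(pos + 1L, min(pos + n, total))
    pos <<- pos + length(take)
    list(index = p$x[take], value = p$y[take])
  }
}

#' Stream segmentation over an iterator source
#'
#' The streaming driver: fills the slide window from `source`, runs the
#' greedy window scan, emits at most `batch_size + 1` character points, then
#' slides the window so that the last emitted character point seeds the next
#' pass, guaranteeing segment continuity across windows. When a window
#' compresses nothing (every point is a character point, i.e. the data are
#' locally random) all window points are emitted and the window is emptied.
#' Each source point is read exactly once and emission begins before the
#' source is exhausted.
#'
#' @param source a function `f(n)` returning the next at-most-`n` stream
#'   points as a list/data.frame with `index` and `value` entries, or `NULL`
#'   when the stream has ended. A short read (fewer than `n` points) must
#'   only happen at the end of the stream. See [series_source()].
#' @param config a [segmenter_config()].
#' @param sink optional function `f(index, value, projection)` called with
#'   each batch of emitted character points; when `NULL`, emitted points are
#'   accumulated and returned.
#' @return An object of class `presee_result`: list with `points` (data.frame
#'   `index`, `value`, `projection`; `NULL` when a `sink` is used), `n_in`,
#'   `n_out`, `compress_rate`, `evals` (criterion evaluations) and
#'   `reads_at_first_emit` (source points read when the first character point
#'   was released).
#' @seealso [presee()] for in-memory series, [segment_file()] for files.
#' @export
presee_stream <- function(source, config = segmenter_config(), sink = NULL) {
  cap <- config$window_size
  batch <- config$batch_size
  w <- config$weights

  acc <- if (is.null(sink)) new_accumulator()
  n_in <- 0
  n_out <- 0
  evals <- 0
  reads_at_first_emit <- NA_real_
  last_index <- -Inf
  last_emitted <- 0       # global 1-based position of last emitted point
  offset <- 0             # global position of window[1] is offset + 1

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

    final <- exhausted
    limit <- if (final) 0L else batch + 1L
    r <- .greedy_scan_cpp(wx, wy, w$wp, w$wa, limit)
    evals <- evals + r$evals

    if (final) {
      keep <- r$cp[offset + r$cp > last_emitted]
      if (length(keep)) emit(wx[keep], wy[keep], offset + keep)
      break
    }
    if (r$all_points) {
      # no proper segment exists: keep everything, empty the window
      keep <- seq_len(m)[offset + seq_len(m) > last_emitted]
      if (length(keep)) emit(wx[keep], wy[keep], offset + keep)
      wx <- numeric(0)
      wy <- numeric(0)
      offset <- offset + m
    } else {
      take <- r$cp[seq_len(min(batch + 1L, length(r$cp)))]
      new <- take[offset + take > last_emitted]
      if (length(new)) emit(wx[new], wy[new], offset + new)
      lastp <- take[length(take)]
      wx <- wx[lastp:m]
      wy <- wy[lastp:m]
      offset <- offset + lastp - 1
    }
  }

  structure(list(points = if (is.null(sink)) acc$drain(),
                 n_in = n_in,
                 n_out = n_out,
                 compress_rate = if (n_in > 0) n_out / n_in else NA_real_,
                 evals = evals,
                 reads_at_first_emit = reads_at_first_emit,
                 config = config),
            class = "presee_result")
}

#' @export
print.presee_result <- function(x, ...) {
  cat(sprintf(paste0("MDL stream segmentation: %s points in, %s character ",
                     "points out\ncompress rate %.5f (window %d, batch %d, ",
                     "wp %.2f, wa %.2f)\n"),
              format(x$n_in, big.mark = ","), format(x$n_out, big.mark = ","),
              x$compress_rate, x$config$window_size, x$config$batch_size,
              x$config$weights$wp, x$config$weights$wa))
  invisible(x)
}

#' Segment an in-memory time series
#'
#' Convenience wrapper running [presee_stream()] over a series already held
#' in memory. With the default configuration the segmenter is parameter-free.
#'
#' @param x stream points (see [hypothesis_cost()] for accepted forms).
#' @param config a [segmenter_config()].
#' @return A `presee_result` (see [presee_stream()]).
#' @examples
#' r <- presee(c(0, 0, 0, 5, 10, 15, 20, 20, 20))
#' r$points
#' @export
presee <- function(x, config = segmenter_config()) {
  presee_stream(points_source(x), config)
}

#' Segment a stream file into a character-point file
#'
#' Streams a plain-text series through [presee_stream()] with memory bounded
#' by the window size, writing character points as they are released.
#'
#' @param in_path input stream file (see [read_series()] for the dialects).
#' @param out_path output file; rows are `index,value` or
#'   `index,value,projection`.
#' @param config a [segmenter_config()].
#' @param dialect,delimiter,header passed to [series_source()].
#' @param projection write the 1-based stream position as a third column.
#' @param progress_every report points read/emitted via [message()] every
#'   this many input points; `0` disables logging.
#' @return Invisibly, a list with `n_in`, `n_out` and `compress_rate`.
#' @export
segment_file <- function(in_path, out_path, config = segmenter_config(),
                         dialect = "auto", delimiter = NULL, header = FALSE,
                         projection = FALSE, progress_every = 0) {
  src <- series_source(in_path, dialect = dialect, delimiter = delimiter,
                       header = header)
  con <- file(out_path, open = "wt")
  on.exit(close(con), add = TRUE)
  n_read <- 0
  next_report <- progress_every
  counting_src <- function(n) {
    ch <- src(n)
    if (!is.null(ch)) {
      n_read <<- n_read + length(ch$index)
      if (progress_every > 0 && n_read >= next_report) {
        message(sprintf("read %d points", n_read))
        next_report <<- next_report + progress_every
      }
    }
    ch
  }
  sink <- function(ix, vv, proj) {
    lines <- if (projection) {
      sprintf("%s,%s,%d", format_num(ix), format_num(vv), as.integer(proj))
    } else {
      sprintf("%s,%s", format_num(ix), format_num(vv))
    }
    writeLines(lines, con)
  }
  r <- presee_stream(counting_src, config, sink)
  if (progress_every > 0) {
    message(sprintf("done: %d points read, %d character points emitted",
                    r$n_in, r$n_out))
  }
  invisible(list(n_in = r$n_in, n_out = r$n_out,
                 compress_rate = r$compress_rate))
}
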