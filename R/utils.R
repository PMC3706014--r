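# internal coercion and validation helpers

# Coerce a point set to list(x = index, y = value).
# Accepts a data.frame with index/value columns (or first two columns),
# a two-column matrix, or a bare numeric vector (0-based serial indices).
as_points <- function(points) {
  if (is.numeric(points) && is.null(dim(points))) {
    return(list(x = as.numeric(seq_along(points) - 1), y = as.numeric(points)))
  }
  if (is.matrix(points)) {
    stopifnot(ncol(points) >= 2)
    return(list(x = as.numeric(points[, 1]), y = as.numeric(points[, 2])))
  }
  if (is.data.frame(points)) {
    nm <- names(points)
    ix <- if ("index" %in% nm) points[["index"]] else points[[1]]
    vv <- if ("value" %in% nm) points[["value"]] else points[[2]]
    return(list(x = as.numeric(ix), y = as.numeric(vv)))
  }
  stop("cannot interpret `points`: need a numeric vector, matrix or data.frame")
}

check_point_order <- function(x) {
  if (length(x) > 1 && any(diff(x) <= 0)) {
    stop("stream indices must be strictly increasing", call. = FALSE)
  }
  invisible(x)
}

# code-length term helper: log2 clamped below at an argument of 1
log2_floor1 <- function(v) {
  out <- log2(pmax(1, v))
  out
}

# growing accumulator for emitted points (amortized O(1) append)
new_accumulator <- function(init = 1024L) {
  buf_i <- numeric(init); buf_v <- numeric(init); buf_p <- numeric(init)
  n <- 0L
  list(
    add = function(idx, val, proj) {
      k <- length(idx)
      if (n + k > length(buf_i)) {
        newlen <- max(2L * length(buf_i), n + k)
        length(buf_i) <<- newlen; length(buf_v) <<- newlen; length(buf_p) <<- newlen
      }
      buf_i[(n + 1L):(n + k)] <<- idx
      buf_v[(n + 1L):(n + k)] <<- val
      buf_p[(n + 1L):(n + k)] <<- proj
      n <<- n + k
    },
    size = function() n,
    drain = function() {
      data.frame(index = buf_i[seq_len(n)], value = buf_v[seq_len(n)],
                 projection = buf_p[seq_len(n)])
    }
  )
}
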