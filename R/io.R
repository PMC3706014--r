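# Plain-text stream files: headerless CSV/TSV with columns index,value, or a
# single-column dialect whose rows get 0-based serial indices.

format_num <- function(v) {
  ifelse(v == round(v) & abs(v) < 1e15,
         sprintf("%.0f", v),
         formatC(v, digits = 17, format = "g"))
}

#' Chunked reader over a stream file
#'
#' Returns a source function for [presee_stream()] / [swbu_stream()]: calling
#' it with `n` yields the next at-most-`n` points as `list(index, value)`
#' (plus `NULL` once the file is drained), holding only one chunk in memory
#' at a time. Indices are validated to be strictly increasing; malformed rows
#' raise an error naming the offending line.
#'
#' @param path path to the stream file.
#' @param dialect `"index_value"` (two columns), `"value_only"` (one column,
#'   0-based serial indices are assigned), or `"auto"` to decide from the
#'   first row.
#' @param delimiter field separator; `NULL` auto-detects comma or tab.
#' @param header skip a header row.
#' @return A function `f(n)`; it also accepts `f(0)` as a no-op peek.
#' @seealso [read_series()] for eager reading.
#' @export
series_source <- function(path, dialect = c("auto", "index_value", "value_only"),
                          delimiter = NULL, header = FALSE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  con <- file(path, open = "rt")
  open_flag <- TRUE
  line_no <- 0
  serial <- 0
  last_index <- -Inf
  if (header) {
    readLines(con, n = 1L)
    line_no <- 1
  }

  parse_chunk <- function(lines) {
    first <- line_no + 1
    line_no <<- line_no + length(lines)
    keep <- nzchar(trimws(lines))
    lines <- lines[keep]
    if (!length(lines)) return(list(index = numeric(0), value = numeric(0)))
    lineno <- (first:(first + length(keep) - 1))[keep]
    if (is.null(delimiter)) {
      delimiter <<- if (grepl("\t", lines[1], fixed = TRUE)) "\t" else ","
    }
    parts <- strsplit(lines, delimiter, fixed = TRUE)
    nf <- lengths(parts)
    if (dialect == "auto") {
      dialect <<- if (nf[1] >= 2) "index_value" else "value_only"
    }
    want <- if (dialect == "index_value") 2L else 1L
    bad <- which(nf < want)
    if (length(bad)) {
      stop(sprintf("parse error at line %d of %s: expected %d field(s)",
                   lineno[bad[1]], path, want), call. = FALSE)
    }
    f1 <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 1L)))
    if (dialect == "index_value") {
      f2 <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L)))
      bad <- which(!is.finite(f1) | !is.finite(f2))
      if (length(bad)) {
        stop(sprintf("parse error at line %d of %s: non-numeric field",
                     lineno[bad[1]], path), call. = FALSE)
      }
      index <- f1
      value <- f2
    } else {
      bad <- which(!is.finite(f1))
      if (length(bad)) {
        stop(sprintf("parse error at line %d of %s: non-numeric field",
                     lineno[bad[1]], path), call. = FALSE)
      }
      index <- serial + seq_along(f1) - 1
      serial <<- serial + length(f1)
      value <- f1
    }
    if (index[1] <= last_index || (length(index) > 1 && any(diff(index) <= 0))) {
      stop(sprintf("ordering violation near line %d of %s: indices must be strictly increasing",
                   lineno[1], path), call. = FALSE)
    }
    last_index <<- index[length(index)]
    list(index = index, value = value)
  }

  function(n) {
    if (n <= 0) return(list(index = numeric(0), value = numeric(0)))
    if (!open_flag) return(NULL)
    repeat {
      lines <- readLines(con, n = n)
      if (!length(lines)) {
        close(con)
        open_flag <<- FALSE
        return(NULL)
      }
      short <- length(lines) < n
      ch <- tryCatch(parse_chunk(lines), error = function(e) {
        close(con)
        open_flag <<- FALSE
        stop(e)
      })
      if (short) {  # hit end of file: release the connection eagerly
        close(con)
        open_flag <<- FALSE
      }
      if (length(ch$index)) return(ch)  # skip all-blank chunks
      if (short) return(NULL)
    }
  }
}

#' Read a whole stream file
#'
#' Eager counterpart of [series_source()], returning the full series.
#'
#' @inheritParams series_source
#' @param chunk_size rows pulled per read.
#' @return A data.frame with columns `index` and `value`.
#' @examples
#' f <- tempfile()
#' writeLines(c("0,1.5", "1,2.5"), f)
#' read_series(f)
#' @export
read_series <- function(path, dialect = c("auto", "index_value", "value_only"),
                        delimiter = NULL, header = FALSE, chunk_size = 65536L) {
  src <- series_source(path, dialect = dialect, delimiter = delimiter,
                       header = header)
  ix <- list()
  vv <- list()
  k <- 0
  repeat {
    ch <- src(chunk_size)
    if (is.null(ch)) break
    k <- k + 1
    ix[[k]] <- ch$index
    vv[[k]] <- ch$value
  }
  data.frame(index = unlist(ix) %||% numeric(0),
             value = unlist(vv) %||% numeric(0))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write stream points to a plain-text file
#'
#' Writes headerless comma-separated rows. Values round-trip exactly through
#' [read_series()] at the default precision.
#'
#' @param points a data.frame with `index` and `value` (and optionally
#'   `projection`) columns, or any form accepted by [segment_window()].
#' @param path output file path.
#' @param projection also write the `projection` column (requires it to be
#'   present in `points`).
#' @param digits round values to this many decimal places (`NULL` keeps full
#'   precision).
#' @return Invisibly, the number of rows written.
#' @export
write_points <- function(points, path, projection = FALSE, digits = NULL) {
  proj <- if (is.data.frame(points) && "projection" %in% names(points)) {
    points$projection
  }
  p <- as_points(points)
  val <- if (is.null(digits)) format_num(p$y) else sprintf("%.*f", digits, p$y)
  lines <- if (projection) {
    if (is.null(proj)) stop("`points` carries no projection column")
    sprintf("%s,%s,%d", format_num(p$x), val, as.integer(proj))
  } else {
    sprintf("%s,%s", format_num(p$x), val)
  }
  writeLines(lines, path)
  invisible(length(lines))
}
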