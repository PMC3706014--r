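test_that("segment_window keeps endpoints and compresses straight stretches", {
  two <- data.frame(index = c(0, 5), value = c(1, 2))
  expect_equal(segment_window(two)$projection, c(1, 2))
  # well-spaced collinear points collapse to the endpoints
  line <- data.frame(index = c(0, 10, 20, 30), value = 0)
  expect_equal(segment_window(line)$projection, c(1, 4))
  # a large saw-tooth cannot be merged: every point is a character point
  saw <- data.frame(index = c(0, 10, 20, 30), value = c(0, 10, 0, 10))
  expect_equal(segment_window(saw)$projection, 1:4)
  expect_error(segment_window(data.frame(index = 0, value = 1)), "at least 2")
})

test_that("compiled window scan agrees with the plain-R greedy", {
  set.seed(31)
  for (rep in 1:40) {
    pts <- rand_walk(sample(5:40, 1), scale = stats::runif(1, 0.5, 10))
    expect_equal(segment_window(pts)$projection, ref_greedy(pts))
  }
})

test_that("streaming equals the whole-buffer scan when input fits one window", {
  set.seed(32)
  pts <- rand_walk(400, scale = 6)
  whole <- segment_window(pts)$projection
  streamed <- presee(pts, segmenter_config(window_size = 1000))$points$projection
  expect_equal(streamed, as.numeric(whole))
  # and the result is identical for any batch size on one window
  for (b in c(2, 5, 50)) {
    r <- presee(pts, segmenter_config(window_size = 1000, batch_size = b))
    expect_equal(r$points$projection, as.numeric(whole))
  }
})

test_that("constant streams emit character points at window joins only", {
  n <- 2000
  w <- 100
  pts <- data.frame(index = 0:(n - 1), value = 10 * (0:(n - 1)))  # steep line
  r <- presee(pts, segmenter_config(window_size = w))
  expect_equal(r$n_out, ceiling((n - 1) / (w - 1)) + 1)
  proj <- r$points$projection
  expect_equal(proj[1], 1)
  expect_equal(proj[length(proj)], n)
  expect_true(all(diff(proj) > 0))
})

test_that("locally random data pass through uncompressed", {
  alt <- data.frame(index = 0:199, value = rep(c(0, 500), 100))
  r <- presee(alt, segmenter_config(window_size = 50))
  expect_equal(r$n_out, 200)
  expect_equal(r$points$value, alt$value)
})

test_that("each source point is read exactly once and order is enforced", {
  set.seed(33)
  pts <- rand_walk(1200, scale = 4)
  reads <- 0
  base <- make_source(pts)
  src <- function(n) {
    ch <- base(n)
    if (!is.null(ch)) reads <<- reads + length(ch$index)
    ch
  }
  r <- presee_stream(src, segmenter_config(window_size = 150))
  expect_equal(reads, 1200)
  expect_equal(r$n_in, 1200)
  bad <- make_source(data.frame(index = c(0, 2, 1), value = 0))
  expect_error(presee_stream(bad, segmenter_config()), "order violation")
  empty <- function(n) NULL
  r0 <- presee_stream(empty, segmenter_config())
  expect_equal(r0$n_out, 0)
})

test_that("criterion evaluations scale linearly with stream length", {
  ev <- vapply(c(20000, 40000), function(n) {
    s <- generate_stream(synth_config(n, seed = 5))
    presee(s, segmenter_config(window_size = 200))$evals
  }, numeric(1))
  expect_gte(ev[2] / ev[1], 1.8)
  expect_lte(ev[2] / ev[1], 2.6)
})

test_that("projections are monotone and preserve both stream endpoints", {
  set.seed(34)
  for (wsize in c(20, 100)) {
    pts <- rand_walk(500, scale = 3)
    r <- presee(pts, segmenter_config(window_size = wsize))
    proj <- r$points$projection
    expect_true(all(diff(proj) > 0))
    expect_equal(proj[1], 1)
    expect_equal(proj[length(proj)], 500)
    expect_equal(r$points$index, pts$index[proj])
    expect_equal(r$points$value, pts$value[proj])
  }
})

test_that("window size barely affects the emitted character points", {
  s <- generate_stream(synth_config(10000, seed = 42))
  a <- presee(s, segmenter_config(window_size = 100))$points$projection
  b <- presee(s, segmenter_config(window_size = 1000))$points$projection
  agreement <- length(intersect(a, b)) / max(length(a), length(b))
  expect_gte(agreement, 0.9)
})

test_that("buffering is bounded by the window size", {
  set.seed(35)
  pts <- rand_walk(4000, scale = 4)
  wsize <- 128
  requests <- integer(0)
  base <- make_source(pts)
  src <- function(n) {
    requests <<- c(requests, n)
    base(n)
  }
  r <- presee_stream(src, segmenter_config(window_size = wsize))
  # the driver never asks for more than one window of points at a time, and
  # refills incrementally rather than slurping the stream
  expect_lte(max(requests), wsize)
  expect_gte(length(requests), 4000 / wsize)
  expect_lte(r$reads_at_first_emit, wsize)
})

test_that("segment_file streams a file through the segmenter", {
  line <- data.frame(index = c(0, 10, 20), value = 0)
  fin <- tempfile(fileext = ".csv")
  fout <- tempfile(fileext = ".csv")
  write_points(line, fin)
  r <- segment_file(fin, fout)
  expect_equal(r$n_in, 3)
  expect_equal(r$n_out, 2)
  expect_equal(read_series(fout), data.frame(index = c(0, 20), value = c(0, 0)))

  # empty input file
  writeLines(character(0), fin)
  r0 <- segment_file(fin, fout)
  expect_equal(r0$n_in, 0)
  expect_equal(nrow(read_series(fout)), 0)

  # a single window of saw-tooth data passes through like segment_window
  saw <- data.frame(index = 0:49, value = rep(c(0, 300), 25))
  write_points(saw, fin)
  r2 <- segment_file(fin, fout, segmenter_config(window_size = 100))
  expect_equal(r2$n_out, nrow(segment_window(saw)))
})
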