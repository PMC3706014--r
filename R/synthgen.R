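#' Configuration of the synthetic stream generator
#'
#' Parameters of the bounded random walk emitted by [generate_stream()]:
#' values start at the midpoint `(lb + ub) / 2` and fluctuate by
#' `sign * (U mod max(1, floor(B))) * sharpness`, where the sign is chosen
#' uniformly, `U` is a uniform integer and `B` is the distance from the
#' current value to the bound in the direction of motion — so steps meet
#' increasing resistance the further the walk strays from the midpoint, and
#' values stay inside `[lb, ub]`.
#'
#' @param size number of records (at least 1).
#' @param lb,ub lower and upper value bounds, `lb < ub`.
#' @param sharpness non-negative fluctuation power scaling every step;
#'   `0` yields a constant series at the midpoint.
#' @param seed optional RNG seed applied by [generate_stream()].
#' @return An object of class `presee_synth_config`.
#' @examples
#' synth_config(10000, 0, 3000, 0.001, seed = 1)
#' @export
synth_config <- function(size, lb = 0, ub = 3000, sharpness = 0.001,
                         seed = NULL) {
  if (size < 1) stop("size must be at least 1")
  if (!(lb < ub)) stop("need lb < ub")
  if (sharpness < 0) stop("sharpness must be non-negative")
  structure(list(size = size, lb = lb, ub = ub, sharpness = sharpness,
                 seed = seed),
            class = "presee_synth_config")
}

#' Benchmark presets for the synthetic generator
#'
#' The eleven standard parameterizations used by the package's benchmark
#' experiments: sizes from 1e4 to 1e10 records, bounds `[0, 3000]` (presets
#' 1-9) or `[0, 5000]` (presets 10-11), and sharpness from 1e-3 down to 1e-5.
#'
#' @param dataset_number integer in 1..11.
#' @param seed optional RNG seed stored in the returned config.
#' @return A [synth_config()].
#' @examples
#' synth_preset(1) # 1e4 records in [0, 3000], sharpness 0.001
#' @export
synth_preset <- function(dataset_number, seed = NULL) {
  presets <- list(
    list(1e4,  0, 3000, 0.001),
    list(1e5,  0, 3000, 0.001),
    list(1e6,  0, 3000, 0.001),
    list(1e7,  0, 3000, 0.001),
    list(1e7,  0, 3000, 0.002),
    list(1e7,  0, 3000, 0.0005),
    list(1e7,  0, 3000, 0.0002),
    list(1e7,  0, 3000, 0.0001),
    list(1e8,  0, 3000, 0.00005),
    list(1e9,  0, 5000, 0.00001),
    list(1e10, 0, 5000, 0.00001)
  )
  if (!(dataset_number %in% seq_along(presets))) {
    stop("dataset_number must be an integer in 1..11")
  }
  p <- presets[[dataset_number]]
  synth_config(p[[1]], p[[2]], p[[3]], p[[4]], seed = seed)
}

#' Generate a bounded random-walk stream
#'
#' Deterministic given `config$seed` (or the current RNG state when no seed is
#' set). Indices are 0-based serial numbers.
#'
#' @param config a [synth_config()].
#' @return A data.frame with columns `index` and `value`.
#' @examples
#' head(generate_stream(synth_config(100, 0, 3000, 0.001, seed = 7)))
#' @export
generate_stream <- function(config) {
  if (!inherits(config, "presee_synth_config")) {
    stop("config must be a synth_config()")
  }
  if (!is.null(config$seed)) set.seed(config$seed)
  v <- if (config$sharpness == 0) {
    rep((config$lb + config$ub) / 2, config$size)
  } else {
    .gen_walk_cpp(config$size, config$lb, config$ub, config$sharpness)
  }
  data.frame(index = as.numeric(seq_len(config$size) - 1), value = v)
}
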