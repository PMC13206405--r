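#' Gaussian-source environment specification
#'
#' An environment is a set of Gaussian sources; at each timestep one source
#' is chosen uniformly at random and emits one observation. The generating
#' source of an observation is latent to the learner but recorded as ground
#' truth.
#'
#' @param means source means.
#' @param sds source standard deviations (positive).
#' @return list of class `cbsl_environment` with `means` and `sds`.
#' @export
environment_spec <- function(means, sds) {
  means <- as.numeric(means)
  sds <- rep_len(as.numeric(sds), length(means))
  if (!length(means)) stop("environment needs at least one source",
                           call. = FALSE)
  .assert_finite(c(means, sds), "environment spec")
  if (any(sds <= 0)) stop("source standard deviations must be positive",
                          call. = FALSE)
  structure(list(means = means, sds = sds), class = "cbsl_environment")
}

#' The standard three-source environment
#'
#' Three Gaussian sources of standard deviation 1 with equal spacing between
#' neighbouring means. Spacing 6 gives the unambiguous environment (virtually
#' no overlap), 3 the ambiguous one, 1 the very ambiguous one. Means are
#' placed at `{0, d, 2d}`; only the spacing matters, as the learner is
#' translation-equivariant.
#'
#' @param distance spacing between neighbouring source means (> 0).
#' @return a [environment_spec()].
#' @export
make_standard_environment <- function(distance) {
  if (!is.finite(distance) || distance <= 0) {
    stop("distance must be a positive number", call. = FALSE)
  }
  environment_spec(means = c(0, distance, 2 * distance), sds = c(1, 1, 1))
}

#' @export
print.cbsl_environment <- function(x, ...) {
  cat(sprintf("<cbsl environment> %d Gaussian source(s)\n", length(x$means)))
  print(data.frame(mean = x$means, sd = x$sds), row.names = FALSE)
  invisible(x)
}

#' Sample an observation stream with ground-truth labels
#'
#' Each record is drawn by a uniform source choice followed by a Gaussian
#' draw. The stream is fully determined by `seed`; source choices and value
#' draws use separate derived substreams, so extending `T` extends a stream
#' rather than reshuffling it. The environment is open loop: streams never
#' depend on model state.
#'
#' @param env a [environment_spec()].
#' @param T number of observations (>= 0).
#' @param seed integer seed.
#' @return data.frame with columns `t`, `o`, `source` (1-based source index).
#' @export
sample_stream <- function(env, T, seed) {
  T <- as.integer(T)
  if (T < 0) stop("T must be nonnegative", call. = FALSE)
  if (T == 0) {
    return(data.frame(t = integer(0), o = numeric(0), source = integer(0)))
  }
  ss <- derive_seeds(seed, 2)
  k <- length(env$means)
  src <- withr::with_seed(ss[1], sample.int(k, T, replace = TRUE))
  z <- withr::with_seed(ss[2], rnorm(T))
  data.frame(t = seq_len(T),
             o = env$means[src] + env$sds[src] * z,
             source = src)
}

#' Sample a balanced test set
#'
#' Draws exactly `n_per_source` observations from each source, with ground
#' truth labels, for the frozen-model behavioural test phase.
#'
#' @param env a [environment_spec()].
#' @param n_per_source observations per source (default 20).
#' @param seed integer seed.
#' @return data.frame with columns `t`, `o`, `source`.
#' @export
sample_test_set <- function(env, n_per_source = 20, seed) {
  n_per_source <- as.integer(n_per_source)
  if (n_per_source < 1) stop("n_per_source must be >= 1", call. = FALSE)
  k <- length(env$means)
  src <- rep(seq_len(k), each = n_per_source)
  z <- withr::with_seed(as.integer(seed), rnorm(k * n_per_source))
  data.frame(t = seq_along(src),
             o = env$means[src] + env$sds[src] * z,
             source = src)
}

#' Write / read an observation stream as CSV
#'
#' Two-column CSV (`observation`, `source_label`) with a header row.
#'
#' @param stream data.frame as from [sample_stream()].
#' @param path file path.
#' @return `read_stream()` returns a data.frame with columns `t`, `o`,
#'   `source`.
#' @export
write_stream <- function(stream, path) {
  write.csv(data.frame(observation = stream$o, source_label = stream$source),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_stream
#' @export
read_stream <- function(path) {
  df <- read.csv(path)
  if (!all(c("observation", "source_label") %in% names(df))) {
    stop("stream CSV must have columns 'observation' and 'source_label'",
         call. = FALSE)
  }
  data.frame(t = seq_len(nrow(df)), o = as.numeric(df$observation),
             source = as.integer(df$source_label))
}
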