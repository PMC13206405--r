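# numerical guards shared across the package

# precisions are floored here; exp() arguments are clipped so that extreme
# sigma/lambda sweeps cannot overflow to Inf during long runs
.PREC_FLOOR <- 1e-12

.clip_exp <- function(x) exp(pmin(pmax(x, -700), 700))

.assert_finite <- function(x, what) {
  if (!all(is.finite(x))) {
    stop(sprintf("non-finite value in %s", what), call. = FALSE)
  }
  invisible(x)
}

#' Derive child seeds from a master seed
#'
#' Splits one master seed into `n` independent substream seeds without
#' disturbing the caller's RNG state. This is the seed discipline used
#' throughout the experiment harness (master seed, then per-replicate
#' seeds, then separate training/test substreams), so that, e.g., test-phase
#' draws never perturb training streams. Derived seeds stay below 2^31 - 1.
#'
#' @param seed master integer seed.
#' @param n number of child seeds.
#' @return integer vector of length `n`.
#' @export
derive_seeds <- function(seed, n) {
  withr::with_seed(as.integer(seed), sample.int(2147483646L, n))
}
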