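#' Component-level learner: a two-parent Hierarchical Gaussian Filter
#'
#' Each representational component learns through an isolated HGF consisting
#' of a continuous input node with a value parent (tracking the location of
#' observations) and a noise parent (tracking their log-variance). All update
#' magnitudes are scaled by an externally supplied activity level `a`, which
#' is how the system level gates component learning.
#'
#' All functions here are vectorised over components: a "state" is a list of
#' equal-length numeric vectors, so a whole ensemble can be predicted and
#' updated in one call.
#'
#' @param zeta tonic observation-noise constant of the input node
#'   (log-variance scale). Set from the system parameter `sigma` at birth and
#'   immutable afterwards.
#' @param mu_value,pi_value mean and precision of the value parent.
#' @param mu_noise,pi_noise mean and precision of the noise parent
#'   (log-variance scale).
#' @return `hgf_state()` returns a list of class `cbsl_hgf_state` with fields
#'   `zeta`, `mu_value`, `pi_value`, `mu_noise`, `pi_noise`.
#' @export
hgf_state <- function(zeta, mu_value, pi_value = 1, mu_noise = 0,
                      pi_noise = 1) {
  n <- length(mu_value)
  st <- list(
    zeta = rep_len(as.numeric(zeta), n),
    mu_value = as.numeric(mu_value),
    pi_value = rep_len(as.numeric(pi_value), n),
    mu_noise = rep_len(as.numeric(mu_noise), n),
    pi_noise = rep_len(as.numeric(pi_noise), n)
  )
  .assert_finite(unlist(st, use.names = FALSE), "HGF state")
  if (any(st$pi_value <= 0) || any(st$pi_noise <= 0)) {
    stop("HGF precisions must be positive", call. = FALSE)
  }
  structure(st, class = "cbsl_hgf_state")
}

#' Initialise a fresh component anchored on an observation
#'
#' A new component starts with its value-parent mean at the current
#' observation, unit parent precisions, a zero noise-parent mean and a tonic
#' noise constant equal to the system parameter `sigma` at the moment of
#' birth (which it keeps for life, even if `sigma` later changes).
#'
#' @param o observation (finite real) the component is anchored on.
#' @param sigma system-level initial-precision parameter; becomes the
#'   component's `zeta`.
#' @return an [hgf_state()].
#' @export
init_component <- function(o, sigma) {
  .assert_finite(o, "observation")
  hgf_state(zeta = sigma, mu_value = o, pi_value = 1, mu_noise = 0,
            pi_noise = 1)
}

#' One-step-ahead HGF prediction
#'
#' Computes the predicted means and precisions for the input node and both
#' parents. Parent means carry over; parent precisions leak by `exp(omega)`
#' added to the variance, so predicted precision is strictly below the
#' posterior precision it was derived from. The input-node precision
#' prediction is `1 / exp(zeta + mu_noise)` with the pre-update noise mean.
#'
#' @param state an [hgf_state()] (vectorised over components).
#' @param omega global baseline-uncertainty parameter shared by both parents.
#' @return list with `mu_hat_input`, `pi_hat_input`, `mu_hat_value`,
#'   `pi_hat_value`, `mu_hat_noise`, `pi_hat_noise`.
#' @export
hgf_predict <- function(state, omega) {
  .assert_finite(unlist(unclass(state), use.names = FALSE), "HGF state")
  eo <- .clip_exp(omega)
  list(
    mu_hat_input = state$mu_value,
    pi_hat_input = pmax(.clip_exp(-(state$zeta + state$mu_noise)),
                        .PREC_FLOOR),
    mu_hat_value = state$mu_value,
    pi_hat_value = pmax(1 / (1 / state$pi_value + eo), .PREC_FLOOR),
    mu_hat_noise = state$mu_noise,
    pi_hat_noise = pmax(1 / (1 / state$pi_noise + eo), .PREC_FLOOR)
  )
}

#' Activity-scaled HGF update
#'
#' Applies the precision-weighted prediction-error updates, every increment
#' multiplied by the activity level `a` in `[0, 1]`. The order matters: the
#' value-parent precision is updated first, the value-parent mean uses that
#' posterior precision, the noise prediction error `epsilon` uses the
#' posterior value precision, and the noise-parent mean uses the posterior
#' noise precision. `a = 0` is an exact fixed point (no learning).
#'
#' @param state an [hgf_state()] the prediction was computed from.
#' @param pred the matching [hgf_predict()] output.
#' @param o scalar observation.
#' @param a activity level(s) in `[0, 1]`, recycled over components.
#' @param omega global HGF parameter (unused directly here; kept so the pair
#'   `(predict, update)` shares one signature shape).
#' @return list with `state` (posterior [hgf_state()]) and `errors` (list of
#'   `delta`, the value prediction error, and `epsilon`, the noise prediction
#'   error, which is always `>= -1`).
#' @export
hgf_update <- function(state, pred, o, a, omega) {
  .assert_finite(o, "observation")
  if (any(a < 0) || any(a > 1) || any(!is.finite(a))) {
    stop("activity level must lie in [0, 1]", call. = FALSE)
  }
  delta <- o - pred$mu_hat_input
  pi_value <- pmax(pred$pi_hat_value + pred$pi_hat_input * a, .PREC_FLOOR)
  mu_value <- pred$mu_hat_value + (pred$pi_hat_input / pi_value) * delta * a
  # noise prediction error: precision-weighted squared error plus the
  # posterior-uncertainty correction, minus its expectation of 1
  epsilon <- pred$pi_hat_input * delta^2 +
    pred$pi_hat_input / pi_value - 1
  pi_noise <- pmax(pred$pi_hat_noise + ((1 + epsilon) / 2) * a, .PREC_FLOOR)
  mu_noise <- pred$mu_hat_noise + (epsilon / (2 * pi_noise)) * a
  list(
    state = hgf_state(state$zeta, mu_value, pi_value, mu_noise, pi_noise),
    errors = list(delta = delta, epsilon = epsilon)
  )
}
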