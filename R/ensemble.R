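#' System-level parameters
#'
#' The three system-level free parameters plus the component-level HGF
#' parameter, with the standard parametrisation as defaults.
#'
#' @param sigma initial-precision parameter: a newborn component's capacity
#'   precision is `exp(-sigma)`, so lower `sigma` means sharper newborns and
#'   a stronger propensity for structural expansion.
#' @param lambda internal-constraint scale: larger `lambda` relaxes the
#'   constraint function `g` towards 1 (weights track activity fully);
#'   strongly negative `lambda` drives `g` towards 0 (weights freeze).
#' @param alpha birth weight and removal threshold, in `[0, 1]`.
#' @param omega HGF baseline-uncertainty (learning-rate) parameter shared by
#'   all parent nodes of all components.
#' @return list of class `cbsl_params`.
#' @export
standard_params <- function(sigma = 0, lambda = 0.7, alpha = 0.01,
                            omega = -6) {
  p <- list(sigma = as.numeric(sigma), lambda = as.numeric(lambda),
            alpha = as.numeric(alpha), omega = as.numeric(omega))
  .assert_finite(unlist(p), "system parameters")
  if (p$alpha < 0 || p$alpha > 1) {
    stop("alpha must lie in [0, 1]", call. = FALSE)
  }
  structure(p, class = "cbsl_params")
}

#' Create an empty ensemble
#'
#' The ensemble holds all live components in birth order as parallel vectors
#' (identity, birth time, HGF state fields, weight) together with the system
#' parameters and the timestep counter. Component ids are never reused: a
#' removed id is retired permanently.
#'
#' @param params a [standard_params()] list.
#' @return object of class `cbsl_ensemble`.
#' @export
new_ensemble <- function(params = standard_params()) {
  if (!inherits(params, "cbsl_params")) {
    params <- do.call(standard_params, as.list(params))
  }
  structure(list(
    t = 0L,
    next_id = 1L,
    id = integer(0),
    birth = integer(0),
    zeta = numeric(0),
    mu_value = numeric(0),
    pi_value = numeric(0),
    mu_noise = numeric(0),
    pi_noise = numeric(0),
    weight = numeric(0),
    params = params
  ), class = "cbsl_ensemble")
}

#' @export
print.cbsl_ensemble <- function(x, ...) {
  p <- x$params
  cat(sprintf(
    "<cbsl ensemble> t = %d, %d component(s) | sigma=%g lambda=%g alpha=%g omega=%g\n",
    x$t, length(x$id), p$sigma, p$lambda, p$alpha, p$omega))
  if (length(x$id)) {
    caps <- capacities(x)
    df <- data.frame(id = x$id, birth = x$birth, weight = x$weight,
                     mu = caps$mu, tau = caps$tau)
    print(head(df, 10L), row.names = FALSE)
    if (length(x$id) > 10L) cat(sprintf("... and %d more\n", length(x$id) - 10L))
  }
  invisible(x)
}

#' @export
as.data.frame.cbsl_ensemble <- function(x, ...) {
  caps <- capacities(x)
  data.frame(id = x$id, birth = x$birth, weight = x$weight,
             mu = caps$mu, tau = caps$tau, zeta = x$zeta,
             mu_value = x$mu_value, pi_value = x$pi_value,
             mu_noise = x$mu_noise, pi_noise = x$pi_noise)
}

# internal: view the ensemble's component vectors as one vectorised HGF state
.ens_state <- function(ens) {
  structure(list(zeta = ens$zeta, mu_value = ens$mu_value,
                 pi_value = ens$pi_value, mu_noise = ens$mu_noise,
                 pi_noise = ens$pi_noise), class = "cbsl_hgf_state")
}

#' Representational capacities of the live components
#'
#' A component's representational capacity is the Gaussian over observation
#' space given by the HGF input-node predictions: location `mu` is the
#' predicted input mean and precision `tau` the predicted input precision.
#'
#' @param ens a `cbsl_ensemble`.
#' @return data.frame with columns `id`, `mu`, `tau`.
#' @export
capacities <- function(ens) {
  pred <- hgf_predict(.ens_state(ens), ens$params$omega)
  data.frame(id = ens$id, mu = pred$mu_hat_input, tau = pred$pi_hat_input)
}

#' Gaussian density in precision parametrisation
#'
#' `f(o; mu, tau) = sqrt(tau / 2 pi) * exp(-tau (o - mu)^2 / 2)`, the
#' external-constraint factor in the activity computation.
#'
#' @param o observation(s).
#' @param mu,tau capacity location and precision (`tau > 0`).
#' @param log return the log-density (used internally to avoid underflow at
#'   large standardised distances).
#' @return (log-)density values.
#' @export
gaussian_density <- function(o, mu, tau, log = FALSE) {
  ld <- 0.5 * (log(tau) - log(2 * pi)) - 0.5 * tau * (o - mu)^2
  if (log) ld else exp(ld)
}

#' Internal-constraint function g
#'
#' `g(lambda, o, theta) = (2/pi) * atan(exp(lambda) / ((o - mu)^2 * tau))`,
#' a structure-independent relevance of the observation to a component:
#' it decreases with the squared distance between observation and capacity
#' location (scaled by the capacity precision) and increases with `lambda`.
#' At zero distance the limit value 1 is returned.
#'
#' @param lambda internal-constraint scale parameter.
#' @param o observation.
#' @param mu,tau capacity location and precision.
#' @return values in `(0, 1]`.
#' @export
internal_constraint <- function(lambda, o, mu, tau) {
  d2t <- (o - mu)^2 * tau
  out <- (2 / pi) * atan(.clip_exp(lambda) / d2t)
  out[d2t == 0] <- 1
  out
}

#' Instantiate the candidate component for the current cycle
#'
#' Every update cycle begins by anchoring a new component on the current
#' observation, with birth weight `alpha` and a fresh, never-reused id. The
#' candidate is only realised if its end-of-cycle weight reaches `alpha`.
#'
#' @param ens a `cbsl_ensemble`.
#' @param o the current observation.
#' @return list with `id`, `birth_time`, `hgf` (an [hgf_state()]) and
#'   `weight`.
#' @export
spawn_candidate <- function(ens, o) {
  .assert_finite(o, "observation")
  list(id = ens$next_id, birth_time = ens$t,
       hgf = init_component(o, ens$params$sigma),
       weight = ens$params$alpha)
}

# internal: joint activity computation in log space.
# Established components score g * f * w; the candidate scores alpha^2 * f
# (both its constraint factor and its weight are alpha at birth). Scores are
# normalised jointly so the activity entries always sum to 1.
.activity_scores <- function(log_g_established, log_f_established,
                             w_established, log_f_cand, alpha) {
  log_s <- c(log_g_established + log_f_established + log(w_established),
             2 * log(alpha) + log_f_cand)
  m <- max(log_s)
  if (!is.finite(m)) {
    warning("all activity scores underflowed; falling back to uniform",
            call. = FALSE)
    return(rep(1 / length(log_s), length(log_s)))
  }
  s <- exp(log_s - m)
  s / sum(s)
}

#' Activity distribution over components including the candidate
#'
#' Computes the categorical activity distribution for one cycle: each
#' established component scores `g * f * w` (internal constraint, capacity
#' density at the observation, weight) and the candidate scores
#' `alpha^2 * f`; the scores are normalised jointly so the entries sum to 1.
#'
#' @param ens a `cbsl_ensemble`.
#' @param candidate the component returned by [spawn_candidate()] this cycle.
#' @param o the current observation.
#' @return named numeric vector of activities (names are component ids, the
#'   candidate's last); sums to 1.
#' @export
activity_levels <- function(ens, candidate, o) {
  p <- ens$params
  caps <- if (length(ens$id)) {
    pred <- hgf_predict(.ens_state(ens), p$omega)
    list(mu = pred$mu_hat_input, tau = pred$pi_hat_input)
  } else list(mu = numeric(0), tau = numeric(0))
  cand_pred <- hgf_predict(candidate$hgf, p$omega)
  a <- .activity_scores(
    log(internal_constraint(p$lambda, o, caps$mu, caps$tau)),
    gaussian_density(o, caps$mu, caps$tau, log = TRUE),
    ens$weight,
    gaussian_density(o, cand_pred$mu_hat_input, cand_pred$pi_hat_input,
                     log = TRUE),
    p$alpha
  )
  names(a) <- c(ens$id, candidate$id)
  a
}

#' Update component weights from the activity distribution
#'
#' Established components move towards their activity level with step size
#' `g` (`w <- w + g * (a - w)`, a convex combination, so weights stay in
#' `[0, 1]`); the candidate's weight is set to its activity level exactly.
#'
#' @param ens a `cbsl_ensemble`.
#' @param candidate this cycle's [spawn_candidate()] output.
#' @param act activity distribution from [activity_levels()].
#' @param o the current observation.
#' @return the ensemble with updated weights, the candidate appended.
#' @export
update_weights <- function(ens, candidate, act, o) {
  p <- ens$params
  if (length(ens$id)) {
    caps <- capacities(ens)
    g <- internal_constraint(p$lambda, o, caps$mu, caps$tau)
    a_est <- unname(act[match(ens$id, as.integer(names(act)))])
    ens$weight <- ens$weight + g * (a_est - ens$weight)
  }
  .append_candidate(ens, candidate,
                    unname(act[[as.character(candidate$id)]]))
}

# internal: realise the candidate into the component vectors
.append_candidate <- function(ens, candidate, weight) {
  h <- candidate$hgf
  ens$id <- c(ens$id, candidate$id)
  ens$birth <- c(ens$birth, candidate$birth_time)
  ens$zeta <- c(ens$zeta, h$zeta)
  ens$mu_value <- c(ens$mu_value, h$mu_value)
  ens$pi_value <- c(ens$pi_value, h$pi_value)
  ens$mu_noise <- c(ens$mu_noise, h$mu_noise)
  ens$pi_noise <- c(ens$pi_noise, h$pi_noise)
  ens$weight <- c(ens$weight, weight)
  ens$next_id <- ens$next_id + 1L
  ens
}

#' Remove components with insufficient weight
#'
#' Every component (the candidate included) whose weight is strictly below
#' `alpha` at the end of the cycle is removed permanently; a weight exactly
#' equal to `alpha` survives. The ensemble may become empty.
#'
#' @param ens a `cbsl_ensemble` whose weights were updated this cycle.
#' @return the pruned ensemble.
#' @export
prune <- function(ens) {
  keep <- ens$weight >= ens$params$alpha
  for (f in c("id", "birth", "zeta", "mu_value", "pi_value", "mu_noise",
              "pi_noise", "weight")) {
    ens[[f]] <- ens[[f]][keep]
  }
  ens
}

#' One full update cycle
#'
#' Executes the four stages on a single observation: (1) spawn a candidate
#' anchored on `o`; (2) compute the activity distribution over all
#' components including the candidate; (3) update every established
#' component's HGF state (scaled by its activity) and weight (towards its
#' activity with step `g`), and set the candidate's weight to its activity;
#' (4) prune components below `alpha` and advance the clock. The cycle is
#' fully deterministic.
#'
#' @param ens a `cbsl_ensemble`.
#' @param o a finite scalar observation.
#' @param details if `TRUE`, return a list with the new ensemble plus the
#'   cycle's activity distribution and its sum (diagnostics).
#' @return the updated ensemble (or a detail list).
#' @export
step_ensemble <- function(ens, o, details = FALSE) {
  .assert_finite(o, "observation")
  p <- ens$params
  n <- length(ens$id)

  cand_hgf <- init_component(o, p$sigma)
  cand_id <- ens$next_id
  ids_in_cycle <- c(ens$id, cand_id)

  if (n) {
    pred <- hgf_predict(.ens_state(ens), p$omega)
    mu <- pred$mu_hat_input
    tau <- pred$pi_hat_input
    g <- internal_constraint(p$lambda, o, mu, tau)
    log_f <- gaussian_density(o, mu, tau, log = TRUE)
  } else {
    g <- numeric(0)
    log_f <- numeric(0)
  }
  tau_cand <- pmax(.clip_exp(-p$sigma), .PREC_FLOOR)
  log_f_cand <- 0.5 * (log(tau_cand) - log(2 * pi))

  act <- .activity_scores(log(g), log_f, ens$weight, log_f_cand, p$alpha)
  a_est <- act[seq_len(n)]
  a_cand <- act[n + 1L]

  if (n) {
    up <- hgf_update(.ens_state(ens), pred, o, a_est, p$omega)
    st <- up$state
    ens$mu_value <- st$mu_value
    ens$pi_value <- st$pi_value
    ens$mu_noise <- st$mu_noise
    ens$pi_noise <- st$pi_noise
    ens$weight <- ens$weight + g * (a_est - ens$weight)
  }
  ens <- .append_candidate(
    ens,
    list(id = cand_id, birth_time = ens$t, hgf = cand_hgf),
    a_cand)
  ens <- prune(ens)
  ens$t <- ens$t + 1L

  if (details) {
    names(act) <- ids_in_cycle
    list(ensemble = ens, activity = act, activity_sum = sum(act))
  } else {
    ens
  }
}

#' Run an ensemble over a stream of observations
#'
#' Convenience wrapper applying [step_ensemble()] to each observation in
#' turn, optionally recording per-timestep diagnostics.
#'
#' @param ens a `cbsl_ensemble`.
#' @param observations numeric vector.
#' @param record_counts record the component count after each cycle.
#' @param record_activity_sum record the sum of the activity distribution at
#'   each cycle (always 1 up to floating-point error; exposed for
#'   verification).
#' @return list with `ensemble` and, when requested, `n_components` and
#'   `activity_sum` vectors aligned with the observations.
#' @export
run_stream <- function(ens, observations, record_counts = TRUE,
                       record_activity_sum = FALSE) {
  T_ <- length(observations)
  counts <- if (record_counts) integer(T_) else NULL
  asums <- if (record_activity_sum) numeric(T_) else NULL
  for (k in seq_len(T_)) {
    if (record_activity_sum) {
      res <- step_ensemble(ens, observations[k], details = TRUE)
      ens <- res$ensemble
      asums[k] <- res$activity_sum
    } else {
      ens <- step_ensemble(ens, observations[k])
    }
    if (record_counts) counts[k] <- length(ens$id)
  }
  list(ensemble = ens, n_components = counts, activity_sum = asums)
}
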