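#' Gaussian mixture container
#'
#' Normalised `(mean, sd, weight)` triples, the operand of the
#' mixture-Wasserstein distance and the form of the perfect-agent benchmark.
#'
#' @param means,sds component means and standard deviations (`sds > 0`).
#' @param weights positive weights summing to 1 (within 1e-9).
#' @return list of class `cbsl_mixture`.
#' @export
gaussian_mixture <- function(means, sds, weights) {
  means <- as.numeric(means); sds <- as.numeric(sds)
  weights <- as.numeric(weights)
  stopifnot(length(sds) == length(means), length(weights) == length(means))
  .assert_finite(c(means, sds, weights), "mixture")
  if (any(sds <= 0) || any(weights <= 0)) {
    stop("mixture sds and weights must be positive", call. = FALSE)
  }
  if (abs(sum(weights) - 1) > 1e-9) {
    stop("mixture weights must sum to 1", call. = FALSE)
  }
  structure(list(means = means, sds = sds, weights = weights),
            class = "cbsl_mixture")
}

#' View an ensemble as a normalised Gaussian mixture
#'
#' One mixture component per model component: mean is the capacity location,
#' sd is `1/sqrt(tau)`, and the weights are the component weights normalised
#' to sum to 1 (the raw weights do not form a distribution on their own).
#'
#' @param ens a nonempty `cbsl_ensemble`.
#' @return a [gaussian_mixture()].
#' @export
model_to_mixture <- function(ens) {
  if (!length(ens$id)) stop("ensemble has no components", call. = FALSE)
  caps <- capacities(ens)
  gaussian_mixture(caps$mu, 1 / sqrt(caps$tau),
                   ens$weight / sum(ens$weight))
}

#' The environment as a Gaussian mixture
#'
#' Uniform source selection makes the environment an equal-weight mixture of
#' its sources.
#'
#' @param env a [environment_spec()].
#' @return a [gaussian_mixture()].
#' @export
environment_mixture <- function(env) {
  k <- length(env$means)
  gaussian_mixture(env$means, env$sds, rep(1 / k, k))
}

#' Mixture-Wasserstein (MW2) distance between Gaussian mixtures
#'
#' The MW2 distance restricts optimal transport to couplings of the mixing
#' weights: the cost of moving mass from component `i` of `A` to component
#' `j` of `B` is the squared 2-Wasserstein distance between the two
#' Gaussians, which in one dimension is
#' `(mu_i - mu_j)^2 + (sd_i - sd_j)^2`. The discrete transport problem is
#' solved exactly by [transport_plan()] and the square root of its optimal
#' value returned.
#'
#' @param A,B [gaussian_mixture()] objects.
#' @return nonnegative distance.
#' @export
mw2 <- function(A, B) {
  stopifnot(inherits(A, "cbsl_mixture"), inherits(B, "cbsl_mixture"))
  cost <- outer(A$means, B$means, function(x, y) (x - y)^2) +
    outer(A$sds, B$sds, function(x, y) (x - y)^2)
  sqrt(max(transport_plan(A$weights, B$weights, cost)$cost, 0))
}

#' Adjusted Rand index between two partitions
#'
#' Hubert-Arabie chance-corrected partition agreement from the pair-count
#' contingency table: `(Index - Expected) / (Max - Expected)`. Identical
#' partitions score 1; the expectation under random labellings is 0. In the
#' degenerate case `Max == Expected` (e.g. both partitions a single
#' cluster), the value is 1 if the partitions are identical and 0 otherwise,
#' so that perfect categorisation is always exactly 1.
#'
#' @param p,q label vectors of equal length; labels are arbitrary, only the
#'   induced partitions matter.
#' @return the ARI.
#' @export
ari <- function(p, q) {
  if (length(p) != length(q)) stop("partitions differ in length",
                                   call. = FALSE)
  if (!length(p)) stop("partitions must be nonempty", call. = FALSE)
  tab <- table(p, q)
  comb2 <- function(x) sum(x * (x - 1) / 2)
  idx <- comb2(tab)
  ra <- comb2(rowSums(tab))
  cb <- comb2(colSums(tab))
  tot <- length(p) * (length(p) - 1) / 2
  expected <- if (tot > 0) ra * cb / tot else 0
  maxi <- (ra + cb) / 2
  if (abs(maxi - expected) < .Machine$double.eps * (1 + maxi)) {
    # identical up to relabelling <=> the contingency table is a
    # (partial) permutation matrix in the nonzero pattern
    same <- all(rowSums(tab > 0) <= 1) && all(colSums(tab > 0) <= 1)
    return(if (same) 1 else 0)
  }
  (idx - expected) / (maxi - expected)
}

#' Frozen-model judgments of a set of observations
#'
#' For each observation, the activity distribution over the established
#' components (no candidate is spawned and no state is changed) is computed
#' as normalised `g * f * w`, and one component id is sampled from it as the
#' model's judgment of which "thing" generated the observation. The label
#' list is a clustering of the observations; the ensemble is left unchanged.
#'
#' @param ens a nonempty `cbsl_ensemble`.
#' @param observations numeric vector.
#' @param seed integer seed for the categorical draws.
#' @return integer vector of component ids, one per observation.
#' @export
judge <- function(ens, observations, seed) {
  if (!length(ens$id)) {
    stop("ensemble has no components: no representational structure to judge",
         call. = FALSE)
  }
  .assert_finite(observations, "observations")
  p <- ens$params
  caps <- capacities(ens)
  # n_obs x n_comp log-score matrix
  log_s <- vapply(seq_along(ens$id), function(i) {
    log(internal_constraint(p$lambda, observations, caps$mu[i],
                            caps$tau[i])) +
      gaussian_density(observations, caps$mu[i], caps$tau[i], log = TRUE) +
      log(ens$weight[i])
  }, numeric(length(observations)))
  log_s <- matrix(log_s, nrow = length(observations))
  withr::with_seed(as.integer(seed), {
    vapply(seq_along(observations), function(r) {
      ls <- log_s[r, ]
      m <- max(ls)
      pr <- if (is.finite(m)) exp(ls - m) else rep(1, length(ls))
      ens$id[sample.int(length(ls), 1L, prob = pr)]
    }, integer(1))
  })
}

#' Perfect-agent benchmark ensemble
#'
#' An ensemble whose representational capacities exactly match the
#' environmental sources (capacity location = source mean, capacity
#' precision = 1/sd^2) with equal weights, judged through the same
#' [judge()] procedure as trained models. "Perfect" refers to perfect
#' representation of the environment, not perfect classification, which is
#' impossible by chance alone in ambiguous environments.
#'
#' @param env a [environment_spec()].
#' @param params system parameters used for judgment (standard by default).
#' @return a `cbsl_ensemble`.
#' @export
perfect_agent <- function(env, params = standard_params()) {
  ens <- new_ensemble(params)
  k <- length(env$means)
  for (i in seq_len(k)) {
    # capacity tau = exp(-(zeta + mu_noise)) with mu_noise = 0, so a zeta
    # of 2*log(sd) pins the capacity precision at 1/sd^2
    cand <- list(id = ens$next_id, birth_time = 0L,
                 hgf = hgf_state(zeta = 2 * log(env$sds[i]),
                                 mu_value = env$means[i]))
    ens <- .append_candidate(ens, cand, 1 / k)
  }
  ens
}

#' Number of live components
#'
#' @param ens a `cbsl_ensemble`.
#' @return integer count.
#' @export
n_components <- function(ens) {
  length(ens$id)
}
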