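test_that("capacities are the predicted input mean and precision", {
  ens <- new_ensemble()
  ens <- step_ensemble(ens, 2)  # lone candidate realised at o = 2
  caps <- capacities(ens)
  expect_equal(caps$mu, 2)
  expect_equal(caps$tau, 1)

  ens2 <- new_ensemble(standard_params(sigma = 2))
  ens2 <- step_ensemble(ens2, 2)
  expect_equal(capacities(ens2)$tau, exp(-2), tolerance = 1e-12)

  # capacity precision rises as the noise-parent mean falls
  st_lo <- hgf_state(0, 0, mu_noise = -1)
  st_hi <- hgf_state(0, 0, mu_noise = 0)
  expect_gt(hgf_predict(st_lo, -6)$pi_hat_input,
            hgf_predict(st_hi, -6)$pi_hat_input)
})

test_that("the Gaussian density uses the precision parametrisation", {
  expect_equal(gaussian_density(0, 0, 1), 1 / sqrt(2 * pi),
               tolerance = 1e-12)
  expect_equal(gaussian_density(1, 0, 1), 0.24197, tolerance = 1e-4)
  expect_equal(gaussian_density(0, 0, 4), dnorm(0, 0, 0.5),
               tolerance = 1e-12)
  expect_equal(gaussian_density(1.3, 0.2, 2.5),
               gaussian_density(-0.9, 0.2, 2.5))  # symmetric in o - mu
})

test_that("the internal-constraint function has the stated values and limits", {
  # exactly 0.5 when the scaled squared distance equals exp(lambda)
  for (lam in c(-1, 0, 0.7, 3)) {
    tau <- 1.7
    d <- sqrt(exp(lam) / tau)
    expect_equal(internal_constraint(lam, d, 0, tau), 0.5,
                 tolerance = 1e-12)
  }
  expect_equal(internal_constraint(0.7, 1, 0, 1),
               (2 / pi) * atan(exp(0.7)), tolerance = 1e-12)
  expect_equal(internal_constraint(0.7, 1, 0, 1), 0.7066, tolerance = 1e-4)
  expect_equal(internal_constraint(0.7, 0.4, 0.4, 5), 1)  # zero-distance limit

  # monotonicity: decreasing in distance^2, increasing in lambda,
  # decreasing in tau at fixed distance
  d <- seq(0.1, 4, by = 0.1)
  g_d <- internal_constraint(0.7, d, 0, 1)
  expect_true(all(diff(g_d) < 0))
  lams <- seq(-4, 4, by = 0.25)
  g_l <- vapply(lams, internal_constraint, numeric(1), o = 1, mu = 0,
                tau = 1)
  expect_true(all(diff(g_l) > 0))
  taus <- seq(0.2, 5, by = 0.2)
  g_t <- vapply(taus, function(tt) internal_constraint(0.7, 1, 0, tt),
                numeric(1))
  expect_true(all(diff(g_t) < 0))

  # lambda limits: fully unconstrained vs fully frozen
  expect_equal(internal_constraint(600, 3, 0, 1), 1, tolerance = 1e-9)
  expect_lt(internal_constraint(-600, 0.01, 0, 1), 1e-9)
})

test_that("candidates are anchored on the observation with weight alpha", {
  ens <- new_ensemble()
  cand <- spawn_candidate(ens, 1.3)
  expect_equal(cand$weight, 0.01)
  expect_equal(cand$hgf$mu_value, 1.3)
  expect_equal(hgf_predict(cand$hgf, -6)$pi_hat_input, 1)
  cand_sharp <- spawn_candidate(new_ensemble(standard_params(sigma = -1)),
                                0)
  expect_equal(hgf_predict(cand_sharp$hgf, -6)$pi_hat_input, exp(1),
               tolerance = 1e-12)

  # successive spawns get distinct, never-reused ids
  e <- new_ensemble()
  id1 <- spawn_candidate(e, 0)$id
  e <- step_ensemble(e, 0)
  id2 <- spawn_candidate(e, 5)$id
  expect_true(id1 != id2)
})

test_that("activity levels normalise to one and match the linear-space oracle", {
  # lone candidate takes all activity
  ens <- new_ensemble()
  cand <- spawn_candidate(ens, 3)
  act <- activity_levels(ens, cand, 3)
  expect_equal(sum(act), 1)
  expect_equal(unname(act), 1)

  # two symmetric established components split activity; a hopeless
  # far-away candidate gets next to nothing
  ens <- new_ensemble()
  ens <- step_ensemble(ens, 0)
  ens$weight <- 0.6
  ens <- .append_candidate(ens, list(id = 99L, birth_time = 0L,
                                     hgf = init_component(0, 0)), 0.6)
  cand <- spawn_candidate(ens, 0)
  act <- activity_levels(ens, cand, 0)
  expect_equal(sum(act), 1, tolerance = 1e-12)
  expect_equal(act[[1]], act[[2]], tolerance = 1e-12)
  expect_lt(act[[3]], 1e-3)

  # random configurations: joint normalisation equals the plain
  # linear-space computation
  withr::with_seed(2024, {
    for (case in 1:50) {
      n <- sample(1:6, 1)
      mu <- runif(n, -8, 8)
      tau <- exp(runif(n, -2, 2))
      w <- runif(n, 0.011, 1)
      o <- runif(1, -8, 8)
      lam <- runif(1, -2, 2)
      sig <- runif(1, -1.5, 1.5)
      ens <- new_ensemble(standard_params(sigma = sig, lambda = lam))
      for (i in seq_len(n)) {
        ens <- .append_candidate(ens, list(
          id = ens$next_id, birth_time = 0L,
          hgf = hgf_state(zeta = -log(tau[i]), mu_value = mu[i])), w[i])
      }
      cand <- spawn_candidate(ens, o)
      act <- activity_levels(ens, cand, o)
      ref <- oracle_activity(o, mu, tau, w, lam, 0.01, sig)
      expect_equal(sum(act), 1, tolerance = 1e-9)
      expect_equal(unname(act), ref, tolerance = 1e-9)
    }
  })
})

test_that("weight updates move toward activity with step g and stay bounded", {
  # a component with capacity (0, 1) at o = 1 under lambda = 0 has g = 1/2
  ens <- new_ensemble(standard_params(lambda = 0))
  ens <- .append_candidate(ens, list(id = 1L, birth_time = 0L,
                                     hgf = init_component(0, 0)), 0.5)
  act <- c("1" = 0.1, "2" = 0.9)
  ens2 <- update_weights(ens, spawn_candidate(ens, 1), act, 1)
  expect_equal(ens2$weight[1], 0.5 + 0.5 * (0.1 - 0.5), tolerance = 1e-12)
  expect_equal(ens2$weight[1], 0.3, tolerance = 1e-12)
  expect_equal(ens2$weight[2], 0.9)  # candidate set to its activity exactly

  # g = 0 freezes the weight; g = 1 sets it to the activity
  ens_frozen <- new_ensemble(standard_params(lambda = -600))
  ens_frozen <- .append_candidate(ens_frozen, list(
    id = 1L, birth_time = 0L, hgf = init_component(0, 0)), 0.5)
  out <- update_weights(ens_frozen, spawn_candidate(ens_frozen, 4), act, 4)
  expect_equal(out$weight[1], 0.5, tolerance = 1e-9)

  # boundedness under adversarial parameter draws
  withr::with_seed(555, {
    for (case in 1:40) {
      p <- standard_params(sigma = runif(1, -4, 4),
                           lambda = runif(1, -5, 5),
                           alpha = runif(1, 0.001, 1),
                           omega = runif(1, -9, 0))
      ens <- new_ensemble(p)
      for (o in rnorm(60, sample(c(-5, 0, 5), 60, TRUE))) {
        ens <- step_ensemble(ens, o)
        expect_true(all(ens$weight >= 0 & ens$weight <= 1))
      }
    }
  })
})

test_that("pruning is strict, permanent and can empty the ensemble", {
  ens <- new_ensemble()
  ens <- step_ensemble(ens, 0)
  # weight exactly alpha survives (strict inequality)
  ens$weight <- ens$params$alpha
  expect_equal(n_components(prune(ens)), 1)
  # weight just below alpha is removed
  ens$weight <- ens$params$alpha - 1e-12
  emptied <- prune(ens)
  expect_equal(n_components(emptied), 0)
  # the next cycle's lone candidate is realised with weight 1
  reborn <- step_ensemble(emptied, 7)
  expect_equal(n_components(reborn), 1)
  expect_equal(reborn$weight, 1)
  expect_equal(reborn$mu_value, 7)
  # the retired id never reappears
  expect_false(ens$id %in% reborn$id)
})

test_that("a candidate near an established component is not realised", {
  ens <- step_ensemble(new_ensemble(), 0)   # one strong component at 0
  before <- n_components(ens)
  ens2 <- step_ensemble(ens, 0.1)           # candidate lands on top of it
  expect_equal(n_components(ens2), before)  # unrealised potential
  expect_equal(ens2$id, ens$id)
})

test_that("one cycle adds at most one component and counts stay below t + 1", {
  withr::with_seed(31, {
    ens <- new_ensemble()
    o <- rnorm(300, sample(c(0, 6, 12), 300, TRUE))
    for (k in seq_along(o)) {
      n_before <- n_components(ens)
      ens <- step_ensemble(ens, o[k])
      expect_lte(n_components(ens), n_before + 1)
      expect_lte(n_components(ens), ens$t + 1)
    }
  })
})

test_that("the update cycle is deterministic", {
  env <- make_standard_environment(3)
  o <- sample_stream(env, 400, 77)$o
  r1 <- run_stream(new_ensemble(), o)
  r2 <- run_stream(new_ensemble(), o)
  expect_identical(r1$ensemble, r2$ensemble)
  expect_identical(r1$n_components, r2$n_components)
})

test_that("short unambiguous runs settle on one dominant component per source", {
  env <- make_standard_environment(6)
  hits <- 0
  for (seed in 1:5) {
    o <- sample_stream(env, 2000, seed)$o
    ens <- run_stream(new_ensemble(), o)$ensemble
    caps <- capacities(ens)
    dom <- ens$weight > 0.5
    covered <- vapply(env$means, function(m) {
      any(abs(caps$mu[dom] - m) < 1)
    }, logical(1))
    if (all(covered) && n_components(ens) <= 8) hits <- hits + 1
  }
  expect_gte(hits, 4)
})

test_that("extreme lambda makes weights track activity or freeze", {
  # lambda -> +inf: established weights equal their activity after update
  ens <- step_ensemble(new_ensemble(standard_params(lambda = 600)), 0)
  det <- step_ensemble(ens, 0.5, details = TRUE)
  est_id <- as.character(ens$id)
  expect_equal(det$ensemble$weight[match(ens$id, det$ensemble$id)],
               unname(det$activity[est_id]), tolerance = 1e-12)
  # lambda -> -inf: established weights freeze
  ensf <- step_ensemble(new_ensemble(standard_params(lambda = -600)), 0)
  w0 <- ensf$weight
  ensf2 <- step_ensemble(ensf, 0.5)
  expect_equal(ensf2$weight[match(ensf$id, ensf2$id)], w0,
               tolerance = 1e-12)
})
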