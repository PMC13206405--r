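#' A training-run condition
#'
#' Bundles system parameters, the environment spacing and the training
#' duration. Typical durations: 100 timesteps (short-term) and 10,000
#' (long-term); most desk-scale studies here use 2,000 as the long horizon.
#'
#' @param params a [standard_params()] list.
#' @param distance spacing between neighbouring source means.
#' @param train_T number of training timesteps (>= 0).
#' @param label optional condition label.
#' @return list of class `cbsl_condition`.
#' @export
run_condition <- function(params = standard_params(), distance = 6,
                          train_T = 100, label = NULL) {
  train_T <- as.integer(train_T)
  if (train_T < 0) stop("train_T must be nonnegative", call. = FALSE)
  structure(list(params = params, distance = distance, train_T = train_T,
                 label = label %||% sprintf("d%g_T%d", distance, train_T)),
            class = "cbsl_condition")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' A span of altered parametrisation
#'
#' During timesteps `t_start + 1` to `t_start + span` (1-based observation
#' index) the given `sigma` and/or `lambda` overrides replace the base
#' values; outside the span the base parametrisation applies exactly.
#' Components keep the `zeta` they inherited at their own birth, so
#' components born inside a `sigma` span remain marked by it.
#'
#' @param t_start last timestep before the span (default 200).
#' @param span span length in timesteps (>= 1).
#' @param sigma,lambda overrides; `NULL` leaves the base value in force.
#' @return list of class `cbsl_schedule`.
#' @export
span_schedule <- function(t_start = 200, span, sigma = NULL, lambda = NULL) {
  span <- as.integer(span)
  if (span < 1) stop("span must be >= 1", call. = FALSE)
  structure(list(t_start = as.integer(t_start), span = span,
                 sigma = sigma, lambda = lambda),
            class = "cbsl_schedule")
}

.altered_params <- function(base, schedule) {
  standard_params(sigma = schedule$sigma %||% base$sigma,
                  lambda = schedule$lambda %||% base$lambda,
                  alpha = base$alpha, omega = base$omega)
}

#' Train an ensemble on a generated observation stream
#'
#' Samples a stream from the condition's environment and consumes it with
#' [step_ensemble()], optionally under a [span_schedule()] and optionally
#' recording behavioural checkpoints (frozen-model ARI on a fresh balanced
#' test set, and MW2 against the environment mixture) every
#' `checkpoint_every` timesteps. Seed discipline: the master seed is split
#' into independent substreams for the training stream and for each
#' checkpoint's test draws and judgments, so checkpointing never perturbs
#' training.
#'
#' @param cond a [run_condition()].
#' @param seed master integer seed.
#' @param schedule optional [span_schedule()].
#' @param checkpoint_every checkpoint interval in timesteps; `NA` disables
#'   checkpoints.
#' @param n_per_source test observations per source at each checkpoint.
#' @param record_activity_sum also record the per-cycle activity sums.
#' @return list with `ensemble`, `env`, `trajectory` (data.frame `t`,
#'   `n_components`, and `activity_sum` if requested) and `checkpoints`
#'   (data.frame `t`, `ari`, `mw2`; `NA` rows where the ensemble was empty).
#' @export
run_training <- function(cond, seed, schedule = NULL,
                         checkpoint_every = NA, n_per_source = 20,
                         record_activity_sum = FALSE) {
  env <- make_standard_environment(cond$distance)
  ss <- derive_seeds(seed, 2)
  stream <- sample_stream(env, cond$train_T, ss[1])
  env_mix <- environment_mixture(env)

  base <- cond$params
  altered <- if (!is.null(schedule)) .altered_params(base, schedule)
  cp_ts <- if (!is.na(checkpoint_every) && cond$train_T > 0) {
    seq_len(cond$train_T)[seq_len(cond$train_T) %% checkpoint_every == 0]
  } else integer(0)
  cp_seeds <- if (length(cp_ts)) derive_seeds(ss[2], 2 * length(cp_ts))

  ens <- new_ensemble(base)
  counts <- integer(cond$train_T)
  asums <- if (record_activity_sum) numeric(cond$train_T)
  cp_ari <- rep(NA_real_, length(cp_ts))
  cp_mw2 <- rep(NA_real_, length(cp_ts))
  cp_idx <- 1L

  for (k in seq_len(cond$train_T)) {
    in_span <- !is.null(schedule) &&
      k > schedule$t_start && k <= schedule$t_start + schedule$span
    ens$params <- if (in_span) altered else base
    if (record_activity_sum) {
      res <- step_ensemble(ens, stream$o[k], details = TRUE)
      ens <- res$ensemble
      asums[k] <- res$activity_sum
    } else {
      ens <- step_ensemble(ens, stream$o[k])
    }
    counts[k] <- length(ens$id)
    if (cp_idx <= length(cp_ts) && k == cp_ts[cp_idx]) {
      if (length(ens$id)) {
        sd_draw <- cp_seeds[2 * cp_idx - 1L]
        sd_judge <- cp_seeds[2 * cp_idx]
        ts <- sample_test_set(env, n_per_source, sd_draw)
        cp_ari[cp_idx] <- ari(judge(ens, ts$o, sd_judge), ts$source)
        cp_mw2[cp_idx] <- mw2(model_to_mixture(ens), env_mix)
      }
      cp_idx <- cp_idx + 1L
    }
  }
  ens$params <- base
  traj <- data.frame(t = seq_len(cond$train_T), n_components = counts)
  if (record_activity_sum) traj$activity_sum <- asums
  list(ensemble = ens, env = env, trajectory = traj,
       checkpoints = data.frame(t = cp_ts, ari = cp_ari, mw2 = cp_mw2))
}

#' Behavioural test phase
#'
#' Draws a balanced test set (default 20 observations per source), obtains
#' frozen-model judgments and returns the ARI against the ground-truth
#' source labels. The ensemble is not modified. An empty ensemble has no
#' structure to judge and yields `NA` (undefined, not zero).
#'
#' @param ens a `cbsl_ensemble`.
#' @param env a [environment_spec()].
#' @param seed master seed, split into draw and judgment substreams.
#' @param n_per_source test observations per source.
#' @return the test ARI, or `NA_real_` for an empty ensemble.
#' @export
test_phase <- function(ens, env, seed, n_per_source = 20) {
  if (!length(ens$id)) return(NA_real_)
  ss <- derive_seeds(seed, 2)
  ts <- sample_test_set(env, n_per_source, ss[1])
  ari(judge(ens, ts$o, ss[2]), ts$source)
}

#' Baseline distributions under the standard parametrisation
#'
#' Replicated training runs across environments and durations, each followed
#' by a behavioural test phase, plus perfect-agent reference rows judged on
#' an independent seed stream. Replication count is a free knob: all
#' comparisons of interest are ordering or threshold properties that hold at
#' reduced replication.
#'
#' @param reps replicates per condition.
#' @param distances environment spacings.
#' @param durations training durations in timesteps.
#' @param seed master seed.
#' @param params system parameters.
#' @param n_per_source test observations per source.
#' @param include_perfect also evaluate the perfect agent per environment.
#' @return data.frame with columns `agent`, `distance`, `duration`, `rep`,
#'   `ari`, `mw2`, `n_components`.
#' @export
baseline_experiment <- function(reps = 200, distances = c(6, 3, 1),
                                durations = c(100, 2000), seed = 1,
                                params = standard_params(),
                                n_per_source = 20,
                                include_perfect = TRUE) {
  if (reps < 1) stop("reps must be >= 1", call. = FALSE)
  conds <- expand.grid(distance = distances, duration = durations)
  cond_seeds <- derive_seeds(seed, nrow(conds) + length(distances))
  rows <- vector("list", nrow(conds) + length(distances))
  for (ci in seq_len(nrow(conds))) {
    d <- conds$distance[ci]; T_ <- conds$duration[ci]
    rep_seeds <- derive_seeds(cond_seeds[ci], reps)
    out <- vapply(seq_len(reps), function(r) {
      ss <- derive_seeds(rep_seeds[r], 2)
      fit <- run_training(run_condition(params, d, T_), ss[1])
      a <- test_phase(fit$ensemble, fit$env, ss[2], n_per_source)
      w <- if (length(fit$ensemble$id)) {
        mw2(model_to_mixture(fit$ensemble), environment_mixture(fit$env))
      } else NA_real_
      c(a, w, length(fit$ensemble$id))
    }, numeric(3))
    rows[[ci]] <- data.frame(agent = "model", distance = d, duration = T_,
                             rep = seq_len(reps), ari = out[1, ],
                             mw2 = out[2, ], n_components = out[3, ])
  }
  if (include_perfect) {
    for (di in seq_along(distances)) {
      d <- distances[di]
      env <- make_standard_environment(d)
      pa <- perfect_agent(env, params)
      pa_mw2 <- mw2(model_to_mixture(pa), environment_mixture(env))
      rep_seeds <- derive_seeds(cond_seeds[nrow(conds) + di], reps)
      aris <- vapply(rep_seeds, function(s) test_phase(pa, env, s,
                                                       n_per_source),
                     numeric(1))
      rows[[nrow(conds) + di]] <- data.frame(
        agent = "perfect", distance = d, duration = NA_integer_,
        rep = seq_len(reps), ari = aris, mw2 = pa_mw2,
        n_components = length(env$means))
    }
  }
  do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
}

#' Mean measures across a parameter sweep or grid
#'
#' Sweeps `sigma`, `lambda`, or their grid, across environments and
#' durations, reporting cell means of the three measures. Within each
#' `(distance, duration)` row the cell with the best mean ARI is flagged.
#'
#' @param axis `"sigma"`, `"lambda"` or `"grid"`.
#' @param values swept values (for `"grid"`, the sigma values).
#' @param lambda_values lambda values for `"grid"`.
#' @param distances,durations,reps,seed,params,n_per_source as in
#'   [baseline_experiment()].
#' @return data.frame of cell means with columns `sigma`, `lambda`,
#'   `distance`, `duration`, `mean_ari`, `mean_mw2`, `mean_n_components`,
#'   `n_reps`, `is_row_max`.
#' @export
parameter_sweep <- function(axis = c("sigma", "lambda", "grid"), values,
                            lambda_values = NULL, distances = c(6, 3, 1),
                            durations = c(100, 2000), reps = 50, seed = 1,
                            params = standard_params(), n_per_source = 20) {
  axis <- match.arg(axis)
  if (!length(values)) stop("values must be nonempty", call. = FALSE)
  cells <- switch(axis,
    sigma = expand.grid(sigma = values, lambda = params$lambda),
    lambda = expand.grid(sigma = params$sigma, lambda = values),
    grid = {
      if (is.null(lambda_values)) {
        stop("grid mode needs lambda_values", call. = FALSE)
      }
      expand.grid(sigma = values, lambda = lambda_values)
    })
  cells <- merge(cells, expand.grid(distance = distances,
                                    duration = durations))
  cell_seeds <- derive_seeds(seed, nrow(cells))
  res <- lapply(seq_len(nrow(cells)), function(ci) {
    p <- standard_params(sigma = cells$sigma[ci], lambda = cells$lambda[ci],
                         alpha = params$alpha, omega = params$omega)
    rep_seeds <- derive_seeds(cell_seeds[ci], reps)
    out <- vapply(seq_len(reps), function(r) {
      ss <- derive_seeds(rep_seeds[r], 2)
      fit <- run_training(run_condition(p, cells$distance[ci],
                                        cells$duration[ci]), ss[1])
      a <- test_phase(fit$ensemble, fit$env, ss[2], n_per_source)
      w <- if (length(fit$ensemble$id)) {
        mw2(model_to_mixture(fit$ensemble), environment_mixture(fit$env))
      } else NA_real_
      c(a, w, length(fit$ensemble$id))
    }, numeric(3))
    data.frame(sigma = cells$sigma[ci], lambda = cells$lambda[ci],
               distance = cells$distance[ci], duration = cells$duration[ci],
               mean_ari = mean(out[1, ], na.rm = TRUE),
               mean_mw2 = mean(out[2, ], na.rm = TRUE),
               mean_n_components = mean(out[3, ]), n_reps = reps)
  })
  res <- do.call(rbind, res)
  res$is_row_max <- FALSE
  for (gr in split(seq_len(nrow(res)),
                   interaction(res$distance, res$duration, drop = TRUE))) {
    res$is_row_max[gr[which.max(res$mean_ari[gr])]] <- TRUE
  }
  res
}

#' Averaged trajectories under a span of altered parametrisation
#'
#' Runs replicated simulations of `total_T` timesteps with the base
#' parametrisation, overridden by the schedule inside its span, and averages
#' the per-timestep component count (and, at checkpoints, ARI and MW2)
#' across replicates.
#'
#' @param distance environment spacing.
#' @param schedule a [span_schedule()]; must fit inside `total_T`.
#' @param total_T total timesteps per replicate.
#' @param reps replicates.
#' @param seed master seed.
#' @param params base parametrisation.
#' @param checkpoint_every checkpoint interval (`NA` for counts only).
#' @param n_per_source test observations per source at checkpoints.
#' @return list with `trajectory` (data.frame `t`, `mean_n_components`),
#'   `checkpoints` (data.frame `t`, `mean_ari`, `mean_mw2`), `schedule` and
#'   `reps`.
#' @export
span_perturbation <- function(distance = 6, schedule, total_T = 2000,
                              reps = 100, seed = 1,
                              params = standard_params(),
                              checkpoint_every = NA, n_per_source = 20) {
  if (schedule$t_start + schedule$span > total_T) {
    stop("schedule does not fit inside total_T", call. = FALSE)
  }
  reps <- as.integer(reps)
  cond <- run_condition(params, distance, total_T)
  rep_seeds <- derive_seeds(seed, reps)
  count_sum <- numeric(total_T)
  cp_acc <- NULL
  for (r in seq_len(reps)) {
    fit <- run_training(cond, rep_seeds[r], schedule = schedule,
                        checkpoint_every = checkpoint_every,
                        n_per_source = n_per_source)
    count_sum <- count_sum + fit$trajectory$n_components
    if (nrow(fit$checkpoints)) {
      if (is.null(cp_acc)) {
        cp_acc <- list(t = fit$checkpoints$t,
                       ari = matrix(NA_real_, reps,
                                    nrow(fit$checkpoints)),
                       mw2 = matrix(NA_real_, reps,
                                    nrow(fit$checkpoints)))
      }
      cp_acc$ari[r, ] <- fit$checkpoints$ari
      cp_acc$mw2[r, ] <- fit$checkpoints$mw2
    }
  }
  checkpoints <- if (is.null(cp_acc)) {
    data.frame(t = integer(0), mean_ari = numeric(0), mean_mw2 = numeric(0))
  } else {
    data.frame(t = cp_acc$t,
               mean_ari = colMeans(cp_acc$ari, na.rm = TRUE),
               mean_mw2 = colMeans(cp_acc$mw2, na.rm = TRUE))
  }
  list(trajectory = data.frame(t = seq_len(total_T),
                               mean_n_components = count_sum / reps),
       checkpoints = checkpoints, schedule = schedule, reps = reps)
}
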