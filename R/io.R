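# Configuration, result and snapshot plumbing. JSON or YAML configs are
# validated strictly (unknown keys fail loudly); snapshots round-trip the
# full numeric state bit-exactly.

.CONFIG_KEYS <- list(
  params = c("sigma", "lambda", "alpha", "omega"),
  environment = c("distance", "n_sources", "sd"),
  schedule = c("t_start", "span", "sigma", "lambda"),
  top = c("params", "environment", "schedule", "timesteps", "reps", "seed",
          "output", "checkpoint_every")
)

.check_keys <- function(x, allowed, where) {
  unknown <- setdiff(names(x), allowed)
  if (length(unknown)) {
    stop(sprintf("unknown configuration key%s in %s: %s",
                 if (length(unknown) > 1) "s" else "", where,
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
}

.check_number <- function(x, key, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x)) {
    stop(sprintf("configuration key '%s' must be a finite number", key),
         call. = FALSE)
  }
  if (x < lo || x > hi) {
    stop(sprintf("configuration key '%s' must lie in [%g, %g]", key, lo, hi),
         call. = FALSE)
  }
  as.numeric(x)
}

#' Load and validate a run configuration
#'
#' Reads a JSON (`.json`) or YAML (`.yaml`/`.yml`) configuration, fills the
#' standard parametrisation and standard environment for omitted fields and
#' rejects unknown keys and out-of-range values with a message naming the
#' offending key. An empty configuration yields the full defaults.
#'
#' @param path configuration file path.
#' @return validated configuration list of class `cbsl_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such config file: %s", path),
                               call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    yaml = ,
    yml = yaml::read_yaml(path),
    stop(sprintf("unsupported config extension '.%s' (use .json or .yaml)",
                 ext), call. = FALSE))
  if (is.null(raw)) raw <- list()
  normalize_config(raw)
}

#' @rdname load_config
#' @param config a raw configuration list (possibly partial).
#' @export
normalize_config <- function(config = list()) {
  .check_keys(config, .CONFIG_KEYS$top, "top level")
  pr <- config$params %||% list()
  .check_keys(pr, .CONFIG_KEYS$params, "params")
  params <- standard_params(
    sigma = .check_number(pr$sigma %||% 0, "params.sigma"),
    lambda = .check_number(pr$lambda %||% 0.7, "params.lambda"),
    alpha = .check_number(pr$alpha %||% 0.01, "params.alpha", 0, 1),
    omega = .check_number(pr$omega %||% -6, "params.omega"))
  ev <- config$environment %||% list()
  .check_keys(ev, .CONFIG_KEYS$environment, "environment")
  environment <- list(
    distance = .check_number(ev$distance %||% 6, "environment.distance",
                             lo = .Machine$double.xmin),
    n_sources = as.integer(.check_number(ev$n_sources %||% 3,
                                         "environment.n_sources", 1)),
    sd = .check_number(ev$sd %||% 1, "environment.sd",
                       lo = .Machine$double.xmin))
  schedule <- NULL
  if (!is.null(config$schedule)) {
    sc <- config$schedule
    .check_keys(sc, .CONFIG_KEYS$schedule, "schedule")
    if (is.null(sc$span)) stop("schedule needs a 'span'", call. = FALSE)
    schedule <- span_schedule(
      t_start = .check_number(sc$t_start %||% 200, "schedule.t_start", 0),
      span = .check_number(sc$span, "schedule.span", 1),
      sigma = if (!is.null(sc$sigma)) .check_number(sc$sigma,
                                                    "schedule.sigma"),
      lambda = if (!is.null(sc$lambda)) .check_number(sc$lambda,
                                                      "schedule.lambda"))
  }
  structure(list(
    params = params,
    environment = environment,
    schedule = schedule,
    timesteps = as.integer(.check_number(config$timesteps %||% 100,
                                         "timesteps", 0)),
    reps = as.integer(.check_number(config$reps %||% 200, "reps", 1)),
    seed = as.integer(.check_number(config$seed %||% 1, "seed")),
    output = config$output %||% "cbsl_results",
    checkpoint_every = if (is.null(config$checkpoint_every)) NA_integer_
                       else as.integer(.check_number(config$checkpoint_every,
                                                     "checkpoint_every", 1))
  ), class = "cbsl_config")
}

#' Write a configuration back to disk
#'
#' @param config a `cbsl_config`.
#' @param path target path (`.json`, `.yaml` or `.yml`).
#' @export
save_config <- function(config, path) {
  out <- list(
    params = unclass(config$params),
    environment = config$environment,
    timesteps = config$timesteps, reps = config$reps, seed = config$seed,
    output = config$output)
  if (!is.null(config$schedule)) {
    out$schedule <- Filter(Negate(is.null), unclass(config$schedule))
  }
  if (!is.na(config$checkpoint_every)) {
    out$checkpoint_every <- config$checkpoint_every
  }
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    json = jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                                pretty = TRUE),
    yaml = ,
    yml = yaml::write_yaml(out, path),
    stop(sprintf("unsupported config extension '.%s'", ext), call. = FALSE))
  invisible(path)
}

#' Save a results table with its manifest
#'
#' Writes `<path>.csv` (fixed column order, six significant digits for
#' human-facing numbers) and `<path>_manifest.json` holding the full
#' configuration, every seed used and the package version, so any result
#' file can be regenerated from its manifest alone. Byte output is
#' deterministic for identical inputs.
#'
#' @param table results data.frame.
#' @param manifest named list (configuration, seeds, anything reproducers
#'   need); the package version is added.
#' @param path output path prefix (no extension).
#' @return invisibly, the two file paths.
#' @export
save_results <- function(table, manifest, path) {
  csv <- paste0(path, ".csv")
  man <- paste0(path, "_manifest.json")
  dir.create(dirname(csv), recursive = TRUE, showWarnings = FALSE)
  tab <- as.data.frame(table)
  for (cl in names(tab)) {
    if (is.double(tab[[cl]])) tab[[cl]] <- signif(tab[[cl]], 6)
  }
  write.csv(tab, csv, row.names = FALSE, quote = FALSE)
  manifest$package_version <- as.character(utils::packageVersion("cbsl"))
  jsonlite::write_json(manifest, man, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(c(csv, man))
}

#' Snapshot an ensemble to JSON and back
#'
#' The snapshot holds the timestep, the parameters, the id counter and every
#' component's identity, birth time, weight and HGF state at full precision;
#' reading it back reproduces the ensemble bit-exactly.
#'
#' @param ens a `cbsl_ensemble`.
#' @param path JSON file path.
#' @export
write_snapshot <- function(ens, path) {
  components <- lapply(seq_along(ens$id), function(i) list(
    id = ens$id[i], birth_time = ens$birth[i], weight = ens$weight[i],
    hgf = list(zeta = ens$zeta[i], mu_value = ens$mu_value[i],
               pi_value = ens$pi_value[i], mu_noise = ens$mu_noise[i],
               pi_noise = ens$pi_noise[i])))
  # 17 significant digits: enough for a bit-exact double round trip
  jsonlite::write_json(
    list(t = ens$t, next_id = ens$next_id, params = unclass(ens$params),
         components = components),
    path, auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  invisible(path)
}

#' @rdname write_snapshot
#' @return `read_snapshot()` returns the reconstructed `cbsl_ensemble`.
#' @export
read_snapshot <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  ens <- new_ensemble(do.call(standard_params, raw$params))
  ens$t <- as.integer(raw$t)
  for (cmp in raw$components) {
    ens$id <- c(ens$id, as.integer(cmp$id))
    ens$birth <- c(ens$birth, as.integer(cmp$birth_time))
    ens$weight <- c(ens$weight, as.numeric(cmp$weight))
    ens$zeta <- c(ens$zeta, as.numeric(cmp$hgf$zeta))
    ens$mu_value <- c(ens$mu_value, as.numeric(cmp$hgf$mu_value))
    ens$pi_value <- c(ens$pi_value, as.numeric(cmp$hgf$pi_value))
    ens$mu_noise <- c(ens$mu_noise, as.numeric(cmp$hgf$mu_noise))
    ens$pi_noise <- c(ens$pi_noise, as.numeric(cmp$hgf$pi_noise))
  }
  ens$next_id <- as.integer(raw$next_id)
  ens
}
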