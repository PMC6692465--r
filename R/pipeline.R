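#' Pipeline configuration
#'
#' Collects every stage parameter of the end-to-end analysis into one
#' validated list. Either \code{session_files} (CSV paths in the layout of
#' \code{\link{write_session_csv}}) or \code{sim_params} (a
#' \code{\link{fitts_sim_params}}, used to simulate the input) must be
#' supplied; simulation is the default.
#'
#' @param sim_params Simulation parameters, or NULL when reading CSVs.
#' @param session_files Character vector of session CSV paths, or NULL.
#' @param epoch_sizes Cycle counts per epoch (default \code{c(20, 40, 80)}).
#' @param q_min,q_max,q_step Moment-order grid (default -5..5 by 0.25).
#' @param r_min Fit-correlation threshold for retaining a moment order.
#' @param n_surrogates Surrogates per epoch and channel (default 30).
#' @param max_iter Surrogate iteration cap, see \code{\link{iaaft_surrogate}}.
#' @param hand_policy Measure policy for the hand channel, see
#'   \code{\link{analyze_session}}.
#' @param se_mode "sem" or "sd", see \code{\link{tmf_stat}}.
#' @param n_boot Bootstrap resamples for the power analysis; 0 skips it.
#' @param alpha Significance level for the power analysis.
#' @param method Mixed-model estimation method.
#' @param seed Global seed fanned out to every stage.
#' @param out_dir Output directory for tables, reports and the manifest.
#' @return List of class \code{"pipeline_config"}.
#' @export
pipeline_config <- function(sim_params = fitts_sim_params(),
                            session_files = NULL,
                            epoch_sizes = c(20, 40, 80),
                            q_min = -5, q_max = 5, q_step = 0.25,
                            r_min = 0.995, n_surrogates = 30, max_iter = 100,
                            hand_policy = "abs-increments",
                            se_mode = "sem", n_boot = 0, alpha = 0.05,
                            method = "REML", seed = 1,
                            out_dir = "mfaim-run") {
  if (is.null(sim_params) && is.null(session_files))
    stop("supply either `sim_params` or `session_files`", call. = FALSE)
  if (!is.null(session_files)) {
    missing <- session_files[!file.exists(session_files)]
    if (length(missing))
      stop("input files not found: ", paste(missing, collapse = ", "),
           call. = FALSE)
  }
  if (any(epoch_sizes <= 0)) stop("epoch sizes must be positive", call. = FALSE)
  if (n_surrogates < 2) stop("`n_surrogates` must be >= 2", call. = FALSE)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Scalar fields in the file override the defaults of
#' \code{\link{pipeline_config}}; a \code{sim_params} block (if present)
#' is passed to \code{\link{fitts_sim_params}}.
#'
#' @param path Path to a \code{.yaml}/\code{.yml} or \code{.json} file.
#' @return A \code{"pipeline_config"}.
#' @export
read_pipeline_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(raw$sim_params))
    raw$sim_params <- do.call(fitts_sim_params, raw$sim_params)
  do.call(pipeline_config, raw)
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate (or load) -> kinematics -> spectra -> surrogates
#' -> t_MF -> mixed model -> reports, writing every artifact under
#' \code{config$out_dir}: \code{epochs.csv} (per-epoch records),
#' \code{coefficients.csv} and \code{model.json} (model report),
#' \code{power.csv} (when \code{n_boot > 0}), \code{effect_range.json},
#' and \code{manifest.json} (configuration, seed, package version,
#' exclusion counts, completed stages). Re-running with the same
#' configuration and seed reproduces every output bit-for-bit.
#'
#' @param config A \code{\link{pipeline_config}}.
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("mfaim")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    config = lapply(unclass(config), function(v)
      if (inherits(v, "fitts_sim_params")) unclass(v) else v),
    stages = character(0))
  finish <- function(stage) {
    manifest$stages <<- c(manifest$stages, stage)
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, null = "null", digits = NA,
                         pretty = TRUE)
  }
  # stage 1: input sessions
  sessions <- if (!is.null(config$session_files)) {
    lapply(config$session_files, read_session_csv)
  } else {
    prm <- config$sim_params
    prm$seed <- child_seed(config$seed, "simulate")
    simulate_fitts_study(prm)
  }
  finish("input")
  # stage 2: per-epoch records
  qgrid <- seq(config$q_min, config$q_max, by = config$q_step)
  records <- analyze_study(sessions, epoch_sizes = config$epoch_sizes,
                           q = qgrid, r_min = config$r_min,
                           n_surrogates = config$n_surrogates,
                           max_iter = config$max_iter,
                           hand_policy = config$hand_policy,
                           se_mode = config$se_mode,
                           seed = child_seed(config$seed, "analyze"))
  utils::write.csv(records, file.path(config$out_dir, "epochs.csv"),
                   row.names = FALSE)
  manifest$n_epochs <- nrow(records)
  manifest$n_flagged <- sum(records$flagged)
  finish("analyze")
  # stage 3: mixed model
  fit <- fit_aim_model(records, method = config$method)
  utils::write.csv(
    fit$coefficients[, c("label", "estimate", "se", "p")],
    file.path(config$out_dir, "coefficients.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(fit_r = fit$fit_r, n_records = fit$n_records,
         n_participants = fit$n_participants,
         ranef_sd = fit$ranef_sd, resid_sd = fit$resid_sd,
         dropped_terms = fit$dropped),
    file.path(config$out_dir, "model.json"),
    auto_unbox = TRUE, null = "null", digits = NA, pretty = TRUE)
  manifest$fit_r <- fit$fit_r
  finish("model")
  # stage 4: bootstrap power (optional)
  if (config$n_boot > 0) {
    pw <- bootstrap_power(records, n_boot = config$n_boot,
                          alpha = config$alpha,
                          seed = child_seed(config$seed, "power"),
                          method = config$method)
    utils::write.csv(pw, file.path(config$out_dir, "power.csv"),
                     row.names = FALSE)
    manifest$power_n_failed <- attr(pw, "n_failed")
    finish("power")
  }
  # stage 5: nonlinearity effect range
  nc <- nonlinearity_contributions(fit)
  er <- summarize_effect_range(nc$contributions,
                               observed = fit$design$records$sd_aim)
  jsonlite::write_json(
    list(predicted_range = er$predicted_range,
         observed_iqr = er$observed_iqr,
         coverage_pct = er$coverage_pct,
         tmf_hand_quartiles = unname(nc$quartiles_hand),
         tmf_head_quartiles = unname(nc$quartiles_head)),
    file.path(config$out_dir, "effect_range.json"),
    auto_unbox = TRUE, null = "null", digits = NA, pretty = TRUE)
  finish("report")
  invisible(manifest)
}
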