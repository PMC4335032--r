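# Run manifests and command-style entry points. The thin command-line
# wrapper in inst/cli/wmattractor dispatches to the cmd_* functions; they
# are equally usable from an interactive session.

#' Write a reproducibility manifest for a run
#'
#' Records the command, the full parameter set (so the configuration is
#' recomputable from the manifest alone), every seed, the engine, the
#' protocol list and output paths as JSON next to the results.
#'
#' @param path output JSON path.
#' @param command character tag of the command run.
#' @param pars the \code{wm_parameters} used.
#' @param seeds named list/vector of seeds (quenched, noise, ...).
#' @param engine engine name or \code{NULL}.
#' @param protocols list of \code{wm_protocol} objects or \code{NULL}.
#' @param outputs character vector of result paths.
#' @return \code{path}, invisibly.
#' @export
write_manifest <- function(path, command, pars, seeds = list(),
                           engine = NULL, protocols = NULL,
                           outputs = character()) {
  manifest <- list(
    command = command,
    package_version = as.character(utils::packageVersion("wmattractor")),
    parameters = unclass(pars),
    seeds = seeds,
    engine = engine,
    protocols = if (!is.null(protocols)) {
      lapply(protocols, function(p) list(kind = p$kind, sample = p$sample,
                                         epochs = p$epochs))
    },
    outputs = outputs,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, dataframe = "columns")
  invisible(path)
}

#' Calibrate a configuration file
#'
#' Loads a configuration, calibrates the mean external currents by the
#' mean-field equations, writes the calibrated configuration and a small
#' report (solution rates and residual, re-evaluated independently of the
#' solver).
#'
#' @param config path to a YAML configuration ([load_parameters()]).
#' @param out path for the calibrated configuration (YAML).
#' @param report optional path for a JSON report.
#' @return the calibrated \code{wm_parameters}, invisibly.
#' @export
cmd_calibrate <- function(config, out, report = NULL) {
  pars <- load_parameters(config)
  pars <- calibrate_external_currents(pars)
  sol <- solve_spontaneous_state(pars)
  resid <- max(abs(sol$rates - rate_map(sol$rates, pars, "spontaneous")))
  save_parameters(pars, out)
  if (!is.null(report)) {
    jsonlite::write_json(list(
      mu_ext_E = pars$mu_ext_E, mu_ext_I = pars$mu_ext_I,
      spontaneous_rates = as.list(sol$rates),
      residual_hz = resid), report, auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
  }
  message(sprintf("calibrated: mu_ext_E = %.6f mV, mu_ext_I = %.6f mV (residual %.2e Hz)",
                  pars$mu_ext_E, pars$mu_ext_I, resid))
  invisible(pars)
}

#' Simulate protocols and write results
#'
#' Runs match and/or non-match trials for every stimulus on the chosen
#' engine and writes rate traces (CSV), the response table (CSV), per-trial
#' survival flags (CSV), optional rasters (TSV) and a manifest.
#'
#' @param config path to a calibrated YAML configuration.
#' @param out_dir output directory (created if needed).
#' @param protocol \code{"match"}, \code{"nonmatch"} or \code{"both"}.
#' @param engine \code{"spiking"} or \code{"rate"}.
#' @param n_trials trials per protocol (spiking engine).
#' @param seed base seed; the quenched stream uses \code{seed + 1e6}.
#' @param alpha,beta,sigma_S stimulus parameters (mV).
#' @param write_rasters also write per-trial spike rasters.
#' @return the experiment object, invisibly.
#' @export
cmd_simulate <- function(config, out_dir, protocol = "match",
                         engine = "spiking", n_trials = 1L, seed = 1L,
                         alpha = 1.5, beta = 1.8, sigma_S = 2,
                         write_rasters = FALSE) {
  pars <- load_parameters(config)
  if (!is_calibrated(pars)) {
    stop("configuration is not calibrated; run cmd_calibrate() first",
         call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stim <- stimulus_parameters(alpha, beta, sigma_S, n_stimuli = pars$p)
  quenched_seed <- as.integer(seed) + 1000000L
  inputs <- draw_quenched_inputs(pars, stim, seed = quenched_seed)
  kinds <- if (protocol == "both") c("match", "nonmatch") else protocol
  protos <- list()
  for (kind in kinds) {
    for (s in seq_len(pars$p)) {
      protos[[length(protos) + 1]] <- build_protocol(
        kind, sample = s,
        foil = if (kind == "nonmatch") (s %% pars$p) + 1L)
    }
  }
  exper <- run_experiment(pars, inputs, protos, n_trials = n_trials,
                          engine = engine, seed = seed, stim = stim,
                          record_raster = write_rasters)
  outputs <- character()
  if (engine == "spiking") {
    rt <- count_responses(exper)
    resp_path <- file.path(out_dir, "responses.csv")
    utils::write.csv(responses_to_df(rt), resp_path, row.names = FALSE)
    surv <- do.call(rbind, lapply(seq_along(exper$trials), function(i) {
      tr <- exper$trials[[i]]
      delays <- which(tr$epochs$role == "delay")
      data.frame(trial = i, kind = tr$protocol$kind,
                 sample = tr$protocol$sample,
                 delay = seq_along(delays),
                 memory_survived = tr$survival[delays])
    }))
    surv_path <- file.path(out_dir, "survival.csv")
    utils::write.csv(surv, surv_path, row.names = FALSE)
    outputs <- c(resp_path, surv_path)
    if (write_rasters) {
      for (i in seq_along(exper$trials)) {
        rp <- file.path(out_dir, sprintf("raster_trial%03d.tsv", i))
        write_raster(exper$trials[[i]]$raster, pars, rp)
        outputs <- c(outputs, rp)
      }
    }
  }
  traces_path <- file.path(out_dir, "traces.csv")
  traces <- do.call(rbind, lapply(seq_along(exper$trials), function(i) {
    tr <- exper$trials[[i]]
    cbind(trial = i, tr$traces)
  }))
  utils::write.csv(traces, traces_path, row.names = FALSE)
  outputs <- c(outputs, traces_path)
  write_manifest(file.path(out_dir, "manifest.json"), "simulate", pars,
                 seeds = list(seed = seed, quenched = quenched_seed),
                 engine = engine, protocols = protos, outputs = outputs)
  invisible(exper)
}

responses_to_df <- function(rt) {
  idx <- expand.grid(neuron = seq_len(nrow(rt$delay)),
                     stimulus = seq_len(ncol(rt$delay)))
  out <- data.frame(idx, representation = rt$sel_pop[idx$neuron])
  for (r in dimnames(rt$resp)[[3]]) {
    out[[gsub("-", "_", r)]] <- rt$resp[cbind(idx$neuron, idx$stimulus,
                                              match(r, dimnames(rt$resp)[[3]]))]
  }
  out$delay_hz <- rt$delay[cbind(idx$neuron, idx$stimulus)]
  out
}

#' Analyze a simulated results directory
#'
#' Reads the response table written by [cmd_simulate()] and writes summary
#' metrics (match-effect indices, suppressed fraction, mean sparseness,
#' sample-delay correlations) as JSON. Never mutates simulation outputs;
#' re-running is idempotent.
#'
#' @param results_dir directory produced by [cmd_simulate()].
#' @param out path of the metrics JSON (default inside \code{results_dir}).
#' @return the metrics list, invisibly.
#' @export
cmd_analyze <- function(results_dir,
                        out = file.path(results_dir, "metrics.json")) {
  resp_path <- file.path(results_dir, "responses.csv")
  if (!file.exists(resp_path)) {
    stop("no responses.csv in ", results_dir,
         "; run cmd_simulate() with the spiking engine first", call. = FALSE)
  }
  df <- utils::read.csv(resp_path)
  need <- c("neuron", "stimulus", "representation", "sample")
  if (!all(need %in% names(df))) {
    stop("malformed responses.csv: expected columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  rt <- df_to_responses(df)
  metrics <- list(n_pairs = sum(!is.na(rt$resp[, , "sample"])))
  supp <- tryCatch(fraction_suppressed(rt), error = function(e) NULL)
  if (!is.null(supp)) metrics <- c(metrics, supp)
  idx <- match_effect_indices(rt)
  metrics$enhancement_index <- idx$enhancement
  metrics$suppression_index <- idx$suppression
  metrics$match_nonmatch_index <- idx$match_nonmatch
  metrics$mean_sparseness_sample <-
    mean(response_sparseness(rt, "sample"), na.rm = TRUE)
  corr <- sample_delay_correlation(rt)
  metrics$r_sample_delay <- corr$mean_r
  jsonlite::write_json(metrics, out, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(metrics)
}

df_to_responses <- function(df) {
  n_sel <- max(df$neuron)
  p <- max(df$stimulus)
  roles <- c("sample", "match", "nonmatch", "repeated-nonmatch", "distractor")
  resp <- array(NA_real_, c(n_sel, p, length(roles)),
                dimnames = list(NULL, NULL, roles))
  for (r in roles) {
    col <- gsub("-", "_", r)
    if (col %in% names(df)) {
      resp[cbind(df$neuron, df$stimulus, match(r, roles))] <- df[[col]]
    }
  }
  delay <- matrix(NA_real_, n_sel, p)
  if ("delay_hz" %in% names(df)) {
    delay[cbind(df$neuron, df$stimulus)] <- df$delay_hz
  }
  sel_pop <- df$representation[match(seq_len(n_sel), df$neuron)]
  structure(list(resp = resp, n = NULL, delay = delay, sel_pop = sel_pop,
                 window = 0.2),
            class = "wm_responses")
}

#' Mean-field bifurcation scan to CSV
#'
#' @param config path to a calibrated YAML configuration.
#' @param out CSV path for the branch table.
#' @param from,to,by scan grid of \code{J_plus} (mV).
#' @return the \code{wm_bifurcation} object, invisibly.
#' @export
cmd_meanfield_scan <- function(config, out, from = 0.12, to = 0.18,
                               by = 0.002) {
  pars <- load_parameters(config)
  if (!is_calibrated(pars)) {
    stop("configuration is not calibrated; run cmd_calibrate() first",
         call. = FALSE)
  }
  scan <- scan_bifurcation(pars, seq(from, to, by = by))
  utils::write.csv(scan$branches, out, row.names = FALSE)
  message(sprintf("critical J_plus: %s mV",
                  format(scan$critical_J_plus, digits = 6)))
  invisible(scan)
}
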