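#' Build a delayed match-to-sample protocol
#'
#' Constructs the epoch schedule of a trial. All trials begin with a
#' pre-stimulus interval (1 s by default) of spontaneous activity; stimuli
#' are presented for 0.5 s, separated by 0.7 s delays. Variants:
#' \describe{
#'   \item{match}{sample, delay, identical test stimulus.}
#'   \item{nonmatch}{sample, delay, different test stimulus (\code{foil}).}
#'   \item{abba}{sample A, a distractor B presented twice (repeating
#'     distractor), then the match A, with delays in between.}
#'   \item{distractors}{sample, then \code{n_distractors} (0, 1 or 2)
#'     distinct non-sample distractors, then a match or non-match test.
#'     With 0 distractors this reduces to the plain match/nonmatch
#'     schedule.}
#' }
#' Stimulus and delay durations are identical in all variants.
#'
#' @param kind one of \code{"match"}, \code{"nonmatch"}, \code{"abba"},
#'   \code{"distractors"}.
#' @param sample sample stimulus id in \code{1..p}.
#' @param foil test stimulus for \code{nonmatch} (and for
#'   \code{distractors} with \code{test = "nonmatch"}); must differ from the
#'   sample.
#' @param distractor distractor id for \code{abba}; must differ from the
#'   sample.
#' @param distractors vector of distinct distractor ids for
#'   \code{distractors}; none may equal the sample (nor the foil).
#' @param test \code{"match"} or \code{"nonmatch"} ending for
#'   \code{distractors}.
#' @param durations named vector with elements \code{pre}, \code{stim},
#'   \code{delay} (s).
#' @return an object of class \code{wm_protocol}: list with \code{kind} and
#'   \code{epochs}, a data frame with columns \code{role} (pre, sample,
#'   delay, match, nonmatch, repeated-nonmatch, distractor),
#'   \code{stimulus} (id or \code{NA}) and \code{duration} (s).
#' @export
build_protocol <- function(kind = c("match", "nonmatch", "abba",
                                    "distractors"),
                           sample, foil = NULL, distractor = NULL,
                           distractors = NULL,
                           test = c("match", "nonmatch"),
                           durations = c(pre = 1, stim = 0.5, delay = 0.7)) {
  kind <- match.arg(kind)
  test <- match.arg(test)
  stopifnot(all(c("pre", "stim", "delay") %in% names(durations)))
  sample <- as.integer(sample)
  ep <- function(role, stimulus, duration) {
    data.frame(role = role, stimulus = stimulus, duration = duration)
  }
  pre <- ep("pre", NA_integer_, durations[["pre"]])
  stim_ep <- function(role, s) ep(role, as.integer(s), durations[["stim"]])
  delay <- ep("delay", NA_integer_, durations[["delay"]])
  epochs <- switch(kind,
    match = rbind(pre, stim_ep("sample", sample), delay,
                  stim_ep("match", sample)),
    nonmatch = {
      if (is.null(foil) || foil == sample) {
        stop("nonmatch requires a foil different from the sample",
             call. = FALSE)
      }
      rbind(pre, stim_ep("sample", sample), delay, stim_ep("nonmatch", foil))
    },
    abba = {
      if (is.null(distractor) || distractor == sample) {
        stop("abba requires a distractor different from the sample",
             call. = FALSE)
      }
      rbind(pre, stim_ep("sample", sample), delay,
            stim_ep("nonmatch", distractor), delay,
            stim_ep("repeated-nonmatch", distractor), delay,
            stim_ep("match", sample))
    },
    distractors = {
      distractors <- as.integer(distractors)
      if (anyDuplicated(distractors) || any(distractors == sample)) {
        stop("distractors must be distinct and differ from the sample",
             call. = FALSE)
      }
      if (test == "nonmatch") {
        if (is.null(foil) || foil == sample || foil %in% distractors) {
          stop("nonmatch test requires a foil distinct from sample and distractors",
               call. = FALSE)
        }
      }
      out <- rbind(pre, stim_ep("sample", sample), delay)
      for (d in distractors) {
        out <- rbind(out, stim_ep("distractor", d), delay)
      }
      test_id <- if (test == "match") sample else as.integer(foil)
      rbind(out, stim_ep(test, test_id))
    })
  used <- stats::na.omit(epochs$stimulus)
  structure(list(kind = kind, sample = sample, epochs = epochs,
                 n_stimuli_used = length(unique(used))),
            class = "wm_protocol")
}

#' @export
print.wm_protocol <- function(x, ...) {
  cat(sprintf("<wm_protocol: %s, sample %d>\n", x$kind, x$sample))
  print(x$epochs)
  invisible(x)
}

# Simulate one spiking trial of a protocol: returns epoch table with
# absolute times, 200 ms response counts for selective neurons at each
# stimulus epoch, end-of-delay rates, survival flags, traces.
simulate_trial_spiking <- function(pars, inputs, protocol,
                                   response_window = 0.2,
                                   survival_window = 0.1,
                                   survival_factor = 5,
                                   record_raster = FALSE) {
  epochs <- protocol$epochs
  epochs$t_end <- cumsum(epochs$duration)
  epochs$t_start <- epochs$t_end - epochs$duration
  state <- new_spiking_state(pars)
  n_sel <- pars$N_E_sel
  sel_ids <- seq_len(n_sel)
  pop <- population_index(pars)
  counts <- matrix(NA_real_, n_sel, nrow(epochs))
  delay_rates <- matrix(NA_real_, n_sel, nrow(epochs))
  survival <- rep(NA, nrow(epochs))
  traces_all <- list()
  rasters <- list()
  fg_pop <- protocol$sample
  fg_ids <- which(pop == fg_pop)
  for (e in seq_len(nrow(epochs))) {
    res <- run_epoch(state, pars, inputs,
                     active_stimulus = if (is.na(epochs$stimulus[e])) NULL
                                       else epochs$stimulus[e],
                     duration = epochs$duration[e])
    state <- res$state
    traces_all[[e]] <- res$traces
    if (record_raster) rasters[[e]] <- res$raster
    role <- epochs$role[e]
    if (!is.na(epochs$stimulus[e])) {
      counts[, e] <- window_counts(res$raster, sel_ids, epochs$t_start[e],
                                   epochs$t_start[e] + response_window)
    } else if (role == "delay") {
      delay_rates[, e] <- window_counts(res$raster, sel_ids,
                                        epochs$t_end[e] - response_window,
                                        epochs$t_end[e]) / response_window
      fg_rate <- sum(res$raster$time >= epochs$t_end[e] - survival_window &
                       res$raster$neuron %in% fg_ids) /
        (length(fg_ids) * survival_window)
      survival[e] <- fg_rate > survival_factor * pars$nu_E_sp
    }
  }
  structure(list(protocol = protocol, epochs = epochs, counts = counts,
                 delay_rates = delay_rates, survival = survival,
                 p = pars$p, sel_pop = pop[seq_len(n_sel)],
                 traces = do.call(rbind, traces_all),
                 raster = if (record_raster) do.call(rbind, rasters) else NULL,
                 engine = "spiking"),
            class = "wm_trial")
}

#' Run a multi-trial experiment on the spiking or rate engine
#'
#' Runs \code{n_trials} of every protocol. For the spiking engine, trials
#' share the frozen quenched inputs and differ only in the fast-noise
#' stream, seeded deterministically from \code{seed}; each trial restarts
#' from fresh initial conditions. A delay epoch's \code{memory_survived}
#' flag records whether the sample representation's rate over the last
#' 100 ms of the delay exceeded 5 times the target spontaneous rate
#' (configurable threshold; the model's memory and spontaneous rates differ
#' by more than an order of magnitude, so results are insensitive to the
#' factor). The rate engine is deterministic, so each protocol is
#' integrated once regardless of \code{n_trials}.
#'
#' @param pars a calibrated \code{wm_parameters} object.
#' @param inputs a \code{wm_quenched} object (spiking engine).
#' @param protocols a list of \code{wm_protocol} objects.
#' @param n_trials trials per protocol.
#' @param engine \code{"spiking"} or \code{"rate"}.
#' @param seed integer base seed for the fast-noise streams.
#' @param stim a \code{wm_stimulus} (rate engine only).
#' @param survival_factor threshold multiple of \code{nu_E_sp} for the
#'   survival flag.
#' @param record_raster keep full per-trial rasters (memory-heavy).
#' @return an object of class \code{wm_experiment}: list of \code{wm_trial}
#'   objects (field \code{trials}) plus bookkeeping (\code{engine},
#'   \code{seed}, protocol list).
#' @export
run_experiment <- function(pars, inputs = NULL, protocols, n_trials = 1L,
                           engine = c("spiking", "rate"), seed = 1L,
                           stim = NULL, survival_factor = 5,
                           record_raster = FALSE) {
  engine <- match.arg(engine)
  if (inherits(protocols, "wm_protocol")) protocols <- list(protocols)
  trials <- list()
  if (engine == "spiking") {
    if (is.null(inputs)) stop("spiking engine requires quenched inputs",
                              call. = FALSE)
    counter <- 0L
    for (pr in protocols) {
      for (tr in seq_len(n_trials)) {
        counter <- counter + 1L
        set.seed((as.integer(seed) * 10007L + counter) %% .Machine$integer.max)
        trials[[length(trials) + 1]] <-
          simulate_trial_spiking(pars, inputs, pr,
                                 survival_factor = survival_factor,
                                 record_raster = record_raster)
      }
    }
  } else {
    if (is.null(stim)) stim <- inputs$stim
    if (is.null(stim)) stop("rate engine requires stimulus parameters",
                            call. = FALSE)
    for (pr in protocols) {
      rt <- integrate_rate_trial(pars, pr, stim)
      rt$protocol <- pr
      trials[[length(trials) + 1]] <- rt
    }
  }
  structure(list(trials = trials, engine = engine, seed = seed,
                 protocols = protocols, n_trials = n_trials),
            class = "wm_experiment")
}

#' @export
print.wm_experiment <- function(x, ...) {
  cat(sprintf("<wm_experiment: %d %s trial(s), %d protocol(s), seed %s>\n",
              length(x$trials), x$engine, length(x$protocols),
              format(x$seed)))
  invisible(x)
}

#' Survival probability of the sample memory per number of distractors
#'
#' @param experiment a spiking \code{wm_experiment} over distractor
#'   protocols.
#' @return data frame with \code{n_distractors}, \code{n_trials} and the
#'   fraction of trials whose final delay still held the sample memory.
#' @export
survival_by_distractors <- function(experiment) {
  rows <- lapply(experiment$trials, function(tr) {
    nd <- sum(tr$epochs$role == "distractor")
    delays <- which(tr$epochs$role == "delay")
    data.frame(n_distractors = nd,
               survived = tr$survival[delays[length(delays)]])
  })
  df <- do.call(rbind, rows)
  agg <- stats::aggregate(survived ~ n_distractors, df, mean)
  cnt <- stats::aggregate(survived ~ n_distractors, df, length)
  data.frame(n_distractors = agg$n_distractors, n_trials = cnt$survived,
             p_survived = agg$survived)
}

#' Restrict an experiment to trials whose sample memory survived
#'
#' Keeps the trials in which the sample representation was still active at
#' the end of every delay epoch. The distractor-protocol analyses of match
#' effects presuppose that the memory is present at test time; this filter
#' makes that conditioning explicit.
#'
#' @param experiment a spiking \code{wm_experiment}.
#' @return the experiment with non-surviving trials removed.
#' @export
filter_survived <- function(experiment) {
  stopifnot(experiment$engine == "spiking")
  keep <- vapply(experiment$trials, function(tr) {
    delays <- which(tr$epochs$role == "delay")
    all(tr$survival[delays])
  }, logical(1))
  experiment$trials <- experiment$trials[keep]
  experiment
}
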