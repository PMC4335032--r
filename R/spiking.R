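#' Block connectivity map of the structured network
#'
#' The network is all-to-all (no self-connections) with efficacies that
#' depend only on the population pair. Excitatory synapses onto a selective
#' neuron are potentiated (\code{J_plus}) from its own representation and
#' depressed (\code{J_minus}) from the other representations and from the
#' non-selective pool; synapses onto non-selective neurons keep the baseline
#' \code{J_EE}. \code{J_IE}, \code{J_EI} and \code{J_II} connect the
#' inhibitory population.
#'
#' @param pars a \code{wm_parameters} object.
#' @return a \code{(p+2) x (p+2)} matrix \code{J[post, pre]} in mV, with
#'   dimnames \code{sel1..selp, ns, inh}.
#' @export
build_connectivity <- function(pars) {
  p <- pars$p
  n_pops <- p + 2L
  labels <- c(paste0("sel", seq_len(p)), "ns", "inh")
  J <- matrix(0, n_pops, n_pops, dimnames = list(labels, labels))
  for (k in seq_len(p)) {
    J[k, seq_len(p)] <- pars$J_minus
    J[k, k] <- pars$J_plus
    J[k, p + 1L] <- pars$J_minus
  }
  J[p + 1L, seq_len(p + 1L)] <- pars$J_EE
  J[n_pops, seq_len(p + 1L)] <- pars$J_IE
  J[seq_len(p + 1L), n_pops] <- pars$J_EI
  J[n_pops, n_pops] <- pars$J_II
  J
}

#' Fresh spiking-network state
#'
#' Membrane potentials are drawn uniformly in \code{[V_R, theta)} from the
#' current RNG stream; synaptic currents start at zero; no neuron is
#' refractory. A 1 s pre-stimulus interval in the standard protocols washes
#' out this initialisation.
#'
#' @param pars a \code{wm_parameters} object.
#' @param t start time (s).
#' @return an object of class \code{wm_spiking_state}.
#' @export
new_spiking_state <- function(pars, t = 0) {
  n <- pars$N_E + pars$N_I
  structure(list(
    V = stats::runif(n, pars$V_R, pars$theta),
    I_N = numeric(n), I_A = numeric(n), I_G = numeric(n),
    refractory_until = numeric(n), t = t
  ), class = "wm_spiking_state")
}

#' Simulate one epoch of the spiking network
#'
#' Euler-integrates the leaky integrate-and-fire network for \code{duration}
#' seconds at \code{dt_spiking}, with the frozen external inputs of
#' \code{inputs} and, optionally, an active stimulus adding the quenched
#' selective currents. Fast membrane noise is drawn from R's RNG: call
#' \code{set.seed()} (or use [run_experiment()]) for reproducible trials.
#'
#' @param state a \code{wm_spiking_state} (see [new_spiking_state()]).
#' @param pars a calibrated \code{wm_parameters} object.
#' @param inputs a \code{wm_quenched} object.
#' @param active_stimulus stimulus id in \code{1..p} or \code{NULL}.
#' @param duration epoch length (s); 0 returns the state unchanged with an
#'   empty raster.
#' @param record_spikes keep the spike raster (time, neuron id); per-population
#'   rate traces are always returned.
#' @param rate_bin width of the rate-trace bins (s); a reporting choice only,
#'   no statistic depends on it.
#' @return list with \code{state} (advanced), \code{raster} (data frame
#'   \code{time}, \code{neuron}), and \code{traces} (data frame: bin start
#'   time plus one mean-rate column per population, Hz).
#' @export
run_epoch <- function(state, pars, inputs, active_stimulus = NULL,
                      duration, record_spikes = TRUE, rate_bin = 0.01) {
  stopifnot(inherits(state, "wm_spiking_state"))
  if (duration < 0) stop("duration must be non-negative", call. = FALSE)
  labels <- c(paste0("sel", seq_len(pars$p)), "ns", "inh")
  if (duration == 0) {
    empty <- data.frame(time = numeric(0), neuron = integer(0))
    tr <- as.data.frame(matrix(numeric(0), 0, pars$p + 3,
                               dimnames = list(NULL, c("time", labels))))
    return(list(state = state, raster = empty, traces = tr))
  }
  n_steps <- as.integer(round(duration / pars$dt_spiking))
  bin_steps <- max(1L, as.integer(round(rate_bin / pars$dt_spiking)))
  pop <- population_index(pars)
  mu <- epoch_drive(inputs, active_stimulus)
  J <- build_connectivity(pars)
  n_pops <- pars$p + 2L
  pop_tau <- c(rep(pars$tau_E, pars$p + 1L), pars$tau_I)
  pop_X <- c(rep(pars$X_E, pars$p + 1L), pars$X_I)
  pop_inh <- c(rep(FALSE, pars$p + 1L), TRUE)
  res <- spiking_run_epoch_cpp(state$V, state$I_N, state$I_A, state$I_G,
                               state$refractory_until, state$t,
                               pop, mu, J, pop_inh, pop_tau, pop_X,
                               pars$tau_NMDA, pars$tau_AMPA, pars$tau_GABA,
                               pars$theta, pars$V_R, pars$tau_arp,
                               pars$sigma, pars$dt_spiking, n_steps,
                               bin_steps, record_spikes,
                               noise_seed = stats::runif(1))
  new_state <- structure(list(V = res$V, I_N = res$I_N, I_A = res$I_A,
                              I_G = res$I_G,
                              refractory_until = res$refractory_until,
                              t = res$t),
                         class = "wm_spiking_state")
  pop_sizes <- tabulate(pop, n_pops)
  n_bins <- nrow(res$bin_counts)
  steps_in_bin <- pmin(bin_steps, n_steps - (seq_len(n_bins) - 1L) * bin_steps)
  rates <- sweep(res$bin_counts, 2, pop_sizes, "/") /
    (steps_in_bin * pars$dt_spiking)
  traces <- data.frame(time = state$t + (seq_len(n_bins) - 1L) * bin_steps *
                         pars$dt_spiking, rates)
  names(traces) <- c("time", labels)
  raster <- data.frame(time = res$spike_times, neuron = res$spike_ids)
  list(state = new_state, raster = raster, traces = traces)
}

#' Spike counts of selected neurons in a time window
#'
#' @param raster data frame with columns \code{time}, \code{neuron}.
#' @param neurons integer vector of neuron ids.
#' @param t_start,t_end window \code{[t_start, t_end)} in seconds.
#' @return integer vector of counts, one per requested neuron.
#' @export
window_counts <- function(raster, neurons, t_start, t_end) {
  sel <- raster$time >= t_start & raster$time < t_end
  counts <- tabulate(factor(raster$neuron[sel], levels = neurons),
                     nbins = length(neurons))
  stats::setNames(counts, neurons)
}

#' Write a spike raster as tab-separated text
#'
#' Columns: \code{time_s}, \code{neuron_id}, \code{population_label}.
#'
#' @param raster data frame with columns \code{time}, \code{neuron}.
#' @param pars the \code{wm_parameters} of the simulated network.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_raster <- function(raster, pars, path) {
  lab <- population_labels(pars)
  out <- data.frame(time_s = raster$time, neuron_id = raster$neuron,
                    population_label = lab[raster$neuron])
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
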