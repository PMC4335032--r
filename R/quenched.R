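#' Stimulus parameters
#'
#' Describes the selective external currents elicited by stimulus
#' presentation. Every neuron of the memory representations receives, for
#' each stimulus, a frozen current drawn once at network construction:
#' from a Gaussian with mean \code{alpha + beta} if the neuron belongs to the
#' representation of the presented stimulus (the selective foreground), and
#' from a Gaussian with mean \code{beta} otherwise (the selective
#' background); both have SD \code{sigma_S}. Defaults are the standard
#' regime (\code{alpha} = 1.5 mV, \code{beta} = 1.8 mV);
#' [distractor_regime()] gives the weaker-input regime used for protocols
#' with intervening stimuli.
#'
#' @param alpha mean selective-input advantage of the foreground (mV).
#' @param beta mean selective input to all representations (mV).
#' @param sigma_S SD of the quenched selective currents (mV).
#' @param n_stimuli number of stimuli; must equal \code{p}.
#' @return an object of class \code{wm_stimulus}.
#' @export
stimulus_parameters <- function(alpha = 1.5, beta = 1.8, sigma_S = 2,
                                n_stimuli = 6L) {
  if (alpha < 0) stop("alpha must be non-negative", call. = FALSE)
  if (sigma_S < 0) stop("sigma_S must be non-negative", call. = FALSE)
  structure(list(alpha = alpha, beta = beta, sigma_S = sigma_S,
                 n_stimuli = as.integer(n_stimuli)),
            class = "wm_stimulus")
}

#' @rdname stimulus_parameters
#' @details \code{distractor_regime()} returns the reduced-amplitude inputs
#'   (\code{alpha} = 0.84 mV, \code{beta} = 1.7 mV) under which persistent
#'   activity survives a distractor with high probability but is occasionally
#'   disrupted by it.
#' @export
distractor_regime <- function(sigma_S = 2, n_stimuli = 6L) {
  stimulus_parameters(alpha = 0.84, beta = 1.7, sigma_S = sigma_S,
                      n_stimuli = n_stimuli)
}

#' Draw the frozen (quenched) external-input structure
#'
#' Draws, once per network realisation, (i) each neuron's mean background
#' current from a Gaussian with mean \code{mu_ext_E} (excitatory) or
#' \code{mu_ext_I} (inhibitory) and SD \code{sigma_BG}, and (ii) for every
#' selective excitatory neuron and every stimulus, the selective current
#' added during that stimulus' presentation. Both structures are frozen: the
#' same seed reproduces them bit-exactly, and the presentation of a given
#' stimulus always elicits the same current in a given neuron, across trials
#' and epochs. Non-selective excitatory neurons and inhibitory neurons
#' receive no selective current. Draws are not truncated; negative currents
#' are allowed.
#'
#' @param pars a calibrated \code{wm_parameters} object.
#' @param stim a \code{wm_stimulus} object; its \code{n_stimuli} must equal
#'   \code{pars$p}.
#' @param seed integer seed for the quenched draws (kept separate from the
#'   fast-noise seeds used at simulation time).
#' @return an object of class \code{wm_quenched}: list with
#'   \code{mu_ext_background} (length \code{N_E + N_I}), \code{mu_sel}
#'   (matrix \code{N_E_sel x p}, rows follow the global neuron ordering of
#'   [population_labels()]), \code{population}, \code{stim}, \code{seed}.
#' @export
draw_quenched_inputs <- function(pars, stim, seed) {
  if (!is_calibrated(pars)) {
    stop("external currents not calibrated; run calibrate_external_currents() first",
         call. = FALSE)
  }
  if (stim$n_stimuli != pars$p) {
    stop("n_stimuli must equal the number of representations p", call. = FALSE)
  }
  n <- pars$N_E + pars$N_I
  pop <- population_index(pars)
  withr_seed <- function(expr) { # local RNG, leave global stream untouched
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
            else rm(".Random.seed", envir = globalenv()))
    set.seed(seed)
    expr
  }
  res <- withr_seed({
    mu_bg <- numeric(n)
    exc <- seq_len(pars$N_E)
    mu_bg[exc] <- stats::rnorm(pars$N_E, pars$mu_ext_E, pars$sigma_BG)
    mu_bg[-exc] <- stats::rnorm(pars$N_I, pars$mu_ext_I, pars$sigma_BG)
    mu_sel <- matrix(stats::rnorm(pars$N_E_sel * pars$p,
                                  mean = stim$beta, sd = stim$sigma_S),
                     nrow = pars$N_E_sel, ncol = pars$p)
    sel_pop <- pop[seq_len(pars$N_E_sel)]
    for (s in seq_len(pars$p)) {
      fg <- which(sel_pop == s)
      mu_sel[fg, s] <- stats::rnorm(length(fg), mean = stim$alpha + stim$beta,
                                    sd = stim$sigma_S)
    }
    list(mu_bg = mu_bg, mu_sel = mu_sel)
  })
  structure(list(mu_ext_background = res$mu_bg,
                 mu_sel = res$mu_sel,
                 population = pop,
                 stim = stim,
                 seed = as.integer(seed)),
            class = "wm_quenched")
}

#' Total mean external drive of one neuron
#'
#' Returns the mean external current and the fast-noise amplitude for a
#' neuron, with or without an active stimulus. During stimulus presentation
#' selective neurons receive their frozen selective current on top of the
#' background; non-selective and inhibitory neurons receive the background
#' only. The fast-noise amplitude is \code{sigma} in all cases.
#'
#' @param inputs a \code{wm_quenched} object.
#' @param pars the \code{wm_parameters} the inputs were drawn for.
#' @param neuron neuron index (global ordering).
#' @param active_stimulus stimulus id in \code{1..p}, or \code{NULL} for no
#'   stimulus.
#' @return list with \code{mu} (mV) and \code{sigma} (mV).
#' @export
total_drive <- function(inputs, pars, neuron, active_stimulus = NULL) {
  n <- length(inputs$mu_ext_background)
  if (neuron < 1 || neuron > n) stop("invalid neuron index", call. = FALSE)
  mu <- inputs$mu_ext_background[neuron]
  if (!is.null(active_stimulus)) {
    s <- as.integer(active_stimulus)
    if (s < 1 || s > ncol(inputs$mu_sel)) {
      stop("unknown stimulus id: ", active_stimulus, call. = FALSE)
    }
    if (neuron <= nrow(inputs$mu_sel)) mu <- mu + inputs$mu_sel[neuron, s]
  }
  list(mu = mu, sigma = pars$sigma)
}

#' Per-neuron mean drive vector for a whole epoch
#'
#' Vectorised version of [total_drive()] used by the simulation engines.
#'
#' @inheritParams total_drive
#' @return numeric vector of length \code{N_E + N_I} of mean external
#'   currents (mV).
#' @keywords internal
epoch_drive <- function(inputs, active_stimulus = NULL) {
  mu <- inputs$mu_ext_background
  if (!is.null(active_stimulus)) {
    s <- as.integer(active_stimulus)
    if (s < 1 || s > ncol(inputs$mu_sel)) {
      stop("unknown stimulus id: ", active_stimulus, call. = FALSE)
    }
    nsel <- nrow(inputs$mu_sel)
    mu[seq_len(nsel)] <- mu[seq_len(nsel)] + inputs$mu_sel[, s]
  }
  mu
}

#' Serialise quenched inputs to a tabular file
#'
#' Writes one row per neuron: id, population label, background mean and (for
#' selective neurons) the per-stimulus selective currents, as tab-separated
#' text.
#'
#' @param inputs a \code{wm_quenched} object.
#' @param pars the matching \code{wm_parameters}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_quenched_inputs <- function(inputs, pars, path) {
  n <- length(inputs$mu_ext_background)
  lab <- population_labels(pars)
  sel <- matrix(NA_real_, nrow = n, ncol = pars$p)
  sel[seq_len(nrow(inputs$mu_sel)), ] <- inputs$mu_sel
  df <- data.frame(neuron = seq_len(n), population = lab,
                   mu_background = inputs$mu_ext_background, sel,
                   check.names = FALSE)
  names(df)[-(1:3)] <- paste0("mu_sel_stim", seq_len(pars$p))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
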