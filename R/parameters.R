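#' Network parameters for the attractor model
#'
#' Constructs and validates the full parameter set of the model: population
#' sizes and coding level, leaky integrate-and-fire constants, synaptic
#' kinetics and efficacies, quenched- and fast-noise amplitudes, target
#' spontaneous rates and integration steps. Defaults reproduce the standard
#' parameter set of the model (6 memory representations of 80 neurons each
#' inside a 1600-excitatory / 400-inhibitory network).
#'
#' The depressed efficacy \code{J_minus} is always derived from the balance
#' condition \eqn{f J_+ + (1-f) J_- = J_{EE}}, which keeps the spontaneous
#' rates of the selective populations independent of the potentiation
#' \code{J_plus}.
#'
#' @param p number of selective populations (memory representations).
#' @param f coding level: fraction of excitatory neurons per representation.
#' @param N_E,N_I excitatory / inhibitory neuron counts.
#' @param tau_E,tau_I membrane time constants (s).
#' @param theta firing threshold (mV).
#' @param V_R reset potential (mV).
#' @param tau_arp absolute refractory period (s).
#' @param sigma fast-noise amplitude of the external current (mV); the same
#'   value is the noise entering the mean-field transfer function.
#' @param sigma_BG SD of the quenched per-neuron background current (mV).
#' @param sigma_S SD of the quenched per-neuron selective stimulus current (mV).
#' @param tau_AMPA,tau_NMDA,tau_GABA synaptic current decay constants (s).
#' @param X_E,X_I fraction of excitatory synaptic charge carried by the slow
#'   (NMDA-like) channel on excitatory / inhibitory targets.
#' @param J_EE baseline excitatory-to-excitatory efficacy (mV).
#' @param J_IE,J_EI,J_II other baseline efficacies (mV).
#' @param J_plus potentiated efficacy within a memory representation (mV).
#' @param nu_E_sp,nu_I_sp target spontaneous rates (Hz) used by calibration.
#' @param dt_spiking,dt_rate Euler steps of the spiking and rate models (s).
#' @param mu_ext_E,mu_ext_I mean external currents (mV); \code{NA} until set
#'   by [calibrate_external_currents()].
#' @return an object of class \code{wm_parameters} (a validated list with a
#'   derived \code{J_minus} and the selective-neuron count \code{N_E_sel}).
#' @seealso [load_parameters()], [fixture_parameters()],
#'   [calibrate_external_currents()]
#' @examples
#' pars <- network_parameters()
#' pars$J_minus            # (J_EE - J_plus * f) / (1 - f)
#' pars$N_E_sel            # 480 selective neurons at defaults
#' @export
network_parameters <- function(p = 6L,
                               f = 0.05,
                               N_E = 1600L,
                               N_I = 400L,
                               tau_E = 0.02,
                               tau_I = 0.01,
                               theta = 20,
                               V_R = 10,
                               tau_arp = 0.0025,
                               sigma = 0.75,
                               sigma_BG = 1,
                               sigma_S = 2,
                               tau_AMPA = 0.005,
                               tau_NMDA = 0.05,
                               tau_GABA = 0.005,
                               X_E = 0.7,
                               X_I = 0.002,
                               J_EE = 0.025,
                               J_IE = 2.5 * J_EE,
                               J_EI = 3 * J_EE,
                               J_II = 4 * J_EE,
                               J_plus = 0.156,
                               nu_E_sp = 0.75,
                               nu_I_sp = 5,
                               dt_spiking = 1e-4,
                               dt_rate = 1e-3,
                               mu_ext_E = NA_real_,
                               mu_ext_I = NA_real_) {
  pars <- list(
    p = as.integer(p), f = f, N_E = as.integer(N_E), N_I = as.integer(N_I),
    tau_E = tau_E, tau_I = tau_I, theta = theta, V_R = V_R,
    tau_arp = tau_arp, sigma = sigma, sigma_BG = sigma_BG, sigma_S = sigma_S,
    tau_AMPA = tau_AMPA, tau_NMDA = tau_NMDA, tau_GABA = tau_GABA,
    X_E = X_E, X_I = X_I,
    J_EE = J_EE, J_IE = J_IE, J_EI = J_EI, J_II = J_II,
    J_plus = J_plus,
    nu_E_sp = nu_E_sp, nu_I_sp = nu_I_sp,
    dt_spiking = dt_spiking, dt_rate = dt_rate,
    mu_ext_E = mu_ext_E, mu_ext_I = mu_ext_I
  )
  pars$J_minus <- (J_EE - J_plus * f) / (1 - f)
  pars$N_E_sel <- as.integer(round(p * f * N_E))
  class(pars) <- "wm_parameters"
  validate_parameters(pars)
  pars
}

#' @export
print.wm_parameters <- function(x, ...) {
  cat("<wm_parameters>\n")
  cat(sprintf("  populations: p = %d selective (f = %.3g) + non-selective + inhibitory\n",
              x$p, x$f))
  cat(sprintf("  sizes: N_E = %d (%d selective), N_I = %d\n",
              x$N_E, x$N_E_sel, x$N_I))
  cat(sprintf("  efficacies (mV): J_EE = %.4g, J_plus = %.4g, J_minus = %.5g\n",
              x$J_EE, x$J_plus, x$J_minus))
  cat(sprintf("  external means (mV): mu_ext_E = %s, mu_ext_I = %s\n",
              format(x$mu_ext_E, digits = 6), format(x$mu_ext_I, digits = 6)))
  invisible(x)
}

validate_parameters <- function(pars) {
  stopifnot(inherits(pars, "wm_parameters"))
  fail <- function(msg) stop("invalid parameters: ", msg, call. = FALSE)
  if (!(pars$f > 0 && pars$f < 1)) fail("coding level f must be in (0, 1)")
  if (pars$p * pars$f > 1 + 1e-12) fail("p * f must not exceed 1")
  tcs <- c(tau_E = pars$tau_E, tau_I = pars$tau_I, tau_arp = pars$tau_arp,
           tau_AMPA = pars$tau_AMPA, tau_NMDA = pars$tau_NMDA,
           tau_GABA = pars$tau_GABA, dt_spiking = pars$dt_spiking,
           dt_rate = pars$dt_rate)
  if (any(tcs <= 0)) {
    fail(paste("time constants must be positive:",
               paste(names(tcs)[tcs <= 0], collapse = ", ")))
  }
  if (!(pars$theta > pars$V_R)) fail("theta must exceed V_R")
  if (pars$X_E < 0 || pars$X_E > 1 || pars$X_I < 0 || pars$X_I > 1) {
    fail("NMDA charge fractions X_E, X_I must lie in [0, 1]")
  }
  if (pars$sigma < 0) fail("fast-noise amplitude sigma must be non-negative")
  if (pars$sigma_BG < 0 || pars$sigma_S < 0) fail("quenched SDs must be non-negative")
  jm <- (pars$J_EE - pars$J_plus * pars$f) / (1 - pars$f)
  if (abs(pars$J_minus - jm) > 1e-12 * max(1, abs(pars$J_EE))) {
    fail("J_minus must equal (J_EE - J_plus * f) / (1 - f)")
  }
  if (abs(pars$f * pars$J_plus + (1 - pars$f) * pars$J_minus - pars$J_EE) >
      1e-12 * max(1, abs(pars$J_EE))) {
    fail("f * J_plus + (1 - f) * J_minus must equal J_EE")
  }
  if (pars$N_E_sel != round(pars$p * pars$f * pars$N_E)) {
    fail("N_E_sel must equal p * f * N_E")
  }
  if (abs(pars$p * pars$f * pars$N_E - round(pars$p * pars$f * pars$N_E)) > 1e-9) {
    fail("p * f * N_E must be an integer (whole representations)")
  }
  invisible(pars)
}

#' Whether external currents have been calibrated
#'
#' @param pars a \code{wm_parameters} object.
#' @return \code{TRUE} if both \code{mu_ext_E} and \code{mu_ext_I} are set.
#' @export
is_calibrated <- function(pars) {
  is.finite(pars$mu_ext_E) && is.finite(pars$mu_ext_I)
}

.parameter_keys <- function() {
  c("p", "f", "N_E", "N_I", "tau_E", "tau_I", "theta", "V_R", "tau_arp",
    "sigma", "sigma_BG", "sigma_S", "tau_AMPA", "tau_NMDA", "tau_GABA",
    "X_E", "X_I", "J_EE", "J_IE", "J_EI", "J_II", "J_plus",
    "nu_E_sp", "nu_I_sp", "dt_spiking", "dt_rate")
}

#' Load parameters from a YAML configuration file
#'
#' Reads a key-value configuration and returns a validated parameter object.
#' The shipped canonical configuration is
#' \code{system.file("extdata", "table1.yaml", package = "wmattractor")}.
#' \code{J_minus} is never read: it is derived from \code{J_EE}, \code{J_plus}
#' and \code{f}. Keys \code{mu_ext_E} / \code{mu_ext_I} are optional (written
#' by the calibration step); all other keys are required.
#'
#' @param path path to a YAML file.
#' @return a \code{wm_parameters} object.
#' @seealso [save_parameters()], [network_parameters()]
#' @export
load_parameters <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  required <- .parameter_keys()
  missing <- setdiff(required, names(cfg))
  if (length(missing) > 0) {
    stop("configuration error: missing key(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  args <- cfg[intersect(names(cfg), c(required, "mu_ext_E", "mu_ext_I"))]
  args$mu_ext_E <- if (is.null(cfg$mu_ext_E)) NA_real_ else as.numeric(cfg$mu_ext_E)
  args$mu_ext_I <- if (is.null(cfg$mu_ext_I)) NA_real_ else as.numeric(cfg$mu_ext_I)
  do.call(network_parameters, args)
}

#' Write parameters to a YAML configuration file
#'
#' Serialises all fields, including derived ones and any calibrated external
#' currents, such that [load_parameters()] reproduces the object exactly.
#'
#' @param pars a \code{wm_parameters} object.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
save_parameters <- function(pars, path) {
  validate_parameters(pars)
  out <- unclass(pars)[c(.parameter_keys(), "mu_ext_E", "mu_ext_I",
                         "J_minus", "N_E_sel")]
  if (!is.finite(out$mu_ext_E)) out$mu_ext_E <- NULL
  if (!is.finite(out$mu_ext_I)) out$mu_ext_I <- NULL
  yaml::write_yaml(out, path, precision = 17L)
  invisible(path)
}

#' Reduced-size test network preserving the mean-field structure
#'
#' Shrinks \code{N_E} and \code{N_I} by an integer factor while keeping the
#' coding level \code{f} and the number of representations \code{p}, and
#' rescales all efficacies by the same factor so that the products
#' \eqn{N J} that enter the mean recurrent currents are unchanged. The
#' mean-field fixed points of the fixture network are therefore identical to
#' those of the full network; finite-size fluctuations are larger. Intended
#' for fast tests only, not for production simulations.
#'
#' @param pars a \code{wm_parameters} object.
#' @param scale integer divisor of the population sizes (e.g. 8 maps
#'   1600/400 to 200/50).
#' @return a \code{wm_parameters} object.
#' @export
fixture_parameters <- function(pars = network_parameters(), scale = 8L) {
  scale <- as.integer(scale)
  stopifnot(scale >= 1L)
  N_E <- pars$N_E / scale
  N_I <- pars$N_I / scale
  if (N_E != round(N_E) || N_I != round(N_I) ||
      abs(pars$p * pars$f * N_E - round(pars$p * pars$f * N_E)) > 1e-9) {
    stop("fixture scale must divide N_E, N_I and the representation size",
         call. = FALSE)
  }
  network_parameters(
    p = pars$p, f = pars$f, N_E = as.integer(N_E), N_I = as.integer(N_I),
    tau_E = pars$tau_E, tau_I = pars$tau_I, theta = pars$theta,
    V_R = pars$V_R, tau_arp = pars$tau_arp, sigma = pars$sigma,
    sigma_BG = pars$sigma_BG, sigma_S = pars$sigma_S,
    tau_AMPA = pars$tau_AMPA, tau_NMDA = pars$tau_NMDA,
    tau_GABA = pars$tau_GABA, X_E = pars$X_E, X_I = pars$X_I,
    J_EE = pars$J_EE * scale, J_IE = pars$J_IE * scale,
    J_EI = pars$J_EI * scale, J_II = pars$J_II * scale,
    J_plus = pars$J_plus * scale,
    nu_E_sp = pars$nu_E_sp, nu_I_sp = pars$nu_I_sp,
    dt_spiking = pars$dt_spiking, dt_rate = pars$dt_rate,
    mu_ext_E = pars$mu_ext_E, mu_ext_I = pars$mu_ext_I
  )
}

#' Replace the potentiated efficacy, rederiving the depressed one
#'
#' @param pars a \code{wm_parameters} object.
#' @param J_plus new potentiated efficacy (mV).
#' @return a \code{wm_parameters} object with \code{J_minus} rederived from
#'   the balance condition (spontaneous rates are then unchanged).
#' @export
set_J_plus <- function(pars, J_plus) {
  pars$J_plus <- J_plus
  pars$J_minus <- (pars$J_EE - J_plus * pars$f) / (1 - pars$f)
  validate_parameters(pars)
  pars
}

#' Population labels of every neuron in the network
#'
#' Neurons are ordered: the \code{p} memory representations first (each
#' \code{f * N_E} neurons), then the non-selective excitatory neurons, then
#' the inhibitory population.
#'
#' @param pars a \code{wm_parameters} object.
#' @return character vector of length \code{N_E + N_I} with labels
#'   \code{"sel1"} ... \code{"selp"}, \code{"ns"}, \code{"inh"}.
#' @export
population_labels <- function(pars) {
  n_per <- as.integer(round(pars$f * pars$N_E))
  c(rep(paste0("sel", seq_len(pars$p)), each = n_per),
    rep("ns", pars$N_E - pars$p * n_per),
    rep("inh", pars$N_I))
}

#' Integer population index of every neuron
#'
#' @param pars a \code{wm_parameters} object.
#' @return integer vector: 1..p for selective representations, p+1 for the
#'   non-selective excitatory pool, p+2 for the inhibitory pool.
#' @keywords internal
population_index <- function(pars) {
  n_per <- as.integer(round(pars$f * pars$N_E))
  c(rep(seq_len(pars$p), each = n_per),
    rep(pars$p + 1L, pars$N_E - pars$p * n_per),
    rep(pars$p + 2L, pars$N_I))
}
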