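# Shared fixtures, cached per test session. Calibration is deterministic, so
# caching does not couple tests.

.fix_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fix_cache[[key]])) .fix_cache[[key]] <- force(expr)
  .fix_cache[[key]]
}

# Full-size calibrated parameter set.
full_pars <- function() {
  cached("full", calibrate_external_currents(network_parameters()))
}

# Reduced network (N_E = 200, N_I = 50) with N*J preserved: identical
# mean-field fixed points, larger finite-size fluctuations. Used for fast
# dynamical tests.
fix_pars <- function(scale = 8L) {
  cached(paste0("fix", scale),
         calibrate_external_currents(
           fixture_parameters(network_parameters(), scale)))
}

# A tiny two-representation network (12 neurons) for exact oracle
# comparisons; calibration is irrelevant there, external means are set by
# hand.
tiny_pars <- function(sigma = 0, J_EE = 0.5, J_plus = 1.0, mu_E = 21,
                      mu_I = 20) {
  network_parameters(p = 2L, f = 0.25, N_E = 8L, N_I = 4L,
                     sigma = sigma, sigma_BG = 0, sigma_S = 0,
                     J_EE = J_EE, J_IE = 2.5 * J_EE, J_EI = 3 * J_EE,
                     J_II = 4 * J_EE, J_plus = J_plus,
                     mu_ext_E = mu_E, mu_ext_I = mu_I)
}

tiny_inputs <- function(pars, alpha = 1, beta = 0.5, seed = 5) {
  draw_quenched_inputs(pars, stimulus_parameters(alpha, beta,
                                                 sigma_S = pars$sigma_S,
                                                 n_stimuli = pars$p), seed)
}

# Monte-Carlo transfer-function comparison at five drive levels, computed
# once per session (used by the transfer-function unit test and the
# property checks).
mc_phi_levels <- function() {
  cached("mc_phi", {
    set.seed(20)
    lapply(c(19, 20.5, 22, 24, 27), function(mu) {
      mc <- mc_lif_rate(mu, 0.75, 0.02, 20, 10, 0.0025)
      list(mu = mu, rate = mc$rate, sem = mc$sem)
    })
  })
}
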