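# Independent oracles. These deliberately avoid the package's computational
# paths: the naive simulator uses an explicit per-synapse weight matrix
# instead of block sums, and the Monte-Carlo rate estimate integrates the
# membrane SDE directly instead of evaluating the transfer-function
# integral.

# Naive per-synapse LIF simulation with an explicit (N x N) weight matrix.
# Mirrors the integration conventions (end-of-step delta kicks with one-step
# delay, no self-connections, refractory clamp at V_R, currents integrate
# during refractoriness). Deterministic: sigma is taken as 0.
naive_spiking_run <- function(pars, mu, duration) {
  n <- pars$N_E + pars$N_I
  pop <- rep(seq_len(pars$p), each = round(pars$f * pars$N_E))
  pop <- c(pop, rep(pars$p + 1L, pars$N_E - length(pop)),
           rep(pars$p + 2L, pars$N_I))
  Jb <- build_connectivity(pars)
  W <- Jb[pop, pop]
  diag(W) <- 0
  is_inh <- pop == pars$p + 2L
  tau_m <- ifelse(is_inh, pars$tau_I, pars$tau_E)
  X <- ifelse(is_inh, pars$X_I, pars$X_E)
  dt <- pars$dt_spiking
  V <- rep(pars$V_R + 0.5 * (pars$theta - pars$V_R), n)
  I_N <- I_A <- I_G <- numeric(n)
  refr <- numeric(n)
  n_steps <- round(duration / dt)
  spikes <- list()
  for (k in seq_len(n_steps)) {
    t <- (k - 1) * dt
    I_N <- I_N - dt / pars$tau_NMDA * I_N
    I_A <- I_A - dt / pars$tau_AMPA * I_A
    I_G <- I_G - dt / pars$tau_GABA * I_G
    active <- t >= refr - 1e-12
    V[!active] <- pars$V_R
    Itot <- mu + I_N + I_A - I_G
    V[active] <- V[active] +
      dt / tau_m[active] * (Itot[active] - V[active])
    sp <- active & V >= pars$theta
    if (any(sp)) {
      V[sp] <- pars$V_R
      refr[sp] <- t + dt + pars$tau_arp
      spikes[[length(spikes) + 1]] <- data.frame(time = t + dt,
                                                 neuron = which(sp))
      sumE <- as.vector(W[, sp & !is_inh, drop = FALSE] %*%
                          rep(1, sum(sp & !is_inh)))
      sumI <- as.vector(W[, sp & is_inh, drop = FALSE] %*%
                          rep(1, sum(sp & is_inh)))
      I_N <- I_N + X * tau_m / pars$tau_NMDA * sumE
      I_A <- I_A + (1 - X) * tau_m / pars$tau_AMPA * sumE
      I_G <- I_G + tau_m / pars$tau_GABA * sumI
    }
  }
  list(V = V, I_N = I_N, I_A = I_A, I_G = I_G,
       raster = if (length(spikes)) do.call(rbind, spikes)
                else data.frame(time = numeric(0), neuron = integer(0)))
}

# Monte-Carlo estimate of the stationary rate of a single noise-driven LIF
# neuron by direct Euler-Maruyama integration of the membrane SDE over an
# ensemble, with burn-in. Discrete threshold detection biases the rate by
# O(sqrt(dt)), so the estimate is Richardson-extrapolated from two step
# sizes (bias(4h) = 2 bias(h) for sqrt-order bias). Returns the
# extrapolated rate and its standard error.
mc_lif_rate <- function(mu, sigma, tau_m, theta, V_R, tau_arp,
                        nn = 400L, t_burn = 0.1, t_meas = 0.15) {
  one <- function(dt) {
    V <- runif(nn, V_R, theta)
    refr <- numeric(nn)
    counts <- integer(nn)
    sdn <- sigma * sqrt(dt / tau_m)
    n_steps <- round((t_burn + t_meas) / dt)
    for (k in seq_len(n_steps)) {
      t <- (k - 1) * dt
      act <- refr <= t
      V[act] <- V[act] + (dt / tau_m) * (mu - V[act]) + rnorm(sum(act)) * sdn
      sp <- act & V >= theta
      V[sp] <- V_R
      refr[sp] <- t + dt + tau_arp
      V[!act] <- V_R
      if (t >= t_burn) counts[sp] <- counts[sp] + 1L
    }
    rate <- counts / t_meas
    list(rate = mean(rate), sem = stats::sd(rate) / sqrt(nn))
  }
  coarse <- one(4e-5)
  fine <- one(1e-5)
  list(rate = 2 * fine$rate - coarse$rate,
       sem = sqrt(4 * fine$sem^2 + coarse$sem^2))
}

# Construct a wm_responses object from explicit arrays (for analysis-module
# oracles on hand-built tables).
make_responses <- function(sample, match = NULL, nonmatch = NULL,
                           repeated = NULL, delay = NULL, sel_pop = NULL,
                           window = 0.2) {
  roles <- c("sample", "match", "nonmatch", "repeated-nonmatch", "distractor")
  n <- nrow(sample); p <- ncol(sample)
  resp <- array(NA_real_, c(n, p, length(roles)),
                dimnames = list(NULL, NULL, roles))
  resp[, , "sample"] <- sample
  if (!is.null(match)) resp[, , "match"] <- match
  if (!is.null(nonmatch)) resp[, , "nonmatch"] <- nonmatch
  if (!is.null(repeated)) resp[, , "repeated-nonmatch"] <- repeated
  if (is.null(delay)) delay <- matrix(NA_real_, n, p)
  if (is.null(sel_pop)) sel_pop <- rep(seq_len(p), length.out = n)
  structure(list(resp = resp, n = NULL, delay = delay, sel_pop = sel_pop,
                 window = window),
            class = "wm_responses")
}
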