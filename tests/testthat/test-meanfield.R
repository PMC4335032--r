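tab1 <- list(sigma = 0.75, tau_E = 0.02, tau_I = 0.01, theta = 20,
             V_R = 10, tau_arp = 0.0025)

phi_tab1 <- function(mu, tau_m = tab1$tau_E) {
  phi_transfer(mu, tab1$sigma, tau_m, tab1$theta, tab1$V_R, tab1$tau_arp)
}

test_that("transfer function: monotone, bounded, correct limits", {
  mus <- seq(5, 60, by = 0.5)   # below ~5 mV the rate underflows to 0
  rates <- phi_tab1(mus)
  expect_true(all(diff(rates) > 0))
  expect_true(all(rates >= 0 & rates <= 1 / tab1$tau_arp))
  # refractory-limited saturation: 1/tau_arp = 400 Hz as mu -> infinity
  expect_equal(phi_tab1(1e6), 400, tolerance = 1e-3)
  expect_gt(phi_tab1(1e6), phi_tab1(1e4))
  expect_lt(phi_tab1(0), 1e-200)                      # deep subthreshold
  expect_error(phi_transfer(20, 0, 0.02, 20, 10, 0.0025), "sigma")
})

test_that("transfer function matches adaptive quadrature to 1e-10", {
  # 1 + erf(u) underflows to 0 for u < -5.8, so the oracle evaluates the
  # equivalent product exp(u^2) * erfc(-u): both factors stay representable
  # for |u| < 26.3, i.e. for every drive up to ~29.7 mV
  ref <- function(mu) {
    a <- (tab1$theta - mu) / tab1$sigma
    b <- (tab1$V_R - mu) / tab1$sigma
    I <- stats::integrate(function(u) exp(u^2) * pracma::erfc(-u),
                          b, a, rel.tol = 1e-12, subdivisions = 2000L)$value
    1 / (tab1$tau_arp + tab1$tau_E * sqrt(pi) * I)
  }
  for (mu in c(15, 17.5, 19, 21, 25, 29)) {
    expect_equal(phi_tab1(mu), ref(mu), tolerance = 1e-10)
  }
})

test_that("transfer function agrees with a Monte-Carlo membrane-SDE oracle", {
  for (mc in mc_phi_levels()) {
    expect_lt(abs(phi_tab1(mc$mu) - mc$rate), 3 * mc$sem)
  }
})

test_that("quenched averaging: degenerate case and adaptive reference", {
  qa <- function(mu, sBG) {
    quenched_average_rate(mu, sBG, tab1$sigma, tab1$tau_E, tab1$theta,
                          tab1$V_R, tab1$tau_arp)
  }
  expect_equal(qa(19, 0), phi_tab1(19))
  ref <- function(mu, sBG) {
    stats::integrate(function(x) stats::dnorm(x, 0, sBG) * phi_tab1(mu + x),
                     -10 * sBG, 10 * sBG, rel.tol = 1e-12)$value
  }
  for (mu in c(16, 17.5, 19, 21)) {
    expect_equal(qa(mu, 1), ref(mu, 1), tolerance = 1e-10)
  }
})

test_that("calibration hits the target spontaneous rates exactly", {
  pars <- full_pars()
  sol <- solve_spontaneous_state(pars)
  expect_lt(sol$residual_norm, 1e-8)
  expect_equal(unname(sol$rates[paste0("sel", 1:6)]), rep(0.75, 6),
               tolerance = 1e-8)
  expect_equal(sol$rates[["ns"]], 0.75, tolerance = 1e-8)
  expect_equal(sol$rates[["inh"]], 5, tolerance = 1e-8)
  # independent re-evaluation of the self-consistency residual
  resid <- max(abs(sol$rates - wmattractor:::rate_map(sol$rates, pars,
                                                      "spontaneous")))
  expect_lt(resid, 1e-8)
})

test_that("calibration is invariant under J_plus with the balance constraint", {
  base <- full_pars()
  alt <- calibrate_external_currents(set_J_plus(network_parameters(), 0.10))
  expect_equal(alt$mu_ext_E, base$mu_ext_E, tolerance = 1e-8)
  expect_equal(alt$mu_ext_I, base$mu_ext_I, tolerance = 1e-8)
  sol <- solve_spontaneous_state(alt)
  expect_equal(sol$rates[["sel1"]], 0.75, tolerance = 1e-6)
})

test_that("calibration inverts the transfer function when sigma_BG = 0", {
  pars <- network_parameters(sigma_BG = 0)
  # hand-pick total currents, define the targets as their transfer rates
  mu_E_tot <- 18.2
  mu_I_tot <- 18.6
  pars$nu_E_sp <- phi_tab1(mu_E_tot)
  pars$nu_I_sp <- phi_tab1(mu_I_tot, tab1$tau_I)
  pars <- calibrate_external_currents(pars)
  target <- c(rep(pars$nu_E_sp, 7), pars$nu_I_sp)
  names(target) <- c(paste0("sel", 1:6), "ns", "inh")
  mu_rec <- recurrent_currents(target, pars, "spontaneous")
  expect_equal(mu_rec[["sel1"]] + pars$mu_ext_E, mu_E_tot, tolerance = 1e-6)
  expect_equal(mu_rec[["inh"]] + pars$mu_ext_I, mu_I_tot, tolerance = 1e-6)
})

test_that("recurrent currents: linearity and the symmetric-rate identity", {
  pars <- network_parameters()
  zero <- c(rep(0, 7), 0)
  names(zero) <- c(paste0("sel", 1:6), "ns", "inh")
  expect_true(all(recurrent_currents(zero, pars, "spontaneous") == 0))
  # with all selective rates equal to nu, the selective bracket is
  # (f g+ + (1-f) g-) nu + non-selective terms; under the balance condition
  # the prefactor is 1, so the selective and non-selective currents differ
  # exactly by (f g+ + (1-f) g- - 1) f N_E J_EE tau_E nu = 0
  nu <- 2.3
  rates <- c(rep(nu, 7), 4)
  names(rates) <- names(zero)
  mu <- recurrent_currents(rates, pars, "spontaneous")
  gap <- (pars$f * pars$J_plus / pars$J_EE +
            (1 - pars$f) * pars$J_minus / pars$J_EE - 1) *
    pars$N_E * pars$J_EE * pars$tau_E * nu
  expect_equal(mu[["sel1"]] - mu[["ns"]], gap, tolerance = 1e-12)
  expect_equal(gap, 0, tolerance = 1e-12)
  # delay structure with sf = sb reproduces the spontaneous selective current
  rates4 <- c(sf = nu, sb = nu, ns = nu, inh = 4)
  mu4 <- recurrent_currents(rates4, pars, "delay", gamma = 1L)
  expect_equal(mu4[["sf"]], mu[["sel1"]], tolerance = 1e-12)
  expect_equal(mu4[["sb"]], mu[["sel1"]], tolerance = 1e-12)
})

test_that("delay-state landscape at the standard potentiation", {
  pars <- full_pars()
  sols <- solve_delay_state(pars, all_branches = TRUE)
  branches <- vapply(sols, function(s) s$branch, character(1))
  expect_setequal(unique(branches), c("spontaneous", "memory", "unstable"))
  mem <- sols[[which(branches == "memory")[1]]]
  spo <- sols[[which(branches == "spontaneous")[1]]]
  uns <- sols[[which(branches == "unstable")[1]]]
  expect_gt(mem$rates[["sf"]], 20)
  expect_lt(mem$rates[["sb"]], 0.75)         # background below spontaneous
  expect_gt(mem$rates[["inh"]], 5)           # inhibition above spontaneous
  # spontaneous solution of the 4-population system matches the p+2 system
  expect_equal(spo$rates[["sf"]], 0.75, tolerance = 1e-8)
  expect_equal(spo$rates[["sb"]], 0.75, tolerance = 1e-8)
  # unstable foreground rate between the two stable branches
  expect_gt(uns$rates[["sf"]], spo$rates[["sf"]])
  expect_lt(uns$rates[["sf"]], mem$rates[["sf"]])
  for (s in sols) expect_lt(s$residual_norm, 1e-8)
})

test_that("unstructured network has no memory branch", {
  pars <- full_pars()
  sols <- solve_delay_state(set_J_plus(pars, pars$J_EE), all_branches = TRUE)
  expect_false(any(vapply(sols, function(s) s$branch == "memory",
                          logical(1))))
})

test_that("critical potentiation: below the standard value, bisection = grid scan", {
  pars <- full_pars()
  crit <- cached("crit", critical_J_plus(pars, 0.10, 0.156, tol = 1e-4))
  expect_lt(crit, 0.156)
  expect_gt(crit, 0.10)
  # dense-grid oracle around the bisection value
  grid <- seq(crit - 2e-4, crit + 2e-4, by = 1e-4)
  has_mem <- vapply(grid, function(jp) {
    sols <- tryCatch(solve_delay_state(pars, J_plus = jp, all_branches = TRUE),
                     error = function(e) list())
    any(vapply(sols, function(s) s$branch == "memory", logical(1)))
  }, logical(1))
  expect_true(any(has_mem) && !all(has_mem))
  grid_crit <- grid[which(has_mem)[1]]
  # bisection (with continuation guesses) and the cold grid scan agree to
  # the combined resolution of the two methods
  expect_lt(abs(crit - grid_crit), 2e-4)
})

test_that("bifurcation scan: branch ordering and monotone memory rate", {
  pars <- full_pars()
  scan <- cached("scan",
                 scan_bifurcation(pars, seq(0.138, 0.160, by = 0.004)))
  expect_false(is.na(scan$critical_J_plus))
  expect_lt(scan$critical_J_plus, 0.156)
  mem <- subset(scan$branches, branch == "memory")
  expect_true(all(diff(mem$nu_sf[order(mem$J_plus)]) > 0))
  expect_true(all(diff(mem$nu_inh[order(mem$J_plus)]) > 0))
  # no memory branch below critical
  below <- subset(scan$branches, J_plus < scan$critical_J_plus)
  expect_false(any(below$branch == "memory"))
  # unstable branch sandwiched between spontaneous and memory
  for (jp in unique(mem$J_plus)) {
    uns <- subset(scan$branches, J_plus == jp & branch == "unstable")
    if (nrow(uns) == 1) {
      expect_gt(uns$nu_sf, 0.75)
      expect_lt(uns$nu_sf, mem$nu_sf[mem$J_plus == jp])
    }
  }
})
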