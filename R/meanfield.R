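# Mean-field self-consistency machinery.
#
# Stationary rates solve nu_K = <Phi(mu_rec_K(nu) + mu_ext, sigma)>_BG where
# <.>_BG is a Gaussian average over the quenched background current and Phi is
# the first-passage-time transfer function of the white-noise-driven LIF
# neuron. Only the external noise sigma enters the fluctuation term; the
# recurrent spiking contribution to the variance is neglected, which is why
# spiking simulations agree with the theory only approximately.

# Scaled complementary error function exp(x^2) * erfc(x), stable for large
# positive x (asymptotic series). For x < -26.6 the true value overflows
# double precision; +Inf is returned, which downstream code treats as a zero
# firing rate.
erfcx <- function(x) {
  out <- numeric(length(x))
  hi <- x > 26
  out[!hi] <- exp(x[!hi]^2) * 2 * stats::pnorm(-sqrt(2) * x[!hi])
  if (any(hi)) {
    z <- x[hi] # asymptotic: 1/(x sqrt(pi)) (1 - 1/(2x^2) + 3/(4x^4) - ...)
    iz2 <- 1 / z^2
    out[hi] <- (1 - 0.5 * iz2 * (1 - 1.5 * iz2 * (1 - 2.5 * iz2))) /
      (z * sqrt(pi))
  }
  out
}

.gl_cache <- new.env(parent = emptyenv())
gl_nodes <- function(n) {
  key <- as.character(n)
  if (is.null(.gl_cache[[key]])) {
    .gl_cache[[key]] <- pracma::gaussLegendre(n, 0, 1)
  }
  .gl_cache[[key]]
}
gh_nodes <- function(n) {
  key <- paste0("gh", n)
  if (is.null(.gl_cache[[key]])) {
    .gl_cache[[key]] <- pracma::gaussHermite(n)
  }
  .gl_cache[[key]]
}

#' Transfer function of the noisy leaky integrate-and-fire neuron
#'
#' Stationary firing rate of an LIF neuron driven by a mean current \code{mu}
#' and white noise of amplitude \code{sigma}:
#' \deqn{\Phi(\mu,\sigma) = \left[\tau_{arp} + \tau_m \sqrt{\pi}
#'   \int_{b}^{a} e^{u^2}(1+\mathrm{erf}(u))\,du\right]^{-1}}
#' with \eqn{a = (\theta-\mu)/\sigma}, \eqn{b = (V_R-\mu)/\sigma}. The
#' integrand is evaluated as \eqn{\mathrm{erfcx}(-u)} on Gauss-Legendre
#' nodes, which avoids overflow of \eqn{e^{u^2}} for all but extremely
#' subthreshold drives (where the rate underflows to 0).
#'
#' @param mu mean current (mV); vectorised.
#' @param sigma noise amplitude (mV), must be positive.
#' @param tau_m membrane time constant (s).
#' @param theta firing threshold (mV).
#' @param V_R reset potential (mV).
#' @param tau_arp refractory period (s).
#' @param n_quad number of Gauss-Legendre nodes.
#' @return firing rate(s) in Hz, bounded by \code{1/tau_arp}.
#' @export
phi_transfer <- function(mu, sigma, tau_m, theta, V_R, tau_arp,
                         n_quad = 100L) {
  if (any(sigma <= 0)) stop("sigma must be positive", call. = FALSE)
  a <- (theta - mu) / sigma
  b <- (V_R - mu) / sigma
  gl <- gl_nodes(n_quad)
  # u = b + (a-b) t, t in [0,1]
  u <- outer(b, gl$x * 0, `+`) + outer(a - b, gl$x)
  vals <- matrix(erfcx(-u), nrow = length(mu))
  integral <- (a - b) * as.vector(vals %*% gl$w)
  rate <- 1 / (tau_arp + tau_m * sqrt(pi) * integral)
  rate[!is.finite(integral)] <- 0
  rate
}

#' Quenched-average firing rate over the background-current distribution
#'
#' Gaussian-weighted average of [phi_transfer()] over the per-neuron quenched
#' external current (mean \code{mu_mean}, SD \code{sigma_BG}), by fixed-order
#' Gauss-Hermite quadrature. With \code{sigma_BG = 0} this reduces to a
#' single transfer-function evaluation.
#'
#' @param mu_mean total mean current: recurrent plus mean external (mV);
#'   vectorised.
#' @param sigma_BG SD of the quenched background current (mV).
#' @param sigma fast-noise amplitude (mV).
#' @inheritParams phi_transfer
#' @param n_gh number of Gauss-Hermite nodes. The transfer function varies
#'   nearly exponentially across the background distribution, so moderate
#'   orders converge slowly; the default reaches about 1e-11 Hz against
#'   adaptive quadrature (order 64 reaches about 1e-8 Hz, enough for the
#'   dynamical engines).
#' @return average firing rate(s) in Hz.
#' @export
quenched_average_rate <- function(mu_mean, sigma_BG, sigma, tau_m, theta,
                                  V_R, tau_arp, n_gh = 200L) {
  if (sigma_BG < 0) stop("sigma_BG must be non-negative", call. = FALSE)
  if (sigma_BG == 0) {
    return(phi_transfer(mu_mean, sigma, tau_m, theta, V_R, tau_arp))
  }
  gh <- gh_nodes(n_gh)
  mus <- outer(mu_mean, sqrt(2) * sigma_BG * gh$x, `+`)
  rates <- matrix(phi_transfer(as.vector(mus), sigma, tau_m, theta, V_R,
                               tau_arp),
                  nrow = length(mu_mean))
  as.vector(rates %*% gh$w) / sqrt(pi)
}

# Convenience wrappers bound to a parameter set. The solvers use order 100
# (rate error ~2e-8 Hz, one third the cost of the public default).
phi_E <- function(pars, mu, n_gh = 100L) {
  quenched_average_rate(mu, pars$sigma_BG, pars$sigma, pars$tau_E,
                        pars$theta, pars$V_R, pars$tau_arp, n_gh = n_gh)
}
phi_I <- function(pars, mu, n_gh = 100L) {
  quenched_average_rate(mu, pars$sigma_BG, pars$sigma, pars$tau_I,
                        pars$theta, pars$V_R, pars$tau_arp, n_gh = n_gh)
}

#' Mean recurrent currents of the population structure
#'
#' Implements the bracketed mean-current expressions of the stationary
#' theory, with \eqn{g_+ = J_+/J_{EE}} and \eqn{g_- = J_-/J_{EE}}.
#' Two bookkeepings are supported: the \code{"spontaneous"} structure with
#' \code{p} selective populations plus non-selective plus inhibitory
#' (rates named \code{sel1..selp, ns, inh}), and the \code{"delay"}
#' structure with selective foreground / selective background /
#' non-selective / inhibitory (rates named \code{sf, sb, ns, inh}), where
#' \code{gamma} representations are in the foreground.
#'
#' @param rates named rate vector (Hz), see Details.
#' @param pars a \code{wm_parameters} object.
#' @param structure \code{"spontaneous"} or \code{"delay"}.
#' @param gamma number of foreground representations (delay structure).
#' @param split if \code{TRUE}, return a list with the excitatory
#'   (\code{recE}) and inhibitory (\code{recI}, positive magnitude)
#'   components separately (used by the rate dynamics); total is
#'   \code{recE - recI}.
#' @return named vector of mean recurrent currents (mV), or a list of two
#'   such vectors when \code{split = TRUE}.
#' @export
recurrent_currents <- function(rates, pars,
                               structure = c("spontaneous", "delay"),
                               gamma = 1L, split = FALSE) {
  structure <- match.arg(structure)
  g_plus <- pars$J_plus / pars$J_EE
  g_minus <- pars$J_minus / pars$J_EE
  f <- pars$f
  p <- pars$p
  cEE <- pars$N_E * pars$J_EE * pars$tau_E
  cIE <- pars$N_E * pars$J_IE * pars$tau_I
  cEI <- pars$N_I * pars$J_EI * pars$tau_E
  cII <- pars$N_I * pars$J_II * pars$tau_I
  if (structure == "spontaneous") {
    sel <- rates[paste0("sel", seq_len(p))]
    nu0 <- rates[["ns"]]; nuI <- rates[["inh"]]
    sum_sel <- sum(sel)
    recE <- c(
      cEE * (f * g_plus * sel + f * g_minus * (sum_sel - sel) +
               (1 - p * f) * g_minus * nu0),
      ns = cEE * (f * sum_sel + (1 - p * f) * nu0),
      inh = cIE * (f * sum_sel + (1 - p * f) * nu0)
    )
    names(recE)[seq_len(p)] <- paste0("sel", seq_len(p))
    recI <- c(rep(cEI * nuI, p + 1), cII * nuI)
    names(recI) <- names(recE)
  } else {
    nusf <- rates[["sf"]]; nusb <- rates[["sb"]]
    nu0 <- rates[["ns"]]; nuI <- rates[["inh"]]
    recE <- c(
      sf = cEE * (f * nusf * (g_plus + (gamma - 1) * g_minus) +
                    f * nusb * (p - gamma) * g_minus +
                    (1 - p * f) * g_minus * nu0),
      sb = cEE * (f * nusf * gamma * g_minus +
                    f * nusb * (g_plus + (p - gamma - 1) * g_minus) +
                    (1 - p * f) * g_minus * nu0),
      ns = cEE * (f * nusf * gamma + f * nusb * (p - gamma) +
                    (1 - p * f) * nu0),
      inh = cIE * (f * nusf * gamma + f * nusb * (p - gamma) +
                     (1 - p * f) * nu0)
    )
    recI <- c(sf = cEI * nuI, sb = cEI * nuI, ns = cEI * nuI, inh = cII * nuI)
  }
  if (split) list(recE = recE, recI = recI) else recE - recI
}

# Self-consistency map nu -> <Phi>(mu_rec(nu) + mu_ext) for either structure.
rate_map <- function(rates, pars, structure = "spontaneous", gamma = 1L) {
  rate_map_batch(matrix(rates, ncol = 1,
                        dimnames = list(names(rates), NULL)),
                 pars, structure, gamma)[, 1]
}

# Batched variant: one transfer-function evaluation for m rate vectors
# (columns), used to build finite-difference Jacobians cheaply.
rate_map_batch <- function(rate_cols, pars, structure = "spontaneous",
                           gamma = 1L) {
  m <- ncol(rate_cols)
  n <- nrow(rate_cols)
  mu <- matrix(NA_real_, n, m)
  for (j in seq_len(m)) {
    r <- rate_cols[, j]
    names(r) <- rownames(rate_cols)
    mu[, j] <- recurrent_currents(r, pars, structure, gamma) +
      c(rep(pars$mu_ext_E, n - 1), pars$mu_ext_I)
  }
  out <- mu
  out[-n, ] <- phi_E(pars, as.vector(mu[-n, , drop = FALSE]))
  out[n, ] <- phi_I(pars, mu[n, ])
  rownames(out) <- rownames(rate_cols)
  out
}

# Damped Newton-Raphson with forward-difference Jacobian on
# F(nu) = nu - rate_map(nu).
newton_rates <- function(rates0, pars, structure = "spontaneous", gamma = 1L,
                         tol = 1e-10, max_iter = 200L) {
  nu <- rates0
  n <- length(nu)
  for (iter in seq_len(max_iter)) {
    Fv <- nu - rate_map(nu, pars, structure, gamma)
    if (max(abs(Fv)) < tol) {
      return(list(rates = nu, residual = max(abs(Fv)), converged = TRUE,
                  iterations = iter))
    }
    h <- pmax(1e-6, 1e-6 * abs(nu))
    pert <- matrix(nu, n, n, dimnames = list(names(nu), NULL)) +
      diag(h, n)
    G <- rate_map_batch(pert, pars, structure, gamma)
    J <- ((pert - G) - Fv) / rep(h, each = n)
    step <- tryCatch(solve(J, Fv), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) {
      return(list(rates = nu, residual = max(abs(Fv)), converged = FALSE,
                  iterations = iter))
    }
    lambda <- 1
    repeat { # damping: keep rates in [0, 1/tau_arp], require residual decrease
      nu_new <- pmin(pmax(nu - lambda * step, 0), 1 / pars$tau_arp)
      F_new <- nu_new - rate_map(nu_new, pars, structure, gamma)
      if (max(abs(F_new)) <= max(abs(Fv)) || lambda < 1 / 64) break
      lambda <- lambda / 2
    }
    nu <- nu_new
  }
  Fv <- nu - rate_map(nu, pars, structure, gamma)
  list(rates = nu, residual = max(abs(Fv)), converged = max(abs(Fv)) < tol,
       iterations = max_iter)
}

mf_solution <- function(fit, pars, structure, gamma = 1L, branch) {
  mu_rec <- recurrent_currents(fit$rates, pars, structure, gamma)
  structure(list(rates = fit$rates, mu_rec = mu_rec, branch = branch,
                 residual_norm = fit$residual, converged = fit$converged,
                 structure = structure, gamma = gamma),
            class = "wm_meanfield")
}

#' @export
print.wm_meanfield <- function(x, ...) {
  cat(sprintf("<wm_meanfield: %s branch (%s structure), residual %.2e Hz>\n",
              x$branch, x$structure, x$residual_norm))
  print(round(x$rates, 4))
  invisible(x)
}

#' Calibrate the mean external currents to the target spontaneous rates
#'
#' Finds \code{mu_ext_E} and \code{mu_ext_I} such that the spontaneous fixed
#' point of the (p+2)-population self-consistency equations sits at the
#' target rates \code{nu_E_sp} (all excitatory populations) and
#' \code{nu_I_sp} (inhibitory). Because the targets pin the recurrent
#' currents, the problem reduces to a two-dimensional root find, solved by
#' damped Newton-Raphson with a finite-difference Jacobian after a coarse
#' bracketing scan. The balance condition on \code{J_minus} makes the result
#' independent of \code{J_plus}.
#'
#' @param pars a \code{wm_parameters} object.
#' @param tol tolerance on the rate residual (Hz).
#' @param max_iter maximum Newton iterations.
#' @return the parameters with \code{mu_ext_E}, \code{mu_ext_I} filled in.
#' @export
calibrate_external_currents <- function(pars, tol = 1e-10, max_iter = 200L) {
  target <- c(rep(pars$nu_E_sp, pars$p + 1), pars$nu_I_sp)
  names(target) <- c(paste0("sel", seq_len(pars$p)), "ns", "inh")
  mu_rec <- recurrent_currents(target, pars, "spontaneous")
  n <- length(mu_rec)
  resid <- function(x) {
    c(phi_E(pars, mu_rec[[1]] + x[1]) - pars$nu_E_sp,
      phi_I(pars, mu_rec[[n]] + x[2]) - pars$nu_I_sp)
  }
  # coarse bracket: quenched-average rate is strictly increasing in mu
  bracket <- function(mu_rec_k, fphi, nu_target) {
    grid <- seq(pars$V_R, 2 * pars$theta + 20, by = 0.25)
    vals <- fphi(pars, mu_rec_k + grid) - nu_target
    i <- which(vals > 0)[1]
    if (is.na(i) || i == 1) stop("calibration target unreachable", call. = FALSE)
    mean(grid[c(i - 1, i)])
  }
  x <- c(bracket(mu_rec[[1]], phi_E, pars$nu_E_sp),
         bracket(mu_rec[[n]], phi_I, pars$nu_I_sp))
  for (iter in seq_len(max_iter)) {
    Fv <- resid(x)
    if (max(abs(Fv)) < tol) break
    h <- 1e-6
    J <- cbind((resid(x + c(h, 0)) - Fv) / h, (resid(x + c(0, h)) - Fv) / h)
    step <- solve(J, Fv)
    lambda <- 1
    repeat {
      x_new <- x - lambda * step
      if (max(abs(resid(x_new))) <= max(abs(Fv)) || lambda < 1 / 64) break
      lambda <- lambda / 2
    }
    x <- x_new
  }
  if (max(abs(resid(x))) >= tol) {
    stop(sprintf("calibration failed to converge: residual %.3e Hz",
                 max(abs(resid(x)))), call. = FALSE)
  }
  pars$mu_ext_E <- x[1]
  pars$mu_ext_I <- x[2]
  pars
}

#' Solve the spontaneous-state fixed point of the (p+2)-population system
#'
#' @param pars a calibrated \code{wm_parameters} object.
#' @param initial_guess optional named rate vector (Hz); defaults to the
#'   calibration targets.
#' @param tol,max_iter Newton controls.
#' @return a \code{wm_meanfield} solution with branch \code{"spontaneous"}.
#' @export
solve_spontaneous_state <- function(pars, initial_guess = NULL,
                                    tol = 1e-10, max_iter = 200L) {
  if (!is_calibrated(pars)) {
    stop("external currents not calibrated; run calibrate_external_currents() first",
         call. = FALSE)
  }
  if (is.null(initial_guess)) {
    initial_guess <- c(rep(pars$nu_E_sp, pars$p + 1), pars$nu_I_sp)
    names(initial_guess) <- c(paste0("sel", seq_len(pars$p)), "ns", "inh")
  }
  fit <- newton_rates(initial_guess, pars, "spontaneous", tol = tol,
                      max_iter = max_iter)
  if (!fit$converged) {
    stop(sprintf("spontaneous-state solver did not converge (residual %.3e Hz)",
                 fit$residual), call. = FALSE)
  }
  mf_solution(fit, pars, "spontaneous", branch = "spontaneous")
}

# Stability of a fixed point of tau nu_dot = -nu + G(nu): stable iff all
# eigenvalues of dG/dnu have real part < 1.
classify_stability <- function(rates, pars, structure, gamma = 1L) {
  n <- length(rates)
  J <- matrix(0, n, n)
  G0 <- rate_map(rates, pars, structure, gamma)
  h <- pmax(1e-6, 1e-6 * abs(rates))
  for (j in seq_len(n)) {
    r <- rates
    r[j] <- r[j] + h[j]
    J[, j] <- (rate_map(r, pars, structure, gamma) - G0) / h[j]
  }
  max(Re(eigen(J, only.values = TRUE)$values)) < 1
}

#' Solve delay-period fixed points of the four-population system
#'
#' Solves the selective-foreground / selective-background / non-selective /
#' inhibitory self-consistency equations by Newton-Raphson from one or
#' several initial guesses. With the default multi-start, the spontaneous
#' solution, the memory (persistent-activity) solution and, when bracketed
#' by those two, the intermediate unstable solution are all searched for.
#'
#' @param pars a calibrated \code{wm_parameters} object.
#' @param J_plus optional potentiation override (mV); \code{J_minus} is
#'   rederived.
#' @param gamma number of foreground representations (the standard scenario
#'   is 1).
#' @param initial_guess optional named rate vector \code{c(sf, sb, ns, inh)};
#'   if given, only that start is used.
#' @param all_branches if \code{TRUE} (default) return every distinct
#'   converged solution, tagged \code{spontaneous} / \code{memory} /
#'   \code{unstable}; otherwise return the memory branch if found, else the
#'   spontaneous one.
#' @param tol,max_iter Newton controls.
#' @return a \code{wm_meanfield} object, or a list of them when
#'   \code{all_branches = TRUE}.
#' @export
solve_delay_state <- function(pars, J_plus = NULL, gamma = 1L,
                              initial_guess = NULL, all_branches = FALSE,
                              tol = 1e-10, max_iter = 200L) {
  if (!is_calibrated(pars)) {
    stop("external currents not calibrated; run calibrate_external_currents() first",
         call. = FALSE)
  }
  if (!is.null(J_plus)) pars <- set_J_plus(pars, J_plus)
  sp <- c(sf = pars$nu_E_sp, sb = pars$nu_E_sp, ns = pars$nu_E_sp,
          inh = pars$nu_I_sp)
  starts <- if (!is.null(initial_guess)) {
    list(initial_guess)
  } else {
    list(sp,
         c(sf = 50, sb = 0.2, ns = 0.5, inh = 8),
         c(sf = 25, sb = 0.4, ns = 0.6, inh = 6))
  }
  sols <- list()
  for (s0 in starts) {
    fit <- newton_rates(s0, pars, "delay", gamma, tol, max_iter)
    if (!fit$converged) next
    dup <- any(vapply(sols, function(s) max(abs(s$rates - fit$rates)) < 1e-6,
                      logical(1)))
    if (!dup) sols[[length(sols) + 1]] <- fit
  }
  if (length(sols) == 0) {
    stop("delay-state solver did not converge from any start", call. = FALSE)
  }
  # unstable solution: Newton from midpoints between distinct branches
  if (is.null(initial_guess) && length(sols) >= 2) {
    for (i in seq_len(length(sols) - 1)) {
      mid <- (sols[[i]]$rates + sols[[i + 1]]$rates) / 2
      fit <- newton_rates(mid, pars, "delay", gamma, tol, max_iter)
      if (fit$converged &&
          !any(vapply(sols, function(s) max(abs(s$rates - fit$rates)) < 1e-6,
                      logical(1)))) {
        sols[[length(sols) + 1]] <- fit
      }
    }
  }
  tag <- function(fit) {
    stable <- classify_stability(fit$rates, pars, "delay", gamma)
    if (!stable) "unstable"
    else if (fit$rates[["sf"]] > 5 * pars$nu_E_sp) "memory"
    else "spontaneous"
  }
  out <- lapply(sols, function(fit) mf_solution(fit, pars, "delay", gamma,
                                                branch = tag(fit)))
  if (all_branches) return(out)
  branches <- vapply(out, function(s) s$branch, character(1))
  if ("memory" %in% branches) out[[which(branches == "memory")[1]]]
  else out[[which(branches == "spontaneous")[1]]]
}

#' Bifurcation scan of delay states along the potentiated efficacy
#'
#' Continuation along a grid of \code{J_plus} values: at each point the
#' delay-state system is solved reusing the previous memory solution as a
#' guess; stable spontaneous and memory branches and the intermediate
#' unstable branch are reported, along with the critical \code{J_plus}
#' (onset of the memory branch) refined by bisection on branch existence.
#'
#' @param pars a calibrated \code{wm_parameters} object.
#' @param J_plus_grid increasing grid of potentiation values (mV) spanning
#'   the critical point.
#' @param gamma foreground multiplicity.
#' @return an object of class \code{wm_bifurcation}: list with
#'   \code{branches} (data frame: J_plus, branch, nu_sf, nu_sb, nu_ns,
#'   nu_inh) and \code{critical_J_plus} (mV; \code{NA} if the memory branch
#'   exists nowhere on the grid).
#' @export
scan_bifurcation <- function(pars, J_plus_grid, gamma = 1L) {
  if (!is_calibrated(pars)) {
    stop("external currents not calibrated; run calibrate_external_currents() first",
         call. = FALSE)
  }
  J_plus_grid <- sort(J_plus_grid)
  rows <- list()
  memory_guess <- NULL
  has_memory <- logical(length(J_plus_grid))
  # descend from above so continuation tracks the memory branch down to its fold
  for (i in rev(seq_along(J_plus_grid))) {
    jp <- J_plus_grid[i]
    pj <- set_J_plus(pars, jp)
    sols <- tryCatch(
      solve_delay_state(pj, gamma = gamma, all_branches = TRUE),
      error = function(e) list())
    if (!is.null(memory_guess)) {
      extra <- tryCatch(
        newton_rates(memory_guess, pj, "delay", gamma),
        error = function(e) NULL)
      if (!is.null(extra) && extra$converged &&
          extra$rates[["sf"]] > 5 * pars$nu_E_sp &&
          !any(vapply(sols, function(s) max(abs(s$rates - extra$rates)) < 1e-6,
                      logical(1)))) {
        st <- classify_stability(extra$rates, pj, "delay", gamma)
        sols[[length(sols) + 1]] <- mf_solution(
          extra, pj, "delay", gamma, branch = if (st) "memory" else "unstable")
      }
    }
    for (s in sols) {
      if (s$branch == "memory") memory_guess <- s$rates
      rows[[length(rows) + 1]] <- data.frame(
        J_plus = jp, branch = s$branch,
        nu_sf = s$rates[["sf"]], nu_sb = s$rates[["sb"]],
        nu_ns = s$rates[["ns"]], nu_inh = s$rates[["inh"]])
    }
    has_memory[i] <- any(vapply(sols, function(s) s$branch == "memory",
                                logical(1)))
  }
  branches <- do.call(rbind, rows)
  branches <- branches[order(branches$J_plus, branches$branch), ]
  rownames(branches) <- NULL
  crit <- NA_real_
  if (any(has_memory)) {
    first <- which(has_memory)[1]
    if (first == 1) {
      crit <- J_plus_grid[1] # branch exists on whole grid; true onset below it
    } else {
      crit <- critical_J_plus(pars, J_plus_grid[first - 1], J_plus_grid[first],
                              gamma = gamma,
                              memory_guess = memory_guess)
    }
  }
  structure(list(branches = branches, critical_J_plus = crit,
                 J_plus_grid = J_plus_grid),
            class = "wm_bifurcation")
}

#' Locate the critical potentiation by bisection on memory-branch existence
#'
#' @param pars a calibrated \code{wm_parameters} object.
#' @param lo,hi bracketing potentiation values (mV): no memory branch at
#'   \code{lo}, memory branch at \code{hi}.
#' @param tol bisection tolerance (mV).
#' @param gamma foreground multiplicity.
#' @param memory_guess optional rate vector used as Newton start.
#' @return the critical \code{J_plus} (mV).
#' @export
critical_J_plus <- function(pars, lo, hi, tol = 1e-5, gamma = 1L,
                            memory_guess = NULL) {
  if (is.null(memory_guess)) {
    memory_guess <- c(sf = 40, sb = 0.3, ns = 0.6, inh = 6)
  }
  exists_memory <- function(jp) {
    pj <- set_J_plus(pars, jp)
    for (g in list(memory_guess, c(sf = 50, sb = 0.2, ns = 0.5, inh = 8),
                   c(sf = 25, sb = 0.4, ns = 0.6, inh = 6))) {
      fit <- newton_rates(g, pj, "delay", gamma)
      if (fit$converged && fit$rates[["sf"]] > 5 * pars$nu_E_sp &&
          classify_stability(fit$rates, pj, "delay", gamma)) {
        memory_guess <<- fit$rates
        return(TRUE)
      }
    }
    FALSE
  }
  if (exists_memory(lo)) return(lo)
  if (!exists_memory(hi)) stop("no memory branch at upper bracket", call. = FALSE)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (exists_memory(mid)) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}
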