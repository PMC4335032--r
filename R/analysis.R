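response_roles <- c("sample", "match", "nonmatch", "repeated-nonmatch",
                    "distractor")

#' Build the per-neuron response table of an experiment
#'
#' Aggregates, for every selective neuron and every stimulus, the mean spike
#' count in the first 200 ms of each presentation epoch, keyed by the
#' epoch's role (sample / match / nonmatch / repeated-nonmatch /
#' distractor), averaged across trials. Delay activity is recorded as the
#' mean rate over the final 200 ms of the delay that follows the sample,
#' keyed by the sample's identity.
#'
#' @param experiment a spiking \code{wm_experiment}.
#' @param window response window (s). Counts are collected at simulation
#'   time with a 200 ms window; requesting a different window requires
#'   trials recorded with \code{record_raster = TRUE}.
#' @return an object of class \code{wm_responses}: list with arrays
#'   \code{resp} and \code{n} \code{[neuron, stimulus, role]} (mean counts
#'   per window and trial tallies), matrix \code{delay} \code{[neuron,
#'   stimulus]} (Hz), \code{sel_pop} (representation of each neuron),
#'   \code{window}.
#' @export
count_responses <- function(experiment, window = 0.2) {
  stopifnot(inherits(experiment, "wm_experiment"),
            experiment$engine == "spiking")
  tr1 <- experiment$trials[[1]]
  n_sel <- nrow(tr1$counts)
  p <- tr1$p
  use_raster <- abs(window - 0.2) > 1e-12
  if (use_raster && is.null(tr1$raster)) {
    stop("window != 0.2 s requires trials recorded with record_raster = TRUE",
         call. = FALSE)
  }
  acc <- array(0, dim = c(n_sel, p, length(response_roles)),
               dimnames = list(NULL, NULL, response_roles))
  n <- acc
  delay_acc <- matrix(0, n_sel, p)
  delay_n <- matrix(0, n_sel, p)
  for (tr in experiment$trials) {
    max_stim <- max(stats::na.omit(tr$epochs$stimulus))
    if (any(tr$epochs$duration[!is.na(tr$epochs$stimulus)] < window - 1e-9)) {
      stop("response window exceeds a stimulus epoch", call. = FALSE)
    }
    for (e in seq_len(nrow(tr$epochs))) {
      s <- tr$epochs$stimulus[e]
      role <- tr$epochs$role[e]
      if (!is.na(s) && role %in% response_roles) {
        cts <- if (use_raster) {
          window_counts(tr$raster, seq_len(n_sel), tr$epochs$t_start[e],
                        tr$epochs$t_start[e] + window)
        } else tr$counts[, e]
        acc[, s, role] <- acc[, s, role] + cts
        n[, s, role] <- n[, s, role] + 1
      }
      if (role == "delay" && e >= 2 &&
          identical(tr$epochs$role[e - 1], "sample")) {
        delay_acc[, tr$epochs$stimulus[e - 1]] <-
          delay_acc[, tr$epochs$stimulus[e - 1]] + tr$delay_rates[, e]
        delay_n[, tr$epochs$stimulus[e - 1]] <-
          delay_n[, tr$epochs$stimulus[e - 1]] + 1
      }
    }
  }
  resp <- acc / ifelse(n > 0, n, NA)
  delay <- delay_acc / ifelse(delay_n > 0, delay_n, NA)
  structure(list(resp = resp, n = n, delay = delay, sel_pop = tr1$sel_pop,
                 window = window),
            class = "wm_responses")
}

#' Sparseness (selectivity) index of a response profile
#'
#' \eqn{A = (\sum_i \nu_i/n)^2 / (\sum_i \nu_i^2/n)} and
#' \eqn{S = (1 - A)/(1 - 1/n)}: 0 when the neuron responds identically to
#' all \code{n} stimuli, 1 when it responds to exactly one.
#'
#' @param rates non-negative response vector across the stimulus set (any
#'   common scale; the index is invariant under uniform rescaling).
#' @param n number of stimuli (defaults to \code{length(rates)}).
#' @return S in \code{[0, 1]}, or \code{NA} for an all-zero profile.
#' @export
sparseness_index <- function(rates, n = length(rates)) {
  if (n < 2) stop("sparseness needs at least 2 stimuli", call. = FALSE)
  if (any(rates < 0)) stop("rates must be non-negative", call. = FALSE)
  if (all(rates == 0)) return(NA_real_)
  A <- (sum(rates) / n)^2 / (sum(rates^2) / n)
  (1 - A) / (1 - 1 / n)
}

#' Sparseness of every neuron in a response table
#'
#' @param responses a \code{wm_responses} object.
#' @param role which epoch role to use.
#' @return numeric vector of per-neuron sparseness indices (NA where the
#'   neuron never responded).
#' @export
response_sparseness <- function(responses, role = "sample") {
  apply(responses$resp[, , role, drop = FALSE], 1, function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 2) NA_real_ else sparseness_index(v)
  })
}

#' Match-effect indices of a response table
#'
#' Ratios of population-averaged responses: the enhancement index is
#' match/sample over foreground pairs (neuron in the representation of the
#' presented stimulus), the suppression index is match/sample over
#' background pairs, and the match/non-match indices compare the match and
#' non-match responses of the test stimulus' representation (active) and of
#' the remaining representations (inactive).
#'
#' @param responses a \code{wm_responses} object.
#' @return list of class \code{wm_indices}: \code{enhancement},
#'   \code{suppression}, \code{match_nonmatch},
#'   \code{match_nonmatch_inactive}, and \code{per_representation} (data
#'   frame of per-representation match/non-match ratios, where measured).
#'   Ratios with a zero or missing denominator are \code{NA}.
#' @export
match_effect_indices <- function(responses) {
  stopifnot(inherits(responses, "wm_responses"))
  p <- ncol(responses$delay)
  fg <- outer(responses$sel_pop, seq_len(p), "==")
  ratio <- function(num, den) {
    num <- mean(num, na.rm = TRUE); den <- mean(den, na.rm = TRUE)
    if (!is.finite(den) || den == 0) NA_real_ else num / den
  }
  S <- responses$resp[, , "sample"]
  M <- responses$resp[, , "match"]
  NM <- responses$resp[, , "nonmatch"]
  per_rep <- data.frame(representation = seq_len(p), match_nonmatch = NA_real_)
  for (k in seq_len(p)) {
    per_rep$match_nonmatch[k] <- ratio(M[fg[, k], k], NM[fg[, k], k])
  }
  structure(list(
    enhancement = ratio(M[fg], S[fg]),
    suppression = ratio(M[!fg], S[!fg]),
    match_nonmatch = ratio(M[fg], NM[fg]),
    match_nonmatch_inactive = ratio(M[!fg], NM[!fg]),
    per_representation = per_rep
  ), class = "wm_indices")
}

#' Fraction of suppressed cell/stimulus combinations
#'
#' Classifies every (selective neuron, stimulus) pair by its trial-averaged
#' 200 ms spike counts: suppressed if the match response is strictly below
#' the sample response, enhanced if strictly above, tied otherwise. The
#' three fractions sum to one and are all reported.
#'
#' Tied pairs are overwhelmingly cells that fired in neither window: weakly
#' driven background cells whose response to the repetition, like their
#' sample response, is nil (the limiting case of complete adaptation).
#' \code{ties} controls the headline \code{fraction_suppressed}:
#' \code{"separate"} (default) counts only strict inequalities, so the
#' headline fraction grows with the number of trials as ties resolve;
#' \code{"suppressed"} counts every non-enhanced pair, the convention under
#' which the suppressed fraction is the complement of the enhanced one and
#' is stable in the trial count (about 5/6 at the standard parameters,
#' where one representation in six is enhanced).
#'
#' @param responses a \code{wm_responses} object with sample and match
#'   responses for every pair.
#' @param ties \code{"separate"} or \code{"suppressed"} (see Details).
#' @return list with \code{fraction_suppressed}, \code{fraction_enhanced},
#'   \code{fraction_tied} and \code{n_pairs}; \code{fraction_tied} is
#'   always the raw tie fraction.
#' @export
fraction_suppressed <- function(responses, ties = c("separate", "suppressed")) {
  ties <- match.arg(ties)
  S <- responses$resp[, , "sample"]
  M <- responses$resp[, , "match"]
  ok <- !is.na(S) & !is.na(M)
  if (!any(ok)) stop("no cell/stimulus pairs with sample and match responses",
                     call. = FALSE)
  n_pairs <- sum(ok)
  strict <- sum(M[ok] < S[ok]) / n_pairs
  tied <- sum(M[ok] == S[ok]) / n_pairs
  list(fraction_suppressed = if (ties == "suppressed") strict + tied
                             else strict,
       fraction_enhanced = sum(M[ok] > S[ok]) / n_pairs,
       fraction_tied = tied,
       n_pairs = n_pairs)
}

#' Ranked single-neuron tuning curves
#'
#' For each neuron, stimuli are ranked from best to worst by the sample
#' response (ties broken by stimulus id); every other epoch role and the
#' delay activity are re-indexed by that ranking, exposing the sharpening
#' of tuning upon repetition.
#'
#' @param responses a \code{wm_responses} object.
#' @param roles epoch roles to include.
#' @return list with \code{curves}, an array \code{[neuron, rank, role]}
#'   (the \code{"delay"} layer holds delay rates), and \code{ranking}, the
#'   \code{[neuron, rank]} matrix of stimulus ids.
#' @export
tuning_curves <- function(responses, roles = c("sample", "match")) {
  S <- responses$resp[, , "sample"]
  p <- ncol(S)
  if (p < 2) stop("tuning curves need at least 2 stimuli", call. = FALSE)
  n_sel <- nrow(S)
  ranking <- t(apply(S, 1, function(v) order(-v, seq_along(v))))
  layers <- c(roles, "delay")
  curves <- array(NA_real_, c(n_sel, p, length(layers)),
                  dimnames = list(NULL, NULL, layers))
  for (i in seq_len(n_sel)) {
    for (r in roles) curves[i, , r] <- responses$resp[i, ranking[i, ], r]
    curves[i, , "delay"] <- responses$delay[i, ranking[i, ]]
  }
  list(curves = curves, ranking = ranking)
}

#' Mean correlation between epoch responses and delay activity
#'
#' For each selective neuron, the Pearson correlation across the stimulus
#' set between its responses in a presentation epoch (sample or match) and
#' its delay-period activity, averaged across neurons. Neurons with fewer
#' than 3 stimuli measured in both epochs, or with zero variance in either
#' vector, are excluded and counted.
#'
#' @param responses a \code{wm_responses} object.
#' @param role epoch role correlated against delay activity.
#' @return list with \code{mean_r}, \code{n_neurons} (used) and
#'   \code{n_excluded}.
#' @export
sample_delay_correlation <- function(responses, role = "sample") {
  R <- responses$resp[, , role]
  D <- responses$delay
  rs <- rep(NA_real_, nrow(R))
  for (i in seq_len(nrow(R))) {
    ok <- !is.na(R[i, ]) & !is.na(D[i, ])
    if (sum(ok) < 3) next
    if (stats::sd(R[i, ok]) == 0 || stats::sd(D[i, ok]) == 0) next
    rs[i] <- stats::cor(R[i, ok], D[i, ok])
  }
  list(mean_r = mean(rs, na.rm = TRUE), n_neurons = sum(!is.na(rs)),
       n_excluded = sum(is.na(rs)))
}

#' Correlation structure across input-heterogeneity levels
#'
#' Runs a match experiment (all stimuli) at each requested stimulus-input
#' SD \code{sigma_s}, redrawing the quenched selective currents, and
#' reports the mean sample-delay and match-delay correlations. Increasing
#' heterogeneity decorrelates the sensory from the mnemonic representation,
#' and does so faster for the sample than for the match response.
#'
#' @param pars a calibrated \code{wm_parameters} object.
#' @param sigma_s_values vector of stimulus-input SDs (mV).
#' @param alpha,beta stimulus means (mV).
#' @param n_trials match trials per stimulus.
#' @param quenched_seed,noise_seed RNG seeds.
#' @return data frame with columns \code{sigma_s}, \code{r_sample_delay},
#'   \code{r_match_delay}, \code{n_neurons}.
#' @export
heterogeneity_correlations <- function(pars, sigma_s_values = c(2, 3, 4),
                                       alpha = 1.5, beta = 1.8,
                                       n_trials = 1L, quenched_seed = 101L,
                                       noise_seed = 1L) {
  rows <- lapply(sigma_s_values, function(ss) {
    stim <- stimulus_parameters(alpha = alpha, beta = beta, sigma_S = ss,
                                n_stimuli = pars$p)
    inputs <- draw_quenched_inputs(pars, stim, seed = quenched_seed)
    protos <- lapply(seq_len(pars$p), function(s)
      build_protocol("match", sample = s))
    exper <- run_experiment(pars, inputs, protos, n_trials = n_trials,
                            engine = "spiking", seed = noise_seed)
    rt <- count_responses(exper)
    cs <- sample_delay_correlation(rt, "sample")
    cm <- sample_delay_correlation(rt, "match")
    data.frame(sigma_s = ss, r_sample_delay = cs$mean_r,
               r_match_delay = cm$mean_r, n_neurons = cs$n_neurons)
  })
  do.call(rbind, rows)
}

#' Distractor-count dependence of match suppression
#'
#' For experiments with 0, 1 and 2 intervening distractors, averages the
#' test-epoch responses of the suppressed populations (selective neurons
#' outside the test stimulus' representation) separately for match and
#' non-match endings. In the regime where distractors occasionally disrupt
#' the sample memory, the match and non-match responses converge as the
#' number of distractors grows, i.e. suppression wanes.
#'
#' @param experiment a spiking \code{wm_experiment} whose protocols are
#'   \code{distractors} variants covering \code{n_distractors} 0, 1 and 2
#'   with both match and non-match tests.
#' @param only_survived restrict to trials whose final delay still held the
#'   sample memory (control: suppression then no longer wanes with the
#'   distractor count).
#' @return data frame: \code{n_distractors}, \code{condition},
#'   \code{mean_hz}, \code{sem_hz}, \code{n_trials}; plus the suppression
#'   magnitude (non-match minus match mean, Hz) as attribute
#'   \code{"suppression"} (one value per distractor count).
#' @export
distractor_decay <- function(experiment, only_survived = FALSE) {
  stopifnot(experiment$engine == "spiking")
  rows <- list()
  for (tr in experiment$trials) {
    last <- nrow(tr$epochs)
    cond <- tr$epochs$role[last]
    if (!cond %in% c("match", "nonmatch")) next
    nd <- sum(tr$epochs$role == "distractor")
    if (only_survived) {
      delays <- which(tr$epochs$role == "delay")
      if (!isTRUE(tr$survival[delays[length(delays)]])) next
    }
    test_stim <- tr$epochs$stimulus[last]
    suppressed <- tr$sel_pop != test_stim
    rows[[length(rows) + 1]] <- data.frame(
      n_distractors = nd, condition = cond,
      mean_hz = mean(tr$counts[suppressed, last]) / 0.2)
  }
  df <- do.call(rbind, rows)
  needed <- 0:2
  if (!all(needed %in% df$n_distractors)) {
    stop("experiments must cover 0, 1 and 2 distractors", call. = FALSE)
  }
  agg <- do.call(rbind, lapply(split(df, df[c("condition", "n_distractors")]),
    function(g) data.frame(
      n_distractors = g$n_distractors[1], condition = g$condition[1],
      mean_hz = mean(g$mean_hz),
      sem_hz = stats::sd(g$mean_hz) / sqrt(nrow(g)), n_trials = nrow(g))))
  rownames(agg) <- NULL
  agg <- agg[order(agg$n_distractors, agg$condition), ]
  supp <- vapply(needed, function(nd) {
    agg$mean_hz[agg$n_distractors == nd & agg$condition == "nonmatch"] -
      agg$mean_hz[agg$n_distractors == nd & agg$condition == "match"]
  }, numeric(1))
  attr(agg, "suppression") <- stats::setNames(supp, paste0("n", needed))
  agg
}

#' ABBA repeating-distractor response pattern
#'
#' Averages, across trials and stimuli of an ABBA experiment, the responses
#' of the enhancement population (the sample's representation) and the
#' suppression population (the other representations) at sample, non-match,
#' repeated non-match and match presentations.
#'
#' @param responses a \code{wm_responses} object built from ABBA trials.
#' @return data frame: \code{population} (enhancement / suppression),
#'   \code{role}, \code{mean_hz}.
#' @export
abba_pattern <- function(responses) {
  p <- ncol(responses$delay)
  fg <- outer(responses$sel_pop, seq_len(p), "==")
  roles <- c("sample", "nonmatch", "repeated-nonmatch", "match")
  rows <- list()
  for (r in roles) {
    R <- responses$resp[, , r]
    rows[[length(rows) + 1]] <- data.frame(
      population = c("enhancement", "suppression"), role = r,
      mean_hz = c(mean(R[fg], na.rm = TRUE),
                  mean(R[!fg], na.rm = TRUE)) / responses$window)
  }
  do.call(rbind, rows)
}
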