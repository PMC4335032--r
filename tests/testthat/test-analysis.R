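test_that("sparseness index: exact cases and invariances", {
  expect_equal(sparseness_index(rep(3.2, 6)), 0)          # uniform
  expect_equal(sparseness_index(c(9, 0, 0, 0, 0, 0)), 1)  # one-hot
  # direct formula evaluation: nu = (10,5,1,0,0,0), n = 6
  nu <- c(10, 5, 1, 0, 0, 0)
  A <- (sum(nu) / 6)^2 / (sum(nu^2) / 6)
  expect_equal(sparseness_index(nu), (1 - A) / (1 - 1 / 6))
  expect_equal(sparseness_index(nu), 0.7936508, tolerance = 1e-6)
  # scale-free
  expect_equal(sparseness_index(nu * 17.3), sparseness_index(nu))
  expect_true(is.na(sparseness_index(rep(0, 6))))
  expect_error(sparseness_index(5), "stimuli")
  expect_error(sparseness_index(c(-1, 2)), "non-negative")
})

test_that("suppressed fraction counts strict inequalities and partitions", {
  # 4 cells x 2 stimuli, exactly 3 of 8 pairs suppressed, 1 tied
  S <- matrix(c(5, 5, 5, 5,
                5, 5, 5, 5), nrow = 4)
  M <- matrix(c(4, 4, 4, 6,
                6, 6, 6, 5), nrow = 4)
  rt <- make_responses(S, match = M)
  fs <- fraction_suppressed(rt)
  expect_equal(fs$fraction_suppressed, 3 / 8)
  expect_equal(fs$fraction_enhanced, 4 / 8)
  expect_equal(fs$fraction_tied, 1 / 8)
  expect_equal(fs$fraction_suppressed + fs$fraction_enhanced +
                 fs$fraction_tied, 1)
  # all suppressed
  rt2 <- make_responses(S, match = S - 1)
  expect_equal(fraction_suppressed(rt2)$fraction_suppressed, 1)
})

test_that("match-effect indices from synthetic counts", {
  # 2 representations x 2 neurons each; foreground M/S = 2, background M/S = 0.5
  sel_pop <- c(1L, 1L, 2L, 2L)
  S <- matrix(10, 4, 2)
  M <- matrix(5, 4, 2)
  M[cbind(1:4, sel_pop)] <- 20
  rt <- make_responses(S, match = M, sel_pop = sel_pop)
  idx <- match_effect_indices(rt)
  expect_equal(idx$enhancement, 2.0)
  expect_equal(idx$suppression, 0.5)
  # missing non-match data flagged as NA, not an error
  expect_true(is.na(idx$match_nonmatch))
})

test_that("tuning curves: ranking, ties and permutation invariance", {
  S <- rbind(c(6, 5, 4, 3), c(1, 1, 8, 2))  # row 2 has a tie at stimuli 1,2
  M <- rbind(c(60, 50, 40, 30), c(10, 11, 80, 20))
  rt <- make_responses(S, match = M, sel_pop = c(1L, 2L))
  tc <- tuning_curves(rt)
  expect_equal(tc$ranking[1, ], 1:4)                 # monotone -> identity
  expect_equal(tc$ranking[2, ], c(3L, 4L, 1L, 2L))   # tie broken by id
  expect_equal(tc$curves[1, , "match"], c(60, 50, 40, 30))
  # permuting the stimulus axis leaves ranked curves unchanged
  perm <- c(3, 1, 4, 2)
  rt_p <- make_responses(S[, perm], match = M[, perm], sel_pop = c(1L, 2L))
  tc_p <- tuning_curves(rt_p)
  expect_equal(tc_p$curves[, , "sample"], tc$curves[, , "sample"])
  expect_equal(tc_p$curves[, , "match"], tc$curves[, , "match"])
})

test_that("sample-delay correlation equals the covariance formula", {
  S <- rbind(c(2, 4, 6, 8), c(1, 3, 2, 5))
  D <- rbind(c(2, 4, 6, 8), c(5, 1, 4, 2))
  rt <- make_responses(S, delay = D, sel_pop = c(1L, 2L))
  out <- sample_delay_correlation(rt)
  # brute-force Pearson for each neuron
  r_manual <- function(x, y) {
    mean((x - mean(x)) * (y - mean(y))) /
      sqrt(mean((x - mean(x))^2) * mean((y - mean(y))^2))
  }
  expect_equal(out$mean_r,
               mean(c(r_manual(S[1, ], D[1, ]), r_manual(S[2, ], D[2, ]))))
  expect_equal(r_manual(S[1, ], D[1, ]), 1)  # identical vectors
  # zero-variance neurons are excluded and counted
  S2 <- rbind(S, c(3, 3, 3, 3))
  D2 <- rbind(D, c(1, 2, 3, 4))
  rt2 <- make_responses(S2, delay = D2, sel_pop = c(1L, 2L, 1L))
  out2 <- sample_delay_correlation(rt2)
  expect_equal(out2$n_excluded, 1)
  expect_equal(out2$mean_r, out$mean_r)
})

test_that("response tables aggregate spiking trials correctly", {
  pars <- fix_pars()
  inputs <- draw_quenched_inputs(pars, stimulus_parameters(), seed = 12)
  protos <- list(build_protocol("match", sample = 1),
                 build_protocol("nonmatch", sample = 1, foil = 2))
  ex <- run_experiment(pars, inputs, protos, n_trials = 2, seed = 9)
  rt <- count_responses(ex)
  expect_equal(dim(rt$resp)[1], pars$N_E_sel)
  # sample responses to stimulus 1 come from 4 trials, match from 2
  expect_true(all(rt$n[, 1, "sample"] == 4))
  expect_true(all(rt$n[, 1, "match"] == 2))
  expect_true(all(rt$n[, 2, "nonmatch"] == 2))
  expect_true(all(is.na(rt$resp[, 3, "sample"])))
  # manual re-aggregation of one neuron's sample response
  manual <- mean(vapply(ex$trials, function(tr) tr$counts[7, 2], numeric(1)))
  expect_equal(as.numeric(rt$resp[7, 1, "sample"]), manual)
  # delay activity keyed by the sample stimulus
  expect_false(any(is.na(rt$delay[, 1])))
  expect_true(all(is.na(rt$delay[, 3])))
})

test_that("distractor-decay requires all distractor counts and respects filtering", {
  # synthetic experiment: 2 representations x 2 neurons, counts crafted so
  # suppression (nonmatch - match of non-test representations) shrinks with n
  fake_trial <- function(nd, cond, survived, supp_level) {
    roles <- c("pre", "sample", "delay",
               rep(c("distractor", "delay"), nd), cond)
    stimulus <- c(NA, 1L, NA, rep(c(2L, NA), nd),
                  if (cond == "match") 1L else 3L)
    epochs <- data.frame(role = roles, stimulus = stimulus,
                         duration = c(1, rep(0.5, length(roles) - 1)))
    epochs$t_end <- cumsum(epochs$duration)
    epochs$t_start <- epochs$t_end - epochs$duration
    counts <- matrix(NA_real_, 6, nrow(epochs))
    test_col <- nrow(epochs)
    base <- if (cond == "match") 10 - supp_level else 10
    counts[, test_col] <- base
    survival <- rep(NA, nrow(epochs))
    survival[epochs$role == "delay"] <- survived
    structure(list(protocol = list(kind = "distractors", sample = 1L),
                   epochs = epochs, counts = counts,
                   delay_rates = matrix(NA_real_, 6, nrow(epochs)),
                   survival = survival, p = 3L,
                   sel_pop = rep(1:3, each = 2), engine = "spiking"),
              class = "wm_trial")
  }
  trials <- list()
  for (nd in 0:2) for (cond in c("match", "nonmatch")) {
    supp <- 4 - nd                    # suppression wanes with distractors
    trials[[length(trials) + 1]] <- fake_trial(nd, cond, TRUE, supp)
    trials[[length(trials) + 1]] <- fake_trial(nd, cond, TRUE, supp)
  }
  ex <- structure(list(trials = trials, engine = "spiking"),
                  class = "wm_experiment")
  dd <- distractor_decay(ex)
  supp <- attr(dd, "suppression")
  expect_equal(unname(supp), c(4, 3, 2) / 0.2)
  expect_true(all(diff(supp) <= 0))
  # missing level is an argument error
  ex_partial <- structure(list(trials = trials[1:4], engine = "spiking"),
                          class = "wm_experiment")
  expect_error(distractor_decay(ex_partial), "distractors")
  # survival-filtered control: force identical suppression at every n
  trials2 <- list()
  for (nd in 0:2) for (cond in c("match", "nonmatch")) {
    trials2[[length(trials2) + 1]] <- fake_trial(nd, cond, TRUE, 4)
  }
  ex2 <- structure(list(trials = trials2, engine = "spiking"),
                   class = "wm_experiment")
  s2 <- attr(distractor_decay(ex2, only_survived = TRUE), "suppression")
  expect_equal(unname(s2), rep(20, 3))
})
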