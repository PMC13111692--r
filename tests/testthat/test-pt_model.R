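test_that("utility has the stated closed forms and loss/gain ratio", {
  expect_equal(pt_utility(2, pt_params(rho_plus = 0.5)), sqrt(2))
  expect_equal(pt_utility(-2, pt_params(rho_minus = -0.5, lam = 2)),
               -2 * sqrt(2))
  expect_equal(pt_utility(0, REF_PARAMS), 0)
  # at unit outcome, |u(-1)| / u(1) = lam irrespective of the curvatures
  for (rp in c(-0.5, 0, 0.5)) {
    p <- pt_params(rho_plus = rp, rho_minus = -rp, lam = 2.987)
    expect_equal(abs(pt_utility(-1, p)) / pt_utility(1, p), 2.987)
  }
})

test_that("utility is sign-preserving and increasing in x", {
  x <- c(-3, -2, -1, 1, 2, 3)
  for (p in list(neutral_params(), REF_PARAMS,
                 pt_params(rho_plus = 0.9, rho_minus = 0.9, lam = 10))) {
    u <- pt_utility(x, p)
    expect_equal(sign(u), sign(x))
    expect_true(all(diff(u) > 0))
  }
})

test_that("Prelec weighting has its fixed points and monotonicity", {
  for (a in c(0.3, 0.655, 1, 1.208, 3)) {
    expect_equal(prelec_weight(1, a), 1)
    expect_equal(prelec_weight(exp(-1), a), exp(-1))
    grid <- seq(0.01, 1, by = 0.01)
    expect_true(all(diff(prelec_weight(grid, a)) > 0))
  }
  expect_equal(prelec_weight(0.25, 1), 0.25)
  expect_error(prelec_weight(0, 1), "\\(0, 1\\]")
  expect_error(prelec_weight(0.5, -1), "alpha")
})

test_that("weighting crosses the identity only at exp(-1) and 1", {
  grid <- seq(0.02, 0.98, by = 0.005)
  for (a in c(0.5, 0.7, 1.5, 2.5)) {
    d <- prelec_weight(grid, a) - grid
    # sign flips exactly once strictly inside (0, 1), at exp(-1)
    flips <- which(diff(sign(d)) != 0)
    expect_length(flips, 1L)
    expect_lt(abs(grid[flips] - exp(-1)), 0.01)
  }
})

test_that("subjective expected value reduces to EV at neutral parameters", {
  np <- neutral_params()
  expect_equal(pt_sev(1, 1, np), 1.0)
  expect_equal(pt_sev(2, 0.25, np), expected_value(2, 0.25))
  expect_equal(pt_sev(FULL_BATTERY$left_outcome, FULL_BATTERY$left_prob, np),
               expected_value(FULL_BATTERY$left_outcome, FULL_BATTERY$left_prob))
  expect_equal(pt_sev(-3, 0.5, pt_params(lam = 3)), -4.5)
})

test_that("sev uses the weighting exponent of the outcome's domain", {
  p <- pt_params(alpha_plus = 2, alpha_minus = 0.5)
  expect_equal(pt_sev(2, 0.25, p), prelec_weight(0.25, 2) * pt_utility(2, p))
  expect_equal(pt_sev(-2, 0.25, p),
               prelec_weight(0.25, 0.5) * pt_utility(-2, p))
})

test_that("choice rule is a symmetric sigmoid in the SEV difference", {
  same <- data.frame(left_outcome = 2, left_prob = 0.5,
                     right_outcome = 2, right_prob = 0.5)
  expect_equal(choice_prob_right(same, neutral_params()), 0.5)
  # identical lotteries: P(right) = plogis(x0) whatever the other params
  p_bias <- pt_params(rho_plus = 0.4, lam = 3, mu = 7, x0 = 1.2)
  expect_equal(choice_prob_right(same, p_bias), plogis(1.2))
  # equal-EV tradeoff at neutral parameters
  eq_ev <- data.frame(left_outcome = 1, left_prob = 0.5,
                      right_outcome = 2, right_prob = 0.25)
  expect_equal(choice_prob_right(eq_ev, neutral_params(mu = 5)), 0.5)
})

test_that("P(right) increases in the SEV difference and x0 shifts it up", {
  pairs <- data.frame(left_outcome = 1, left_prob = 0.5,
                      right_outcome = c(1, 2, 3), right_prob = 0.5)
  pr <- choice_prob_right(pairs, neutral_params(mu = 2))
  expect_true(all(diff(pr) > 0))
  pr_bias <- choice_prob_right(pairs, neutral_params(mu = 2, x0 = 0.8))
  expect_true(all(pr_bias > pr))
})

test_that("left/right swap with negated bias gives complementary probabilities", {
  bat <- FULL_BATTERY
  swapped <- data.frame(left_outcome = bat$right_outcome,
                        left_prob = bat$right_prob,
                        right_outcome = bat$left_outcome,
                        right_prob = bat$left_prob)
  p1 <- choice_prob_right(bat, REF_PARAMS)
  neg <- REF_PARAMS; neg[["x0"]] <- -neg[["x0"]]
  p2 <- choice_prob_right(swapped, neg)
  expect_equal(p1 + p2, rep(1, nrow(bat)))
})

test_that("negative log-likelihood matches closed forms and is additive", {
  tr1 <- make_trials(1, 0.5, 1, 0.5, "right")
  expect_equal(pt_nll(tr1, neutral_params()), log(2))
  trn <- make_trials(rep(1, 7), 0.5, rep(1, 7), 0.5,
                     rep(c("right", "left"), length.out = 7))
  expect_equal(pt_nll(trn, neutral_params()), 7 * log(2))
  expect_error(pt_nll(trn[0, ], neutral_params()), "empty")
})

test_that("the likelihood is maximised near the generating parameters", {
  tr <- simulate_choices(REF_PARAMS, FULL_BATTERY, 5000, seed = 31)
  nll_true <- pt_nll(tr, REF_PARAMS)
  for (nm in ptrank:::PT_PARAM_NAMES) {
    pert <- unclass(REF_PARAMS)
    pert[nm] <- pert[nm] + 0.3
    pert <- do.call(pt_params, as.list(pert))
    expect_gt(pt_nll(tr, pert), nll_true)
  }
})

test_that("likelihood evaluation is overflow-safe at extreme steepness", {
  tr <- make_trials(c(1, -3), c(0.5, 1), c(3, -1), c(0.5, 1),
                    c("left", "right"))
  v <- pt_nll(tr, pt_params(lam = 15, mu = 25, x0 = 10))
  expect_true(is.finite(v) && v >= 0)
  # floored choice probabilities cap the per-trial cost at -log(1e-12)
  expect_lte(v, 2 * -log(1e-12))
})

test_that("parameter validation rejects inadmissible values", {
  expect_error(pt_params(lam = 0), "lam")
  expect_error(pt_params(alpha_plus = -1), "alpha")
  expect_error(pt_params(rho_plus = 1), "rho_plus")
  expect_error(pt_params(rho_minus = -1), "rho_minus")
  expect_error(pt_params(mu = -2), "mu")
  expect_error(as_pt_params(list(rho_plus = 0.1)), "fields")
  rt <- pt_params_from_list(pt_params_to_list(REF_PARAMS))
  expect_equal(unclass(rt), unclass(REF_PARAMS))
})
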