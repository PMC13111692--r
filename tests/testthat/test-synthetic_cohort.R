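# Small cohorts keep these structural checks fast; the full-scale
# end-to-end recovery lives in test-acceptance.R.

small_config <- function(seed = 33, ...) {
  cohort_config(n_individuals = 6, n_males = 3, months = 6,
                trials_per_individual = 600, chunk_size = 200,
                events_per_day = 8, seed = seed, ...)
}

test_that("the generator emits consistent logs for every individual", {
  coh <- generate_cohort(small_config())
  ids <- coh$metadata$individual_id
  expect_length(ids, 6L)
  expect_setequal(unique(coh$trials$individual_id), ids)
  expect_setequal(unique(coh$truth_chunks$individual_id), ids)
  expect_true(all(c(coh$events$winner_id, coh$events$loser_id) %in% ids))
  expect_equal(nrow(coh$trials), 6 * 600)
  expect_equal(nrow(coh$truth_chunks), 6 * 3)
  # trials are chronologically indexed per individual
  for (id in ids) {
    sub <- coh$trials[coh$trials$individual_id == id, ]
    expect_equal(sub$trial_index, seq_len(nrow(sub)))
    expect_true(!is.unsorted(sub$timestamp))
  }
  # default scale: 18 individuals in every output
  def <- cohort_config()
  expect_equal(def$n_individuals, 18)
  expect_equal(def$trials_per_individual, 75000)
  expect_equal(def$months, 40)
})

test_that("generation is bitwise reproducible under the config seed", {
  c1 <- generate_cohort(small_config())
  c2 <- generate_cohort(small_config())
  expect_identical(c1$trials, c2$trials)
  expect_identical(c1$events, c2$events)
  expect_identical(c1$truth_chunks, c2$truth_chunks)
  c3 <- generate_cohort(small_config(seed = 34))
  expect_false(identical(c1$trials, c3$trials))
})

test_that("without rank link and jitter all chunks share the base parameters", {
  zero <- c(rho_plus = 0, rho_minus = 0, log_lam = 0,
            log_alpha_plus = 0, log_alpha_minus = 0)
  coh <- generate_cohort(small_config(rank_link = zero,
                                      chunk_jitter_sds = zero))
  tc <- merge(coh$truth_chunks, coh$truth_individuals,
              by = "individual_id", suffixes = c("", "_base"))
  expect_equal(tc$rho_plus, pmin(pmax(tc$rho_plus_base, -0.9), 0.9))
  expect_equal(tc$lam, pmin(pmax(exp(tc$log_lam), 0.1), 12))
  # per individual, every chunk identical
  spread <- tapply(tc$rho_plus, tc$individual_id, function(v) diff(range(v)))
  expect_true(all(spread == 0))
})

test_that("the conflict model produces the COP U-shape over rank", {
  coh <- generate_cohort(cohort_config(
    n_individuals = 12, n_males = 6, months = 12,
    trials_per_individual = 1500, chunk_size = 500,
    events_per_day = 10, seed = 41))
  tc <- coh$truth_chunks
  m <- lm(cop ~ elo_z_true + I(elo_z_true^2), data = tc)
  co <- summary(m)$coefficients["I(elo_z_true^2)", ]
  expect_gt(co["Estimate"], 0)
  expect_lt(co["Pr(>|t|)"], 0.001)
})

test_that("the rank link writes the configured quadratic structure into the truth", {
  # base parameters nearly homogeneous so the plain regression isolates
  # the link structure
  coh <- generate_cohort(cohort_config(
    n_individuals = 12, n_males = 6, months = 12,
    trials_per_individual = 5000, chunk_size = 500,
    events_per_day = 10, seed = 42,
    base_sds = c(rho_plus = 0.05, rho_minus = 0.05, log_lam = 0.05,
                 log_alpha_plus = 0.05, log_alpha_minus = 0.05,
                 mu = 0.5, x0 = 0.1)))
  tc <- coh$truth_chunks
  m_gain <- lm(rho_plus ~ elo_z_true + I(elo_z_true^2), data = tc)
  expect_gt(coef(m_gain)[["I(elo_z_true^2)"]], 0)
  expect_lt(summary(m_gain)$coefficients["I(elo_z_true^2)", "Pr(>|t|)"],
            0.01)
  # no loss-domain link by default
  m_loss <- lm(rho_minus ~ elo_z_true + I(elo_z_true^2), data = tc)
  expect_gt(summary(m_loss)$coefficients["I(elo_z_true^2)", "Pr(>|t|)"],
            0.01)
})

test_that("pathology injection is controlled and bounded", {
  coh <- generate_cohort(small_config())
  expect_identical(inject_pathologies(coh$trials, character(0)), coh$trials)
  expect_error(inject_pathologies(coh$trials, "id01", rate = 0.4), "rate")
  expect_error(inject_pathologies(coh$trials, "id01", rate = 1.1), "rate")
  full <- inject_pathologies(coh$trials, c("id01", "id02"), rate = 1,
                             side = "right", seed = 2)
  expect_true(all(full$choice[full$individual_id %in% c("id01", "id02")]
                  == "right"))
  expect_identical(full$choice[full$individual_id == "id03"],
                   coh$trials$choice[coh$trials$individual_id == "id03"])
  # rate 0.75 leaves roughly a quarter of choices on the minority side
  part <- inject_pathologies(coh$trials, "id01", rate = 0.75,
                             side = "left", seed = 3)
  frac <- mean(part$choice[part$individual_id == "id01"] == "left")
  expect_gt(binom.test(round(frac * 600), 600, 0.75)$p.value, 0.001)
})

test_that("one-sided individuals are excluded by the filtering stages", {
  coh <- generate_cohort(cohort_config(
    n_individuals = 8, n_males = 4, months = 8,
    trials_per_individual = 2000, chunk_size = 400,
    events_per_day = 8, seed = 44))
  bad <- c("id01", "id02")
  trials <- inject_pathologies(coh$trials, bad, rate = 1, seed = 4)
  fits <- fit_chunks(trials, fit_config(seed = 5, n_multistart = 2),
                     chunk_size = 400)
  filt <- iqr_filter(fits)
  ex <- exclude_individuals(filt$retained, min_chunks = 3,
                            roster = coh$metadata$individual_id)
  expect_true(all(bad %in% ex$excluded))
  expect_false(any(bad %in% ex$roster))
})
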