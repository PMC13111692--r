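# Shared fixtures, built in code at test time.

FULL_BATTERY <- generate_battery()

neutral_params <- function(mu = 1, x0 = 0) {
  pt_params(rho_plus = 0, rho_minus = 0, lam = 1,
            alpha_plus = 1, alpha_minus = 1, mu = mu, x0 = x0)
}

# A moderately non-neutral agent used across tests.
REF_PARAMS <- pt_params(rho_plus = 0.3, rho_minus = -0.4, lam = 2.5,
                        alpha_plus = 1.2, alpha_minus = 0.7, mu = 4,
                        x0 = 0.3)

# Minimal trial data.frame from explicit lottery columns and choices.
make_trials <- function(left_outcome, left_prob, right_outcome, right_prob,
                        choice, individual_id = "m1") {
  n <- max(length(left_outcome), length(choice))
  df <- data.frame(
    individual_id = individual_id,
    timestamp = as.POSIXct("2020-02-01", tz = "UTC") + seq_len(n) * 60,
    trial_index = seq_len(n),
    left_outcome = left_outcome, left_prob = left_prob,
    right_outcome = right_outcome, right_prob = right_prob,
    choice = choice)
  cls <- ptrank:::classify_pairs(df)
  df$condition <- cls$condition
  df$domain <- cls$domain
  df
}

# Displacement events at day offsets from a fixed origin.
make_events <- function(winner_id, loser_id, day = seq_along(winner_id)) {
  data.frame(
    timestamp = as.POSIXct("2020-02-01 12:00:00", tz = "UTC") + day * 86400,
    winner_id = winner_id, loser_id = loser_id)
}

# Small analysis-table design for LMM simulations: `n_ind` individuals with
# `n_chunks` rows each, Elo z-scores spread over a fixed range per
# individual plus within-individual drift.
make_lmm_design <- function(n_ind = 18, n_chunks = 12, seed = 1) {
  ptrank:::with_seed(seed, {
    ind <- sprintf("id%02d", seq_len(n_ind))
    base <- rnorm(n_ind)
    rows <- expand.grid(individual_id = ind,
                        chunk_index = seq_len(n_chunks),
                        KEEP.OUT.ATTRS = FALSE,
                        stringsAsFactors = FALSE)
    rows <- rows[order(rows$individual_id, rows$chunk_index), ]
    elo <- base[match(rows$individual_id, ind)] +
      0.3 * rnorm(nrow(rows))
    rows$elo_z <- as.numeric(scale(elo))
    rows$experience_z <- as.numeric(scale(rows$chunk_index))
    rows$age_category <- factor(
      sample(c("adult", "subadult", "juvenile"), n_ind, replace = TRUE,
             prob = c(0.6, 0.25, 0.15))[match(rows$individual_id, ind)],
      levels = c("adult", "subadult", "juvenile"))
    rows$sex <- factor(
      sample(c("male", "female"), n_ind, replace = TRUE)[
        match(rows$individual_id, ind)],
      levels = c("male", "female"))
    rownames(rows) <- NULL
    rows
  })
}
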