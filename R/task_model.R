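# Lottery representation, the task's lottery battery, and forward simulation
# of agent choices.
#
# A lottery is a pair (outcome, probability): `outcome` tokens (a non-zero
# integer between -3 and +3) are delivered with probability `probability`
# (one of 0.25, 0.50, 0.75, 1.00); the complementary event delivers zero
# tokens. A trial presents two lotteries side by side on a touchscreen and
# records which side the animal chose.

TOKEN_OUTCOMES <- 1:3
TOKEN_PROBS <- c(0.25, 0.50, 0.75, 1.00)
TRIAL_LOG_COLUMNS <- c("individual_id", "timestamp", "trial_index",
                       "left_outcome", "left_prob", "right_outcome",
                       "right_prob", "choice", "condition", "domain")

validate_lottery <- function(outcome, probability) {
  if (any(!is.finite(outcome)) || any(outcome == 0))
    stop("lottery outcomes must be finite and non-zero", call. = FALSE)
  if (any(!is.finite(probability)) || any(probability <= 0) || any(probability > 1))
    stop("lottery probabilities must lie in (0, 1]", call. = FALSE)
  invisible(NULL)
}

#' Expected value of a lottery
#'
#' The objective (risk-neutral) value of a lottery delivering `outcome`
#' tokens with probability `probability` and zero tokens otherwise, i.e.
#' `probability * outcome`. Vectorised over both arguments.
#'
#' @param outcome Non-zero token outcome(s).
#' @param probability Probability/probabilities in (0, 1] of receiving
#'   `outcome`.
#' @return Numeric vector of expected values in tokens.
#' @examples
#' expected_value(2, 0.25)  # 0.5, same as expected_value(1, 0.5)
#' @export
expected_value <- function(outcome, probability) {
  validate_lottery(outcome, probability)
  outcome * probability
}

#' Battery configuration
#'
#' Describes which lottery pairs the task generator enumerates. The task
#' probes three conditions: `"quantity"` (same probability, different
#' outcome magnitude), `"probability"` (same outcome, different
#' probability) and `"tradeoff"` (the larger-magnitude outcome carries the
#' lower probability). Each condition is produced in the gain domain
#' (positive outcomes) and the loss domain (negated outcomes);
#' mixed-domain pairs (one gain lottery against one loss lottery) are off
#' by default.
#'
#' @param outcomes Positive integer outcome magnitudes (default 1:3).
#' @param probabilities Probabilities used by the task (default
#'   0.25/0.50/0.75/1.00).
#' @param conditions Subset of `c("quantity", "probability", "tradeoff")`.
#' @param domains Subset of `c("gain", "loss")` (default both).
#' @param include_mixed Logical; also generate gain-vs-loss pairs.
#' @param condition_weights Optional named sampling weights over
#'   `conditions` used by [simulate_choices()]; must sum to 1. `NULL`
#'   means uniform over battery rows.
#' @return An object of class `battery_config`.
#' @export
battery_config <- function(outcomes = TOKEN_OUTCOMES,
                           probabilities = TOKEN_PROBS,
                           conditions = c("quantity", "probability", "tradeoff"),
                           domains = c("gain", "loss"),
                           include_mixed = FALSE,
                           condition_weights = NULL) {
  outcomes <- sort(unique(as.integer(outcomes)))
  probabilities <- sort(unique(probabilities))
  if (any(outcomes <= 0)) stop("outcomes are magnitudes: must be positive")
  validate_lottery(outcomes, probabilities)
  conditions <- match.arg(conditions, c("quantity", "probability", "tradeoff"),
                          several.ok = TRUE)
  domains <- match.arg(domains, c("gain", "loss"), several.ok = TRUE)
  if (!is.null(condition_weights)) {
    if (!setequal(names(condition_weights), conditions) ||
        abs(sum(condition_weights) - 1) > 1e-8)
      stop("condition_weights must be named after `conditions` and sum to 1")
  }
  structure(list(outcomes = outcomes, probabilities = probabilities,
                 conditions = conditions, domains = domains,
                 include_mixed = include_mixed,
                 condition_weights = condition_weights),
            class = "battery_config")
}

# Enumerate unordered (magnitude, probability) pairs for one condition.
# Returns a data.frame with columns x1, p1, x2, p2 where (x2, p2) is the
# "larger magnitude" side for quantity/tradeoff pairs.
enumerate_condition_pairs <- function(condition, outcomes, probabilities) {
  out <- list()
  if (condition == "quantity") {
    for (p in probabilities)
      for (i in seq_along(outcomes))
        for (j in seq_along(outcomes))
          if (i < j)
            out[[length(out) + 1L]] <- c(outcomes[i], p, outcomes[j], p)
  } else if (condition == "probability") {
    for (x in outcomes)
      for (i in seq_along(probabilities))
        for (j in seq_along(probabilities))
          if (i < j)
            out[[length(out) + 1L]] <- c(x, probabilities[i], x, probabilities[j])
  } else { # tradeoff: larger |x| has the lower p
    for (i in seq_along(outcomes))
      for (j in seq_along(outcomes))
        if (i < j)
          for (a in seq_along(probabilities))
            for (b in seq_along(probabilities))
              if (a < b)
                out[[length(out) + 1L]] <-
                  c(outcomes[i], probabilities[b], outcomes[j], probabilities[a])
  }
  if (length(out) == 0L) return(NULL)
  m <- do.call(rbind, out)
  data.frame(x1 = m[, 1], p1 = m[, 2], x2 = m[, 3], p2 = m[, 4])
}

#' Generate the task's lottery battery
#'
#' Enumerates every lottery pair consistent with the configured condition
#' predicates over the outcome and probability grids, in both the gain and
#' the loss domain. With a `seed`, the left/right assignment of each pair
#' is randomised (reproducibly); without one, the enumeration order is
#' canonical.
#'
#' @param config A [battery_config()].
#' @param seed Optional integer seed for the side assignment.
#' @return A data.frame with columns `left_outcome`, `left_prob`,
#'   `right_outcome`, `right_prob`, `condition`, `domain`.
#' @export
generate_battery <- function(config = battery_config(), seed = NULL) {
  stopifnot(inherits(config, "battery_config"))
  rows <- list()
  for (cond in config$conditions) {
    pairs <- enumerate_condition_pairs(cond, config$outcomes, config$probabilities)
    if (is.null(pairs)) next
    if ("gain" %in% config$domains)
      rows[[length(rows) + 1L]] <-
        data.frame(left_outcome = pairs$x1, left_prob = pairs$p1,
                   right_outcome = pairs$x2, right_prob = pairs$p2,
                   condition = cond, domain = "gain")
    if ("loss" %in% config$domains)
      rows[[length(rows) + 1L]] <-
        data.frame(left_outcome = -pairs$x1, left_prob = pairs$p1,
                   right_outcome = -pairs$x2, right_prob = pairs$p2,
                   condition = cond, domain = "loss")
    if (config$include_mixed) {
      mixed <- data.frame(left_outcome = pairs$x1, left_prob = pairs$p1,
                          right_outcome = -pairs$x2, right_prob = pairs$p2,
                          condition = cond, domain = "mixed")
      rows[[length(rows) + 1L]] <- mixed
    }
  }
  if (length(rows) == 0L)
    stop("battery is empty: configuration excludes all conditions", call. = FALSE)
  battery <- do.call(rbind, rows)
  if (!is.null(seed)) {
    battery <- with_seed(seed, {
      flip <- sample(c(TRUE, FALSE), nrow(battery), replace = TRUE)
      swapped <- battery
      swapped[flip, c("left_outcome", "left_prob")] <-
        battery[flip, c("right_outcome", "right_prob")]
      swapped[flip, c("right_outcome", "right_prob")] <-
        battery[flip, c("left_outcome", "left_prob")]
      swapped
    })
  }
  rownames(battery) <- NULL
  attr(battery, "condition_weights") <- config$condition_weights
  battery
}

# Classify condition and domain from raw lottery columns (used when reading
# logs that lack those columns).
classify_pairs <- function(trials) {
  ax_l <- abs(trials$left_outcome); ax_r <- abs(trials$right_outcome)
  condition <- ifelse(trials$left_prob == trials$right_prob, "quantity",
               ifelse(ax_l == ax_r, "probability", "tradeoff"))
  sl <- sign(trials$left_outcome); sr <- sign(trials$right_outcome)
  domain <- ifelse(sl > 0 & sr > 0, "gain", ifelse(sl < 0 & sr < 0, "loss", "mixed"))
  data.frame(condition = condition, domain = domain)
}

#' Simulate choices of a Prospect Theory agent
#'
#' Draws `n_trials` lottery pairs from the battery and samples the choice
#' on each trial from the agent's sigmoid choice rule
#' ([choice_prob_right()]). Sides are re-randomised per trial so that a
#' side-bias parameter is identifiable from the simulated log.
#'
#' @param params A [pt_params()] vector for the simulated agent.
#' @param battery Battery data.frame from [generate_battery()].
#' @param n_trials Number of trials to simulate (>= 1).
#' @param seed Integer seed; the full record list is reproducible.
#' @param individual_id Identifier written into the log.
#' @param start_time POSIXct of the first trial; trials are spaced
#'   `spacing_s` seconds apart.
#' @param spacing_s Seconds between consecutive trials (default 60).
#' @return A trial-log data.frame (see package vignette for the column
#'   contract).
#' @export
simulate_choices <- function(params, battery, n_trials, seed = NULL,
                             individual_id = "sim",
                             start_time = as.POSIXct("2020-02-01", tz = "UTC"),
                             spacing_s = 60) {
  params <- as_pt_params(params)
  stopifnot(n_trials >= 1)
  stopifnot_cols(battery, c("left_outcome", "left_prob", "right_outcome", "right_prob"))
  with_seed(seed, {
    weights <- battery_row_weights(battery)
    idx <- sample.int(nrow(battery), n_trials, replace = TRUE, prob = weights)
    tr <- battery[idx, , drop = FALSE]
    flip <- sample(c(TRUE, FALSE), n_trials, replace = TRUE)
    lo <- ifelse(flip, tr$right_outcome, tr$left_outcome)
    lp <- ifelse(flip, tr$right_prob, tr$left_prob)
    ro <- ifelse(flip, tr$left_outcome, tr$right_outcome)
    rp <- ifelse(flip, tr$left_prob, tr$right_prob)
    p_right <- choice_prob_right(data.frame(left_outcome = lo, left_prob = lp,
                                            right_outcome = ro, right_prob = rp),
                                 params)
    choice <- ifelse(stats::runif(n_trials) < p_right, "right", "left")
    out <- data.frame(
      individual_id = individual_id,
      timestamp = start_time + (seq_len(n_trials) - 1L) * spacing_s,
      trial_index = seq_len(n_trials),
      left_outcome = lo, left_prob = lp,
      right_outcome = ro, right_prob = rp,
      choice = choice)
    cls <- classify_pairs(out)
    out$condition <- cls$condition
    out$domain <- cls$domain
    rownames(out) <- NULL
    out
  })
}

# Per-row sampling weights implementing the battery's condition mix.
battery_row_weights <- function(battery) {
  w <- attr(battery, "condition_weights")
  if (is.null(w)) return(NULL)
  tab <- table(battery$condition)
  as.numeric(w[battery$condition] / tab[battery$condition])
}
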