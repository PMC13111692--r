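# Synthetic cohort generator: complete trial logs, displacement logs and
# metadata with known ground truth, emulating a group of ~18 semi-free
# ranging macaques with months of round-the-clock access to gambling
# devices. Every pipeline stage can be checked against the generative
# values it should recover.
#
# Generative structure:
#   - each individual has a latent dominance strength; dyadic displacement
#     events are a Poisson process over the activity window, with the
#     stronger individual winning with probability increasing in the
#     strength gap (so conflicts between closely matched individuals are
#     intrinsically less predictable - the source of the COP U-shape);
#   - each individual has base PT parameters drawn around group means;
#   - each 1500-trial chunk's true parameters are the base values plus a
#     rank link (quadratic coefficients on the concurrent z-scored Elo, or
#     a COP link) plus chunk-level jitter, so longitudinal rank changes
#     propagate into risk-attitude changes;
#   - choices are simulated from the sigmoid choice rule with the chunk's
#     true parameters.

#' Cohort configuration
#'
#' Study-condition defaults: 18 individuals (11 males), 40 months of
#' activity, 75,000 trials per individual (50 chunks of 1500), ages
#' centred on 7.24 +/- 4.56 years, and group-mean PT parameters matching
#' the group-level estimates the analysis is designed to detect
#' (`rho_plus` 0.182, `rho_minus` -0.508, `lam` 2.987, `alpha_plus`
#' 1.208, `alpha_minus` 0.655). The default rank link puts a quadratic
#' effect of z-scored Elo on `rho_plus` (+0.08), `log_alpha_plus`
#' (-0.10) and `log_lam` (-0.25) with zero links in the loss domain.
#'
#' @param n_individuals Number of individuals (default 18).
#' @param n_males Number of males among them (default 11).
#' @param months Months of activity (default 40).
#' @param trials_per_individual Trials per individual (default 75000).
#' @param chunk_size Decisions per chunk (default 1500).
#' @param start_date First day of the activity window.
#' @param age_mean,age_sd,age_min,age_max Age-at-start distribution
#'   (truncated normal, years).
#' @param events_per_day Mean displacement events per day (default 10).
#' @param strength_scale Logistic scale of the win-probability model
#'   (smaller = more deterministic conflicts; default 0.5).
#' @param base_means,base_sds Named vectors of the between-individual
#'   distribution of base parameters (log scale for `lam`/`alpha`).
#' @param rank_link Named quadratic coefficients mapping the link
#'   variable to chunk parameters.
#' @param link_variable `"elo_z2"` (square of concurrent z-scored Elo,
#'   default) or `"cop"`.
#' @param chunk_jitter_sds Named chunk-level parameter jitter sds.
#' @param battery Lottery battery (default [generate_battery()]).
#' @param seed Integer seed.
#' @return Object of class `cohort_config`.
#' @export
cohort_config <- function(n_individuals = 18, n_males = 11, months = 40,
                          trials_per_individual = 75000, chunk_size = 1500,
                          start_date = as.Date("2020-02-01"),
                          age_mean = 7.24, age_sd = 4.56,
                          age_min = 1, age_max = 20,
                          events_per_day = 10, strength_scale = 0.5,
                          base_means = c(rho_plus = 0.182,
                                         rho_minus = -0.508,
                                         log_lam = log(2.987),
                                         log_alpha_plus = log(1.208),
                                         log_alpha_minus = log(0.655),
                                         mu = 5, x0 = 0),
                          base_sds = c(rho_plus = 0.25, rho_minus = 0.10,
                                       log_lam = 0.40,
                                       log_alpha_plus = 0.30,
                                       log_alpha_minus = 0.25,
                                       mu = 1, x0 = 0.2),
                          rank_link = c(rho_plus = 0.08, rho_minus = 0,
                                        log_lam = -0.25,
                                        log_alpha_plus = -0.10,
                                        log_alpha_minus = 0),
                          link_variable = c("elo_z2", "cop"),
                          chunk_jitter_sds = c(rho_plus = 0.15,
                                               rho_minus = 0.08,
                                               log_lam = 0.15,
                                               log_alpha_plus = 0.12,
                                               log_alpha_minus = 0.12),
                          battery = generate_battery(),
                          seed = 1L) {
  stopifnot(n_individuals >= 2, n_males <= n_individuals,
            trials_per_individual >= chunk_size,
            all(base_sds >= 0), all(chunk_jitter_sds >= 0),
            events_per_day > 0)
  link_variable <- match.arg(link_variable)
  structure(as.list(environment()), class = "cohort_config")
}

LINK_PARAMS <- c("rho_plus", "rho_minus", "log_lam", "log_alpha_plus",
                 "log_alpha_minus")

# Keep true parameter values inside the model's admissible region (and
# inside the default fitting box).
clip_params <- function(p) {
  p$rho_plus <- pmin(pmax(p$rho_plus, -0.9), 0.9)
  p$rho_minus <- pmin(pmax(p$rho_minus, -0.9), 0.9)
  p$lam <- pmin(pmax(p$lam, 0.1), 12)
  p$alpha_plus <- pmin(pmax(p$alpha_plus, 0.1), 4)
  p$alpha_minus <- pmin(pmax(p$alpha_minus, 0.1), 4)
  p$mu <- pmin(pmax(p$mu, 0.5), 20)
  p
}

#' Generate a complete synthetic cohort
#'
#' Produces a trial log, a displacement-event log, individual metadata
#' and ground-truth tables (per-individual base parameters, per-chunk
#' true parameters with the concurrent hierarchy measures). Bitwise
#' reproducible given `config$seed`.
#'
#' @param config A [cohort_config()].
#' @return List of class `ptrank_cohort`: `trials`, `events`,
#'   `metadata`, `truth_individuals`, `truth_chunks`, `elo` (true
#'   trajectory), `config`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  seeds <- derive_seeds(config$seed, 6L)
  n <- config$n_individuals
  days <- round(config$months * 30.44)
  t0 <- as.POSIXct(paste(config$start_date, "00:00:00"), tz = "UTC")
  t1 <- t0 + days * 86400

  # --- individuals -------------------------------------------------------
  metadata <- with_seed(seeds[1], {
    ids <- sprintf("id%02d", seq_len(n))
    sex <- sample(c(rep("male", config$n_males),
                    rep("female", n - config$n_males)))
    age <- pmin(pmax(stats::rnorm(n, config$age_mean, config$age_sd),
                     config$age_min), config$age_max)
    data.frame(individual_id = ids, sex = sex,
               birth_date = config$start_date - round(age * 365.25),
               latent_strength = stats::rnorm(n))
  })

  # --- base PT parameters ------------------------------------------------
  truth_ind <- with_seed(seeds[2], {
    draw <- function(nm) stats::rnorm(n, config$base_means[[nm]],
                                      config$base_sds[[nm]])
    data.frame(individual_id = metadata$individual_id,
               rho_plus = draw("rho_plus"), rho_minus = draw("rho_minus"),
               log_lam = draw("log_lam"),
               log_alpha_plus = draw("log_alpha_plus"),
               log_alpha_minus = draw("log_alpha_minus"),
               mu = draw("mu"), x0 = draw("x0"))
  })

  # --- displacement events ----------------------------------------------
  events <- with_seed(seeds[3], {
    n_ev <- stats::rpois(1, config$events_per_day * days)
    if (n_ev == 0)
      stop("infeasible config: no conflicts generated", call. = FALSE)
    ts <- sort(t0 + stats::runif(n_ev) * as.numeric(t1 - t0, units = "secs"))
    i <- sample.int(n, n_ev, replace = TRUE)
    j <- sample.int(n - 1L, n_ev, replace = TRUE)
    j <- ifelse(j >= i, j + 1L, j)
    s <- metadata$latent_strength
    p_i_wins <- stats::plogis((s[i] - s[j]) / config$strength_scale)
    i_wins <- stats::runif(n_ev) < p_i_wins
    data.frame(timestamp = ts,
               winner_id = metadata$individual_id[ifelse(i_wins, i, j)],
               loser_id = metadata$individual_id[ifelse(i_wins, j, i)])
  })
  elo <- compute_elo(events, metadata$individual_id,
                     date_range = c(as.Date(t0), as.Date(t1)))

  # --- trial timestamps and chunk structure ------------------------------
  n_chunks <- config$trials_per_individual %/% config$chunk_size
  n_trials_used <- n_chunks * config$chunk_size
  stamp_seeds <- derive_seeds(seeds[4], n)
  spans <- list(); stamps <- list()
  for (k in seq_len(n)) {
    ts <- with_seed(stamp_seeds[k], {
      sort(t0 + stats::runif(config$trials_per_individual) *
             as.numeric(t1 - t0, units = "secs"))
    })
    stamps[[k]] <- ts[seq_len(n_trials_used)]
    ci <- rep(seq_len(n_chunks), each = config$chunk_size)
    spans[[k]] <- data.frame(
      individual_id = metadata$individual_id[k],
      chunk_index = seq_len(n_chunks),
      t_start = as.POSIXct(tapply(stamps[[k]], ci, min), tz = "UTC"),
      t_end = as.POSIXct(tapply(stamps[[k]], ci, max), tz = "UTC"))
  }
  spans <- do.call(rbind, spans)

  # --- true chunk parameters via the rank link ---------------------------
  hier <- align_hierarchy_to_chunks(elo, events, spans)
  truth_chunks <- merge(spans, hier, by = c("individual_id", "chunk_index"))
  truth_chunks$elo_z_true <- as.numeric(scale(truth_chunks$mean_elo))
  link_value <- if (config$link_variable == "elo_z2")
    truth_chunks$elo_z_true^2 else truth_chunks$cop
  link_value[is.na(link_value)] <- 0
  truth_chunks$link_value <- link_value

  truth_chunks <- with_seed(seeds[5], {
    base <- truth_ind[match(truth_chunks$individual_id,
                            truth_ind$individual_id), ]
    m <- nrow(truth_chunks)
    pl <- list()
    for (nm in LINK_PARAMS) {
      pl[[nm]] <- base[[nm]] + config$rank_link[[nm]] * link_value +
        stats::rnorm(m, 0, config$chunk_jitter_sds[[nm]])
    }
    truth_chunks$rho_plus <- pl$rho_plus
    truth_chunks$rho_minus <- pl$rho_minus
    truth_chunks$lam <- exp(pl$log_lam)
    truth_chunks$alpha_plus <- exp(pl$log_alpha_plus)
    truth_chunks$alpha_minus <- exp(pl$log_alpha_minus)
    truth_chunks$mu <- base$mu
    truth_chunks$x0 <- base$x0
    clip_params(truth_chunks)
  })

  # --- choices -----------------------------------------------------------
  choice_seeds <- derive_seeds(seeds[6], nrow(truth_chunks))
  trials <- vector("list", nrow(truth_chunks))
  for (r in seq_len(nrow(truth_chunks))) {
    params <- pt_params(rho_plus = truth_chunks$rho_plus[r],
                        rho_minus = truth_chunks$rho_minus[r],
                        lam = truth_chunks$lam[r],
                        alpha_plus = truth_chunks$alpha_plus[r],
                        alpha_minus = truth_chunks$alpha_minus[r],
                        mu = truth_chunks$mu[r], x0 = truth_chunks$x0[r])
    tr <- simulate_choices(params, config$battery, config$chunk_size,
                           seed = choice_seeds[r],
                           individual_id = truth_chunks$individual_id[r])
    k <- match(truth_chunks$individual_id[r], metadata$individual_id)
    offset <- (truth_chunks$chunk_index[r] - 1L) * config$chunk_size
    tr$trial_index <- offset + seq_len(config$chunk_size)
    tr$timestamp <- stamps[[k]][tr$trial_index]
    trials[[r]] <- tr
  }
  trials <- do.call(rbind, trials)
  trials <- trials[order(trials$individual_id, trials$trial_index), ,
                   drop = FALSE]
  rownames(trials) <- NULL

  structure(list(trials = trials, events = events, metadata = metadata,
                 truth_individuals = truth_ind,
                 truth_chunks = truth_chunks,
                 elo = elo, config = config),
            class = "ptrank_cohort")
}

#' @export
print.ptrank_cohort <- function(x, ...) {
  cat(sprintf(paste0("synthetic cohort: %d individuals, %d trials, ",
                     "%d displacement events over %d months\n"),
              nrow(x$metadata), nrow(x$trials), nrow(x$events),
              x$config$months))
  invisible(x)
}

#' Inject one-sided responding into a trial log
#'
#' Overwrites the choices of the selected individuals with one-sided
#' responding at the stated rate (each trial independently lands on the
#' individual's biased side with probability `rate`). Used to verify
#' that the filtering stages exclude animals whose logs reflect a
#' positional heuristic rather than value-based choice.
#'
#' @param trials Trial-log data.frame.
#' @param individuals Ids whose choices are overwritten (empty vector =
#'   identity).
#' @param rate Probability of the biased side, in [0.5, 1].
#' @param side `"left"`, `"right"`, or `NULL` to pick per individual at
#'   random.
#' @param seed Integer seed.
#' @return The modified trial log.
#' @export
inject_pathologies <- function(trials, individuals, rate = 1, side = NULL,
                               seed = 1L) {
  if (rate < 0.5 || rate > 1)
    stop("rate must lie in [0.5, 1]", call. = FALSE)
  if (length(individuals) == 0L) return(trials)
  stopifnot(all(individuals %in% trials$individual_id))
  with_seed(seed, {
    for (id in individuals) {
      sel <- trials$individual_id == id
      bias <- side %||% sample(c("left", "right"), 1L)
      other <- if (bias == "left") "right" else "left"
      biased <- stats::runif(sum(sel)) < rate
      trials$choice[sel] <- ifelse(biased, bias, other)
    }
    trials
  })
}
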