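# Dominance hierarchy from displacement events: Elo-rating trajectories,
# ordinal ranks, and conflict outcome predictability (COP).
#
# A displacement event records a winner supplanting a loser at a testing
# device. Ratings follow the classical Elo scheme: everyone starts at 1000,
# the winner gains (and the loser loses) k * (1 - E_w) points, where E_w is
# the winner's expected score under the logistic base-10 / scale-400 rule.
# Total points are conserved at every update.

#' Elo configuration
#'
#' @param start_rating Initial rating for every individual (default 1000).
#' @param k Update constant (default 100).
#' @param scale Logistic expectation scale (default 400, base 10).
#' @return Object of class `elo_config`.
#' @export
elo_config <- function(start_rating = 1000, k = 100, scale = 400) {
  stopifnot(k > 0, scale > 0)
  structure(list(start_rating = start_rating, k = k, scale = scale),
            class = "elo_config")
}

#' Single Elo update
#'
#' @param r_winner,r_loser Current ratings.
#' @param config An [elo_config()].
#' @return Named vector `c(winner = , loser = )` of updated ratings; the
#'   sum of the two ratings is unchanged.
#' @export
elo_update <- function(r_winner, r_loser, config = elo_config()) {
  stopifnot(is.finite(r_winner), is.finite(r_loser))
  e_w <- 1 / (1 + 10^((r_loser - r_winner) / config$scale))
  d <- config$k * (1 - e_w)
  c(winner = r_winner + d, loser = r_loser - d)
}

#' Daily Elo-rating trajectories from a displacement log
#'
#' Applies [elo_update()] sequentially in event order (events are
#' time-sorted first if needed) and emits one rating per individual per
#' day: the value after the day's last event, carried forward over days
#' without events. All roster members are initialised at the start
#' rating.
#'
#' @param events Data.frame with columns `timestamp`, `winner_id`,
#'   `loser_id`.
#' @param roster Character vector of all individual ids; an event naming
#'   an id outside the roster is an error.
#' @param config An [elo_config()].
#' @param date_range Optional `Date` vector of length 2 delimiting the
#'   daily grid (defaults to the span of the events).
#' @return Long-format data.frame (`date`, `individual_id`, `rating`) of
#'   class `elo_trajectory`.
#' @export
compute_elo <- function(events, roster, config = elo_config(),
                        date_range = NULL) {
  stopifnot_cols(events, c("timestamp", "winner_id", "loser_id"))
  roster <- as.character(roster)
  ids <- unique(c(events$winner_id, events$loser_id))
  if (!all(ids %in% roster))
    stop("event log names individual(s) outside the roster: ",
         paste(setdiff(ids, roster), collapse = ", "), call. = FALSE)
  if (any(events$winner_id == events$loser_id))
    stop("winner and loser must differ", call. = FALSE)
  events <- events[order(events$timestamp), , drop = FALSE]
  ratings <- stats::setNames(rep(config$start_rating, length(roster)), roster)
  ev_date <- as.Date(events$timestamp)
  if (is.null(date_range)) {
    if (nrow(events) > 0L) date_range <- range(ev_date)
    else stop("empty event log needs an explicit date_range", call. = FALSE)
  }
  days <- seq(as.Date(date_range[1]), as.Date(date_range[2]), by = "day")
  snap <- matrix(config$start_rating, nrow = length(days), ncol = length(roster),
                 dimnames = list(NULL, roster))
  di <- 1L
  for (i in seq_len(nrow(events))) {
    d <- ev_date[i]
    while (di <= length(days) && days[di] < d) {
      snap[di, ] <- ratings
      di <- di + 1L
    }
    upd <- elo_update(ratings[[events$winner_id[i]]],
                      ratings[[events$loser_id[i]]], config)
    ratings[[events$winner_id[i]]] <- upd[["winner"]]
    ratings[[events$loser_id[i]]] <- upd[["loser"]]
  }
  while (di <= length(days)) {
    snap[di, ] <- ratings
    di <- di + 1L
  }
  out <- data.frame(
    date = rep(days, times = length(roster)),
    individual_id = rep(roster, each = length(days)),
    rating = as.vector(snap))
  class(out) <- c("elo_trajectory", "data.frame")
  attr(out, "config") <- config
  out
}

#' Ordinal rank table on a given day
#'
#' Dense ranks of that day's ratings (1 = highest); individuals with
#' equal ratings share a rank, and rows are ordered by rank then by
#' identifier.
#'
#' @param trajectory An `elo_trajectory` from [compute_elo()].
#' @param date A `Date` inside the trajectory span.
#' @return Data.frame `individual_id`, `rating`, `rank`.
#' @export
ordinal_rank <- function(trajectory, date) {
  date <- as.Date(date)
  if (date < min(trajectory$date) || date > max(trajectory$date))
    stop("date outside trajectory span", call. = FALSE)
  day <- trajectory[trajectory$date == date, , drop = FALSE]
  lev <- sort(unique(day$rating), decreasing = TRUE)
  out <- data.frame(individual_id = day$individual_id, rating = day$rating,
                    rank = match(day$rating, lev))
  out <- out[order(out$rank, out$individual_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Conflict outcome predictability
#'
#' `|wins - losses| / (wins + losses)` for one individual over a time
#' window: 1 means fully predictable outcomes (all wins or all losses),
#' 0 a 50/50 split. With zero conflicts in the window the score is
#' undefined (`NA`), not 0.
#'
#' @param events Displacement-event data.frame.
#' @param individual Individual id.
#' @param window Length-2 vector (start, end) of timestamps; inclusive.
#' @return Data.frame row: `individual_id`, `start`, `end`,
#'   `n_conflicts`, `score`.
#' @export
cop <- function(events, individual, window) {
  stopifnot_cols(events, c("timestamp", "winner_id", "loser_id"))
  stopifnot(length(window) == 2L)
  inw <- events$timestamp >= window[1] & events$timestamp <= window[2]
  wins <- sum(inw & events$winner_id == individual)
  losses <- sum(inw & events$loser_id == individual)
  n <- wins + losses
  data.frame(individual_id = individual, start = window[1], end = window[2],
             n_conflicts = n,
             score = if (n > 0) abs(wins - losses) / n else NA_real_)
}

#' Align hierarchy measures to trial chunks
#'
#' For each chunk time span, the mean of the individual's daily Elo
#' ratings over the span and the COP score over the same window. Spans
#' with no rating days yield `NA` and are flagged by `n_days = 0`.
#'
#' @param trajectory An `elo_trajectory`.
#' @param events Displacement-event data.frame (for COP).
#' @param spans Data.frame with columns `individual_id`, `chunk_index`,
#'   `t_start`, `t_end`.
#' @return Data.frame `individual_id`, `chunk_index`, `mean_elo`, `cop`,
#'   `n_conflicts`, `n_days`.
#' @export
align_hierarchy_to_chunks <- function(trajectory, events, spans) {
  stopifnot_cols(spans, c("individual_id", "chunk_index", "t_start", "t_end"))
  out <- spans[, c("individual_id", "chunk_index")]
  out$mean_elo <- NA_real_
  out$cop <- NA_real_
  out$n_conflicts <- 0L
  out$n_days <- 0L
  for (i in seq_len(nrow(spans))) {
    d0 <- as.Date(spans$t_start[i]); d1 <- as.Date(spans$t_end[i])
    sel <- trajectory$individual_id == spans$individual_id[i] &
      trajectory$date >= d0 & trajectory$date <= d1
    n_days <- sum(sel)
    out$n_days[i] <- n_days
    if (n_days > 0L) out$mean_elo[i] <- mean(trajectory$rating[sel])
    cp <- cop(events, spans$individual_id[i],
              c(spans$t_start[i], spans$t_end[i]))
    out$cop[i] <- cp$score
    out$n_conflicts[i] <- cp$n_conflicts
  }
  out
}
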