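# Maximum-likelihood estimation of PT parameters on trial chunks, and the
# trial-requirement simulation that motivates the 1500-trial window.
#
# All seven parameters are fitted jointly on a chunk's gain and loss trials
# together. The shared choice steepness `mu` is what ties the two domains to
# a common utility scale: without it (one steepness per domain and no mixed
# pairs) the loss-aversion parameter trades off exactly against the
# loss-domain steepness and is unidentifiable. The likelihood is multimodal
# in (alpha, mu), so each chunk is fitted from multiple starts inside a
# bounded box and the best optimum kept.

#' Fitting configuration
#'
#' Bounds of the search box, the number of multistart runs, and optimizer
#' control for [fit_chunk()].
#'
#' @param lower,upper Named numeric vectors of box bounds over the seven
#'   parameters.
#' @param n_multistart Number of optimizer starts per chunk (>= 1); the
#'   first start is always the neutral parameter vector, the rest are
#'   uniform draws in the box.
#' @param maxit Maximum L-BFGS-B iterations per start.
#' @param factr L-BFGS-B convergence tolerance factor.
#' @param seed Integer seed for the random starts.
#' @return An object of class `fit_config`.
#' @export
fit_config <- function(lower = c(rho_plus = -0.95, rho_minus = -0.95,
                                 lam = 0.05, alpha_plus = 0.05,
                                 alpha_minus = 0.05, mu = 0, x0 = -10),
                       upper = c(rho_plus = 0.95, rho_minus = 0.95,
                                 lam = 15, alpha_plus = 5,
                                 alpha_minus = 5, mu = 25, x0 = 10),
                       n_multistart = 10, maxit = 300, factr = 1e7,
                       seed = 1L) {
  stopifnot(all(PT_PARAM_NAMES %in% names(lower)),
            all(PT_PARAM_NAMES %in% names(upper)))
  lower <- lower[PT_PARAM_NAMES]; upper <- upper[PT_PARAM_NAMES]
  if (any(!is.finite(lower)) || any(!is.finite(upper)) || any(lower >= upper))
    stop("bounds must be finite with lower < upper", call. = FALSE)
  stopifnot(n_multistart >= 1)
  structure(list(lower = lower, upper = upper,
                 n_multistart = as.integer(n_multistart),
                 maxit = maxit, factr = factr, seed = as.integer(seed)),
            class = "fit_config")
}

NEUTRAL_THETA <- c(rho_plus = 0, rho_minus = 0, lam = 1, alpha_plus = 1,
                   alpha_minus = 1, mu = 1, x0 = 0)

#' Fit the PT model to one chunk of trials
#'
#' Minimises the negative log-likelihood over the bounded box from
#' `n_multistart` starts (neutral parameters plus uniform draws) and
#' returns the best optimum with diagnostics. Chunks with no loss (or no
#' gain) trials are fitted but flagged: the parameters of the absent
#' domain (and `lam`, which needs both) have a flat likelihood profile
#' and should not be interpreted.
#'
#' @param trials Trial-log data.frame for a single individual,
#'   chronologically ordered.
#' @param config A [fit_config()].
#' @return An object of class `chunk_fit`: list with `params`
#'   ([pt_params()]), `nll`, `nll_neutral`, `converged`, `n_trials`,
#'   `n_gain_trials`, `n_loss_trials`, `side_bias`, `time_span`,
#'   `gain_identifiable`, `loss_identifiable`, `start_seed`.
#' @export
fit_chunk <- function(trials, config = fit_config()) {
  stopifnot(inherits(config, "fit_config"))
  if (length(unique(trials$individual_id %||% "sim")) > 1L)
    stop("fit_chunk expects trials from a single individual", call. = FALSE)
  design <- pt_design(trials)
  starts <- fit_starts(config)
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    opt <- stats::optim(starts[i, ], fn = pt_nll_design, gr = pt_nll_grad_design,
                        design = design, method = "L-BFGS-B",
                        lower = config$lower, upper = config$upper,
                        control = list(maxit = config$maxit, factr = config$factr))
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  theta <- best$par
  names(theta) <- PT_PARAM_NAMES
  n_gain <- sum(trials$left_outcome > 0 & trials$right_outcome > 0)
  n_loss <- sum(trials$left_outcome < 0 & trials$right_outcome < 0)
  has_gain <- any(trials$left_outcome > 0 | trials$right_outcome > 0)
  has_loss <- any(trials$left_outcome < 0 | trials$right_outcome < 0)
  ts <- trials$timestamp %||% rep(NA, nrow(trials))
  structure(list(
    params = structure(theta, class = "pt_params"),
    nll = best$value,
    nll_neutral = pt_nll_design(unname(NEUTRAL_THETA), design),
    converged = best$convergence == 0L,
    n_trials = nrow(trials),
    n_gain_trials = n_gain,
    n_loss_trials = n_loss,
    side_bias = side_bias(trials),
    time_span = c(min(ts), max(ts)),
    gain_identifiable = has_gain,
    loss_identifiable = has_loss && has_gain,
    start_seed = config$seed
  ), class = "chunk_fit")
}

fit_starts <- function(config) {
  k <- length(PT_PARAM_NAMES)
  starts <- matrix(NEUTRAL_THETA, nrow = 1L,
                   dimnames = list(NULL, PT_PARAM_NAMES))
  if (config$n_multistart > 1L) {
    rand <- with_seed(config$seed, {
      m <- matrix(stats::runif((config$n_multistart - 1L) * k),
                  ncol = k, dimnames = list(NULL, PT_PARAM_NAMES))
      sweep(sweep(m, 2L, config$upper - config$lower, "*"), 2L,
            config$lower, "+")
    })
    starts <- rbind(starts, rand)
  }
  starts
}

#' @export
print.chunk_fit <- function(x, ...) {
  cat(sprintf("PT chunk fit: %d trials (%d gain / %d loss), nll = %.2f%s\n",
              x$n_trials, x$n_gain_trials, x$n_loss_trials, x$nll,
              if (x$converged) "" else " (not converged)"))
  print(x$params)
  if (!x$loss_identifiable)
    cat("NOTE: loss-domain parameters (rho_minus, alpha_minus, lam) are not identifiable for this chunk\n")
  invisible(x)
}

# One row of the tabular chunk-fit representation used by the pipeline.
chunk_fit_row <- function(fit, individual_id, chunk_index, mean_trial_index) {
  data.frame(individual_id = individual_id, chunk_index = chunk_index,
             as.list(unclass(fit$params)),
             nll = fit$nll, converged = fit$converged,
             n_trials = fit$n_trials,
             n_gain_trials = fit$n_gain_trials,
             n_loss_trials = fit$n_loss_trials,
             side_bias = fit$side_bias,
             t_start = fit$time_span[1], t_end = fit$time_span[2],
             loss_identifiable = fit$loss_identifiable,
             mean_trial_index = mean_trial_index)
}

#' Fit all complete chunks of a multi-individual trial log
#'
#' Segments each individual's trial sequence into consecutive windows of
#' `chunk_size` decisions ([chunk_trials()]) and fits each window with
#' [fit_chunk()]. Start seeds are derived per chunk from `config$seed` so
#' the whole table is reproducible.
#'
#' @param trials Trial-log data.frame (any number of individuals).
#' @param config A [fit_config()].
#' @param chunk_size Trials per window (default 1500).
#' @return Data.frame, one row per fitted chunk.
#' @export
fit_chunks <- function(trials, config = fit_config(), chunk_size = 1500) {
  chunked <- chunk_trials(trials, size = chunk_size)
  chunked <- chunked[!is.na(chunked$chunk_index), , drop = FALSE]
  if (nrow(chunked) == 0L) stop("no individual has a complete chunk", call. = FALSE)
  keys <- unique(chunked[, c("individual_id", "chunk_index")])
  keys <- keys[order(keys$individual_id, keys$chunk_index), , drop = FALSE]
  seeds <- derive_seeds(config$seed, nrow(keys))
  rows <- vector("list", nrow(keys))
  for (i in seq_len(nrow(keys))) {
    sel <- chunked$individual_id == keys$individual_id[i] &
      chunked$chunk_index == keys$chunk_index[i]
    ch <- chunked[sel, , drop = FALSE]
    cfg_i <- config; cfg_i$seed <- seeds[i]
    fit <- fit_chunk(ch, cfg_i)
    rows[[i]] <- chunk_fit_row(fit, keys$individual_id[i], keys$chunk_index[i],
                               mean(ch$trial_index))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Trials needed for reliable parameter estimation
#'
#' Recovery simulation: for each of `n_agents` simulated players, true
#' parameters are drawn uniformly inside the fitting box, a long choice
#' sequence is simulated, and the model is refitted on the first `n`
#' trials for every `n` in `trial_grid`. The error metric is the absolute
#' estimation error per parameter standardised by that parameter's box
#' width, averaged over the five PT parameters (`rho_plus`, `rho_minus`,
#' `lam`, `alpha_plus`, `alpha_minus`) and over agents.
#'
#' @param n_agents Number of simulated players (default 25).
#' @param trial_grid Increasing vector of trial counts to evaluate.
#' @param config A [fit_config()].
#' @param seed Integer seed for the whole simulation.
#' @param battery Lottery battery to simulate from.
#' @return Data.frame with one row per grid point: `n_trials`, the
#'   standardised error per parameter (`err_<name>`), and `err_aggregate`.
#' @export
trial_requirement_curve <- function(n_agents = 25,
                                    trial_grid = c(250, 500, 1000, 1500, 3000),
                                    config = fit_config(), seed = 1L,
                                    battery = generate_battery()) {
  stopifnot(n_agents >= 1, all(diff(trial_grid) > 0))
  if (any(trial_grid < 100))
    warning("grid points below 100 trials give unstable fits")
  pt_names <- c("rho_plus", "rho_minus", "lam", "alpha_plus", "alpha_minus")
  ranges <- (config$upper - config$lower)[pt_names]
  seeds <- derive_seeds(seed, 2L * n_agents)
  errs <- array(NA_real_, dim = c(n_agents, length(trial_grid), length(pt_names)))
  for (a in seq_len(n_agents)) {
    true <- with_seed(seeds[a], stats::runif(length(PT_PARAM_NAMES),
                                             config$lower, config$upper))
    names(true) <- PT_PARAM_NAMES
    trials <- simulate_choices(structure(true, class = "pt_params"), battery,
                               n_trials = max(trial_grid),
                               seed = seeds[n_agents + a])
    for (g in seq_along(trial_grid)) {
      cfg_a <- config; cfg_a$seed <- seeds[a]
      fit <- fit_chunk(trials[seq_len(trial_grid[g]), , drop = FALSE], cfg_a)
      errs[a, g, ] <- abs(fit$params[pt_names] - true[pt_names]) / ranges
    }
  }
  per_par <- apply(errs, c(2L, 3L), mean)
  colnames(per_par) <- paste0("err_", pt_names)
  out <- data.frame(n_trials = trial_grid, per_par,
                    err_aggregate = rowMeans(per_par))
  attr(out, "error_metric") <-
    "mean |estimate - truth| / box width, over rho_plus, rho_minus, lam, alpha_plus, alpha_minus"
  out
}
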