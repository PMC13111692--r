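# The behavioural model: reference-dependent utility, Prelec probability
# weighting, subjective expected value (SEV), the sigmoid choice rule, and
# the likelihood of a set of trials.
#
# Parameterisation:
#   u(x) = x^(1 - rho_plus)            for x > 0
#        = -lam * (-x)^(1 + rho_minus) for x < 0
#        = 0                           for x = 0
#   w(p) = exp(-(-ln p)^alpha)         (Prelec I), alpha > 0
#   P(right) = 1 / (1 + exp(-(mu * Delta + x0))),
#     Delta = w(p_right) u(x_right) - w(p_left) u(x_left)
#
# rho = 0 is risk neutrality in this gauge (u linear); rho_plus > 0 bends the
# gain curve concave (risk averse), rho_minus < 0 bends the loss curve convex
# (risk seeking). lam > 1 is loss aversion. alpha is domain-specific: the
# gain-domain exponent applies to lotteries with positive outcomes, the
# loss-domain exponent to negative ones. x0 > 0 is a right-side bias.

PT_PARAM_NAMES <- c("rho_plus", "rho_minus", "lam", "alpha_plus",
                    "alpha_minus", "mu", "x0")

#' Prospect Theory parameter vector
#'
#' Constructs and validates the seven-parameter behavioural model:
#' utility curvature in gains (`rho_plus`, 0 = risk neutral, > 0 = risk
#' averse) and losses (`rho_minus`, 0 = neutral, < 0 = risk seeking),
#' loss aversion `lam` (> 1 means losses loom larger), Prelec weighting
#' exponents `alpha_plus` / `alpha_minus` per outcome domain, choice
#' steepness `mu`, and side bias `x0` (> 0 = right-side bias).
#'
#' @param rho_plus Gain-domain curvature, must be < 1.
#' @param rho_minus Loss-domain curvature, must be > -1.
#' @param lam Loss aversion, > 0.
#' @param alpha_plus,alpha_minus Prelec exponents, > 0.
#' @param mu Sigmoid steepness, >= 0.
#' @param x0 Side-bias offset.
#' @return Named numeric vector of class `pt_params`.
#' @export
pt_params <- function(rho_plus = 0, rho_minus = 0, lam = 1,
                      alpha_plus = 1, alpha_minus = 1, mu = 1, x0 = 0) {
  p <- c(rho_plus = rho_plus, rho_minus = rho_minus, lam = lam,
         alpha_plus = alpha_plus, alpha_minus = alpha_minus, mu = mu, x0 = x0)
  validate_pt_params(p)
  structure(p, class = "pt_params")
}

#' @rdname pt_params
#' @param x A named numeric vector, list, or `pt_params` object.
#' @export
as_pt_params <- function(x) {
  if (inherits(x, "pt_params")) return(x)
  x <- unlist(x)
  if (!all(PT_PARAM_NAMES %in% names(x)))
    stop("pt_params requires fields: ", paste(PT_PARAM_NAMES, collapse = ", "),
         call. = FALSE)
  do.call(pt_params, as.list(x[PT_PARAM_NAMES]))
}

validate_pt_params <- function(p) {
  if (any(!is.finite(p)))
    stop("PT parameters must be finite", call. = FALSE)
  if (p[["lam"]] <= 0) stop("lam must be > 0", call. = FALSE)
  if (p[["alpha_plus"]] <= 0 || p[["alpha_minus"]] <= 0)
    stop("alpha exponents must be > 0", call. = FALSE)
  if (p[["mu"]] < 0) stop("mu must be >= 0", call. = FALSE)
  if (p[["rho_plus"]] >= 1) stop("rho_plus must be < 1", call. = FALSE)
  if (p[["rho_minus"]] <= -1) stop("rho_minus must be > -1", call. = FALSE)
  invisible(p)
}

#' @export
print.pt_params <- function(x, ...) {
  cat("PT parameters:\n")
  print(round(unclass(x), 4))
  invisible(x)
}

#' Subjective utility of a token outcome
#'
#' @param x Integer token outcomes (vectorised).
#' @param params A [pt_params()] vector.
#' @return Utility in utils; sign-preserving, u(0) = 0.
#' @export
pt_utility <- function(x, params) {
  params <- as_pt_params(params)
  u <- numeric(length(x))
  pos <- x > 0; neg <- x < 0
  u[pos] <- x[pos]^(1 - params[["rho_plus"]])
  u[neg] <- -params[["lam"]] * (-x[neg])^(1 + params[["rho_minus"]])
  u
}

#' Prelec-I probability weighting
#'
#' `w(p) = exp(-(-ln p)^alpha)`; the identity at `alpha = 1`, fixed points
#' at `p = exp(-1)` and `p = 1`.
#'
#' @param p Probabilities in (0, 1].
#' @param alpha Prelec exponent, > 0.
#' @return Weighted probabilities in (0, 1].
#' @export
prelec_weight <- function(p, alpha) {
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1))
    stop("p must lie in (0, 1]", call. = FALSE)
  if (!is.finite(alpha) || alpha <= 0) stop("alpha must be > 0", call. = FALSE)
  exp(-(-log(p))^alpha)
}

#' Subjective expected value of a lottery
#'
#' `w(p) * u(x)` with the weighting exponent chosen by the sign of the
#' outcome (`alpha_plus` for gains, `alpha_minus` for losses).
#'
#' @param x Token outcomes (vectorised with `p`).
#' @param p Probabilities of the non-zero outcome.
#' @param params A [pt_params()] vector.
#' @return SEV in utils.
#' @export
pt_sev <- function(x, p, params) {
  params <- as_pt_params(params)
  validate_lottery(x, p)
  alpha <- ifelse(x > 0, params[["alpha_plus"]], params[["alpha_minus"]])
  exp(-(-log(p))^alpha) * pt_utility(x, params)
}

#' Probability of choosing the right-hand lottery
#'
#' The sigmoid choice rule `P(right) = plogis(mu * Delta + x0)` where
#' `Delta` is the right-minus-left SEV difference. `mu` controls
#' steepness (0 = random responding), `x0 > 0` shifts choice toward the
#' right side irrespective of value.
#'
#' @param pair Data.frame with columns `left_outcome`, `left_prob`,
#'   `right_outcome`, `right_prob` (one row per trial).
#' @param params A [pt_params()] vector.
#' @return Vector of probabilities; complements of the swapped pair.
#' @export
choice_prob_right <- function(pair, params) {
  params <- as_pt_params(params)
  stopifnot_cols(pair, c("left_outcome", "left_prob", "right_outcome", "right_prob"))
  delta <- pt_sev(pair$right_outcome, pair$right_prob, params) -
    pt_sev(pair$left_outcome, pair$left_prob, params)
  stats::plogis(params[["mu"]] * delta + params[["x0"]])
}

# ---------------------------------------------------------------------------
# Likelihood machinery.
#
# Trials are collapsed to their unique lottery-pair design points; the
# likelihood then costs O(#design points), not O(#trials), which is what
# makes multistart fitting of hundreds of 1500-trial chunks cheap. The
# outcome/probability grids of the task admit at most a few hundred ordered
# pairs.

# Build the aggregated design from a trial log.
pt_design <- function(trials) {
  stopifnot_cols(trials, c("left_outcome", "left_prob", "right_outcome",
                           "right_prob", "choice"))
  if (nrow(trials) == 0L) stop("empty trial list", call. = FALSE)
  key <- paste(trials$left_outcome, trials$left_prob,
               trials$right_outcome, trials$right_prob, sep = "|")
  right <- trials$choice == "right"
  n_right <- rowsum(as.numeric(right), key)
  n_tot <- rowsum(rep(1, length(key)), key)
  first <- !duplicated(key)
  ord <- match(rownames(n_right), key[first])
  kf <- which(first)[ord]
  xL <- trials$left_outcome[kf]; pL <- trials$left_prob[kf]
  xR <- trials$right_outcome[kf]; pR <- trials$right_prob[kf]
  validate_lottery(c(xL, xR), c(pL, pR))
  list(
    xL = xL, pL = pL, xR = xR, pR = pR,
    nR = as.numeric(n_right), n = as.numeric(n_tot),
    nL = as.numeric(n_tot) - as.numeric(n_right),
    # precomputations used on every likelihood evaluation
    posL = xL > 0, negL = xL < 0, posR = xR > 0, negR = xR < 0,
    lnaxL = log(abs(xL)), lnaxR = log(abs(xR)),
    tL = -log(pL), tR = -log(pR),
    n_trials = nrow(trials)
  )
}

# Utility / weight vectors for one side of the design.
side_uw <- function(theta, pos, neg, lnax, t) {
  u <- numeric(length(lnax))
  u[pos] <- exp((1 - theta[1L]) * lnax[pos])
  u[neg] <- -theta[3L] * exp((1 + theta[2L]) * lnax[neg])
  alpha <- rep.int(theta[5L], length(lnax))
  alpha[pos] <- theta[4L]
  ta <- t^alpha       # t = -ln p >= 0 and alpha > 0, so 0^alpha = 0 at p = 1
  w <- exp(-ta)
  list(u = u, w = w, ta = ta)
}

LOG_P_FLOOR <- log(1e-12)

# Negative log-likelihood on an aggregated design (theta in the canonical
# parameter order). Stable for arbitrarily large |mu * Delta|.
pt_nll_design <- function(theta, design) {
  sL <- side_uw(theta, design$posL, design$negL, design$lnaxL, design$tL)
  sR <- side_uw(theta, design$posR, design$negR, design$lnaxR, design$tR)
  delta <- sR$w * sR$u - sL$w * sL$u
  eta <- theta[6L] * delta + theta[7L]
  logp <- pmax(stats::plogis(eta, log.p = TRUE), LOG_P_FLOOR)
  log1mp <- pmax(stats::plogis(-eta, log.p = TRUE), LOG_P_FLOOR)
  -sum(design$nR * logp + design$nL * log1mp)
}

# Analytic gradient of pt_nll_design in the same parameter order.
pt_nll_grad_design <- function(theta, design) {
  sL <- side_uw(theta, design$posL, design$negL, design$lnaxL, design$tL)
  sR <- side_uw(theta, design$posR, design$negR, design$lnaxR, design$tR)
  delta <- sR$w * sR$u - sL$w * sL$u
  eta <- theta[6L] * delta + theta[7L]
  p <- stats::plogis(eta)
  r <- design$n * p - design$nR   # d NLL / d eta per design point
  mu <- theta[6L]

  k <- length(delta)
  masked <- function(vals, mask) { out <- numeric(k); out[mask] <- vals[mask]; out }
  du_drp_R <- masked(-sR$u * design$lnaxR, design$posR)
  du_drp_L <- masked(-sL$u * design$lnaxL, design$posL)
  du_drm_R <- masked(sR$u * design$lnaxR, design$negR)
  du_drm_L <- masked(sL$u * design$lnaxL, design$negL)
  du_dlam_R <- masked(sR$u / theta[3L], design$negR)
  du_dlam_L <- masked(sL$u / theta[3L], design$negL)

  # dw/dalpha = -w * t^alpha * ln t (zero at p = 1 where t = 0)
  dw_da_R <- numeric(k); iR <- design$tR > 0
  dw_da_R[iR] <- (-sR$w * sR$ta)[iR] * log(design$tR[iR])
  dw_da_L <- numeric(k); iL <- design$tL > 0
  dw_da_L[iL] <- (-sL$w * sL$ta)[iL] * log(design$tL[iL])

  ddelta <- function(dR_u, dL_u, dR_w, dL_w)
    sR$w * dR_u + sR$u * dR_w - sL$w * dL_u - sL$u * dL_w
  z <- numeric(k)

  g_rp <- mu * sum(r * ddelta(du_drp_R, du_drp_L, z, z))
  g_rm <- mu * sum(r * ddelta(du_drm_R, du_drm_L, z, z))
  g_lam <- mu * sum(r * ddelta(du_dlam_R, du_dlam_L, z, z))
  g_ap <- mu * sum(r * ddelta(z, z, masked(dw_da_R, design$posR),
                              masked(dw_da_L, design$posL)))
  g_am <- mu * sum(r * ddelta(z, z, masked(dw_da_R, design$negR),
                              masked(dw_da_L, design$negL)))
  g_mu <- sum(r * delta)
  g_x0 <- sum(r)
  c(g_rp, g_rm, g_lam, g_ap, g_am, g_mu, g_x0)
}

#' Negative log-likelihood of observed choices
#'
#' `-sum(log P(observed choice))` under the sigmoid choice rule, with
#' choice probabilities floored at 1e-12 so the result is always finite.
#'
#' @param trials Trial-log data.frame (non-empty) with lottery columns and
#'   a `choice` column (`"left"`/`"right"`).
#' @param params A [pt_params()] vector.
#' @return A non-negative scalar.
#' @export
pt_nll <- function(trials, params) {
  params <- as_pt_params(params)
  pt_nll_design(as.numeric(params[PT_PARAM_NAMES]), pt_design(trials))
}
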