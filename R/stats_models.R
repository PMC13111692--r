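# The statistical battery on the assembled analysis table: paired
# signed-rank contrasts between the gain and loss domains, the
# within-individual variability comparison, and linear mixed models with
# quadratic hierarchy terms.
#
# Mixed-model contract: Gaussian LMM fitted by REML with a random intercept
# per individual and no random slopes; continuous covariates (Elo,
# experience) enter z-scored; factor references are adult (age) and male
# (sex); two-sided P-values at the conservative 0.01 threshold.

LMM_RESPONSES <- c("rho_plus", "rho_minus", "log_alpha_plus",
                   "log_alpha_minus", "log_lam")

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided signed-rank test on paired vectors, exact for n <= 25
#' (without ties or zero differences), normal approximation otherwise.
#'
#' @param x,y Equal-length paired numeric vectors, n >= 5.
#' @return List with `statistic` (V), `p_value`, `n` and `method`.
#' @export
wilcoxon_paired <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 5L) stop("need at least 5 pairs", call. = FALSE)
  d <- x - y
  if (all(d == 0)) stop("all paired differences are zero", call. = FALSE)
  nz <- d[d != 0]
  ties <- any(duplicated(abs(nz)))
  exact <- length(nz) <= 25L && !ties
  ht <- suppressWarnings(
    stats::wilcox.test(x, y, paired = TRUE, exact = exact, correct = TRUE))
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       n = length(nz),
       method = if (exact) "exact" else "normal approximation")
}

#' Within-individual variability: gains versus losses
#'
#' Computes, per individual, the sample variance of the chunk-level
#' gain-curvature estimates (`rho_plus`) and of the loss-curvature
#' estimates (`rho_minus`), and compares the two sets of variances with
#' a paired signed-rank test across individuals. Individuals with fewer
#' than 2 chunks are skipped.
#'
#' @param table Analysis data.frame with `individual_id`, `rho_plus`,
#'   `rho_minus` (one row per chunk).
#' @return List with `per_individual` (data.frame of variances),
#'   `test` ([wilcoxon_paired()] output) and `n_skipped`.
#' @export
variability_contrast <- function(table) {
  stopifnot_cols(table, c("individual_id", "rho_plus", "rho_minus"))
  counts <- base::table(table$individual_id)
  ok_ids <- names(counts)[counts >= 2L]
  n_skipped <- sum(counts < 2L)
  if (length(ok_ids) < 5L)
    stop("need at least 5 individuals with >= 2 chunks", call. = FALSE)
  sub <- table[table$individual_id %in% ok_ids, , drop = FALSE]
  var_gain <- tapply(sub$rho_plus, sub$individual_id, stats::var)
  var_loss <- tapply(sub$rho_minus, sub$individual_id, stats::var)
  per <- data.frame(individual_id = names(var_gain),
                    var_rho_plus = as.numeric(var_gain),
                    var_rho_minus = as.numeric(var_loss[names(var_gain)]))
  list(per_individual = per,
       test = wilcoxon_paired(per$var_rho_plus, per$var_rho_minus),
       n_skipped = n_skipped)
}

# Shared LMM fitting core. `hier_term` is either "elo_sq" or "cop".
fit_lmm_core <- function(table, response, hier_term, reml) {
  stopifnot_cols(table, c(response, "individual_id", "elo_z",
                          "experience_z", "age_category", "sex",
                          if (hier_term == "cop") "cop"))
  df <- data.frame(
    y = table[[response]],
    age_category = droplevels(factor(table$age_category,
                                     levels = c("adult", "subadult",
                                                "juvenile"))),
    sex = droplevels(factor(table$sex, levels = c("male", "female"))),
    elo_z = table$elo_z,
    experience_z = table$experience_z,
    individual_id = factor(table$individual_id))
  df$elo_sq <- df$elo_z^2
  if (hier_term == "cop") df$cop <- table$cop
  if (length(unique(df$individual_id)) < 2L)
    stop("mixed model needs at least 2 individuals", call. = FALSE)
  terms <- c(
    if (nlevels(df$age_category) > 1L) "age_category",
    if (nlevels(df$sex) > 1L) "sex",
    "elo_z", hier_term, "experience_z")
  # drop covariates that are constant in this table (e.g. a constant COP
  # column would be collinear with the intercept)
  degenerate <- vapply(terms, function(tm) {
    v <- df[[tm]]
    is.numeric(v) && stats::var(v) < 1e-12
  }, logical(1))
  if (any(degenerate))
    warning("dropping constant covariate(s): ",
            paste(terms[degenerate], collapse = ", "), call. = FALSE)
  terms <- terms[!degenerate]
  form <- stats::as.formula(paste(
    "y ~", paste(terms, collapse = " + "), "+ (1 | individual_id)"))
  model <- lmerTest::lmer(form, data = df, REML = reml)
  singular <- lme4::isSingular(model)
  coefs <- as.data.frame(summary(model)$coefficients)
  names(coefs) <- c("estimate", "se", "df", "t", "p_value")
  ci <- stats::confint(model, parm = "beta_", method = "Wald", level = 0.95)
  coefs$ci_lower <- ci[rownames(coefs), 1]
  coefs$ci_upper <- ci[rownames(coefs), 2]
  vc <- as.data.frame(lme4::VarCorr(model))
  tau00 <- vc$vcov[vc$grp == "individual_id"]
  sigma2 <- vc$vcov[vc$grp == "Residual"]
  icc <- tau00 / (tau00 + sigma2)
  # Nakagawa-style R2 for a Gaussian random-intercept model
  beta <- lme4::fixef(model)
  X <- stats::model.matrix(model)
  var_fixed <- stats::var(as.numeric(X %*% beta))
  r2_marginal <- var_fixed / (var_fixed + tau00 + sigma2)
  r2_conditional <- (var_fixed + tau00) / (var_fixed + tau00 + sigma2)
  structure(list(
    response = response,
    hier_term = hier_term,
    formula = form,
    coefficients = coefs,
    sigma2 = sigma2, tau00 = tau00, icc = icc,
    r2_marginal = r2_marginal, r2_conditional = r2_conditional,
    n_individuals = length(unique(df$individual_id)),
    n_obs = nrow(df),
    aic = stats::AIC(model),
    reml = reml,
    singular = singular,
    model = model
  ), class = "lmm_result")
}

#' Mixed model of a PT parameter on hierarchy and demographics
#'
#' Fits `response ~ age_category + sex + elo_z + elo_z^2 + experience_z
#' + (1 | individual_id)` by REML. The quadratic Elo term is the square
#' of the z-scored Elo column, so a positive coefficient is a U-shape
#' over rank (and a negative one an inverted U).
#'
#' @param table Assembled analysis data.frame (see [assemble_table()]).
#' @param response Response column; one of `rho_plus`, `rho_minus`,
#'   `log_alpha_plus`, `log_alpha_minus`, `log_lam` (any numeric column
#'   is accepted).
#' @param reml Fit by REML (default) or ML (needed for AIC comparisons
#'   across fixed-effect structures).
#' @return Object of class `lmm_result`: coefficient table with 95% CI
#'   and two-sided P, variance components (`sigma2`, `tau00`), `icc`,
#'   Nakagawa marginal/conditional R2, `aic`, and the underlying `lmer`
#'   model. A singular random-effect fit sets `singular = TRUE`.
#' @export
fit_lmm <- function(table, response, reml = TRUE) {
  fit_lmm_core(table, response, "elo_sq", reml)
}

#' Mixed model with COP replacing the quadratic Elo term
#'
#' Identical contract to [fit_lmm()] with conflict outcome
#' predictability (`cop`) in place of `elo_z^2`: the linear Elo term is
#' kept, the quadratic term is replaced.
#'
#' @inheritParams fit_lmm
#' @return An `lmm_result`.
#' @export
fit_lmm_cop <- function(table, response, reml = TRUE) {
  fit_lmm_core(table, response, "cop", reml)
}

#' @export
print.lmm_result <- function(x, ...) {
  cat(sprintf("LMM: %s (%s term)%s\n", x$response, x$hier_term,
              if (x$singular) " [singular fit]" else ""))
  print(round(x$coefficients[, c("estimate", "ci_lower", "ci_upper",
                                 "p_value")], 3))
  cat(sprintf("sigma2 %.3f  tau00 %.3f  ICC %.2f  R2m/R2c %.3f/%.3f  N %d obs %d\n",
              x$sigma2, x$tau00, x$icc, x$r2_marginal, x$r2_conditional,
              x$n_individuals, x$n_obs))
  invisible(x)
}

#' Model-assumption diagnostics for an LMM fit
#'
#' Residual normality (Shapiro-Wilk on up to 5000 residuals) and a
#' Breusch-Pagan-style homoscedasticity check (regression of squared
#' residuals on fitted values). Reported for inspection only; never used
#' to gate a fit.
#'
#' @param result An `lmm_result`.
#' @return Data.frame of diagnostic statistics and P-values.
#' @export
lmm_diagnostics <- function(result) {
  stopifnot(inherits(result, "lmm_result"))
  res <- stats::residuals(result$model)
  fitted <- stats::fitted(result$model)
  sw <- stats::shapiro.test(if (length(res) > 5000) sample(res, 5000) else res)
  bp <- summary(stats::lm(I(res^2) ~ fitted))
  fstat <- bp$fstatistic
  data.frame(
    check = c("residual_normality", "homoscedasticity"),
    statistic = c(unname(sw$statistic), unname(fstat[1])),
    p_value = c(sw$p.value,
                stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE)))
}

#' Simulate a response column under a known mixed-model structure
#'
#' Given a design table (covariates and individual ids), draws
#' `y = X beta + b_i + e` with `b_i ~ N(0, tau00)` per individual and
#' `e ~ N(0, sigma2)` per row. Used for type-I-error and power
#' simulations of [fit_lmm()].
#'
#' @param table Design data.frame with `individual_id`, `elo_z`,
#'   `experience_z`, `age_category`, `sex` (and `cop` if used in
#'   `beta`).
#' @param beta Named vector of fixed effects over any of `intercept`,
#'   `elo_z`, `elo_sq`, `cop`, `experience_z`; missing names are 0.
#' @param tau00 Between-individual intercept variance.
#' @param sigma2 Residual variance.
#' @param seed Integer seed.
#' @return The table with a new `y_sim` column.
#' @export
simulate_lmm_response <- function(table, beta = c(), tau00 = 0.07,
                                  sigma2 = 0.06, seed = NULL) {
  b <- function(nm) if (nm %in% names(beta)) beta[[nm]] else 0
  mu <- b("intercept") + b("elo_z") * table$elo_z +
    b("elo_sq") * table$elo_z^2 + b("experience_z") * table$experience_z +
    (if ("cop" %in% names(table)) b("cop") * table$cop else 0)
  ids <- unique(table$individual_id)
  with_seed(seed, {
    u <- stats::setNames(stats::rnorm(length(ids), 0, sqrt(tau00)), ids)
    table$y_sim <- mu + u[as.character(table$individual_id)] +
      stats::rnorm(nrow(table), 0, sqrt(sigma2))
    table
  })
}
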