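---
title: "Modelling risk attitudes and social rank from longitudinal choice logs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling risk attitudes and social rank from longitudinal choice logs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ptrank)
```

## The scientific problem

Group-living primates tested on freely accessible touchscreen devices
produce two longitudinal data streams at once: hundreds of thousands of
two-lottery economic choices, and displacement events (one animal
supplanting another at a device) that track the dominance hierarchy day by
day. `ptrank` implements the full analysis chain that connects the two:
fit a Prospect Theory (PT) model to consecutive windows of choices, track
social rank with Elo-ratings, and ask — with mixed models — whether an
individual's position in the hierarchy predicts its risk attitudes.

## The behavioural model

Each trial presents two lotteries. A lottery delivers `x` tokens
(a non-zero integer in −3..+3) with probability `p` (0.25, 0.50, 0.75 or
1.00), and zero tokens otherwise. The model has seven parameters per
individual and window:

* **Utility curvature.** `u(x) = x^(1−ρ+)` for gains and
  `u(x) = −λ(−x)^(1+ρ−)` for losses, with `u(0) = 0`. In this gauge
  `ρ = 0` is risk neutrality: `ρ+ > 0` bends the gain branch concave
  (risk aversion) and `ρ− < 0` bends the loss branch convex (risk
  seeking). Note that some textbook parameterisations put neutrality at an
  exponent of 1; here the exponent is `1 − ρ+` (gains) and `1 + ρ−`
  (losses), so neutrality is at zero. The package follows this convention
  throughout.
* **Loss aversion.** `λ > 1` means losses loom larger than equal-sized
  gains; at unit outcome `|u(−1)|/u(1) = λ` exactly, whatever the
  curvatures.
* **Probability weighting.** The single-parameter Prelec form
  `w(p) = exp(−(−ln p)^α)`, fitted separately per outcome domain
  (`α+` for gains, `α−` for losses). `α < 1` gives the classic
  inverted-S (overweighting of small probabilities), `α > 1` an S-shape;
  `w` crosses the identity only at `p = e^{−1}` and `p = 1`.
* **Choice rule.** `P(right) = 1/(1 + exp(−(μ·Δ + x0)))` with
  `Δ = w(p_R)u(x_R) − w(p_L)u(x_L)`. `μ ≥ 0` is the steepness of
  value-guided responding (0 = random choice) and `x0` a side bias
  (`x0 > 0` favours the right-hand option at equal value). The sign
  convention is chosen so that both stated interpretations hold: larger
  `μ` means sharper responding, and positive `x0` means right-side bias.

At the neutral point (`ρ± = 0`, `λ = 1`, `α± = 1`, `x0 = 0`) the
subjective value of a lottery reduces exactly to its expected value, a
property the test-suite asserts.

## Fitting and the 1500-trial window

`fit_chunk()` maximises the choice likelihood over a bounded box
(defaults: `ρ± ∈ [−0.95, 0.95]`, `λ ∈ [0.05, 15]`, `α± ∈ [0.05, 5]`,
`μ ∈ [0, 25]`, `x0 ∈ [−10, 10]`) with L-BFGS-B from multiple starts —
one at the neutral parameters, the rest uniform in the box (default 10
starts) — because the likelihood is multimodal in `(α, μ)`. Trials are
collapsed onto their unique lottery-pair design points first, so one
likelihood evaluation costs the number of distinct pairs (≤ ~200), not
the number of trials; an analytic gradient makes a 10-start fit of a
1500-trial chunk take a fraction of a second. Choice probabilities are
floored at 1e−12 so the objective stays finite at extreme steepness.

All seven parameters are fitted **jointly** on a window's gain and loss
trials. The shared `μ` is what makes `λ` identifiable at all when every
pair lives in a single domain: on loss-only trials the likelihood is
exactly invariant under `(λ, μ) → (cλ, μ/c)`, so a per-domain steepness
would leave a flat `(λ, μ−)` profile. The suite demonstrates this
flatness directly. Windows with no loss trials are fitted but flagged
(`loss_identifiable = FALSE`): `ρ−`, `α−` and `λ` have a flat profile
there and must not be interpreted.

The window length is justified by a recovery simulation
(`trial_requirement_curve()`): simulated players with true parameters
drawn uniformly in the fitting box are refitted on the first
`n ∈ {250, 500, 1000, 1500, 3000}` trials of their choice stream. The
error metric — the package's own choice, recorded in the output
metadata — is the absolute error standardised by each parameter's box
width, averaged over the five PT parameters and over players. The error
declines steeply up to roughly 1500 trials and is nearly flat beyond,
which is why 1500 decisions is the unit of all downstream analysis.

## Hierarchy measures

`compute_elo()` implements the classical Elo scheme: everyone starts at
1000 and, after each displacement, the winner gains
`k(1 − E_w)` points (the loser loses the same; `k = 100`), where
`E_w = 1/(1 + 10^{(r_l − r_w)/400})` is the winner's expected score.
Points are conserved at every update. The daily rating is the value
after the day's last event, carried forward over event-free days. The
external Elo package used in the original analyses does not document its
internal expectation function, so exact numeric parity with it is not
promised — parity with the rule above is, and is verified against a
hand-computed sequential oracle.

Conflict outcome predictability (COP) over a window is
`|wins − losses| / conflicts`: 1 means fully predictable outcomes, 0 a
coin flip; zero conflicts give a missing value, not 0.
`align_hierarchy_to_chunks()` attaches to each 1500-trial window the mean
daily Elo over the window's time span and the COP over the same span.

## Filtering and the analysis table

Chunk fits are filtered by the Tukey/IQR rule: fences
`Q1 − 1.5·IQR` and `Q3 + 1.5·IQR` are computed per parameter (`ρ+`,
`ρ−`, `α+`, `α−`, `λ`) on the distribution pooled across all
individuals' windows, and a window is removed when **any** of its five
parameters leaves its fence. Quartiles use linear interpolation (R
quantile type 7), recorded in the `FilterReport` so fences are
reproducible. The window (not the single parameter value) is the unit of
removal, since each downstream model row is a window. Fully one-sided
windows (side bias = 1), whose likelihood carries no information about
the value parameters, are removed in the same step and reported
separately. Individuals with fewer than 10 remaining windows are then
excluded (exactly 10 stays).

`assemble_table()` joins fits, hierarchy measures and metadata, applies
natural logs to `λ` and `α±` (their distributions are skewed;
0.1–1–10 are symmetric intensities on the log scale), z-scores the mean
Elo and the experience covariate (the mean cumulative trial index of the
window — accumulated task exposure, not a window-local count), and
assigns age categories at the window's midpoint date: juvenile < 4
years; subadult 4–8 (males) / 4–7 (females), upper bound exclusive;
adult otherwise.

## The mixed models

For each response (`ρ+`, `ρ−`, `log α+`, `log α−`, `log λ`):

```
response ~ age_category + sex + elo_z + elo_z² + experience_z + (1 | individual)
```

REML, random intercept only (no random slopes: each individual samples
only a narrow band of the rank axis, so individual slopes are not
identified), reference levels adult and male, two-sided P-values with a
conservative 0.01 threshold. Because `elo_z` is z-scored, the `elo_z²`
coefficient reads directly as curvature over rank: positive = U-shape
(extremes high), negative = inverted U. `fit_lmm_cop()` swaps the
quadratic term for the COP score, which is itself U-shaped in rank and
so can account for the same structure. Reported alongside the
coefficients: the variance components `σ²` (residual) and `τ00`
(individual intercepts), `ICC = τ00/(τ00 + σ²)`, and Nakagawa-style
marginal/conditional R² (computed in closed form for the Gaussian
random-intercept case). Residual-normality and homoscedasticity
diagnostics are emitted by `lmm_diagnostics()` for inspection; they
never gate a fit.

## The synthetic cohort

`generate_cohort()` produces a complete, ground-truthed dataset. Its
defaults are the study conditions the package is designed for: 18
individuals (11 males), 40 months of activity, 75,000 trials each (50
windows), ages ~7.2 ± 4.6 years. Dyadic conflicts are a Poisson process
(10/day) between uniformly sampled pairs; the stronger individual wins
with probability `plogis(Δstrength / 0.5)`, so closely matched
(middle-ranking) pairs have intrinsically unpredictable outcomes — this
is the mechanism that makes COP U-shaped over rank in the generated
data, and it emerges rather than being painted on.

Base PT parameters are drawn per individual around group means
`ρ+ = 0.182`, `ρ− = −0.508`, `λ = 2.987`, `α+ = 1.208`, `α− = 0.655`
(log-normal for `λ`, `α±`), with `μ = 5 ± 1` and `x0 = 0 ± 0.2` as the
generator's own choices for a well-trained animal. Between-individual
sds (0.10–0.40 depending on the parameter) were chosen once to put the
mixed-model ICC in the 0.5–0.6 regime; chunk-level jitter sds
(0.08–0.15) set the within-individual variance on top of ~1500-trial
estimation noise. Each window's true parameters are
`base + link·z²_Elo + jitter` where `z_Elo` is the concurrent z-scored
mean Elo of the window — so longitudinal rank changes propagate into
risk-attitude changes. The default link coefficients are `+0.08` on
`ρ+`, `−0.10` on `log α+`, `−0.25` on `log λ`, and zero in the loss
domain; an alternative `link_variable = "cop"` drives parameters from
COP instead, for model-comparison exercises.

What the generator does **not** emulate: real macaque social dynamics
(coalitions, matrilines, rank inheritance), drifting motivation or
session structure, satiety, learning within the task, or unequal trial
counts across individuals. Passing the end-to-end tests therefore shows
that the pipeline recovers the structure it assumes from data of
realistic size and noise — not that the biological claims are true of
any particular dataset.

## Problem sizes used by the validation suite

The package's own validation runs at desk scale, chosen a priori:

* recovery curve: 25 agents × grid {250, 500, 1000, 1500, 3000}, full
  10-start fits;
* end-to-end recovery: 20 cohorts of 18 individuals × 40 windows
  (60,000 trials each, ~700 analysis rows after filtering — near the
  ~900-observation scale the mixed models target), fitted with 2
  optimizer starts — on cohort-scale data a single neutral start already
  reaches the same optima as 10 random starts (checked on a held-out
  cohort: negative log-likelihoods agree to 5e−6), because true
  parameters sit well inside the box;
* type-I control: one rank-link-free cohort's hierarchy design, 200
  simulated-response mixed-model replicates at `τ00 = 0.07`,
  `σ² = 0.06` (full pipeline replicates at that count are not
  desk-scale; the replicate unit is the model table).

## Numerical choices and degenerate inputs

* Choice probabilities floored at 1e−12 in the likelihood; `plogis` with
  `log.p` keeps evaluation overflow-safe at `|μΔ|` in the thousands.
* Optimizer: L-BFGS-B, analytic gradient, `factr = 1e7`, up to 300
  iterations per start; the fitted optimum never exceeds the
  neutral-start objective (asserted per fit).
* Degenerate IQR (all values equal) collapses fences to the quartiles —
  identical windows are all retained and flagged in the report.
* Dense ordinal ranks: tied ratings share a rank; rows are ordered by
  rank then identifier.
* Windows with zero conflicts or no rating days yield missing COP/Elo
  and are dropped from the analysis table with a logged count.
* A constant COP column (collinear with the intercept) is dropped from
  the model with a warning rather than producing an unstable fit.

## Known limitations

* Loss-domain parameters are only as identifiable as the loss-trial
  share of a window; the package flags but does not impute.
* Elo values depend on `k` and the expectation scale; comparisons across
  configurations are not meaningful (z-scoring inside the analysis table
  removes the scale for the models).
* The mixed models treat windows as exchangeable within individual
  beyond the experience covariate; temporal autocorrelation of
  consecutive windows is not modelled.
* Mixed-domain (gain-vs-loss) pairs are supported by the battery
  generator but off by default; whether the live task presented them is
  not established, and λ identifiability changes materially when they
  are present.
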