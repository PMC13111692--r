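# Orchestration: chunking trial logs, outlier filtering of chunk fits by
# the IQR rule, individual exclusions, and assembly of the per-chunk
# analysis table that feeds the mixed models.

IQR_PARAMETERS <- c("rho_plus", "rho_minus", "alpha_plus", "alpha_minus", "lam")

#' Segment trial logs into consecutive fixed-size chunks
#'
#' Assigns each trial (per individual, in chronological order) to
#' consecutive non-overlapping windows of exactly `size` decisions; the
#' trailing remainder shorter than `size` gets `NA`. Individuals with
#' fewer than `size` trials contribute no complete chunk.
#'
#' @param trials Trial-log data.frame sorted by `trial_index` within
#'   individual.
#' @param size Window length in decisions (default 1500).
#' @return The input with an added integer `chunk_index` column (1-based;
#'   `NA` for dropped remainder trials).
#' @export
chunk_trials <- function(trials, size = 1500) {
  stopifnot_cols(trials, c("individual_id", "trial_index"))
  stopifnot(size >= 1)
  ord <- order(trials$individual_id, trials$trial_index)
  trials <- trials[ord, , drop = FALSE]
  pos <- stats::ave(seq_len(nrow(trials)), trials$individual_id,
                    FUN = seq_along)
  n_per <- stats::ave(seq_len(nrow(trials)), trials$individual_id,
                      FUN = length)
  idx <- (pos - 1L) %/% size + 1L
  idx[pos > (n_per %/% size) * size] <- NA_integer_
  trials$chunk_index <- idx
  rownames(trials) <- NULL
  trials
}

#' Restrict a trial log to a date window
#'
#' Input logs are assumed to contain test-phase trials only; when they do
#' not (e.g. training phases are present at the head of the log), this
#' restricts records to `[start, end]` by timestamp. `NULL` bounds are
#' open.
#'
#' @param trials Trial-log data.frame with a `timestamp` column.
#' @param start,end POSIXct (or coercible) window bounds, inclusive.
#' @return The filtered trial log.
#' @export
filter_date_window <- function(trials, start = NULL, end = NULL) {
  stopifnot_cols(trials, "timestamp")
  keep <- rep(TRUE, nrow(trials))
  if (!is.null(start)) keep <- keep & trials$timestamp >= as.POSIXct(start, tz = "UTC")
  if (!is.null(end)) keep <- keep & trials$timestamp <= as.POSIXct(end, tz = "UTC")
  trials[keep, , drop = FALSE]
}

#' Side bias of a choice log
#'
#' The larger of the fractions of left and right choices; 0.5 means
#' perfectly balanced responding, 1 a fully one-sided log.
#'
#' @param records Trial-log data.frame with a `choice` column.
#' @return Scalar in [0.5, 1].
#' @export
side_bias <- function(records) {
  if (nrow(records) == 0L) stop("empty record list", call. = FALSE)
  fr <- mean(records$choice == "right")
  max(fr, 1 - fr)
}

#' IQR outlier filtering of chunk fits
#'
#' Computes, for each of the five PT parameters (`rho_plus`, `rho_minus`,
#' `alpha_plus`, `alpha_minus`, `lam`), Tukey fences `Q1 - 1.5 IQR` and
#' `Q3 + 1.5 IQR` on the distribution pooled across all individuals'
#' chunks (quartiles by linear interpolation, R quantile type 7). A chunk
#' is removed when any of its five parameters falls outside its fence.
#' Chunks from fully one-sided responding (`side_bias == 1`), whose
#' parameters are unconstrained by the data, are also removed when
#' `drop_onesided` is set.
#'
#' @param fits Chunk-fit data.frame from [fit_chunks()] (>= 4 rows when
#'   fences are computed).
#' @param fences Optional frozen fences data.frame from a previous
#'   report; when supplied, fences are reused instead of recomputed.
#' @param drop_onesided Remove `side_bias == 1` chunks (default TRUE).
#' @return List with `retained` (filtered data.frame) and `report` (class
#'   `filter_report`: fences, counts, removed chunks with reasons).
#' @export
iqr_filter <- function(fits, fences = NULL, drop_onesided = TRUE) {
  stopifnot_cols(fits, IQR_PARAMETERS)
  if (is.null(fences)) {
    if (nrow(fits) < 4L)
      stop("need at least 4 pooled chunks to compute IQR fences", call. = FALSE)
    fences <- do.call(rbind, lapply(IQR_PARAMETERS, function(p) {
      q <- stats::quantile(fits[[p]], c(0.25, 0.75), type = 7, names = FALSE)
      iqr <- q[2] - q[1]
      data.frame(parameter = p, q1 = q[1], q3 = q[2],
                 lower = q[1] - 1.5 * iqr, upper = q[2] + 1.5 * iqr,
                 degenerate = iqr == 0)
    }))
    rownames(fences) <- NULL
  }
  out_of_fence <- rep(FALSE, nrow(fits))
  reason <- rep(NA_character_, nrow(fits))
  for (i in seq_len(nrow(fences))) {
    p <- fences$parameter[i]
    bad <- fits[[p]] < fences$lower[i] | fits[[p]] > fences$upper[i]
    reason[bad & !out_of_fence] <- p
    out_of_fence <- out_of_fence | bad
  }
  onesided <- if (drop_onesided && "side_bias" %in% names(fits))
    fits$side_bias >= 1 else rep(FALSE, nrow(fits))
  reason[onesided & !out_of_fence] <- "one_sided"
  removed <- out_of_fence | onesided
  report <- structure(list(
    fences = fences,
    quantile_type = 7L,
    n_input = nrow(fits),
    n_removed = sum(removed),
    n_onesided = sum(onesided),
    removed = cbind(fits[removed, c("individual_id", "chunk_index"),
                         drop = FALSE],
                    reason = reason[removed])
  ), class = "filter_report")
  list(retained = fits[!removed, , drop = FALSE], report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("IQR filter: removed %d of %d chunks (%d one-sided)\n",
              x$n_removed, x$n_input, x$n_onesided))
  print(x$fences, digits = 4)
  invisible(x)
}

#' Exclude individuals with too few retained chunks
#'
#' After outlier filtering, individuals with fewer than `min_chunks`
#' remaining windows are dropped from the analysis ("less than" is
#' strict: exactly `min_chunks` chunks is enough to stay). A side-bias
#' summary (mean +/- sd of per-individual mean side bias) is reported for
#' the excluded and retained groups.
#'
#' @param fits Retained chunk-fit data.frame (post [iqr_filter()]).
#' @param min_chunks Minimum retained chunks to keep an individual
#'   (default 10).
#' @param roster Optional full cohort roster; individuals whose chunks
#'   were all removed upstream (absent from `fits`) are then reported as
#'   excluded rather than silently dropped.
#' @return List with `retained` (data.frame), `roster` (kept ids),
#'   `excluded` (dropped ids) and `side_bias_summary`.
#' @export
exclude_individuals <- function(fits, min_chunks = 10, roster = NULL) {
  counts <- table(fits$individual_id)
  keep_ids <- names(counts)[counts >= min_chunks]
  drop_ids <- setdiff(unique(c(names(counts), roster)), keep_ids)
  if (length(keep_ids) == 0L)
    stop("all individuals excluded: no one has enough retained chunks",
         call. = FALSE)
  sb <- function(ids) {
    if (length(ids) == 0L || !"side_bias" %in% names(fits))
      return(c(mean = NA_real_, sd = NA_real_))
    per <- tapply(fits$side_bias[fits$individual_id %in% ids],
                  fits$individual_id[fits$individual_id %in% ids], mean)
    c(mean = mean(per), sd = stats::sd(per))
  }
  list(retained = fits[fits$individual_id %in% keep_ids, , drop = FALSE],
       roster = keep_ids, excluded = drop_ids,
       side_bias_summary = rbind(excluded = sb(drop_ids),
                                 retained = sb(keep_ids)))
}

#' Age category at a given age
#'
#' Juveniles are individuals under 4 years; subadults are 4-8 years
#' (males) or 4-7 years (females), upper bound exclusive; everyone older
#' is an adult. Vectorised.
#'
#' @param age_years Numeric age(s) in years, >= 0.
#' @param sex `"male"` or `"female"` (recycled).
#' @return Factor with levels `adult`, `subadult`, `juvenile` (adult
#'   first, as the model reference).
#' @export
age_category <- function(age_years, sex) {
  stopifnot(all(age_years >= 0), all(sex %in% c("male", "female")))
  upper <- ifelse(sex == "male", 8, 7)
  out <- ifelse(age_years < 4, "juvenile",
                ifelse(age_years < upper, "subadult", "adult"))
  factor(out, levels = c("adult", "subadult", "juvenile"))
}

#' Assemble the per-chunk analysis table
#'
#' Inner-joins retained chunk fits with chunk-aligned hierarchy measures
#' and individual metadata, applies the natural-log transform to `lam`,
#' `alpha_plus`, `alpha_minus`, z-scores the Elo and experience columns
#' on the assembled table, and derives the age category at each chunk's
#' midpoint date. Chunks without hierarchy overlap are dropped with a
#' message.
#'
#' @param fits Retained chunk-fit data.frame.
#' @param hierarchy Output of [align_hierarchy_to_chunks()].
#' @param metadata Data.frame with `individual_id`, `sex`, `birth_date`.
#' @return Analysis data.frame: one row per chunk with raw and z-scored
#'   covariates (`elo_z`, `experience_z`), `log_lam`, `log_alpha_plus`,
#'   `log_alpha_minus`, `age_category`, `sex`, `cop`.
#' @export
assemble_table <- function(fits, hierarchy, metadata) {
  stopifnot_cols(metadata, c("individual_id", "sex", "birth_date"))
  tab <- merge(fits, hierarchy, by = c("individual_id", "chunk_index"))
  orphan <- is.na(tab$mean_elo)
  if (any(orphan)) {
    message(sum(orphan), " chunk(s) without hierarchy overlap dropped")
    tab <- tab[!orphan, , drop = FALSE]
  }
  tab <- merge(tab, metadata[, c("individual_id", "sex", "birth_date")],
               by = "individual_id")
  midpoint <- as.Date(tab$t_start) + as.numeric(as.Date(tab$t_end) -
                                                  as.Date(tab$t_start)) / 2
  age <- as.numeric(midpoint - as.Date(tab$birth_date)) / 365.25
  tab$age_years <- age
  tab$age_category <- age_category(age, tab$sex)
  tab$sex <- factor(tab$sex, levels = c("male", "female"))
  tab$log_lam <- log(tab$lam)
  tab$log_alpha_plus <- log(tab$alpha_plus)
  tab$log_alpha_minus <- log(tab$alpha_minus)
  tab$experience <- tab$mean_trial_index
  tab$elo_z <- as.numeric(scale(tab$mean_elo))
  tab$experience_z <- as.numeric(scale(tab$experience))
  tab <- tab[order(tab$individual_id, tab$chunk_index), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Run the full analysis pipeline
#'
#' Chunk, fit, compute hierarchy measures, filter, exclude, and assemble:
#' trial log + displacement log + metadata in, per-chunk analysis table
#' out. Deterministic given the inputs and `fit_config$seed`.
#'
#' @param trials Trial-log data.frame.
#' @param events Displacement-event data.frame.
#' @param metadata Data.frame with `individual_id`, `sex`, `birth_date`.
#' @param fit_config A [fit_config()].
#' @param elo_config An [elo_config()].
#' @param chunk_size Decisions per window (default 1500).
#' @param min_chunks Minimum retained chunks per individual (default 10).
#' @return List of class `ptrank_pipeline`: `table` (analysis rows),
#'   `fits` (all chunk fits), `filter_report`, `exclusion`, `elo`
#'   (trajectory), `hierarchy` (chunk-aligned measures),
#'   `trials_discarded_fraction`.
#' @export
run_pipeline <- function(trials, events, metadata,
                         fit_config = ptrank::fit_config(),
                         elo_config = ptrank::elo_config(),
                         chunk_size = 1500, min_chunks = 10) {
  fits <- fit_chunks(trials, fit_config, chunk_size)
  date_range <- range(c(as.Date(trials$timestamp), as.Date(events$timestamp)))
  elo <- compute_elo(events, roster = unique(metadata$individual_id),
                     config = elo_config, date_range = date_range)
  hier <- align_hierarchy_to_chunks(elo, events, fits)
  filt <- iqr_filter(fits)
  excl <- exclude_individuals(filt$retained, min_chunks = min_chunks,
                              roster = unique(metadata$individual_id))
  tab <- assemble_table(excl$retained, hier, metadata)
  structure(list(
    table = tab,
    fits = fits,
    filter_report = filt$report,
    exclusion = excl,
    elo = elo,
    hierarchy = hier,
    trials_discarded_fraction = 1 - nrow(tab) * chunk_size /
      (nrow(fits) * chunk_size)
  ), class = "ptrank_pipeline")
}

#' @export
print.ptrank_pipeline <- function(x, ...) {
  cat(sprintf(paste0(
    "ptrank pipeline: %d analysis rows, %d individuals retained ",
    "(%d excluded), %.1f%% of chunked trials discarded\n"),
    nrow(x$table), length(unique(x$table$individual_id)),
    length(x$exclusion$excluded), 100 * x$trials_discarded_fraction))
  invisible(x)
}
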