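# Batch simulation and behavioural summaries.

#' Run a batch of seeded trials across conditions
#'
#' Builds one generative process and one agent per condition row and
#' simulates `n` independent trials of each, with per-trial seeds derived as
#' `master_seed + trial counter` (recorded in every trial record), so a
#' batch is fully reproducible from its specification and master seed.
#'
#' @param specs data frame with one row per condition. Recognised columns
#'   (all optional except the first three): `context`, `emotion`, `type`,
#'   `variant` (default `"contextualising"`), `z`, `z_tf`, `z_sc`, `mode`
#'   (default `"stochastic"`), `label`.
#' @param n number of trials per condition row.
#' @param master_seed integer master seed.
#' @param horizon,max_iters,tol,learning_rate numerical settings forwarded
#'   to [build_generative_model()].
#' @return a list of `trial_record` objects (see [run_trial()]), each
#'   annotated with its condition label.
#' @export
run_batch <- function(specs, n = 200L, master_seed = 1L, horizon = 8L,
                      max_iters = 64L, tol = 1e-4, learning_rate = 0.25) {
  stopifnot(is.data.frame(specs), n >= 1L)
  records <- vector("list", nrow(specs) * n)
  counter <- 0L
  base <- build_generative_model(horizon = horizon, max_iters = max_iters,
                                 tol = tol, learning_rate = learning_rate)
  for (r in seq_len(nrow(specs))) {
    row <- specs[r, ]
    proc <- build_generative_process(row$context, row$emotion, row$type)
    model <- make_agent_variant(
      base,
      variant = if ("variant" %in% names(specs)) row$variant else "contextualising",
      z = if ("z" %in% names(specs) && !is.na(row$z)) row$z else NULL,
      z_tf = if ("z_tf" %in% names(specs) && !is.na(row$z_tf)) row$z_tf else NULL,
      z_sc = if ("z_sc" %in% names(specs) && !is.na(row$z_sc)) row$z_sc else NULL)
    mode <- if ("mode" %in% names(specs)) row$mode else "stochastic"
    label <- if ("label" %in% names(specs)) row$label else {
      paste(row$context, row$emotion, row$type, sep = "/")
    }
    for (k in seq_len(n)) {
      counter <- counter + 1L
      rec <- run_trial(proc, model, mode = mode, seed = master_seed + counter)
      rec$condition$label <- label
      records[[counter]] <- rec
    }
  }
  records
}

# decision time with undecided trials censored at the horizon
censored_decision_time <- function(rec) {
  if (is.na(rec$decision_time)) rec$horizon else rec$decision_time
}

#' Summarise behavioural performance per condition class
#'
#' Decision time is the time-step index of the report fixation (the initial
#' central fixation is step 1). Undecided trials (no report within the
#' horizon) are excluded from the accuracy denominator and counted
#' separately; their decision times are reported censored at the horizon.
#'
#' @param records list of `trial_record`s.
#' @param by grouping field: `"colour"` (congruence/coherence class) or
#'   `"label"` (condition row).
#' @return a data frame with one row per class: trial counts, decided and
#'   undecided counts, mean/sd decision time among decided trials, mean
#'   censored decision time over all trials, and accuracy among decided
#'   trials (`NA` where undefined).
#' @export
compute_metrics <- function(records, by = c("colour", "label")) {
  by <- match.arg(by)
  if (length(records) == 0L) stop_config("no trial records supplied")
  cls <- vapply(records, function(r) r$condition[[by]], character(1))
  out <- lapply(split(records, cls), function(rs) {
    dt <- vapply(rs, function(r) r$decision_time, numeric(1))
    cens <- vapply(rs, censored_decision_time, numeric(1))
    ok <- vapply(rs, function(r) isTRUE(r$correct), logical(1))
    decided <- !is.na(dt)
    data.frame(
      class = rs[[1L]]$condition[[by]],
      n = length(rs),
      n_decided = sum(decided),
      n_undecided = sum(!decided),
      mean_decision_time = if (any(decided)) mean(dt[decided]) else NA_real_,
      sd_decision_time = if (sum(decided) > 1L) stats::sd(dt[decided]) else NA_real_,
      mean_censored_time = mean(cens),
      accuracy = if (any(decided)) mean(ok[decided]) else NA_real_,
      stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Fixation-location histogram
#'
#' @param records list of `trial_record`s.
#' @return integer vector of length 9: total fixations per location.
#' @export
fixation_histogram <- function(records) {
  tabulate(unlist(lapply(records, function(r) r$where)), nbins = 9L)
}

#' Compare decision times between two sets of trials
#'
#' Compares horizon-censored decision times between two groups by the
#' difference in means with a seeded bootstrap percentile interval and a
#' rank-based two-sample test. Degenerate (constant) samples yield a
#' zero-width interval.
#'
#' @param records_a,records_b lists of `trial_record`s for the two groups.
#' @param n_boot bootstrap replicates.
#' @param seed seed for the bootstrap resampling.
#' @return a list: group means, `diff` (a minus b), `ci` (95% percentile
#'   interval on the difference), `p_value` (Wilcoxon rank-sum), and
#'   `direction` (`"a_faster"`, `"b_faster"` or `"tied"`).
#' @export
compare_conditions <- function(records_a, records_b, n_boot = 2000L,
                               seed = 1L) {
  if (!length(records_a) || !length(records_b)) {
    stop_config("both groups must contain at least one trial")
  }
  ta <- vapply(records_a, censored_decision_time, numeric(1))
  tb <- vapply(records_b, censored_decision_time, numeric(1))
  d <- mean(ta) - mean(tb)
  set.seed(seed)
  boots <- replicate(n_boot, {
    mean(ta[sample.int(length(ta), replace = TRUE)]) -
      mean(tb[sample.int(length(tb), replace = TRUE)])
  })
  ci <- unname(stats::quantile(boots, c(0.025, 0.975)))
  p <- if (stats::sd(c(ta, tb)) == 0) 1 else {
    suppressWarnings(stats::wilcox.test(ta, tb)$p.value)
  }
  list(mean_a = mean(ta), mean_b = mean(tb), diff = d, ci = ci,
       p_value = p,
       direction = if (d < 0) "a_faster" else if (d > 0) "b_faster" else "tied")
}

#' Export scan paths as a tidy fixation table
#'
#' One row per fixation, in trial order, with the scene semantics of each
#' location (quadrant and feature) for downstream plotting.
#'
#' @param records list of `trial_record`s.
#' @return a data frame with columns `trial`, `condition`, `seed`, `step`,
#'   `location`, `quadrant`, `feature`.
#' @export
scanpath_export <- function(records) {
  quadrant <- c("centre", "top_left", "top_left", "top_right", "top_right",
                "bottom_left", "bottom_left", "report", "report")
  feature <- c("fixation_cross", "eyes", "mouth", "eyes", "mouth",
               "eyes", "mouth", "report_happy", "report_sad")
  rows <- lapply(seq_along(records), function(i) {
    r <- records[[i]]
    if (r$n_steps == 0L) return(NULL)
    data.frame(trial = i,
               condition = r$condition$label %||%
                 paste(r$condition$context, r$condition$emotion,
                       r$condition$type, sep = "/"),
               seed = r$seed %||% NA_integer_,
               step = seq_len(r$n_steps),
               location = r$where,
               quadrant = quadrant[r$where],
               feature = feature[r$where],
               stringsAsFactors = FALSE)
  })
  rows <- Filter(Negate(is.null), rows)
  if (!length(rows)) {
    return(data.frame(trial = integer(0), condition = character(0),
                      seed = integer(0), step = integer(0),
                      location = integer(0), quadrant = character(0),
                      feature = character(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
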