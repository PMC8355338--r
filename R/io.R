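# Serialisation of trial records and summaries.

RECORD_SCHEMA_VERSION <- "1.0"

#' Flatten trial records into a tidy per-step table
#'
#' One row per trial step: identifiers, the fixated location, the observed
#' outcome under each modality (as level names), trial-level results
#' (decision time, reported emotion, correctness), and the posterior
#' marginals after the step's observation — all four context levels plus the
#' summed incoherent belief, all four target-face levels plus the derived
#' emotion-happy and type-ambiguous marginals, and the fixation belief.
#'
#' @param records list of `trial_record`s from [run_trial()]/[run_batch()].
#' @return a data frame, one row per trial step.
#' @export
records_to_df <- function(records) {
  expr_lv <- expression_levels()
  fb_lv <- feedback_levels()
  ctx_lv <- context_levels()
  tgt_lv <- target_levels()
  rows <- lapply(seq_along(records), function(i) {
    r <- records[[i]]
    steps <- seq_len(r$n_steps)
    ctx <- t(r$posterior[[1L]])
    tgt <- t(r$posterior[[2L]])
    wh <- t(r$posterior[[3L]])
    colnames(ctx) <- paste0("p_context_", ctx_lv)
    colnames(tgt) <- paste0("p_target_", tgt_lv)
    colnames(wh) <- paste0("p_where_", 1:9)
    cbind(
      data.frame(
        trial = i,
        condition = r$condition$label %||%
          paste(r$condition$context, r$condition$emotion, r$condition$type,
                sep = "/"),
        colour = r$condition$colour,
        variant = r$condition$variant,
        mode = r$condition$mode,
        seed = r$seed %||% NA_integer_,
        step = steps,
        location = r$where,
        obs_expression = expr_lv[r$observations[1L, ]],
        obs_where = r$observations[2L, ],
        obs_feedback = fb_lv[r$observations[3L, ]],
        converged = r$converged,
        decision_time = r$decision_time,
        reported = r$reported,
        correct = r$correct,
        stringsAsFactors = FALSE),
      ctx,
      p_context_incoherent = ctx[, "p_context_incoherent_a"] +
        ctx[, "p_context_incoherent_b"],
      tgt,
      p_emotion_happy = tgt[, "p_target_happy_unambiguous"] +
        tgt[, "p_target_happy_ambiguous"],
      p_type_ambiguous = tgt[, "p_target_happy_ambiguous"] +
        tgt[, "p_target_sad_ambiguous"],
      wh)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write trial records and summaries to disk
#'
#' Trial records are written as a tab-separated table (one row per trial
#' step, see [records_to_df()]); summaries and comparisons as a JSON
#' document carrying a schema version. A written table read back with
#' [read_records()] equals the written one.
#'
#' @param records list of `trial_record`s (or an already-flattened data
#'   frame); `NULL` to skip.
#' @param summaries any JSON-serialisable summary object; `NULL` to skip.
#' @param records_path,summary_path output file paths.
#' @return invisibly, the paths written.
#' @export
write_outputs <- function(records = NULL, summaries = NULL,
                          records_path = NULL, summary_path = NULL) {
  written <- character(0)
  if (!is.null(records) && !is.null(records_path)) {
    df <- if (is.data.frame(records)) records else records_to_df(records)
    ok <- tryCatch({
      utils::write.table(df, records_path, sep = "\t", row.names = FALSE,
                         quote = FALSE)
      TRUE
    }, error = function(e) e)
    if (!isTRUE(ok)) {
      stop_config("failed to write records to '", records_path, "': ",
                  conditionMessage(ok))
    }
    written <- c(written, records_path)
  }
  if (!is.null(summaries) && !is.null(summary_path)) {
    payload <- list(schema_version = RECORD_SCHEMA_VERSION,
                    summaries = summaries)
    ok <- tryCatch({
      jsonlite::write_json(payload, summary_path, auto_unbox = TRUE,
                           digits = NA, pretty = TRUE, na = "null")
      TRUE
    }, error = function(e) e)
    if (!isTRUE(ok)) {
      stop_config("failed to write summary to '", summary_path, "': ",
                  conditionMessage(ok))
    }
    written <- c(written, summary_path)
  }
  invisible(written)
}

#' Read back a written trial-record table
#'
#' @param path a file written by [write_outputs()].
#' @return the per-step data frame.
#' @export
read_records <- function(path) {
  if (!file.exists(path)) stop_config("no such records file: ", path)
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
}
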