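# The perception-action cycle: one simulated trial.

#' Simulate one trial of the perception-action cycle
#'
#' Runs the loop: observe outcomes emitted by the generative process at the
#' currently fixated location, update beliefs about the hidden states,
#' evaluate every policy by its free energy plus expected free energy, and
#' select the next saccade, until either a non-null feedback outcome is
#' observed (the agent has reported) or the horizon is reached. Because
#' messages are passed forward in time, all policies share the beliefs about
#' the observed past and differ only in their predicted next state, so one
#' belief update per step serves every policy.
#'
#' @param process a [build_generative_process()] (the ground-truth
#'   environment emitting observations).
#' @param model a [generative_model()] (the agent; typically
#'   [build_generative_model()] passed through [make_agent_variant()]).
#' @param mode action selection mode, `"map"` or `"stochastic"`; see
#'   [select_action()].
#' @param seed optional integer seed; a seeded trial re-run with the same
#'   configuration is identical.
#' @return an object of class `trial_record` with the fixation sequence,
#'   observations, per-step posterior marginals per factor, per-step policy
#'   posteriors and expected free energies, convergence flags, decision time
#'   (the step index of the report fixation, `NA` if undecided), the
#'   reported emotion and its correctness.
#' @export
run_trial <- function(process, model, mode = c("map", "stochastic"),
                      seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(model, "generative_model"))
  if (!inherits(process, "generative_process")) {
    stop_config("`process` must be a generative_process")
  }
  if (!identical(unname(process$n_out), unname(model$n_out)) ||
      !identical(unname(process$n_states), unname(model$n_states))) {
    stop_config("process and model disagree on outcome or state spaces")
  }
  if (!is.null(seed)) set.seed(seed)

  horizon <- model$horizon
  n_pol <- nrow(model$policies)
  nf <- model$n_factors
  where <- process$start_where
  actions <- integer(0)
  obs_log <- matrix(NA_integer_, model$n_modalities, horizon)
  where_log <- integer(0)
  posterior <- lapply(model$n_states, function(k) matrix(NA_real_, k, horizon))
  pi_log <- matrix(NA_real_, n_pol, horizon)
  G_log <- matrix(NA_real_, n_pol, horizon)
  F_log <- rep(NA_real_, horizon)
  conv <- logical(0)
  q <- NULL
  decision_time <- NA_integer_
  reported <- NA_character_
  correct <- NA

  for (t in seq_len(horizon)) {
    obs <- emit_observation(process, where)
    obs_log[, t] <- obs
    where_log[t] <- where

    prior <- if (t == 1L) model$D else {
      a <- actions[t - 1L]
      lapply(seq_len(nf), function(f) as.vector(model$B[[f]][, , a] %*% q[[f]]))
    }
    fit <- filter_step(model, prior, obs)
    q <- fit$s
    conv[t] <- fit$converged
    for (f in seq_len(nf)) posterior[[f]][, t] <- q[[f]]

    fb <- obs[process$feedback_modality]
    if (!is.na(fb) && fb != process$feedback_null) {
      decision_time <- t
      rep_match <- names(process$report_locations)[process$report_locations == where]
      reported <- if (length(rep_match)) rep_match else NA_character_
      correct <- fb == process$feedback_correct
      break
    }
    if (t == horizon) break

    F_t <- policy_free_energy(fit$eps, fit$s)
    F_pi <- rep(F_t, n_pol)
    G_pi <- vapply(seq_len(n_pol), function(p) {
      a <- model$policies[p, 1L]
      s_next <- lapply(seq_len(nf), function(f) {
        as.vector(model$B[[f]][, , a] %*% q[[f]])
      })
      expected_free_energy(model, s_next)
    }, numeric(1))
    pi_post <- policy_posterior(F_pi, G_pi)
    pi_log[, t] <- pi_post
    G_log[, t] <- G_pi
    F_log[t] <- F_t

    sel <- select_action(pi_post, mode)
    a <- model$policies[sel, 1L]
    actions <- c(actions, a)
    where <- a
  }

  n_steps <- length(where_log)
  structure(list(
    condition = list(context = process$context, emotion = process$emotion,
                     type = process$type, colour = process$colour,
                     variant = model$variant$name %||% "base", mode = mode),
    seed = seed,
    horizon = horizon,
    n_steps = n_steps,
    where = where_log,
    observations = obs_log[, seq_len(n_steps), drop = FALSE],
    posterior = lapply(posterior, function(p) p[, seq_len(n_steps), drop = FALSE]),
    pi_post = pi_log[, seq_len(n_steps), drop = FALSE],
    G = G_log[, seq_len(n_steps), drop = FALSE],
    F_pi = F_log[seq_len(n_steps)],
    converged = conv,
    actions = actions,
    decision_time = decision_time,
    reported = reported,
    correct = correct
  ), class = "trial_record")
}

#' @export
print.trial_record <- function(x, ...) {
  cat("<trial_record> ", x$condition$variant, " agent, ",
      x$condition$context, " context / ", x$condition$emotion, " ",
      x$condition$type, " target (", x$condition$colour, ")\n", sep = "")
  cat("  fixations:", paste(x$where, collapse = " -> "), "\n")
  if (is.na(x$decision_time)) {
    cat("  undecided within horizon", x$horizon, "\n")
  } else {
    cat("  reported ", x$reported, " at step ", x$decision_time,
        if (isTRUE(x$correct)) " (correct)" else " (incorrect)", "\n", sep = "")
  }
  invisible(x)
}
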