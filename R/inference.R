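# Variational state estimation.
#
# Beliefs are mean-field across hidden-state factors: each factor's
# likelihood message is the log of the precision-weighted likelihood array
# contracted against the other factors' current marginals. Messages are
# passed forward in time only: beliefs at each step combine the transition
# of the previous step's converged beliefs with the likelihood of the
# current observation, and future steps under a policy are pure predictions.
# Within a step, the marginals are driven to the fixed point
# s* = softmax(prior message + likelihood message) by a damped gradient
# scheme on the state prediction error eps = ln s* - ln s.

# One filtering step: mean-field fixed point given per-factor prior
# messages and one multi-modality observation.
filter_step <- function(model, prior, obs, learning_rate = NULL,
                        max_iters = NULL, tol = NULL, trace = FALSE) {
  lambda <- learning_rate %||% model$learning_rate
  imax <- max_iters %||% model$max_iters
  tol <- tol %||% model$tol
  ns <- model$n_states
  nf <- model$n_factors

  # the modalities' log-likelihood slices enter every message as a sum, so
  # collapse them once and pre-permute per factor
  lnL <- array(model$lnA_mat[[1L]][obs[1L], ], dim = ns)
  for (m in seq_len(model$n_modalities)[-1L]) {
    lnL <- lnL + array(model$lnA_mat[[m]][obs[m], ], dim = ns)
  }
  perm <- lapply(seq_len(nf), function(f) {
    if (nf == 1L) matrix(lnL, ncol = 1L) else {
      others <- setdiff(seq_len(nf), f)
      a <- aperm(lnL, c(f, others))
      matrix(a, nrow = ns[f], ncol = prod(ns[others]))
    }
  })
  lp <- lapply(prior, function(p) log(p + model$epsilon))
  s <- lapply(ns, function(k) rep(1 / k, k))
  eps <- lapply(ns, function(k) numeric(k))
  converged <- FALSE
  f_trace <- if (trace) numeric(0) else NULL
  iter <- 0L

  while (iter < imax) {
    iter <- iter + 1L
    delta <- 0
    for (f in seq_len(nf)) {
      msg <- if (nf == 1L) as.vector(perm[[f]]) else {
        others <- setdiff(seq_len(nf), f)
        as.vector(perm[[f]] %*% joint_weights(s[others]))
      }
      v <- lp[[f]] + msg
      s_star <- softmax(v)
      e <- log(pmax(s_star, 1e-300)) - log(pmax(s[[f]], 1e-300))
      eps[[f]] <- e
      delta <- max(delta, max(abs(e)))
      s[[f]] <- softmax(log(pmax(s[[f]], 1e-300)) + lambda * e)
    }
    if (trace) {
      f_trace <- c(f_trace, step_free_energy(model, s, prior, list(lnL)))
    }
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  list(s = s, eps = eps, converged = converged, n_iter = iter,
       F_trace = f_trace)
}

# Single-step variational free energy of factorised beliefs `s` given prior
# messages and precomputed log-likelihood slices; used for diagnostics.
step_free_energy <- function(model, s, prior, slices) {
  w <- joint_weights(s)
  accuracy <- sum(vapply(slices, function(sl) sum(w * as.vector(sl)), numeric(1)))
  complexity <- sum(vapply(seq_along(s), function(f) {
    q <- s[[f]]
    sum(q * (log(pmax(q, 1e-300)) - log(prior[[f]] + model$epsilon)))
  }, numeric(1)))
  complexity - accuracy
}

#' Infer hidden states under a policy
#'
#' Runs variational state estimation over an observed sequence. Beliefs about
#' each hidden-state factor are categorical marginals (mean-field across
#' factors); within each time step they are iterated to the fixed point of
#' the softmax update via damped gradient steps on the state prediction
#' error, and likelihood evidence enters only for time steps that have been
#' observed. Steps beyond the data are predicted through the transition
#' arrays using the policy's actions.
#'
#' For a single-factor model observed once, the converged marginals equal
#' the exact Bayes posterior `softmax(ln D + zeta ln A . o)`.
#'
#' @param model a [generative_model()].
#' @param observations integer matrix of observed outcome indices, one row
#'   per modality and one column per observed time step (a vector is taken
#'   as a single step).
#' @param policy integer vector of future actions (possibly length zero);
#'   typically one row of `model$policies`. Used to roll predictions forward
#'   beyond the observed steps, up to the model horizon.
#' @param actions integer vector of the actions already taken (length
#'   `ncol(observations) - 1`).
#' @param learning_rate,max_iters,tol optional overrides of the model's
#'   numerical settings.
#' @param trace if `TRUE`, record the single-step variational free energy at
#'   every gradient sweep (diagnostic).
#' @return a list with elements `s` and `eps` (per-factor matrices of
#'   marginals and prediction errors, states x time), `converged` (logical,
#'   per time step), `n_iter`, `F` (the summed prediction-error free energy
#'   [policy_free_energy()]), and `F_trace` when requested. A warning is
#'   issued if any step hit the iteration cap; the best iterate is returned
#'   and flagged.
#' @export
infer_states <- function(model, observations, policy = integer(0),
                         actions = integer(0), learning_rate = NULL,
                         max_iters = NULL, tol = NULL, trace = FALSE) {
  stopifnot(inherits(model, "generative_model"))
  if (is.vector(observations)) observations <- matrix(observations, ncol = 1L)
  t_obs <- ncol(observations)
  if (nrow(observations) != model$n_modalities) {
    stop_config("`observations` needs one row per outcome modality")
  }
  if (t_obs > model$horizon) stop_config("more observations than the model horizon")
  for (m in seq_len(model$n_modalities)) {
    if (any(observations[m, ] < 1L) || any(observations[m, ] > model$n_out[m])) {
      stop_config("observation indices out of range for modality ", m)
    }
  }
  if (t_obs > 1L && length(actions) < t_obs - 1L) {
    stop_config("`actions` must give the ", t_obs - 1L, " transitions already taken")
  }

  n_fut <- min(length(policy), model$horizon - t_obs)
  n_tau <- t_obs + n_fut
  nf <- model$n_factors
  s <- lapply(model$n_states, function(k) matrix(0, k, n_tau))
  eps <- lapply(model$n_states, function(k) matrix(0, k, n_tau))
  converged <- logical(t_obs)
  n_iter <- integer(t_obs)
  traces <- if (trace) vector("list", t_obs) else NULL

  prev <- model$D
  for (tau in seq_len(t_obs)) {
    prior <- if (tau == 1L) model$D else {
      a <- actions[tau - 1L]
      lapply(seq_len(nf), function(f) as.vector(model$B[[f]][, , a] %*% prev[[f]]))
    }
    fit <- filter_step(model, prior, observations[, tau],
                       learning_rate = learning_rate, max_iters = max_iters,
                       tol = tol, trace = trace)
    for (f in seq_len(nf)) {
      s[[f]][, tau] <- fit$s[[f]]
      eps[[f]][, tau] <- fit$eps[[f]]
    }
    converged[tau] <- fit$converged
    n_iter[tau] <- fit$n_iter
    if (trace) traces[[tau]] <- fit$F_trace
    prev <- fit$s
  }
  if (n_fut > 0L) {
    for (j in seq_len(n_fut)) {
      a <- policy[j]
      prev <- lapply(seq_len(nf), function(f) {
        as.vector(model$B[[f]][, , a] %*% prev[[f]])
      })
      for (f in seq_len(nf)) s[[f]][, t_obs + j] <- prev[[f]]
    }
  }
  if (any(!converged)) {
    warning("state estimation hit the iteration cap at step(s) ",
            paste(which(!converged), collapse = ", "),
            "; best iterate returned", call. = FALSE)
  }
  out <- list(s = s, eps = eps, converged = converged, n_iter = n_iter,
              F = policy_free_energy(eps, s))
  if (trace) out$F_trace <- traces
  out
}

#' Prediction-error free energy of a policy
#'
#' The policy's free energy is the negative sum, over time steps and factors,
#' of the dot product between the state prediction errors and the state
#' marginals. At an exact fixed point of the belief updates it is zero;
#' policies that have seen identical observations carry identical values.
#'
#' @param eps per-factor prediction errors (list of states x time matrices,
#'   or vectors for a single step), as returned by [infer_states()].
#' @param s_pi matching per-factor state marginals.
#' @return a scalar free energy.
#' @export
policy_free_energy <- function(eps, s_pi) {
  if (!is.list(eps)) eps <- list(eps)
  if (!is.list(s_pi)) s_pi <- list(s_pi)
  if (length(eps) != length(s_pi)) {
    stop("prediction errors and marginals must cover the same factors", call. = FALSE)
  }
  total <- 0
  for (f in seq_along(eps)) {
    if (length(eps[[f]]) != length(s_pi[[f]])) {
      stop("prediction errors and marginals have mismatched time ranges", call. = FALSE)
    }
    total <- total + sum(eps[[f]] * s_pi[[f]])
  }
  -total
}
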