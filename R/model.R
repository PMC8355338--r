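#' Construct a generative model for discrete-state active inference
#'
#' Bundles the agent's internal model of a partially observed Markov decision
#' process: likelihood arrays `A` (one per outcome modality, mapping every
#' combination of hidden states to a distribution over outcome levels),
#' transition arrays `B` (one per hidden-state factor, next state x current
#' state x action), log-preferences `C` over outcomes, initial-state priors
#' `D`, a set of depth-one policies, and a precision scheme `zeta` that
#' exponent-weights each likelihood column (see [apply_precision()]).
#'
#' The constructor validates normalisation (columns of every `A` and `B`, and
#' every `D`, must sum to 1), caches the precision-weighted likelihoods and
#' their column entropies (used by [expected_free_energy()]), and records the
#' numerical settings of the variational scheme.
#'
#' @param A list of likelihood arrays, one per modality; dimension 1 indexes
#'   outcome levels, remaining dimensions the hidden-state factors.
#' @param B list of transition arrays, one per factor, with dimensions
#'   (states, states, actions). Factors outside the agent's control carry the
#'   identity in every action slice.
#' @param C list of numeric log-preference vectors over outcome levels, one
#'   per modality, constant over time.
#' @param D list of prior distributions over initial states, one per factor.
#' @param policies integer matrix of action sequences, one row per policy.
#'   Defaults to one depth-one policy per action.
#' @param zeta list of precision-exponent arrays, one per modality, each over
#'   the full state grid; defaults to 1 everywhere (pass-through).
#' @param horizon trial length in time steps (>= 1).
#' @param learning_rate gradient step size of the belief updates (> 0).
#' @param max_iters iteration cap for the fixed-point search.
#' @param tol convergence threshold on the largest absolute state prediction
#'   error.
#' @param epsilon small positive constant used before logarithms.
#' @return an object of class `generative_model`.
#' @seealso [build_generative_model()] for the mental-state-attribution task.
#' @export
generative_model <- function(A, B, C, D, policies = NULL, zeta = NULL,
                             horizon = 1L, learning_rate = 0.25,
                             max_iters = 64L, tol = 1e-4, epsilon = 1e-16) {
  if (!is.list(A) || !is.list(B) || !is.list(C) || !is.list(D)) {
    stop_config("A, B, C and D must be lists (per modality / per factor)")
  }
  n_states <- vapply(D, length, integer(1))
  n_out <- vapply(A, function(a) dim(a)[1L], integer(1))
  n_factors <- length(D)
  tol_norm <- 1e-10

  for (m in seq_along(A)) {
    d <- dim(A[[m]])
    if (length(d) != n_factors + 1L || !all(d[-1L] == n_states)) {
      stop_config("A[[", m, "]] must have dimensions (outcomes, ",
                  paste(n_states, collapse = ", "), ")")
    }
    cs <- colSums(as_lik_matrix(A[[m]]))
    if (any(abs(cs - 1) > tol_norm)) {
      stop_config("columns of A[[", m, "]] must sum to 1")
    }
    if (length(C[[m]]) != d[1L]) {
      stop_config("C[[", m, "]] must have one entry per outcome level of modality ", m)
    }
  }
  n_actions <- dim(B[[1L]])[3L]
  for (f in seq_len(n_factors)) {
    d <- dim(B[[f]])
    if (length(d) != 3L || d[1L] != n_states[f] || d[2L] != n_states[f] ||
        d[3L] != n_actions) {
      stop_config("B[[", f, "]] must have dimensions (", n_states[f], ", ",
                  n_states[f], ", n_actions)")
    }
    for (a in seq_len(n_actions)) {
      if (any(abs(colSums(B[[f]][, , a, drop = FALSE][, , 1L]) - 1) > tol_norm)) {
        stop_config("columns of B[[", f, "]] (action ", a, ") must sum to 1")
      }
    }
    if (abs(sum(D[[f]]) - 1) > tol_norm || any(D[[f]] < 0)) {
      stop_config("D[[", f, "]] must be a probability distribution")
    }
  }
  if (horizon < 1L) stop_config("horizon must be >= 1")
  if (learning_rate <= 0) stop_config("learning_rate must be positive")
  if (epsilon <= 0) stop_config("epsilon must be positive")
  if (is.null(policies)) policies <- matrix(seq_len(n_actions), ncol = 1L)
  policies <- as.matrix(policies)
  if (any(policies < 1L) || any(policies > n_actions)) {
    stop_config("policies must index actions in 1..", n_actions)
  }
  if (is.null(zeta)) {
    zeta <- lapply(seq_along(A), function(m) array(1, dim = n_states))
  }

  model <- structure(
    list(A = A, B = B, C = C, D = D, policies = policies, zeta = zeta,
         horizon = as.integer(horizon), learning_rate = learning_rate,
         max_iters = as.integer(max_iters), tol = tol, epsilon = epsilon,
         n_states = n_states, n_out = n_out, n_factors = n_factors,
         n_modalities = length(A), n_actions = n_actions),
    class = "generative_model")
  refresh_model(model)
}

# Recompute cached quantities that depend on A and zeta: the
# precision-weighted likelihoods, their logs, and the per-column outcome
# entropies H (the ambiguity kernel of the expected free energy).
refresh_model <- function(model) {
  eps <- model$epsilon
  model$Abar <- lapply(seq_len(model$n_modalities), function(m) {
    apply_precision(model$A[[m]], model$zeta[[m]], eps)
  })
  model$Abar_mat <- lapply(model$Abar, as_lik_matrix)
  model$lnA_mat <- lapply(model$Abar_mat, function(M) log(M + eps))
  model$H <- lapply(model$Abar_mat, function(M) {
    -colSums(M * log(M + eps))
  })
  model
}

#' Replace the precision scheme of a generative model
#'
#' @param model a `generative_model`.
#' @param zeta list of precision-exponent arrays, one per modality.
#' @return the model with refreshed precision-weighted likelihoods.
#' @export
set_precision <- function(model, zeta) {
  stopifnot(inherits(model, "generative_model"))
  if (length(zeta) != model$n_modalities) {
    stop_config("`zeta` must have one entry per outcome modality")
  }
  for (m in seq_along(zeta)) {
    if (any(zeta[[m]] < 0)) stop("precision exponents must be non-negative", call. = FALSE)
    if (prod(dim(zeta[[m]]) %||% length(zeta[[m]])) != prod(model$n_states)) {
      stop_config("zeta[[", m, "]] does not match the state grid")
    }
  }
  model$zeta <- zeta
  refresh_model(model)
}

#' @export
print.generative_model <- function(x, ...) {
  cat("<generative_model>\n")
  cat("  factors:   ", paste(x$n_states, collapse = " x "),
      " (", prod(x$n_states), " state combinations)\n", sep = "")
  cat("  modalities:", paste(x$n_out, collapse = ", "), "outcome levels\n")
  cat("  policies:  ", nrow(x$policies), "(depth", ncol(x$policies), ")\n")
  cat("  horizon:   ", x$horizon, "\n")
  invisible(x)
}
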