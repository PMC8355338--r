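# Policy evaluation, action selection, and Bayesian model averaging.

#' Posterior beliefs over policies
#'
#' Policies are scored by the sum of their free energy (evidence from the
#' observations so far) and expected free energy (predicted preference
#' satisfaction and information gain); the posterior is the softmax of the
#' negative sum. Adding a constant to every score leaves it unchanged.
#'
#' @param F_pi numeric vector of per-policy free energies.
#' @param G_pi numeric vector of per-policy expected free energies.
#' @return probability vector over policies.
#' @export
policy_posterior <- function(F_pi, G_pi) {
  if (length(F_pi) != length(G_pi)) {
    stop("F and G must score the same policies", call. = FALSE)
  }
  v <- -F_pi - G_pi
  if (any(!is.finite(v))) {
    stop("non-finite policy scores", call. = FALSE)
  }
  softmax(v)
}

#' Select an action from the policy posterior
#'
#' Under `"map"` selection, one policy is drawn uniformly at random from the
#' set of policies within `tie_tol` of the maximum posterior probability
#' (several saccades often afford exactly the same information, so ties are
#' common). Under `"stochastic"` selection the policy is sampled from the
#' posterior itself, which avoids ceiling effects when comparing conditions.
#' Uses R's global random number generator; seed upstream for
#' reproducibility.
#'
#' @param pi_post probability vector over policies.
#' @param mode `"map"` or `"stochastic"`.
#' @param tie_tol numeric tolerance defining the argmax set for MAP ties.
#' @return the index of the selected policy.
#' @export
select_action <- function(pi_post, mode = c("map", "stochastic"),
                          tie_tol = 1e-8) {
  mode <- match.arg(mode)
  if (length(pi_post) == 0L) stop_config("empty policy set")
  if (mode == "map") {
    top <- argmax_set(pi_post, tie_tol)
    if (length(top) == 1L) top else top[sample.int(length(top), 1L)]
  } else {
    sample.int(length(pi_post), 1L, prob = pi_post)
  }
}

#' Bayesian model averaging of per-policy beliefs and outcome prediction
#'
#' Treats each policy as a model: the policy-averaged state marginals are the
#' posterior-weighted mixture of the per-policy marginals, and predicted
#' outcome distributions are obtained by pushing the averaged marginals
#' through the precision-weighted likelihood.
#'
#' @param pi_post probability vector over policies.
#' @param s_pi per-policy beliefs: a list (one entry per policy) of lists of
#'   per-factor marginal matrices (states x time), as returned by
#'   [infer_states()].
#' @param model a [generative_model()].
#' @return a list with `s_bma` (per-factor averaged marginals, states x
#'   time) and `o_pred` (per-modality predicted outcome distributions,
#'   outcomes x time).
#' @export
bma_and_predict <- function(pi_post, s_pi, model) {
  stopifnot(length(pi_post) == length(s_pi))
  nf <- model$n_factors
  s1 <- s_pi[[1L]]
  as_mat <- function(x) if (is.matrix(x)) x else matrix(x, ncol = 1L)
  s_bma <- lapply(seq_len(nf), function(f) {
    acc <- pi_post[1L] * as_mat(s1[[f]])
    for (p in seq_along(s_pi)[-1L]) {
      acc <- acc + pi_post[p] * as_mat(s_pi[[p]][[f]])
    }
    sweep(acc, 2, colSums(acc), `/`)
  })
  n_tau <- ncol(s_bma[[1L]])
  o_pred <- lapply(seq_len(model$n_modalities), function(m) {
    sapply(seq_len(n_tau), function(tau) {
      w <- joint_weights(lapply(s_bma, function(sf) sf[, tau]))
      o <- as.vector(model$Abar_mat[[m]] %*% w)
      o / sum(o)
    })
  })
  list(s_bma = s_bma, o_pred = o_pred)
}
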