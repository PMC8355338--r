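# Expected free energy and its decompositions.

# Predicted outcome distributions for one future step: the precision-weighted
# likelihood contracted with the (factorised) predicted state marginals.
predict_outcomes <- function(model, s_pred) {
  w <- joint_weights(s_pred)
  lapply(model$Abar_mat, function(M) as.vector(M %*% w))
}

#' Expected free energy of predicted states
#'
#' Scores one predicted future step under a policy. For each outcome
#' modality, the predicted outcome distribution `o` (likelihood contracted
#' with the predicted state marginals) contributes
#' `o . (ln o - C) + H . s`, where `C` is the log-preference vector and `H`
#' holds the outcome entropies of every hidden-state combination. Low values
#' mark policies whose expected outcomes are preferred (extrinsic value) and
#' informative about hidden states (epistemic value); see [efe_decompose()]
#' for the decompositions.
#'
#' @param model a [generative_model()].
#' @param s_pred predicted state marginals for one future time step: a list
#'   with one probability vector per factor. A list of such lists scores
#'   several future steps and sums them.
#' @return scalar expected free energy.
#' @export
expected_free_energy <- function(model, s_pred) {
  if (is.list(s_pred[[1L]])) {
    return(sum(vapply(s_pred, function(sp) expected_free_energy(model, sp),
                      numeric(1))))
  }
  w <- joint_weights(s_pred)
  G <- 0
  for (m in seq_len(model$n_modalities)) {
    o <- as.vector(model$Abar_mat[[m]] %*% w)
    G <- G + sum(o * (log(o + model$epsilon) - model$C[[m]])) +
      sum(model$H[[m]] * w)
  }
  G
}

#' Decompose the expected free energy of predicted states
#'
#' Returns, per modality and in total, the quantities that make up the
#' expected free energy of one predicted step:
#' * `epistemic`: expected information gain about hidden states (the mutual
#'   information between predicted states and outcomes); always >= 0.
#' * `extrinsic`: expected utility `o . C` under the raw log-preferences.
#' * `risk`: KL divergence from the predicted outcomes to the normalised
#'   preference distribution `softmax(C)`; always >= 0.
#' * `ambiguity`: expected outcome entropy given states, `H . s`; >= 0.
#' * `pref_lognorm`: `log sum exp(C)` per modality, the constant separating
#'   the two decompositions.
#'
#' The identities `G = -epistemic - extrinsic` and
#' `G + sum(pref_lognorm) = risk + ambiguity` hold exactly; the constant is
#' shared by every policy and cancels in the policy posterior.
#'
#' @inheritParams expected_free_energy
#' @return a list with components `G`, `epistemic`, `extrinsic`, `risk`,
#'   `ambiguity`, `pref_lognorm` and the predicted outcome distributions
#'   `o_pred`.
#' @export
efe_decompose <- function(model, s_pred) {
  w <- joint_weights(s_pred)
  eps <- model$epsilon
  out <- list(G = 0, epistemic = 0, extrinsic = 0, risk = 0, ambiguity = 0,
              pref_lognorm = 0, o_pred = vector("list", model$n_modalities))
  for (m in seq_len(model$n_modalities)) {
    o <- as.vector(model$Abar_mat[[m]] %*% w)
    Cm <- model$C[[m]]
    lse <- log(sum(exp(Cm - max(Cm)))) + max(Cm)
    amb <- sum(model$H[[m]] * w)
    neg_h_o <- sum(o * log(o + eps))
    out$o_pred[[m]] <- o
    out$ambiguity <- out$ambiguity + amb
    out$epistemic <- out$epistemic + (-neg_h_o - amb)
    out$extrinsic <- out$extrinsic + sum(o * Cm)
    out$risk <- out$risk + sum(o * (log(o + eps) - (Cm - lse)))
    out$pref_lognorm <- out$pref_lognorm + lse
    out$G <- out$G + sum(o * (log(o + eps) - Cm)) + amb
  }
  out
}
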