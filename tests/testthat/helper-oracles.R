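# Test-side oracles and fixture builders. Everything here is independent of
# the engine's message-passing code path: posteriors come from enumeration,
# expected-free-energy pieces from explicit loops over states and outcomes.

softmax <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

rdirich <- function(n) {
  g <- stats::rgamma(n, shape = 1)
  g / sum(g)
}

# Exact posterior over the context x target grid of the task model, by
# enumeration, given the observation history and the (known) fixation
# sequence. Uses the agent's precision-weighted likelihoods.
exact_task_posterior <- function(model, observations, wheres) {
  nc <- model$n_states[1L]
  nt <- model$n_states[2L]
  w <- outer(model$D[[1L]], model$D[[2L]])
  for (tau in seq_len(ncol(observations))) {
    l <- wheres[tau]
    for (i in seq_len(nc)) {
      for (j in seq_len(nt)) {
        lik <- 1
        for (m in seq_len(model$n_modalities)) {
          lik <- lik * model$Abar[[m]][observations[m, tau], i, j, l]
        }
        w[i, j] <- w[i, j] * lik
      }
    }
  }
  w <- w / sum(w)
  list(context = rowSums(w), target = colSums(w), joint = w)
}

# Random small multi-factor generative model with smooth (strictly positive)
# likelihood columns, for expected-free-energy property tests.
random_small_model <- function(seed, smooth = TRUE) {
  set.seed(seed)
  nf <- sample(1:3, 1)
  ns <- sample(2:4, nf, replace = TRUE)
  nm <- sample(1:2, 1)
  no <- sample(2:5, nm, replace = TRUE)
  K <- prod(ns)
  A <- lapply(seq_len(nm), function(m) {
    cols <- replicate(K, if (smooth) rdirich(no[m]) else {
      v <- numeric(no[m]); v[sample(no[m], 1)] <- 1; v
    })
    array(cols, dim = c(no[m], ns))
  })
  B <- lapply(ns, function(k) array(diag(k), dim = c(k, k, 1L)))
  C <- lapply(no, function(k) stats::rnorm(k))
  D <- lapply(ns, function(k) rdirich(k))
  generative_model(A = A, B = B, C = C, D = D, horizon = 2L,
                   max_iters = 512L, tol = 1e-10)
}

random_beliefs <- function(model) lapply(model$n_states, rdirich)

# Brute-force risk + ambiguity of one predicted step, by explicit loops:
# risk is the KL divergence from the predicted outcome distribution to the
# normalised preference distribution, ambiguity the belief-weighted entropy
# of the likelihood columns.
brute_risk_ambiguity <- function(model, s_pred) {
  grid <- as.matrix(expand.grid(lapply(model$n_states, seq_len)))
  p_state <- apply(grid, 1L, function(ix) {
    prod(vapply(seq_along(ix), function(f) s_pred[[f]][ix[f]], numeric(1)))
  })
  risk <- 0
  ambiguity <- 0
  for (m in seq_len(model$n_modalities)) {
    no <- model$n_out[m]
    o <- numeric(no)
    for (r in seq_len(nrow(grid))) {
      col <- model$Abar[[m]][cbind(seq_len(no),
                                   matrix(grid[r, ], no, ncol(grid), byrow = TRUE))]
      o <- o + p_state[r] * col
      h <- -sum(col * log(col + model$epsilon))
      ambiguity <- ambiguity + p_state[r] * h
    }
    pref <- exp(model$C[[m]] - max(model$C[[m]]))
    pref <- pref / sum(pref)
    risk <- risk + sum(o * (log(o + model$epsilon) - log(pref)))
  }
  list(risk = risk, ambiguity = ambiguity)
}

# shorthand: task agents with optionally tightened numerics
task_agent <- function(variant, ..., max_iters = 64L, tol = 1e-4) {
  make_agent_variant(
    build_generative_model(max_iters = max_iters, tol = tol),
    variant = variant, ...)
}

emotion_happy_marginal <- function(record, step) {
  sum(record$posterior[[2L]][c(1L, 3L), step])
}

type_ambiguous_marginal <- function(record, step) {
  sum(record$posterior[[2L]][c(3L, 4L), step])
}
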