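# Internal numerical helpers shared across the engine.

#' Softmax of a numeric vector
#'
#' Numerically stable softmax; maps any finite vector onto the probability
#' simplex. The zero vector maps to the uniform distribution.
#'
#' @param x numeric vector of (finite) log-potentials.
#' @return numeric vector of the same length summing to 1.
#' @keywords internal
softmax <- function(x) {
  x <- x - max(x)
  e <- exp(x)
  e / sum(e)
}

# log with a small clamp so that one-hot columns do not produce -Inf
ln <- function(p, epsilon = 1e-16) log(p + epsilon)

# column-wise softmax of a matrix of log-potentials
col_softmax <- function(L) {
  L <- sweep(L, 2, apply(L, 2, max), `-`)
  E <- exp(L)
  sweep(E, 2, colSums(E), `/`)
}

# Flatten an outcome-likelihood array (outcome level x state grid) into a
# matrix with one column per hidden-state combination.
as_lik_matrix <- function(A) {
  d <- dim(A)
  matrix(A, nrow = d[1L], ncol = prod(d[-1L]))
}

# Joint weight vector over the full state grid implied by independent
# per-factor marginals (column-major order, factor 1 fastest).
joint_weights <- function(beliefs) {
  as.vector(Reduce(function(a, b) outer(a, b), beliefs))
}

# Contract an array defined over the state grid (dims = state space sizes)
# against the beliefs of every factor except `keep`, returning a vector over
# the kept factor's states. This is the mean-field message used when one
# factor receives a log-likelihood contracted against the others' marginals.
contract_grid <- function(arr, beliefs, keep) {
  nf <- length(beliefs)
  if (nf == 1L) return(as.vector(arr))
  others <- setdiff(seq_len(nf), keep)
  perm <- c(keep, others)
  a <- aperm(arr, perm)
  d <- dim(a)
  m <- matrix(a, nrow = d[1L], ncol = prod(d[-1L]))
  w <- joint_weights(beliefs[others])
  as.vector(m %*% w)
}

# argmax set with tolerance (used for MAP tie-breaking)
argmax_set <- function(x, tol = 1e-8) which(x >= max(x) - tol)

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(...) stop(..., call. = FALSE)
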