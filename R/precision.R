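#' Precision-weight a likelihood mapping
#'
#' Applies a precision (inverse-temperature) exponent to each column of a
#' likelihood array and renormalises: every column of the result is the
#' softmax, over outcome levels, of `zeta * log(A + epsilon)`. A precision of
#' 1 leaves a column unchanged (up to the epsilon clamp), a precision of 0
#' renders it uniform (the outcome carries no information about that state
#' combination), and large precisions sharpen it towards a deterministic
#' mapping. This is the gain-control mechanism used for attention and
#' contextual perception: per-state exponents decide how informative each
#' sensory channel is believed to be.
#'
#' @param A likelihood array: outcome levels in the first dimension, one
#'   further dimension per hidden-state factor. Every column (fixing a
#'   state combination) must be a probability distribution.
#' @param zeta precision exponents, either a scalar or an array whose
#'   dimensions match the state grid of `A` (i.e. `dim(A)[-1]`). All entries
#'   must be non-negative.
#' @param epsilon small positive constant added before taking logarithms so
#'   that deterministic (one-hot) columns remain finite.
#' @return an array of the same shape as `A`; every column sums to 1. The
#'   input is not modified.
#' @examples
#' A <- array(c(0.8, 0.2, 0.5, 0.5), dim = c(2, 2))
#' apply_precision(A, c(2, 0))
#' @export
apply_precision <- function(A, zeta, epsilon = 1e-16) {
  d <- dim(A)
  if (is.null(d)) stop_config("`A` must be an array with outcome levels in dimension 1")
  grid <- d[-1L]
  if (length(zeta) == 1L) zeta <- array(zeta, dim = grid)
  zd <- dim(zeta) %||% length(zeta)
  if (prod(zd) != prod(grid)) {
    stop_config("`zeta` has ", prod(zd), " entries but the state grid of `A` has ",
                prod(grid))
  }
  if (length(grid) > 1L && !is.null(dim(zeta)) && !all(dim(zeta) == grid)) {
    stop_config("`zeta` dimensions (", paste(dim(zeta), collapse = "x"),
                ") do not match the state grid of `A` (",
                paste(grid, collapse = "x"), ")")
  }
  if (any(zeta < 0)) stop("precision exponents must be non-negative", call. = FALSE)
  M <- as_lik_matrix(A)
  L <- sweep(log(M + epsilon), 2, as.vector(zeta), `*`)
  out <- col_softmax(L)
  array(out, dim = d, dimnames = dimnames(A))
}
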