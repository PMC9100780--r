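#' Logistic sigmoid
#' @param x Numeric.
#' @return `1 / (1 + exp(-x))`.
#' @keywords internal
sigmoid <- function(x) 1 / (1 + exp(-x))

#' Dendritic response of a single neuron
#'
#' Each of the neuron's dendritic segments computes a linear response
#' \eqn{u_j^\top c} to the context vector.  Under `"max"` gating the
#' largest signed response is selected.  Under `"absolute_max"` gating
#' the response with the largest magnitude is selected and its sign is
#' kept, so a strongly negative segment can actively silence the
#' neuron.
#'
#' @param U Numeric matrix `num_segments x segment_dim`, one row per
#'   segment (segments have no bias).
#' @param c_vec Context vector of length `segment_dim`.
#' @param mode `"absolute_max"` or `"max"`.
#' @return A list with `d` (the selected activation) and `j_star` (the
#'   1-based index of the winning segment).  Ties are broken by lowest
#'   segment index.
#' @export
#' @examples
#' U <- rbind(c(1, 0), c(-2, 0))
#' dendritic_response(U, c(1, 0), "absolute_max") # d = -2, j_star = 2
#' dendritic_response(U, c(1, 0), "max")          # d =  1, j_star = 1
dendritic_response <- function(U, c_vec, mode = c("absolute_max", "max")) {
  mode <- match.arg(mode)
  if (!is.matrix(U)) U <- matrix(U, nrow = 1L)
  if (nrow(U) == 0L)
    stop("neuron has zero dendritic segments", call. = FALSE)
  if (ncol(U) != length(c_vec))
    stop("context length ", length(c_vec), " does not match segment_dim ",
         ncol(U), call. = FALSE)
  r <- drop(U %*% c_vec)
  j <- if (mode == "absolute_max") which.max(abs(r)) else which.max(r)
  list(d = r[[j]], j_star = j)
}

#' Sigmoidal dendritic gating
#'
#' Modulates a feedforward pre-activation by the dendritic activation:
#' `gate(t_hat, d) = t_hat * sigmoid(d)`.  Since the sigmoid lies in
#' `[0, 1]`, gating can only attenuate, never amplify: a strong
#' positive dendritic response retains the feedforward activation while
#' weak or negative responses suppress it.
#'
#' @param t_hat Feedforward pre-activation(s).
#' @param d Dendritic activation(s), recycled against `t_hat`.
#' @return `t_hat * sigmoid(d)`.
#' @export
#' @examples
#' gate(5, 0)    # 2.5: a zero dendritic response halves the activation
gate <- function(t_hat, d) t_hat * sigmoid(d)

#' k-Winner-Take-All activation
#'
#' Keeps the `k` largest entries of `values` verbatim and sets every
#' other entry to exactly zero, modeling local inhibition.  Ties at the
#' threshold are broken by lowest index, so the output always has
#' exactly `k` entries kept.
#'
#' @param values Numeric vector of activations.
#' @param k Number of winners, `1 <= k <= length(values)`.
#' @return Vector of the same length with non-winners zeroed.
#' @export
#' @examples
#' kwta(c(3, 1, 4, 1, 5), 2)   # 0 0 4 0 5
kwta <- function(values, k) {
  n <- length(values)
  if (k < 1L || k > n)
    stop("k must lie in [1, length(values)]", call. = FALSE)
  keep <- order(values, decreasing = TRUE)[seq_len(k)]
  out <- numeric(n)
  out[keep] <- values[keep]
  out
}

# Row-wise kWTA over a matrix of activations.  Returns the sparse
# matrix plus the logical winner mask (used to route gradients and to
# count activations exactly).  order() with method "radix" is stable,
# so ties fall to the lowest column index.
kwta_rows <- function(Y, k) {
  n <- nrow(Y)
  mask <- matrix(FALSE, n, ncol(Y))
  for (i in seq_len(n)) {
    keep <- order(Y[i, ], decreasing = TRUE, method = "radix")[seq_len(k)]
    mask[i, keep] <- TRUE
  }
  list(values = Y * mask, mask = mask)
}

#' Fixed random sparsity mask for feedforward weights
#'
#' Draws a binary mask with exactly `round(weight_sparsity * n)` zeros
#' placed uniformly at random, where `n` is the number of entries.  The
#' mask is drawn once at layer construction and fixed for the life of
#' the layer: masked entries never become non-zero during training.
#'
#' @param shape Integer vector `c(rows, cols)`.
#' @param weight_sparsity Fraction of entries set to zero, in `[0, 1)`.
#' @param seed Integer seed; equal seeds give identical masks.
#' @return A binary matrix of the requested shape.
#' @export
make_sparsity_mask <- function(shape, weight_sparsity, seed = NULL) {
  if (weight_sparsity < 0 || weight_sparsity >= 1)
    stop("weight_sparsity must lie in [0, 1)", call. = FALSE)
  n <- prod(shape)
  M <- matrix(1, shape[1L], shape[2L])
  nz <- round(weight_sparsity * n)
  if (nz > 0) {
    if (!is.null(seed)) {
      old <- get_rng_state()
      on.exit(set_rng_state(old), add = TRUE)
      set.seed(seed)
    }
    M[sample.int(n, nz)] <- 0
  }
  M
}

# Save/restore the global RNG state so that seeded helpers do not
# perturb a caller's random stream.
get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

set_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}
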