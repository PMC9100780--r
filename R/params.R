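#' Instantiate network parameters
#'
#' Creates the full parameter set for an architecture: per hidden layer
#' a feedforward weight matrix `W` (`out x in`), bias `b`, fixed binary
#' sparsity mask `M` (same shape as `W`; masked entries are zero and
#' stay zero), and, for modulated layers, the dendritic weight tensor
#' `U` with dimensions `out x num_segments x segment_dim` (no biases);
#' plus the dense output head.
#'
#' Feedforward weights and biases use the standard fan-in scaled
#' uniform initialization on `(-1/sqrt(fan_in), 1/sqrt(fan_in))`, with
#' the mask applied afterwards.  Dendritic weights are zero-mean
#' uniform on `(-1/sqrt(segment_dim), 1/sqrt(segment_dim))`, so initial
#' segment responses scatter around zero with both signs.
#'
#' @param spec An [network_spec()].
#' @param seed Integer seed; equal seeds give identical parameters.
#' @return An object of class `adn_params`.
#' @export
init_network <- function(spec, seed = 1L) {
  validate_spec(spec)
  old <- get_rng_state()
  on.exit(set_rng_state(old), add = TRUE)
  set.seed(seed)
  dims <- c(spec$input_dim, spec$hidden_dims)
  hidden <- vector("list", length(spec$hidden_dims))
  for (l in seq_along(spec$hidden_dims)) {
    fan_in <- dims[l]
    out <- dims[l + 1L]
    lim <- 1 / sqrt(fan_in)
    W <- matrix(stats::runif(out * fan_in, -lim, lim), out, fan_in)
    b <- stats::runif(out, -lim, lim)
    M <- make_sparsity_mask(c(out, fan_in), spec$weight_sparsity)
    U <- NULL
    if (l %in% spec$modulated_layers) {
      lim_u <- 1 / sqrt(spec$segment_dim)
      U <- array(stats::runif(out * spec$num_segments * spec$segment_dim,
                              -lim_u, lim_u),
                 dim = c(out, spec$num_segments, spec$segment_dim))
    }
    hidden[[l]] <- list(W = W * M, b = b, M = M, U = U)
  }
  fan_in <- spec$hidden_dims[length(spec$hidden_dims)]
  lim <- 1 / sqrt(fan_in)
  Mo <- make_sparsity_mask(c(spec$output_dim, fan_in), spec$weight_sparsity)
  output <- list(
    W = matrix(stats::runif(spec$output_dim * fan_in, -lim, lim),
               spec$output_dim, fan_in) * Mo,
    b = stats::runif(spec$output_dim, -lim, lim),
    M = Mo)
  structure(list(spec = spec, hidden = hidden, output = output),
            class = "adn_params")
}

# Flatten the dendritic tensor of one layer to a (out*S) x ctx matrix
# whose row r = neuron + (segment-1)*out; used for batched responses.
flatten_U <- function(U) {
  d <- dim(U)
  matrix(U, d[1L] * d[2L], d[3L])
}

#' Forward pass of an Active Dendrites Network
#'
#' Runs a batch through the network.  Each modulated hidden layer
#' computes per neuron the gated activation
#' \eqn{\hat y = (w^\top x + b)\,\sigma(d)} with \eqn{d} the selected
#' dendritic response to the context; non-modulated hidden layers
#' compute the plain affine map.  Layers listed in `kwta_layers` then
#' apply k-Winner-Take-All per sample (winner count
#' `max(1, round(activation_density * layer_size))`); other hidden
#' layers apply ReLU.  The output layer is a plain affine map with no
#' gating and no kWTA.
#'
#' @param params An [init_network()] object.
#' @param x Input batch, `n x input_dim` matrix (a single vector is
#'   promoted to one row).
#' @param context Context input: `NULL` (allowed only when no layer is
#'   modulated), a single vector of length `context_dim` shared by the
#'   whole batch, or an `n x context_dim` matrix with one context per
#'   sample.
#' @param keep_trace If `TRUE`, return per-layer traces (`t_hat`, `d`,
#'   `j_star`, winner mask, `k`, post-activation) needed for gradient
#'   computation and analysis.
#' @return A list with `logits` (`n x output_dim`) and, when
#'   `keep_trace`, a `trace` list with one entry per hidden layer.
#' @export
adn_forward <- function(params, x, context = NULL, keep_trace = FALSE) {
  spec <- params$spec
  if (!is.matrix(x)) x <- matrix(x, nrow = 1L)
  if (ncol(x) != spec$input_dim)
    stop("input has ", ncol(x), " columns; expected ", spec$input_dim,
         call. = FALSE)
  n <- nrow(x)
  shared_ctx <- FALSE
  if (length(spec$modulated_layers)) {
    if (is.null(context))
      stop("context is required: the network has modulated layers",
           call. = FALSE)
    if (!is.matrix(context)) {
      if (length(context) != spec$context_dim)
        stop("context length must equal context_dim", call. = FALSE)
      shared_ctx <- TRUE
    } else if (ncol(context) != spec$context_dim || nrow(context) != n) {
      stop("context matrix must be n x context_dim", call. = FALSE)
    }
  }
  H <- x
  trace <- if (keep_trace) vector("list", length(spec$hidden_dims)) else NULL
  for (l in seq_along(spec$hidden_dims)) {
    layer <- params$hidden[[l]]
    t_hat <- H %*% t(layer$W)
    t_hat <- sweep(t_hat, 2L, layer$b, "+")
    out <- ncol(t_hat)
    d <- NULL; j_star <- NULL; sig_d <- NULL
    if (l %in% spec$modulated_layers) {
      Uf <- flatten_U(layer$U)
      S <- dim(layer$U)[2L]
      if (shared_ctx) {
        r <- matrix(drop(Uf %*% context), out, S)
        js <- if (spec$gating_mode == "absolute_max")
          max.col(abs(r), ties.method = "first")
        else max.col(r, ties.method = "first")
        dv <- r[cbind(seq_len(out), js)]
        sig_row <- sigmoid(dv)
        Y <- t_hat * rep(sig_row, each = n)
        d <- matrix(dv, n, out, byrow = TRUE)
        j_star <- matrix(js, n, out, byrow = TRUE)
        sig_d <- matrix(sig_row, n, out, byrow = TRUE)
      } else {
        resp <- context %*% t(Uf)             # n x (out*S)
        m2 <- matrix(resp, n * out, S)        # (sample, neuron) x segment
        js <- if (spec$gating_mode == "absolute_max")
          max.col(abs(m2), ties.method = "first")
        else max.col(m2, ties.method = "first")
        dv <- m2[cbind(seq_len(n * out), js)]
        d <- matrix(dv, n, out)
        j_star <- matrix(js, n, out)
        sig_d <- sigmoid(d)
        Y <- t_hat * sig_d
      }
    } else {
      Y <- t_hat
    }
    if (l %in% spec$kwta_layers) {
      k <- kwta_k(spec$activation_density, out)
      kw <- kwta_rows(Y, k)
      A <- kw$values
      winners <- kw$mask
    } else {
      A <- pmax(Y, 0)                          # ReLU
      winners <- Y > 0
      k <- NA_integer_
    }
    if (keep_trace)
      trace[[l]] <- list(input = H, t_hat = t_hat, d = d, j_star = j_star,
                         sig_d = sig_d, winners = winners, k = k, y = A)
    H <- A
  }
  logits <- H %*% t(params$output$W)
  logits <- sweep(logits, 2L, params$output$b, "+")
  out <- list(logits = logits)
  if (keep_trace) {
    out$trace <- trace
    out$hidden_out <- H
  }
  out
}

#' Census of non-zero entries in instantiated parameters
#'
#' Brute-force count of non-zero values in all feedforward weights,
#' biases, and dendritic tensors.  Agrees exactly with the analytic
#' [count_nonzero_params()] (up to accidental exact zeros, which have
#' probability zero under the continuous initialization).
#'
#' @param params An `adn_params` object.
#' @return A list with `feedforward_count`, `dendritic_count`, `total`.
#' @export
census_nonzero_params <- function(params) {
  ff <- sum(params$output$W != 0) + sum(params$output$b != 0)
  dd <- 0
  for (layer in params$hidden) {
    ff <- ff + sum(layer$W != 0) + sum(layer$b != 0)
    if (!is.null(layer$U)) dd <- dd + sum(layer$U != 0)
  }
  list(feedforward_count = ff, dendritic_count = dd, total = ff + dd)
}

#' Save / load network parameters
#'
#' Parameters (weights, biases, masks, dendritic tensors) are written
#' with the spec embedded, so a saved file is self-describing and can
#' be reloaded into an identical network.
#'
#' @param params An `adn_params` object.
#' @param path File path.
#' @return `adn_load_params` returns the restored `adn_params`.
#' @export
adn_save_params <- function(params, path) {
  stopifnot(inherits(params, "adn_params"))
  saveRDS(params, path)
  invisible(path)
}

#' @rdname adn_save_params
#' @export
adn_load_params <- function(path) {
  params <- readRDS(path)
  stopifnot(inherits(params, "adn_params"))
  params
}
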