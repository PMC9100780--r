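# Gradient computation and optimization for Active Dendrites Networks.
#
# Gradient flow follows the architecture's locality structure exactly:
# units zeroed by kWTA pass zero gradient (so their feedforward rows
# are untouched by a training step), and within a winning neuron only
# the dendritic segment selected by the (absolute) max operator
# receives a non-zero update (subgradient of max).  Masked feedforward
# entries receive zero gradient and are re-masked after each step.

softmax_rows <- function(logits) {
  z <- exp(logits - apply(logits, 1L, max))
  z / rowSums(z)
}

#' Softmax cross-entropy loss
#'
#' @param logits `n x n_classes` matrix.
#' @param labels Integer class labels in `0 .. n_classes-1`.
#' @return Mean negative log-likelihood.
#' @keywords internal
cross_entropy <- function(logits, labels) {
  p <- softmax_rows(logits)
  idx <- cbind(seq_len(nrow(p)), as.integer(labels) + 1L)
  -mean(log(pmax(p[idx], 1e-12)))
}

# Backward pass from a traced forward.  `context` is either a single
# shared vector or an n x context_dim matrix, matching the forward call.
adn_backward <- function(params, fwd, labels, context = NULL) {
  spec <- params$spec
  trace <- fwd$trace
  n <- nrow(fwd$logits)
  P <- softmax_rows(fwd$logits)
  idx <- cbind(seq_len(n), as.integer(labels) + 1L)
  G <- P
  G[idx] <- G[idx] - 1
  G <- G / n
  grads <- list(hidden = vector("list", length(params$hidden)),
                output = list(W = (t(G) %*% fwd$hidden_out) *
                                params$output$M,
                              b = colSums(G)))
  dH <- G %*% params$output$W
  shared_ctx <- !is.null(context) && !is.matrix(context)
  for (l in rev(seq_along(params$hidden))) {
    layer <- params$hidden[[l]]
    tr <- trace[[l]]
    dY <- dH * tr$winners                      # kWTA / ReLU gradient gate
    if (l %in% spec$modulated_layers) {
      sig <- tr$sig_d
      dt_hat <- dY * sig
      ddend <- dY * tr$t_hat * sig * (1 - sig)
      S <- dim(layer$U)[2L]
      dU <- array(0, dim = dim(layer$U))
      for (s in seq_len(S)) {
        Ds <- ddend * (tr$j_star == s)
        if (shared_ctx) {
          dU[, s, ] <- outer(colSums(Ds), context)
        } else {
          dU[, s, ] <- t(Ds) %*% context
        }
      }
    } else {
      dt_hat <- dY
      dU <- NULL
    }
    grads$hidden[[l]] <- list(W = (t(dt_hat) %*% tr$input) * layer$M,
                              b = colSums(dt_hat),
                              U = dU)
    if (l > 1L) dH <- dt_hat %*% layer$W
  }
  grads
}

# Adam optimizer state: first/second moment per tensor plus a step
# counter.  Standard defaults (beta1 = 0.9, beta2 = 0.999, eps = 1e-8).
adam_init <- function(params) {
  zeros_like <- function(x) {
    if (is.null(x)) NULL
    else if (is.null(dim(x))) numeric(length(x))
    else array(0, dim = dim(x))
  }
  st <- list(t = 0L,
             hidden = lapply(params$hidden, function(layer)
               list(mW = zeros_like(layer$W), vW = zeros_like(layer$W),
                    mb = zeros_like(layer$b), vb = zeros_like(layer$b),
                    mU = zeros_like(layer$U), vU = zeros_like(layer$U))),
             output = list(mW = zeros_like(params$output$W),
                           vW = zeros_like(params$output$W),
                           mb = zeros_like(params$output$b),
                           vb = zeros_like(params$output$b)))
  st
}

`%||%` <- function(a, b) if (is.null(a)) b else a

adam_update_tensor <- function(x, g, m, v, lr, t,
                               beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  m <- beta1 * m + (1 - beta1) * g
  v <- beta2 * v + (1 - beta2) * g * g
  mhat <- m / (1 - beta1^t)
  vhat <- v / (1 - beta2^t)
  list(x = x - lr * mhat / (sqrt(vhat) + eps), m = m, v = v)
}

adam_step <- function(params, grads, state, lr) {
  state$t <- state$t + 1L
  t <- state$t
  for (l in seq_along(params$hidden)) {
    layer <- params$hidden[[l]]
    g <- grads$hidden[[l]]
    s <- state$hidden[[l]]
    up <- adam_update_tensor(layer$W, g$W, s$mW, s$vW, lr, t)
    layer$W <- up$x * layer$M                  # mask persistence
    s$mW <- up$m; s$vW <- up$v
    up <- adam_update_tensor(layer$b, g$b, s$mb, s$vb, lr, t)
    layer$b <- up$x; s$mb <- up$m; s$vb <- up$v
    if (!is.null(layer$U)) {
      up <- adam_update_tensor(layer$U, g$U, s$mU, s$vU, lr, t)
      layer$U <- up$x; s$mU <- up$m; s$vU <- up$v
    }
    params$hidden[[l]] <- layer
    state$hidden[[l]] <- s
  }
  g <- grads$output
  s <- state$output
  up <- adam_update_tensor(params$output$W, g$W, s$mW, s$vW, lr, t)
  params$output$W <- up$x * params$output$M; s$mW <- up$m; s$vW <- up$v
  up <- adam_update_tensor(params$output$b, g$b, s$mb, s$vb, lr, t)
  params$output$b <- up$x; s$mb <- up$m; s$vb <- up$v
  state$output <- s
  list(params = params, state = state)
}

#' One stochastic training step
#'
#' Runs a traced forward pass on a batch, computes softmax
#' cross-entropy gradients, and applies one Adam update.  Gradient
#' locality holds by construction: feedforward rows of neurons zeroed
#' by kWTA on every sample of the batch, and dendritic segments never
#' selected by the max operator, receive exactly zero gradient.
#'
#' @param params An `adn_params` object.
#' @param x Input batch (`n x input_dim`).
#' @param labels Integer labels in `0 .. output_dim-1`.
#' @param context Shared context vector or `n x context_dim` matrix
#'   (`NULL` for dendrite-free networks).
#' @param opt_state Adam state from [adam_init()] (created when `NULL`).
#' @param lr Learning rate.
#' @return List with updated `params`, `opt_state`, scalar `loss`, and
#'   the forward `trace`.
#' @export
train_step <- function(params, x, labels, context = NULL,
                       opt_state = NULL, lr = 5e-4) {
  if (is.null(opt_state)) opt_state <- adam_init(params)
  fwd <- adn_forward(params, x, context, keep_trace = TRUE)
  loss <- cross_entropy(fwd$logits, labels)
  grads <- adn_backward(params, fwd, labels, context)
  up <- adam_step(params, grads, opt_state, lr)
  list(params = up$params, opt_state = up$state, loss = loss,
       trace = fwd$trace)
}
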