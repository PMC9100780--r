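#' Per-task activation frequency of hidden neurons
#'
#' For each task, runs test samples through the network with their
#' inferred context (nearest prototype) and records, per neuron of one
#' hidden layer, the fraction of samples for which the neuron survives
#' kWTA.  Rows of the result reveal the task's subnetwork; for a kWTA
#' layer every sample activates exactly `k` units, so each row's mean
#' is exactly `k / layer_size`.
#'
#' @param params Trained or untrained `adn_params`.
#' @param stream The `adn_task_stream` providing test samples.
#' @param store Context store with prototypes (ignored for
#'   dendrite-free networks).
#' @param layer Hidden-layer index to analyze (default: last hidden
#'   layer).
#' @param n_samples Test samples per task (capped at the test-set
#'   size).
#' @param context_mode `"prototype"` routes each sample via
#'   [nearest_prototype()]; `"onehot"` supplies the true task ID.
#' @return A `n_tasks x layer_size` matrix of frequencies in `[0, 1]`.
#' @export
activation_frequency <- function(params, stream, store = NULL,
                                 layer = NULL, n_samples = 500L,
                                 context_mode = "prototype") {
  spec <- params$spec
  if (is.null(layer)) layer <- length(spec$hidden_dims)
  if (n_samples < 1L) stop("n_samples must be >= 1", call. = FALSE)
  has_dendrites <- length(spec$modulated_layers) > 0L
  freq <- matrix(NA_real_, stream$n_tasks, spec$hidden_dims[layer])
  for (tau in seq_len(stream$n_tasks)) {
    task <- stream$tasks[[tau]]
    n <- min(n_samples, nrow(task$test_x))
    X <- task$test_x[seq_len(n), , drop = FALSE]
    ctx <- NULL
    if (has_dendrites) {
      ctx <- if (identical(context_mode, "onehot")) {
        onehot_context(tau, stream$n_tasks)
      } else {
        if (is.null(store) || n_prototypes(store) == 0L)
          stop("prototype analysis requires a non-empty store",
               call. = FALSE)
        P <- store_prototype_matrix(store)
        P[nearest_prototype(X, store), , drop = FALSE]
      }
    }
    fwd <- adn_forward(params, X, ctx, keep_trace = TRUE)
    freq[tau, ] <- colMeans(fwd$trace[[layer]]$winners)
  }
  freq
}

#' Jaccard overlap between task subnetworks
#'
#' Thresholds the activation-frequency matrix into per-task neuron
#' sets \eqn{S_t = \{i : freq(t, i) \ge threshold\}} and returns the
#' pairwise Jaccard index \eqn{|S_a \cap S_b| / |S_a \cup S_b|}.
#' Minimally overlapping subnetworks give small off-diagonal entries.
#' Entries where both sets are empty are `NA`; the diagonal is 1 for
#' non-empty subnetworks.
#'
#' @param freq Matrix from [activation_frequency()].
#' @param threshold Membership threshold in `(0, 1)` (default 0.1).
#' @return A `n_tasks x n_tasks` overlap matrix.
#' @export
subnetwork_overlap <- function(freq, threshold = 0.1) {
  if (threshold <= 0 || threshold >= 1)
    stop("threshold must lie in (0, 1)", call. = FALSE)
  S <- freq >= threshold
  n <- nrow(S)
  out <- matrix(NA_real_, n, n)
  for (a in seq_len(n)) {
    for (b in seq_len(n)) {
      un <- sum(S[a, ] | S[b, ])
      if (un > 0) out[a, b] <- sum(S[a, ] & S[b, ]) / un
    }
  }
  out
}

# Mean of the off-diagonal overlap entries; a scalar summary of how
# much task subnetworks share neurons.
mean_offdiag_overlap <- function(overlap) {
  mean(overlap[row(overlap) != col(overlap)], na.rm = TRUE)
}

#' Raw dendritic segment responses to task contexts
#'
#' Computes \eqn{u_j^\top c} for every neuron, segment, and context —
#' the quantity the max operator selects from, before any gating.
#' Before training, responses scatter around zero with both signs;
#' after sequential training most responses are weak and a few
#' segments respond strongly to "their" task's context.
#'
#' @param params An `adn_params` with at least one modulated layer.
#' @param contexts Matrix with one context vector per row (one per
#'   task), or a single vector.
#' @param layer Modulated hidden-layer index (default: first
#'   modulated layer).
#' @return Array `neurons x segments x contexts` of raw responses.
#' @export
dendrite_responses <- function(params, contexts, layer = NULL) {
  spec <- params$spec
  if (!length(spec$modulated_layers))
    stop("network has no modulated layers", call. = FALSE)
  if (is.null(layer)) layer <- spec$modulated_layers[1L]
  if (!layer %in% spec$modulated_layers)
    stop("layer ", layer, " is not modulated", call. = FALSE)
  if (!is.matrix(contexts)) contexts <- matrix(contexts, nrow = 1L)
  if (ncol(contexts) != spec$context_dim)
    stop("context dimensionality mismatch", call. = FALSE)
  U <- params$hidden[[layer]]$U
  out <- dim(U)[1L]; S <- dim(U)[2L]
  resp <- flatten_U(U) %*% t(contexts)        # (out*S) x n_ctx
  array(resp, dim = c(out, S, ncol(resp)))
}
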