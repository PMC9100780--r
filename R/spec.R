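#' Describe an Active Dendrites Network architecture
#'
#' A `network_spec` is a complete, validated description of an
#' architecture from which parameter tensors can be instantiated and
#' non-zero parameter counts derived exactly.  Hidden layers may carry
#' dendritic segments (`modulated_layers`) and/or a k-Winner-Take-All
#' activation (`kwta_layers`); hidden layers without kWTA use a
#' rectified-linear activation.  The output layer is always a plain
#' affine map with no gating and no kWTA.
#'
#' @param input_dim Positive integer, dimensionality of the feedforward
#'   input.
#' @param hidden_dims Vector of positive integers, one entry per hidden
#'   layer.
#' @param output_dim Positive integer, number of output units (a single
#'   head shared across tasks).
#' @param context_dim Positive integer, dimensionality of the context
#'   vector seen by dendritic segments.  Must equal `segment_dim`.
#' @param weight_sparsity Fraction in `[0, 1)` of feedforward weights
#'   fixed at exactly zero by a random mask drawn once at
#'   initialization.  A value of `s` means `round(s * n)` of the `n`
#'   weight entries in each layer are zero; biases are never masked.
#' @param activation_density Fraction in `(0, 1]` of units kept by kWTA
#'   in each kWTA layer; the winner count is
#'   `k = max(1, round(activation_density * layer_size))`.
#' @param num_segments Non-negative integer, dendritic segments per
#'   modulated neuron.  Typically set to the number of tasks so each
#'   segment can specialize on one context.
#' @param segment_dim Positive integer, weights per dendritic segment;
#'   must equal `context_dim` (segments have no bias term).
#' @param modulated_layers Integer vector of hidden-layer indices whose
#'   neurons carry dendritic segments.
#' @param gating_mode `"absolute_max"` (default) selects the segment
#'   with the largest response magnitude and keeps its sign, so a
#'   strongly negative segment can shut a neuron off; `"max"` selects
#'   the largest signed response.
#' @param kwta_layers Integer vector of hidden-layer indices with kWTA;
#'   defaults to all hidden layers.
#'
#' @return An object of class `adn_spec`.
#' @seealso [count_nonzero_params()], [init_network()], [adn_preset()]
#' @export
#' @examples
#' spec <- network_spec(64, c(256, 256), 10, context_dim = 64,
#'                      weight_sparsity = 0.5, activation_density = 0.05,
#'                      num_segments = 5, segment_dim = 64,
#'                      modulated_layers = c(1, 2))
#' count_nonzero_params(spec)
network_spec <- function(input_dim, hidden_dims, output_dim,
                         context_dim = input_dim,
                         weight_sparsity = 0,
                         activation_density = 1,
                         num_segments = 0L,
                         segment_dim = context_dim,
                         modulated_layers = integer(0),
                         gating_mode = c("absolute_max", "max"),
                         kwta_layers = seq_along(hidden_dims)) {
  gating_mode <- match.arg(gating_mode)
  spec <- structure(
    list(input_dim = as.integer(input_dim),
         hidden_dims = as.integer(hidden_dims),
         output_dim = as.integer(output_dim),
         context_dim = as.integer(context_dim),
         weight_sparsity = as.numeric(weight_sparsity),
         activation_density = as.numeric(activation_density),
         num_segments = as.integer(num_segments),
         segment_dim = as.integer(segment_dim),
         modulated_layers = sort(unique(as.integer(modulated_layers))),
         gating_mode = gating_mode,
         kwta_layers = sort(unique(as.integer(kwta_layers)))),
    class = "adn_spec")
  validate_spec(spec)
  spec
}

validate_spec <- function(spec) {
  stopifnot(inherits(spec, "adn_spec"))
  with(spec, {
    if (input_dim < 1L || output_dim < 1L || any(hidden_dims < 1L))
      stop("layer sizes must be positive integers", call. = FALSE)
    if (segment_dim != context_dim)
      stop("segment_dim must equal context_dim", call. = FALSE)
    if (weight_sparsity < 0 || weight_sparsity >= 1)
      stop("weight_sparsity must lie in [0, 1)", call. = FALSE)
    if (activation_density <= 0 || activation_density > 1)
      stop("activation_density must lie in (0, 1]", call. = FALSE)
    if (num_segments < 0L)
      stop("num_segments must be non-negative", call. = FALSE)
    if (length(modulated_layers) &&
        (min(modulated_layers) < 1L || max(modulated_layers) > length(hidden_dims)))
      stop("modulated_layers must index hidden layers", call. = FALSE)
    if (length(modulated_layers) && num_segments == 0L)
      stop("modulated layers require num_segments >= 1", call. = FALSE)
    if (length(kwta_layers) &&
        (min(kwta_layers) < 1L || max(kwta_layers) > length(hidden_dims)))
      stop("kwta_layers must index hidden layers", call. = FALSE)
    for (l in kwta_layers)
      if (kwta_k(activation_density, hidden_dims[l]) < 1L)
        stop("activation_density keeps no unit in layer ", l, call. = FALSE)
  })
  invisible(spec)
}

# Winner count for a kWTA layer: at least one unit always survives.
kwta_k <- function(density, n) max(1L, as.integer(round(density * n)))

#' @export
print.adn_spec <- function(x, ...) {
  cat("Active Dendrites Network spec\n")
  cat("  layers:", x$input_dim, "->",
      paste(x$hidden_dims, collapse = " -> "), "->", x$output_dim, "\n")
  cat("  weight sparsity:", x$weight_sparsity,
      "| activation density:", x$activation_density, "\n")
  if (length(x$modulated_layers))
    cat("  dendrites:", x$num_segments, "segments x", x$segment_dim,
        "weights on hidden layer(s)",
        paste(x$modulated_layers, collapse = ", "),
        "|", x$gating_mode, "gating\n")
  cat("  kWTA on hidden layer(s):",
      if (length(x$kwta_layers)) paste(x$kwta_layers, collapse = ", ")
      else "none (ReLU)", "\n")
  cnt <- count_nonzero_params(x)
  cat("  non-zero parameters:", format(cnt$total, big.mark = ","),
      "(feedforward", format(cnt$feedforward_count, big.mark = ","),
      "+ dendritic", format(cnt$dendritic_count, big.mark = ","), ")\n")
  invisible(x)
}

#' Count the non-zero parameters of an architecture
#'
#' Feedforward counts are weight entries that survive the fixed
#' sparsity mask (`n - round(weight_sparsity * n)` per weight matrix)
#' plus all biases, which are never masked.  The dendritic count is
#' `units * num_segments * segment_dim` summed over modulated layers;
#' segments carry no biases.  The totals agree exactly with a
#' brute-force census of non-zero entries in instantiated parameters.
#'
#' @param spec An [network_spec()] object.
#' @return A list with `feedforward_count`, `dendritic_count`, `total`.
#' @export
#' @examples
#' # Classic continual-learning MLP-with-dendrites sizing:
#' count_nonzero_params(network_spec(784, c(2048, 2048), 10,
#'   weight_sparsity = 0.5, num_segments = 10, segment_dim = 784,
#'   modulated_layers = c(1, 2)))
count_nonzero_params <- function(spec) {
  validate_spec(spec)
  dims <- c(spec$input_dim, spec$hidden_dims, spec$output_dim)
  ff <- 0
  for (l in seq_len(length(dims) - 1L)) {
    n <- dims[l] * dims[l + 1L]
    ff <- ff + (n - round(spec$weight_sparsity * n)) + dims[l + 1L]
  }
  dd <- as.numeric(sum(spec$hidden_dims[spec$modulated_layers])) *
    spec$num_segments * spec$segment_dim
  list(feedforward_count = ff, dendritic_count = dd, total = ff + dd)
}

#' Preset architectures
#'
#' Two ready-made specifications:
#' \describe{
#'   \item{`"cl-permuted"`}{the permuted-image continual-learning
#'     network: 784 inputs, two hidden layers of 2048 Active Dendrites
#'     Neurons (both modulated, kWTA at 5\% density, 50\% weight
#'     sparsity), a 10-unit single-head output, and `num_tasks`
#'     dendritic segments of 784 weights per neuron.}
#'   \item{`"mt10-policy"`}{the multi-task robotic policy network: 39
#'     inputs, two hidden layers of 2800 units with kWTA at 25\%
#'     density and 10\% weight sparsity, a 4-unit output; only the
#'     second hidden layer is modulated, with 10 segments of 10
#'     weights (a one-hot task-ID context).}
#' }
#'
#' @param name Preset name.
#' @param num_tasks Number of tasks `T`; sets the segment count of the
#'   `"cl-permuted"` preset (ignored by `"mt10-policy"`).
#' @return An `adn_spec`.
#' @export
adn_preset <- function(name = c("cl-permuted", "mt10-policy"), num_tasks = 10L) {
  name <- match.arg(name)
  switch(name,
    "cl-permuted" = network_spec(
      input_dim = 784L, hidden_dims = c(2048L, 2048L), output_dim = 10L,
      context_dim = 784L, weight_sparsity = 0.5, activation_density = 0.05,
      num_segments = as.integer(num_tasks), segment_dim = 784L,
      modulated_layers = c(1L, 2L), gating_mode = "absolute_max",
      kwta_layers = c(1L, 2L)),
    "mt10-policy" = network_spec(
      input_dim = 39L, hidden_dims = c(2800L, 2800L), output_dim = 4L,
      context_dim = 10L, weight_sparsity = 0.10, activation_density = 0.25,
      num_segments = 10L, segment_dim = 10L,
      modulated_layers = 2L, gating_mode = "absolute_max",
      kwta_layers = c(1L, 2L)))
}

#' Size a dense MLP baseline to match an Active Dendrites Network
#'
#' Returns a dense, ReLU, dendrite-free spec with the same number of
#' hidden layers whose common hidden width is the smallest integer
#' giving at least as many non-zero parameters as `spec` (the baseline
#' is never smaller than the dendritic network it is compared with).
#'
#' @param spec An `adn_spec` to match.
#' @return An `adn_spec` describing the baseline MLP.
#' @export
matched_mlp_spec <- function(spec) {
  target <- count_nonzero_params(spec)$total
  nl <- length(spec$hidden_dims)
  count_for <- function(h) {
    count_nonzero_params(network_spec(
      spec$input_dim, rep(h, nl), spec$output_dim,
      context_dim = spec$context_dim, kwta_layers = integer(0)))$total
  }
  lo <- 1L
  hi <- max(spec$hidden_dims)
  while (count_for(hi) < target) hi <- hi * 2L
  while (lo < hi) {           # smallest h with count >= target
    mid <- (lo + hi) %/% 2L
    if (count_for(mid) >= target) hi <- mid else lo <- mid + 1L
  }
  network_spec(spec$input_dim, rep(lo, nl), spec$output_dim,
               context_dim = spec$context_dim, kwta_layers = integer(0))
}
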