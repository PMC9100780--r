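#' Prototype context vector of a set of samples
#'
#' The prototype of a task is the element-wise mean of its training
#' inputs, so context vectors live in input space and have the same
#' dimensionality as the inputs.
#'
#' @param samples `n x d` matrix of samples (a vector is one sample).
#' @return Length-`d` prototype vector.
#' @export
compute_prototype <- function(samples) {
  if (!is.matrix(samples)) samples <- matrix(samples, nrow = 1L)
  if (nrow(samples) == 0L)
    stop("cannot compute a prototype of zero samples", call. = FALSE)
  colMeans(samples)
}

#' Nearest prototype by Euclidean distance
#'
#' Used at inference time, when no task information is available: each
#' test example is routed to the stored prototype closest to it,
#' \eqn{\arg\min_\tau \|x' - p_\tau\|_2}.  Exact distance ties are
#' broken by lowest index (earliest-created prototype).
#'
#' @param x_prime A single sample (vector) or an `n x d` matrix.
#' @param store A [context_store()] with at least one prototype.
#' @return Integer prototype index (vector of indices for a matrix).
#' @export
nearest_prototype <- function(x_prime, store) {
  P <- store_prototype_matrix(store)
  if (nrow(P) == 0L)
    stop("context store holds no prototypes", call. = FALSE)
  if (!is.matrix(x_prime)) x_prime <- matrix(x_prime, nrow = 1L)
  # squared distance via ||x||^2 - 2 x.p + ||p||^2; row-constant ||x||^2
  # does not affect the argmin
  cross <- x_prime %*% t(P)
  d2 <- sweep(-2 * cross, 2L, rowSums(P^2), "+")
  max.col(-d2, ties.method = "first")
}

#' Hotelling's t-squared two-sample statistic
#'
#' The multivariate generalization of the squared unpaired two-sample
#' t statistic:
#' \deqn{t^2 = \frac{|X||Y|}{|X|+|Y|}(\bar x-\bar y)^\top
#'       \Sigma^{-1}(\bar x-\bar y)}
#' with \eqn{\Sigma} the pooled sample covariance.  The inverse is the
#' Moore-Penrose pseudo-inverse, so the statistic is defined even when
#' the pooled covariance is singular (e.g. small batches in high
#' dimension).
#'
#' @param X,Y Sample batches: `n x d` matrices (vectors are treated as
#'   univariate samples).  Both need at least two samples.
#' @param alpha Significance threshold used to fill the `reject` field
#'   (reject when `p_value < alpha`).
#' @return A list of class `adn_t2` with fields `t2`, `f`, `p_value`,
#'   `df` (`c(d, n_x + n_y - d - 1)`), `pooled_cov`, `mean_x`,
#'   `mean_y`, `reject`.  `f`, `p_value` and `reject` are `NA` in the
#'   degenerate case `n_x + n_y <= d + 1`.
#' @export
#' @examples
#' hotellings_t2(c(1, 2, 3), c(4, 5, 6))$t2   # 13.5
hotellings_t2 <- function(X, Y, alpha = 0.01) {
  if (!is.matrix(X)) X <- matrix(X, ncol = 1L)
  if (!is.matrix(Y)) Y <- matrix(Y, ncol = 1L)
  if (nrow(X) < 2L || nrow(Y) < 2L)
    stop("both samples need at least 2 observations", call. = FALSE)
  if (ncol(X) != ncol(Y))
    stop("samples have mismatched dimensionality", call. = FALSE)
  nx <- nrow(X); ny <- nrow(Y); d <- ncol(X)
  mx <- colMeans(X); my <- colMeans(Y)
  Sx <- crossprod(sweep(X, 2L, mx))
  Sy <- crossprod(sweep(Y, 2L, my))
  t2_from_stats(nx, mx, Sx, ny, my, Sy, d, alpha)
}

# Core computation from sufficient statistics (counts, means, centered
# scatter matrices); shared by hotellings_t2 and the cluster store.
t2_from_stats <- function(nx, mx, Sx, ny, my, Sy, d, alpha) {
  pooled <- (Sx + Sy) / (nx + ny - 2)
  delta <- mx - my
  t2 <- (nx * ny / (nx + ny)) *
    drop(crossprod(delta, MASS::ginv(pooled) %*% delta))
  t2 <- max(t2, 0)                # guard tiny negative round-off
  res <- list(t2 = t2, f = NA_real_, p_value = NA_real_,
              df = c(d, nx + ny - d - 1), pooled_cov = pooled,
              mean_x = mx, mean_y = my, reject = NA)
  if (nx + ny - d - 1 > 0) {
    res$f <- t2_to_f(t2, nx, ny, d)
    res$p_value <- stats::pf(res$f, d, nx + ny - d - 1, lower.tail = FALSE)
    res$reject <- res$p_value < alpha
  }
  class(res) <- "adn_t2"
  res
}

#' F transformation of Hotelling's t-squared
#'
#' Maps the statistic to an F-distributed quantity,
#' \deqn{f = \frac{n_x + n_y - d - 1}{d\,(n_x + n_y - 2)} t^2,}
#' which follows an F distribution with `(d, n_x + n_y - d - 1)`
#' degrees of freedom under the null hypothesis of equal means.
#'
#' @param t2 The t-squared statistic.
#' @param n_x,n_y Sample sizes.
#' @param d Dimensionality of the samples.
#' @return The transformed statistic `f`.
#' @export
t2_to_f <- function(t2, n_x, n_y, d) {
  n <- n_x + n_y
  if (n - d - 1 <= 0)
    stop("degenerate dimensionality: need n_x + n_y > d + 1 ",
         "(reduce d or pool more samples)", call. = FALSE)
  (n - d - 1) / (d * (n - 2)) * t2
}

#' @export
print.adn_t2 <- function(x, ...) {
  cat("Hotelling two-sample t-squared test\n")
  cat(sprintf("  t2 = %.4g, f = %.4g on (%d, %d) df, p = %.4g\n",
              x$t2, x$f, x$df[1L], x$df[2L], x$p_value))
  cat("  reject equal means:", x$reject, "\n")
  invisible(x)
}

#' Context store: prototypes and cluster statistics
#'
#' Holds the prototype vectors used as context inputs, and (for the
#' task-free regime) one cluster per discovered task with the state
#' needed for the multivariate t-test: sample count, streaming mean,
#' streaming centered scatter matrix, and a FIFO-capped set of stored
#' exemplars.  Prototypes equal the streaming mean of all samples ever
#' absorbed into the cluster, so the storage cap bounds memory without
#' degrading the prototype or the test's pooled covariance.
#'
#' @param d Sample dimensionality.
#' @param alpha Significance threshold for the batch-to-cluster t-test
#'   (see [assign_batch()]).  The default 0.001 keeps the family-wise
#'   rate of spuriously created clusters small over the hundreds of
#'   batch tests performed in a training run.
#' @param max_stored_per_cluster Cap on raw exemplars kept per cluster
#'   (FIFO); streaming statistics always cover every absorbed sample.
#' @param diagonal_cov If `TRUE`, the t-test uses only the diagonal of
#'   the pooled covariance (faster in high dimension; off by default).
#' @return An object of class `adn_context_store`.
#' @export
context_store <- function(d, alpha = 0.001, max_stored_per_cluster = 2048L,
                          diagonal_cov = FALSE) {
  structure(list(d = as.integer(d), alpha = alpha,
                 max_stored = as.integer(max_stored_per_cluster),
                 diagonal_cov = isTRUE(diagonal_cov),
                 clusters = list()),
            class = "adn_context_store")
}

#' @export
print.adn_context_store <- function(x, ...) {
  cat("Context store:", length(x$clusters), "cluster(s), d =", x$d,
      ", alpha =", x$alpha, "\n")
  for (j in seq_along(x$clusters))
    cat(sprintf("  cluster %d: %d samples absorbed\n", j, x$clusters[[j]]$n))
  invisible(x)
}

#' Number of prototypes (clusters) in a context store
#' @param store An `adn_context_store`.
#' @return Integer count.
#' @export
n_prototypes <- function(store) length(store$clusters)

store_prototype_matrix <- function(store) {
  if (!length(store$clusters))
    return(matrix(numeric(0), 0L, store$d))
  do.call(rbind, lapply(store$clusters, function(cl) cl$mean))
}

#' Prototypes currently held by a store
#' @param store An `adn_context_store`.
#' @return List of prototype vectors in creation order.
#' @export
store_prototypes <- function(store) {
  lapply(store$clusters, function(cl) cl$mean)
}

new_cluster <- function(X, cap) {
  n <- nrow(X)
  m <- colMeans(X)
  list(n = n, mean = m, scatter = crossprod(sweep(X, 2L, m)),
       samples = X[seq_len(min(n, cap)), , drop = FALSE])
}

absorb_into_cluster <- function(cl, X, cap) {
  nb <- nrow(X)
  mb <- colMeans(X)
  Sb <- crossprod(sweep(X, 2L, mb))
  delta <- mb - cl$mean
  ntot <- cl$n + nb
  # Chan et al. pairwise update of mean and centered scatter
  cl$scatter <- cl$scatter + Sb + outer(delta, delta) * (cl$n * nb / ntot)
  cl$mean <- cl$mean + delta * nb / ntot
  cl$n <- ntot
  cl$samples <- rbind(cl$samples, X)
  if (nrow(cl$samples) > cap)
    cl$samples <- cl$samples[seq.int(nrow(cl$samples) - cap + 1L,
                                     nrow(cl$samples)), , drop = FALSE]
  cl
}

#' Assign a batch to a task cluster (task-free context inference)
#'
#' Implements the online clustering used when no task information is
#' available during training.  The inductive bias is that all samples
#' in a batch come from one task.  The batch is compared, in cluster
#' creation order, with each existing cluster via the unpaired
#' multivariate t-test (Hotelling's t-squared, F transformation,
#' Moore-Penrose pseudo-inverse); the first cluster for which the
#' equal-means hypothesis is *not* rejected at level `alpha` absorbs
#' the batch and its prototype is updated to incorporate the new
#' samples.  If every test rejects, a new cluster is created with
#' prototype `colMeans(X)`.
#'
#' @param X Batch of samples, `n x d` matrix with `n >= 2`.
#' @param store An [context_store()].
#' @return List with the updated `store`, the 1-based `cluster` index
#'   the batch was assigned to, and `created` (`TRUE` if a new cluster
#'   was formed).
#' @export
assign_batch <- function(X, store) {
  stopifnot(inherits(store, "adn_context_store"))
  if (!is.matrix(X)) X <- matrix(X, ncol = store$d)
  if (ncol(X) != store$d)
    stop("batch dimensionality does not match the store", call. = FALSE)
  if (nrow(X) < 2L)
    stop("clustering needs at least 2 samples per batch", call. = FALSE)
  nb <- nrow(X)
  mb <- colMeans(X)
  Sb <- crossprod(sweep(X, 2L, mb))
  for (j in seq_along(store$clusters)) {
    cl <- store$clusters[[j]]
    Sx <- Sb; Sy <- cl$scatter
    if (store$diagonal_cov) {
      Sx <- diag(diag(Sx), nrow = store$d)
      Sy <- diag(diag(Sy), nrow = store$d)
    }
    res <- t2_from_stats(nb, mb, Sx, cl$n, cl$mean, Sy, store$d,
                         store$alpha)
    if (!isTRUE(res$reject)) {
      store$clusters[[j]] <- absorb_into_cluster(cl, X, store$max_stored)
      return(list(store = store, cluster = j, created = FALSE))
    }
  }
  store$clusters[[length(store$clusters) + 1L]] <-
    new_cluster(X, store$max_stored)
  list(store = store, cluster = length(store$clusters), created = TRUE)
}

#' Add a prototype computed from task-labeled data
#'
#' Used in the task-aware regime: the full training set of a task is
#' summarized by its element-wise mean and stored as a new cluster.
#'
#' @param store An [context_store()].
#' @param samples The task's training inputs (`n x d`).
#' @return The updated store.
#' @export
store_add_prototype <- function(store, samples) {
  stopifnot(inherits(store, "adn_context_store"))
  if (!is.matrix(samples)) samples <- matrix(samples, ncol = store$d)
  store$clusters[[length(store$clusters) + 1L]] <-
    new_cluster(samples, store$max_stored)
  store
}

#' Save / load a context store
#' @param store An `adn_context_store`.
#' @param path File path.
#' @return `adn_load_store` returns the restored store.
#' @export
adn_save_store <- function(store, path) {
  stopifnot(inherits(store, "adn_context_store"))
  saveRDS(store, path)
  invisible(path)
}

#' @rdname adn_save_store
#' @export
adn_load_store <- function(path) {
  store <- readRDS(path)
  stopifnot(inherits(store, "adn_context_store"))
  store
}

#' One-hot task context vectors
#' @param task Integer task index in `1..n_tasks`.
#' @param n_tasks Number of tasks.
#' @return Length-`n_tasks` one-hot vector.
#' @export
onehot_context <- function(task, n_tasks) {
  v <- numeric(n_tasks)
  v[task] <- 1
  v
}
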