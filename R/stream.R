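# Continual-learning task streams.  A stream is an ordered list of T
# tasks related by pixel-wise permutations: task 1 is the identity and
# every later task applies one fixed random permutation to all of its
# images.  Streams come either from user-supplied MNIST IDX files
# (build_permuted_tasks) or from a bundled synthetic generator with
# the same statistical structure (generate_synthetic_stream).

# Sub-seed table: a fixed block of seeds drawn from the master seed by
# a counter, so adding a consumer never perturbs existing streams.
derive_seeds <- function(master, n) {
  old <- get_rng_state()
  on.exit(set_rng_state(old), add = TRUE)
  set.seed(as.integer(master))
  sample.int(.Machine$integer.max, n)
}

new_task_stream <- function(tasks, dim, n_classes, seed) {
  structure(list(n_tasks = length(tasks), dim = dim,
                 n_classes = n_classes, seed = seed, tasks = tasks),
            class = "adn_task_stream")
}

#' @export
print.adn_task_stream <- function(x, ...) {
  cat("Task stream:", x$n_tasks, "task(s), input dim", x$dim, ",",
      x$n_classes, "classes, seed", x$seed, "\n")
  t1 <- x$tasks[[1L]]
  cat("  per task:", nrow(t1$train_x), "train /", nrow(t1$test_x),
      "test samples\n")
  invisible(x)
}

#' Synthetic permuted-task stream
#'
#' Generates a download-free stand-in for permutedMNIST with the same
#' statistical structure: a base task whose 10 balanced classes are
#' isotropic Gaussians around distinct means, and subsequent tasks
#' that apply a fixed pixel-wise permutation to the base samples.
#' Class mean `k` is `mu0 + class_separation * noise_sd * e_k`, where
#' `e_k` is the `k`-th coordinate vector and `mu0` is a common
#' non-constant baseline (zero-mean uniform on
#' `[-2 * noise_sd, 2 * noise_sd]` per coordinate).  The baseline
#' plays the role of the structured mean image in handwritten-digit
#' data: permuting a non-constant vector moves it, so task prototypes
#' (element-wise means) are well separated across tasks, while
#' pairwise class-mean distances are at least
#' `class_separation * noise_sd * sqrt(2)`, so classes are separable
#' by input mean within every task.  The baseline is centered on zero
#' so that task prototypes do not share a large common-mean component
#' (which would make all task contexts nearly collinear).
#'
#' @param n_classes Number of classes (default 10, labels `0..9`).
#' @param dim Input dimensionality (`>= n_classes`).
#' @param n_tasks Number of tasks `T`.
#' @param class_separation Distance between a class mean and the
#'   baseline, in units of `noise_sd` (default 5).
#' @param noise_sd Isotropic Gaussian noise standard deviation.
#' @param n_train,n_test Samples per task (balanced across classes;
#'   must be multiples of `n_classes`).
#' @param seed Master seed; equal seeds give byte-identical streams.
#' @return An `adn_task_stream`: each task holds `task_id`, `perm`
#'   (permutation of `1..dim`; task 1 is the identity), and
#'   `train_x`/`train_y`/`test_x`/`test_y`.
#' @export
generate_synthetic_stream <- function(n_classes = 10L, dim = 64L,
                                      n_tasks = 5L, class_separation = 5,
                                      noise_sd = 1, n_train = 2000L,
                                      n_test = 500L, seed = 1L) {
  n_classes <- as.integer(n_classes); dim <- as.integer(dim)
  n_tasks <- as.integer(n_tasks)
  if (dim < n_classes)
    stop("dim must be at least n_classes", call. = FALSE)
  if (n_tasks < 1L || n_train < n_classes || n_test < n_classes)
    stop("invalid task or sample counts", call. = FALSE)
  if (n_train %% n_classes || n_test %% n_classes)
    stop("n_train and n_test must be multiples of n_classes",
         call. = FALSE)
  seeds <- derive_seeds(seed, 2L + n_tasks)
  old <- get_rng_state()
  on.exit(set_rng_state(old), add = TRUE)

  set.seed(seeds[1L])
  mu0 <- stats::runif(dim, -2 * noise_sd, 2 * noise_sd)
  means <- matrix(rep(mu0, each = n_classes), n_classes, dim)
  means[cbind(seq_len(n_classes), seq_len(n_classes))] <-
    means[cbind(seq_len(n_classes), seq_len(n_classes))] +
    class_separation * noise_sd

  draw_split <- function(n_per_class) {
    y <- rep(seq_len(n_classes) - 1L, each = n_per_class)
    X <- means[y + 1L, , drop = FALSE] +
      matrix(stats::rnorm(length(y) * dim, sd = noise_sd), ncol = dim)
    idx <- sample.int(length(y))
    list(x = X[idx, , drop = FALSE], y = y[idx])
  }
  set.seed(seeds[2L])
  base_train <- draw_split(n_train %/% n_classes)
  base_test <- draw_split(n_test %/% n_classes)

  tasks <- vector("list", n_tasks)
  for (tau in seq_len(n_tasks)) {
    if (tau == 1L) {
      perm <- seq_len(dim)
    } else {
      set.seed(seeds[2L + tau])
      perm <- sample.int(dim)
    }
    tasks[[tau]] <- list(task_id = tau, perm = perm,
                         train_x = base_train$x[, perm, drop = FALSE],
                         train_y = base_train$y,
                         test_x = base_test$x[, perm, drop = FALSE],
                         test_y = base_test$y)
  }
  new_task_stream(tasks, dim, n_classes, seed)
}

#' Build a permuted-task stream from image data
#'
#' Replicates a labeled image set `T` times, applying to each replica
#' a unique pixel-wise permutation (task 1 is the identity, i.e. the
#' original data).  The same permutation is applied to a task's train
#' and test images, and labels are preserved.  By default the supplied
#' train and test sets are used as-is for every task; with
#' `holdout_test = TRUE` the final 10,000 training images are held out
#' as the test set instead (and `test_x`/`test_y` may be omitted).
#'
#' @param train_x `n x d` matrix of flattened images, values scaled to
#'   `[0, 1]` (e.g. pixel value / 255).
#' @param train_y Integer labels in `0..9`, aligned with `train_x`.
#' @param test_x,test_y Held-out images and labels (same format).
#' @param n_tasks Number of tasks `T >= 1`.
#' @param seed Master seed for the permutations.
#' @param holdout_test If `TRUE`, carve the last 10,000 rows of
#'   `train_x` off as the test set.
#' @return An `adn_task_stream`.
#' @export
build_permuted_tasks <- function(train_x, train_y, test_x = NULL,
                                 test_y = NULL, n_tasks = 10L, seed = 1L,
                                 holdout_test = FALSE) {
  n_tasks <- as.integer(n_tasks)
  if (n_tasks < 1L) stop("n_tasks must be >= 1", call. = FALSE)
  if (nrow(train_x) != length(train_y))
    stop("train_x and train_y lengths differ", call. = FALSE)
  if (holdout_test) {
    n_hold <- min(10000L, nrow(train_x) %/% 6L)
    keep <- seq_len(nrow(train_x) - n_hold)
    test_x <- train_x[-keep, , drop = FALSE]
    test_y <- train_y[-keep]
    train_x <- train_x[keep, , drop = FALSE]
    train_y <- train_y[keep]
  }
  if (is.null(test_x) || is.null(test_y))
    stop("test_x/test_y are required unless holdout_test = TRUE",
         call. = FALSE)
  if (nrow(test_x) != length(test_y))
    stop("test_x and test_y lengths differ", call. = FALSE)
  d <- ncol(train_x)
  seeds <- derive_seeds(seed, n_tasks)
  old <- get_rng_state()
  on.exit(set_rng_state(old), add = TRUE)
  tasks <- vector("list", n_tasks)
  for (tau in seq_len(n_tasks)) {
    if (tau == 1L) {
      perm <- seq_len(d)
    } else {
      set.seed(seeds[tau])
      perm <- sample.int(d)   # seeded Fisher-Yates draw
    }
    tasks[[tau]] <- list(task_id = tau, perm = perm,
                         train_x = train_x[, perm, drop = FALSE],
                         train_y = as.integer(train_y),
                         test_x = test_x[, perm, drop = FALSE],
                         test_y = as.integer(test_y))
  }
  new_task_stream(tasks, d, length(unique(train_y)), seed)
}

#' Read an IDX-format array (MNIST distribution format)
#'
#' Parses the big-endian IDX binary format used by the standard MNIST
#' files: a magic number (two zero bytes, a type code, and the number
#' of dimensions), one big-endian 32-bit size per dimension, then the
#' payload in row-major order.  Only the unsigned-byte type code
#' (0x08) is supported, which covers all MNIST files.
#'
#' @param path Path to an IDX file.
#' @return An integer array with the dimensions declared in the
#'   header (row-major order preserved: for MNIST images the result is
#'   `n x 28 x 28`).
#' @export
read_idx <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  magic <- readBin(con, "integer", n = 4L, size = 1L, signed = FALSE)
  if (length(magic) < 4L || magic[1L] != 0L || magic[2L] != 0L)
    stop("not an IDX file: bad magic number", call. = FALSE)
  if (magic[3L] != 0x08)
    stop("unsupported IDX type code ", magic[3L],
         " (only unsigned byte, 0x08, is supported)", call. = FALSE)
  ndim <- magic[4L]
  dims <- readBin(con, "integer", n = ndim, size = 4L, endian = "big")
  if (length(dims) < ndim || any(dims < 0L))
    stop("truncated or corrupt IDX header", call. = FALSE)
  n <- prod(dims)
  payload <- readBin(con, "integer", n = n, size = 1L, signed = FALSE)
  if (length(payload) < n)
    stop("truncated IDX payload: expected ", n, " bytes, got ",
         length(payload), call. = FALSE)
  if (ndim == 1L) return(payload)
  # payload is row-major (last dimension fastest); fill an array in
  # reversed dimension order and transpose back
  aperm(array(payload, dim = rev(dims)), rev(seq_len(ndim)))
}

#' Write an array in IDX format
#'
#' Inverse of [read_idx()] for unsigned-byte arrays; mainly useful for
#' tests and for preparing small fixtures.
#'
#' @param x Integer array or vector with values in `0..255`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_idx <- function(x, path) {
  dims <- dim(x) %||% length(x)
  if (any(x < 0 | x > 255)) stop("values must be in 0..255", call. = FALSE)
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeBin(as.raw(c(0L, 0L, 0x08, length(dims))), con)
  writeBin(as.integer(dims), con, size = 4L, endian = "big")
  flat <- if (length(dims) > 1L)
    as.vector(aperm(x, rev(seq_along(dims)))) else as.vector(x)
  writeBin(as.raw(flat), con)
  invisible(path)
}

#' Load MNIST IDX files into a permuted-task stream
#'
#' Convenience wrapper: reads the four standard MNIST files from a
#' directory, flattens and scales images to `[0, 1]`, and builds a
#' permuted-task stream.
#'
#' @param dir Directory containing `train-images-idx3-ubyte`,
#'   `train-labels-idx1-ubyte`, `t10k-images-idx3-ubyte`,
#'   `t10k-labels-idx1-ubyte` (optionally with `.idx` suffixes).
#' @param n_tasks,seed,holdout_test Passed to [build_permuted_tasks()].
#' @return An `adn_task_stream`.
#' @export
load_mnist_stream <- function(dir, n_tasks = 10L, seed = 1L,
                              holdout_test = FALSE) {
  find <- function(base) {
    for (cand in c(base, paste0(base, ".idx"))) {
      p <- file.path(dir, cand)
      if (file.exists(p)) return(p)
    }
    stop("MNIST file not found: ", base, call. = FALSE)
  }
  flat <- function(a) {
    d <- dim(a)
    matrix(as.numeric(a), d[1L], d[2L] * d[3L]) / 255
  }
  train_x <- flat(read_idx(find("train-images-idx3-ubyte")))
  train_y <- read_idx(find("train-labels-idx1-ubyte"))
  test_x <- flat(read_idx(find("t10k-images-idx3-ubyte")))
  test_y <- read_idx(find("t10k-labels-idx1-ubyte"))
  build_permuted_tasks(train_x, train_y, test_x, test_y,
                       n_tasks = n_tasks, seed = seed,
                       holdout_test = holdout_test)
}

#' Save / load a task stream
#' @param stream An `adn_task_stream`.
#' @param path File path.
#' @return `adn_load_stream` returns the restored stream.
#' @export
adn_save_stream <- function(stream, path) {
  stopifnot(inherits(stream, "adn_task_stream"))
  saveRDS(stream, path)
  invisible(path)
}

#' @rdname adn_save_stream
#' @export
adn_load_stream <- function(path) {
  stream <- readRDS(path)
  stopifnot(inherits(stream, "adn_task_stream"))
  stream
}
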