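test_that("prototypes are element-wise means in input space", {
  expect_equal(compute_prototype(rbind(c(0, 2), c(2, 0))), c(1, 1))
  x <- rnorm(5)
  expect_equal(compute_prototype(x), x)
  expect_error(compute_prototype(matrix(numeric(0), 0, 3)), "zero samples")
})

test_that("nearest_prototype picks the closest stored prototype", {
  store <- context_store(2)
  store <- store_add_prototype(store, rbind(c(1, 1), c(1, 1)))
  store <- store_add_prototype(store, rbind(c(5, 5), c(5, 5)))
  expect_equal(nearest_prototype(c(0.9, 1.1), store), 1L)
  expect_equal(nearest_prototype(c(5, 5), store), 2L)   # zero distance
  expect_equal(nearest_prototype(rbind(c(0, 0), c(9, 9)), store), c(1L, 2L))
  expect_error(nearest_prototype(c(1, 1), context_store(2)),
               "no prototypes")
})

test_that("test samples route to their own task's prototype", {
  stream <- bench_stream(0)
  store <- context_store(stream$dim)
  for (tau in 1:5)
    store <- store_add_prototype(store, stream$tasks[[tau]]$train_x)
  # 1000 draws from task 2: nearly all must land on prototype 2
  X <- stream$tasks[[2]]$test_x
  idx <- nearest_prototype(X[rep_len(seq_len(nrow(X)), 1000), ], store)
  expect_gte(mean(idx == 2L), 0.99)
  # brute-force distance oracle agrees on a subsample
  P <- do.call(rbind, store_prototypes(store))
  for (i in 1:25) {
    x <- X[i, ]
    expect_equal(idx[i],
                 which.min(apply(P, 1, function(p) sum((x - p)^2))))
  }
})

test_that("hotellings_t2 matches the squared classical t statistic", {
  res <- hotellings_t2(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$t2, 13.5)
  expect_equal(res$f, 13.5)      # prefactor (6-1-1)/(1*(6-2)) = 1
  # 50 seeded univariate instances against stats::t.test
  for (s in 1:50) {
    set.seed(s)
    x <- rnorm(sample(3:30, 1), mean = runif(1, -2, 2), sd = runif(1, 0.5, 2))
    y <- rnorm(sample(3:30, 1), mean = runif(1, -2, 2), sd = runif(1, 0.5, 2))
    oracle <- unname(stats::t.test(x, y, var.equal = TRUE)$statistic)^2
    expect_equal(hotellings_t2(x, y)$t2, oracle, tolerance = 1e-10)
  }
})

test_that("t2 is zero for equal means and follows the closed form", {
  X <- rbind(c(1, 2), c(3, 4), c(5, 0))
  shift <- matrix(rep(c(10, -3), each = 3), 3)
  expect_equal(hotellings_t2(X, X)$t2, 0)
  # engineered pooled identity covariance: t2 = (nx ny/(nx+ny)) ||delta||^2
  A <- rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1)) * sqrt(6 / 4)
  delta <- c(0.7, -0.4)
  X2 <- A                                  # mean 0, scatter = 1.5 * I * ...
  Y2 <- sweep(A, 2, delta, "+")
  res <- hotellings_t2(X2, Y2)
  expect_equal(res$pooled_cov, diag(2) * (2 * 1.5) / (8 - 2) * 2)
  expect_equal(res$t2,
               (4 * 4 / 8) * sum(delta^2) / res$pooled_cov[1, 1])
  expect_error(hotellings_t2(c(1), c(2, 3)), "at least 2")
})

test_that("t2 is symmetric and invariant to common coordinate permutation", {
  set.seed(77)
  for (i in 1:10) {
    X <- matrix(rnorm(8 * 4), 8)
    Y <- matrix(rnorm(6 * 4, mean = 0.5), 6)
    expect_equal(hotellings_t2(X, Y)$t2, hotellings_t2(Y, X)$t2)
    p <- sample(4)
    expect_equal(hotellings_t2(X[, p], Y[, p])$t2,
                 hotellings_t2(X, Y)$t2, tolerance = 1e-8)
  }
})

test_that("t2_to_f applies the printed prefactor and guards degeneracy", {
  expect_equal(t2_to_f(13.5, 3, 3, 1), 13.5)
  expect_equal(t2_to_f(0, 10, 10, 3), 0)
  expect_equal(t2_to_f(4, 10, 10, 2), (17 / 36) * 4)
  expect_error(t2_to_f(1, 3, 3, 6), "degenerate")
  # degenerate case is reported as NA by the test object, not an error
  res <- hotellings_t2(matrix(rnorm(8), 2, 4), matrix(rnorm(8), 2, 4))
  expect_true(is.na(res$f) && is.na(res$reject))
})

test_that("type-I error of the batch test is near its nominal level", {
  set.seed(2024)
  alpha <- 0.05
  rejections <- replicate(300, {
    X <- matrix(rnorm(64 * 5), 64)
    Y <- matrix(rnorm(64 * 5), 64)
    isTRUE(hotellings_t2(X, Y, alpha = alpha)$reject)
  })
  expect_lte(mean(rejections), 2 * alpha)
})

test_that("assign_batch grows and reuses clusters correctly", {
  set.seed(5)
  store <- context_store(3, alpha = 0.01)
  X1 <- matrix(rnorm(40 * 3), 40)
  a1 <- assign_batch(X1, store)
  expect_true(a1$created)
  expect_equal(a1$cluster, 1L)
  expect_equal(store_prototypes(a1$store)[[1]], colMeans(X1))
  # a second batch from the same distribution joins cluster 1
  X2 <- matrix(rnorm(40 * 3), 40)
  a2 <- assign_batch(X2, a1$store)
  expect_false(a2$created)
  expect_equal(a2$cluster, 1L)
  # prototype updated to the mean of all absorbed samples
  expect_equal(store_prototypes(a2$store)[[1]],
               colMeans(rbind(X1, X2)))
  # a 10-pooled-sd shift forms a new cluster
  X3 <- matrix(rnorm(40 * 3, mean = 10), 40)
  a3 <- assign_batch(X3, a2$store)
  expect_true(a3$created)
  expect_equal(a3$cluster, 2L)
})

test_that("cluster store caps exemplars but keeps exact statistics", {
  set.seed(6)
  store <- context_store(2, alpha = 1e-9, max_stored_per_cluster = 30L)
  XA <- matrix(rnorm(25 * 2), 25)
  XB <- matrix(rnorm(25 * 2), 25)
  st <- assign_batch(XB, assign_batch(XA, store)$store)$store
  cl <- st$clusters[[1]]
  expect_equal(nrow(cl$samples), 30L)            # FIFO cap
  expect_equal(cl$n, 50L)                        # streaming count is exact
  all_x <- rbind(XA, XB)
  expect_equal(cl$mean, colMeans(all_x))
  expect_equal(cl$scatter, crossprod(sweep(all_x, 2, colMeans(all_x))),
               tolerance = 1e-10)
})

test_that("online clustering recovers the five tasks of the stream", {
  stream <- bench_stream(0)
  store <- context_store(stream$dim, alpha = 0.001)
  set.seed(123)
  assigned <- matrix(NA_integer_, 5, 8)
  for (tau in 1:5) {
    X <- stream$tasks[[tau]]$train_x
    idx <- sample(nrow(X))
    for (b in 1:8) {
      rows <- idx[((b - 1) * 250 + 1):(b * 250)]
      a <- assign_batch(X[rows, , drop = FALSE], store)
      store <- a$store
      assigned[tau, b] <- a$cluster
    }
  }
  expect_equal(length(store$clusters), 5L)
  # every batch of task tau lands in cluster tau (creation order)
  expect_equal(assigned, matrix(rep(1:5, 8), 5, 8))
})

test_that("context store serialization round-trips", {
  set.seed(3)
  store <- assign_batch(matrix(rnorm(20), 10), context_store(2))$store
  path <- withr::local_tempfile(fileext = ".rds")
  adn_save_store(store, path)
  expect_identical(adn_load_store(path), store)
})
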