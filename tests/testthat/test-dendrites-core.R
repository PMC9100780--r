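test_that("dendritic_response selects segments per gating mode", {
  U <- rbind(c(0.3, 0), c(-1.2, 0), c(0.5, 0))
  ctx <- c(1, 0)
  abs_sel <- dendritic_response(U, ctx, "absolute_max")
  expect_equal(abs_sel$d, -1.2)
  expect_equal(abs_sel$j_star, 2L)
  max_sel <- dendritic_response(U, ctx, "max")
  expect_equal(max_sel$d, 0.5)
  expect_equal(max_sel$j_star, 3L)
  # all-zero segments respond with 0 to any context
  zero <- dendritic_response(matrix(0, 4, 2), rnorm(2))
  expect_equal(zero$d, 0)
  expect_error(dendritic_response(U, c(1, 2, 3)), "segment_dim")
  expect_error(dendritic_response(matrix(numeric(0), 0, 2), ctx),
               "zero dendritic segments")
})

test_that("gate is sigmoidal attenuation", {
  expect_equal(gate(5, 0), 2.5)
  expect_equal(gate(2, -1.2), 2 / (1 + exp(1.2)))
  expect_equal(gate(0, 17), 0)
  # attenuation: |gate| <= |t_hat|; strictly increasing in d for t_hat > 0
  t_hat <- rnorm(200)
  d <- rnorm(200, sd = 3)
  expect_true(all(abs(gate(t_hat, d)) <= abs(t_hat)))
  ds <- sort(rnorm(50))
  expect_true(all(diff(gate(1.7, ds)) > 0))
})

test_that("kwta keeps exactly the top k and zeroes the rest", {
  expect_equal(kwta(c(3, 1, 4, 1, 5), 2), c(0, 0, 4, 0, 5))
  v <- rnorm(20)
  expect_equal(kwta(v, 20), v)
  expect_equal(kwta(c(1, 1, 1), 1), c(1, 0, 0))  # lowest-index tie-break
  expect_error(kwta(v, 0), "k must lie")
  expect_error(kwta(v, 21), "k must lie")
  # conservation: distinct values give exactly k non-zeros, bit-exact
  for (i in 1:20) {
    v <- sample(rnorm(50))
    k <- sample(1:50, 1)
    out <- kwta(v, k)
    expect_identical(sum(out != 0), as.integer(k))
    kept <- which(out != 0)
    expect_identical(out[kept], v[kept])
    expect_true(min(v[kept]) >= max(v[-kept]))
  }
})

test_that("sparsity masks have exact zero counts and are reproducible", {
  expect_equal(make_sparsity_mask(c(3, 4), 0), matrix(1, 3, 4))
  m <- make_sparsity_mask(c(10, 10), 0.1, seed = 5)
  expect_equal(sum(m == 0), 10)
  expect_identical(m, make_sparsity_mask(c(10, 10), 0.1, seed = 5))
  expect_equal(sum(make_sparsity_mask(c(7, 9), 0.33, seed = 1) == 0),
               round(0.33 * 63))
  expect_error(make_sparsity_mask(c(2, 2), 1), "weight_sparsity")
})

test_that("forward pass enforces kWTA sparsity and gating semantics", {
  spec <- tiny_spec()
  params <- init_network(spec, seed = 11)
  x <- matrix(rnorm(6 * 12), 6)
  ctx <- rnorm(12)
  fwd <- adn_forward(params, x, ctx, keep_trace = TRUE)
  expect_equal(dim(fwd$logits), c(6L, 4L))
  for (l in 1:2) {
    tr <- fwd$trace[[l]]
    k <- max(1L, round(0.25 * spec$hidden_dims[l]))
    expect_equal(unname(rowSums(tr$winners)), rep(k, 6))
    expect_equal(unname(rowSums(tr$y != 0)), rep(k, 6))
    # |y_hat| <= |t_hat| elementwise before kWTA: check via gate identity
    expect_true(all(abs(tr$t_hat * tr$sig_d) <= abs(tr$t_hat) + 1e-15))
  }
  # all-zero context: every modulated neuron outputs 0.5 * t_hat pre-kWTA
  fwd0 <- adn_forward(params, x, numeric(12), keep_trace = TRUE)
  tr <- fwd0$trace[[1]]
  expect_equal(tr$t_hat * tr$sig_d, tr$t_hat * 0.5)
  # missing context on a modulated network errors
  expect_error(adn_forward(params, x), "context is required")
})

test_that("RL-style hidden layer yields exactly 25% non-zero activations", {
  spec <- adn_preset("mt10-policy")
  params <- init_network(spec, seed = 2)
  x <- matrix(rnorm(3 * 39), 3)
  fwd <- adn_forward(params, x, onehot_context(4, 10), keep_trace = TRUE)
  expect_equal(unname(rowSums(fwd$trace[[1]]$y != 0)), rep(700, 3))
  expect_equal(unname(rowSums(fwd$trace[[2]]$y != 0)), rep(700, 3))
})

test_that("analytic parameter counts equal a brute-force census", {
  set.seed(404)
  for (i in 1:20) {
    nh <- sample(1:3, 1)
    hidden <- sample(5:40, nh, replace = TRUE)
    mod <- which(stats::runif(nh) < 0.6)
    segs <- if (length(mod)) sample(1:6, 1) else 0L
    ctx <- sample(3:20, 1)
    spec <- network_spec(sample(3:30, 1), hidden, sample(2:12, 1),
                         context_dim = ctx,
                         weight_sparsity = sample(c(0, 0.1, 0.5, 0.9), 1),
                         activation_density = 1,
                         num_segments = segs, segment_dim = ctx,
                         modulated_layers = mod)
    params <- init_network(spec, seed = i)
    expect_identical(unlist(count_nonzero_params(spec)),
                     unlist(census_nonzero_params(params)))
  }
  # dense spec equals the full weight + bias census
  dense <- network_spec(7, c(9, 8), 3)
  expect_equal(count_nonzero_params(dense)$total,
               7 * 9 + 9 * 8 + 8 * 3 + 9 + 8 + 3)
})

test_that("spec validation rejects inconsistent architectures", {
  expect_error(network_spec(10, c(8, 8), 2, context_dim = 5,
                            segment_dim = 4), "segment_dim")
  expect_error(network_spec(10, 8, 2, weight_sparsity = 1), "weight_sparsity")
  expect_error(network_spec(10, 8, 2, modulated_layers = 3,
                            num_segments = 2), "modulated_layers")
  expect_error(network_spec(10, 8, 2, modulated_layers = 1,
                            num_segments = 0), "num_segments")
})

test_that("parameter serialization round-trips", {
  params <- init_network(tiny_spec(), seed = 9)
  path <- withr::local_tempfile(fileext = ".rds")
  adn_save_params(params, path)
  expect_identical(adn_load_params(path), params)
})
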