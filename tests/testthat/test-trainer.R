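# The sequential-task harness.  Small streams and short schedules keep
# these fast; the full benchmark comparison lives in test-acceptance.R.

small_stream <- function(seed = 3L, n_tasks = 2L) {
  generate_synthetic_stream(n_classes = 5, dim = 16, n_tasks = n_tasks,
                            n_train = 200, n_test = 100, seed = seed)
}

small_spec <- function(ctx = 16L) {
  network_spec(16, c(32L, 32L), 5L, context_dim = ctx,
               weight_sparsity = 0.5, activation_density = 0.1,
               num_segments = 2L, segment_dim = ctx,
               modulated_layers = c(1L, 2L))
}

test_that("config validation and per-T hyperparameter defaults", {
  expect_error(train_config(batch_size = 1), "batch_size")
  expect_error(train_config(learning_rate = -1), "learning rate")
  cfg <- adnet:::resolve_config(train_config("prototype_given"), 10L)
  expect_equal(cfg$learning_rate, 5e-4)
  expect_equal(cfg$epochs_per_task, 3L)
  cfg <- adnet:::resolve_config(train_config("prototype_inferred"), 2L)
  expect_equal(cfg$learning_rate, 1e-3)
  expect_equal(cfg$epochs_per_task, 5L)
  # unlisted task counts fall back to the T = 10 row
  cfg <- adnet:::resolve_config(train_config("prototype_given"), 7L)
  expect_equal(cfg$learning_rate, 5e-4)
})

test_that("context dimension mismatches are configuration errors", {
  st <- small_stream()
  expect_error(
    train_continual(small_spec(ctx = 5L), st,
                    train_config("prototype_given", epochs_per_task = 1)),
    "context_dim")
  expect_error(
    train_continual(small_spec(ctx = 16L), st,
                    train_config("onehot", epochs_per_task = 1)),
    "context_dim")
})

test_that("an untrained network scores at chance on balanced classes", {
  st <- small_stream()
  params <- init_network(small_spec(), seed = 5)
  store <- context_store(16)
  for (tau in 1:2)
    store <- store_add_prototype(store, st$tasks[[tau]]$train_x)
  rep <- evaluate_all_tasks(params, st, store, "prototype_given")
  expect_gt(rep$mean_accuracy, 0.05)
  expect_lt(rep$mean_accuracy, 0.40)
})

test_that("single-task training learns separable data", {
  st <- small_stream(n_tasks = 1L)
  cfg <- train_config("prototype_given", epochs_per_task = 50,
                      learning_rate = 1e-2, batch_size = 50L, seed = 0)
  fit <- train_continual(small_spec(), st, cfg)
  expect_length(fit$report$per_task_accuracy, 1L)
  expect_equal(fit$report$mean_accuracy, fit$report$per_task_accuracy[1])
  expect_gte(fit$report$mean_accuracy, 0.9)
  # training accuracy on the task's own data is at least as good
  train_rep <- evaluate_all_tasks(
    fit$params,
    local({ s <- st; s$tasks[[1]]$test_x <- s$tasks[[1]]$train_x
            s$tasks[[1]]$test_y <- s$tasks[[1]]$train_y; s }),
    fit$store, "prototype_given", task_cluster = fit$task_cluster)
  expect_gte(train_rep$mean_accuracy, 0.95)
})

test_that("reports are weighted means with accuracies in [0, 1]", {
  st <- small_stream()
  cfg <- train_config("prototype_given", epochs_per_task = 2, seed = 1)
  fit <- train_continual(small_spec(), st, cfg)
  rep <- fit$report
  expect_true(all(rep$per_task_accuracy >= 0 & rep$per_task_accuracy <= 1))
  expect_equal(rep$mean_accuracy,
               sum(rep$per_task_accuracy * rep$n_test) / sum(rep$n_test))
  # single shared head with n_classes output units, reused across tasks
  expect_equal(nrow(fit$params$output$W), 5L)
})

test_that("identical seeds and configs give identical runs", {
  st <- small_stream()
  cfg <- train_config("prototype_given", epochs_per_task = 2, seed = 11)
  f1 <- train_continual(small_spec(), st, cfg)
  f2 <- train_continual(small_spec(), st, cfg)
  expect_identical(f1$report, f2$report)
  expect_identical(f1$params, f2$params)
})

test_that("one-hot and inferred-context regimes train end to end", {
  st <- small_stream()
  f_one <- train_continual(small_spec(ctx = 2L), st,
                           train_config("onehot", epochs_per_task = 2,
                                        seed = 2))
  expect_length(f_one$report$per_task_accuracy, 2L)
  expect_true(is.na(f_one$report$context_assignment_accuracy))

  f_inf <- train_continual(small_spec(), st,
                           train_config("prototype_inferred",
                                        epochs_per_task = 2, seed = 2,
                                        batch_size = 64L))
  # the two well-separated tasks map to two clusters, in order
  expect_equal(n_prototypes(f_inf$store), 2L)
  expect_equal(f_inf$task_cluster, 1:2)
  expect_gte(f_inf$report$context_assignment_accuracy, 0.95)
})

test_that("run_sweep rows agree with direct training calls", {
  st <- small_stream()
  cfg <- train_config("prototype_given", epochs_per_task = 2, seed = 4)
  spec <- small_spec()
  sw <- run_sweep(spec, st, cfg, "num_segments", values = 2L)
  direct <- train_continual(spec, st, cfg)
  expect_equal(nrow(sw), 1L)
  expect_equal(sw$mean_accuracy, direct$report$mean_accuracy)
  expect_error(run_sweep(spec, st, cfg, "num_segments", numeric(0)),
               "non-empty")
})

test_that("eval history exposes forgetting of the first task", {
  fit <- bench_run("mlp", seed = 0)
  h <- fit$history
  # accuracy on task 1 right after learning it vs after the last task
  expect_gt(h[1, 1], h[5, 1])
})
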