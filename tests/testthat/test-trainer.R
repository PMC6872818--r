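small_ctrl <- function(seed = 1, iterations = 60, particles = 15) {
  swarm_control(particles = particles, iterations = iterations,
                lower = -3, upper = 3, seed = seed)
}

test_that("the training objective is the mean squared error", {
  arch <- network_arch(c(2, 2, 1))
  theta <- rep(0, parameter_count(arch))
  x <- matrix(0, 2, 2)
  expect_equal(training_objective(theta, arch, x, c(1, 1)), 1)
  expect_equal(training_objective(theta, arch, x, c(1, 1)),
               rmsep(c(1, 1), predict_batch(arch, theta, x))^2)
  expect_error(training_objective(theta, arch, matrix(0, 0, 2), numeric(0)),
               class = "capsonet_data_error")
  expect_error(training_objective(theta, arch, x, 1:3),
               class = "capsonet_contract_error")
})

test_that("training is seeded-deterministic and shape-checked up front", {
  task <- teacher_task()
  a <- capso_train(task$train, validation = task$validation,
                   control = small_ctrl())
  b <- capso_train(task$train, validation = task$validation,
                   control = small_ctrl())
  expect_identical(a$theta, b$theta)
  expect_identical(a$train_mse, b$train_mse)
  expect_true(all(diff(a$trace$best_value) <= 0))
  expect_equal(a$evaluations, 15 * (a$iterations_run + 1))

  expect_error(
    capso_train(task$train, arch = network_arch(c(5, 3, 1)),
                control = small_ctrl()),
    class = "capsonet_config_error"
  )
  expect_error(
    capso_train(dplyr::select(task$train, -Os), control = small_ctrl()),
    class = "capsonet_data_error"
  )
  expect_error(capso_train(task$train[0, ], control = small_ctrl()),
               class = "capsonet_data_error")
})

test_that("a zero-iteration budget returns the best random particle", {
  task <- teacher_task()
  fit <- capso_train(task$train, control = small_ctrl(iterations = 0))
  expect_equal(fit$iterations_run, 0L)
  # the model's parameters evaluate exactly to the reported training MSE
  frame <- apply_normalization(task$train, fit$norm)
  x <- as.matrix(frame[, qspr_descriptors()])
  expect_equal(training_objective(fit$theta, fit$arch, x, frame$E),
               fit$train_mse)
})

test_that("checkpoints monitor train and validation MSE", {
  task <- teacher_task()
  fit <- capso_train(task$train, validation = task$validation,
                     control = small_ctrl(iterations = 40),
                     checkpoint_every = 10)
  expect_equal(fit$checkpoints$iteration, c(10, 20, 30, 40))
  expect_true(all(is.finite(fit$checkpoints$val_mse)))
  expect_true(all(diff(fit$checkpoints$train_mse) <= 0))
  expect_equal(fit$checkpoints$train_mse[4], fit$train_mse)
})

test_that("predictions return to the eV scale and augment adds columns", {
  task <- teacher_task()
  fit <- capso_train(task$train, control = small_ctrl())
  p <- predict(fit, task$test)
  expect_length(p, nrow(task$test))
  expect_true(all(p > 0 & p < 12))
  expect_identical(predict(fit, task$test[0, ]), numeric(0))
  aug <- augment(fit, task$test)
  expect_equal(aug$.pred, p)
  expect_equal(aug$.resid, task$test$E - p)
  expect_error(predict(fit, dplyr::select(task$test, -Nc)),
               class = "capsonet_data_error")
})

test_that("broom-style accessors expose the fit", {
  task <- teacher_task()
  fit <- capso_train(task$train, validation = task$validation,
                     control = small_ctrl(iterations = 30))
  td <- tidy(fit)
  expect_equal(nrow(td), 121)
  expect_equal(sum(grepl("^w1", td$term)), 32)
  g <- glance(fit)
  expect_equal(g$architecture, "8-4-4-4-4-4-1")
  expect_equal(g$n_params, 121L)
  expect_s3_class(autoplot(fit), "ggplot")
  expect_s3_class(autoplot(fit, dplyr::bind_rows(task$train, task$test)),
                  "ggplot")
})

test_that("backpropagation gradients match finite differences", {
  arch <- network_arch(c(2, 3, 1))
  withr::with_seed(5, {
    theta <- rnorm(parameter_count(arch), sd = 0.8)
    X <- matrix(runif(10), 5, 2)
    y <- runif(5)
  })
  g <- capsonet:::mse_gradient(theta, c(2L, 3L, 1L), "linear", X, y)$grad
  eps <- 1e-6
  num <- vapply(seq_along(theta), function(i) {
    up <- dn <- theta
    up[i] <- up[i] + eps
    dn[i] <- dn[i] - eps
    (training_objective(up, arch, X, y) -
        training_objective(dn, arch, X, y)) / (2 * eps)
  }, numeric(1))
  expect_equal(g, num, tolerance = 1e-6)

  arch_s <- network_arch(c(2, 3, 1), output = "sigmoid")
  gs <- capsonet:::mse_gradient(theta, c(2L, 3L, 1L), "sigmoid", X, y)$grad
  num_s <- vapply(seq_along(theta), function(i) {
    up <- dn <- theta
    up[i] <- up[i] + eps
    dn[i] <- dn[i] - eps
    (training_objective(up, arch_s, X, y) -
        training_objective(dn, arch_s, X, y)) / (2 * eps)
  }, numeric(1))
  expect_equal(gs, num_s, tolerance = 1e-6)
})

test_that("gradient refinement never worsens the training MSE", {
  task <- teacher_task()
  fit <- capso_train(task$train, control = small_ctrl(iterations = 30))
  same <- gradient_refine(fit, task$train, epochs = 0)
  expect_identical(same$theta, fit$theta)
  polished <- gradient_refine(fit, task$train, rate = 0.5, epochs = 50)
  expect_lte(polished$train_mse, fit$train_mse)
  expect_true(polished$refined)
  frame <- apply_normalization(task$train, fit$norm)
  x <- as.matrix(frame[, qspr_descriptors()])
  expect_equal(training_objective(polished$theta, fit$arch, x, frame$E),
               polished$train_mse)
})

test_that("refinement is available from the trainer and helps", {
  task <- teacher_task()
  plain <- capso_train(task$train, control = small_ctrl(iterations = 40))
  refined <- capso_train(task$train, control = small_ctrl(iterations = 40),
                         refine = TRUE, refine_epochs = 40)
  expect_lte(refined$train_mse, plain$train_mse)
})

test_that("architecture search selects the validation-MSE minimizer", {
  task <- teacher_task()
  res <- search_architecture(task$train, task$validation, nodes = c(3, 4, 5),
                             hidden_layers = 5,
                             control = small_ctrl(iterations = 40))
  expect_s3_class(res, "arch_search")
  ok <- res$results[is.na(res$results$error), ]
  expect_equal(res$selected, ok$nodes[which.min(ok$val_mse)])
  expect_equal(tidy(res), res$results)
  expect_equal(glance(res)$selected, res$selected)
  expect_s3_class(autoplot(res), "ggplot")

  single <- search_architecture(task$train, task$validation, nodes = 4,
                                control = small_ctrl(iterations = 10))
  expect_equal(single$selected, 4L)
  expect_error(search_architecture(task$train, task$validation,
                                   nodes = integer(0)),
               class = "capsonet_config_error")
})

test_that("models persist to JSON bit-exactly", {
  task <- teacher_task()
  fit <- capso_train(task$train, control = small_ctrl(iterations = 20))
  path <- withr::local_tempfile(fileext = ".json")
  write_model(fit, path)
  back <- read_model(path)
  expect_identical(back$theta, fit$theta)
  expect_identical(back$norm$center, fit$norm$center)
  expect_identical(back$norm$scale, fit$norm$scale)
  expect_equal(back$arch$layers, fit$arch$layers)
  expect_equal(predict(back, task$test), predict(fit, task$test))
})
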