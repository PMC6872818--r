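sphere <- function(x) sum(x^2)

test_that("logistic map step is exact and domain-checked", {
  expect_equal(logistic_step(0.5), 1)
  expect_equal(logistic_step(0.75), 0.75)
  expect_equal(logistic_step(0.2), 0.64)
  expect_equal(logistic_step(c(0, 1)), c(0, 0))
  expect_error(logistic_step(1.2), class = "capsonet_domain_error")
  expect_error(logistic_step(-0.1), class = "capsonet_domain_error")
})

test_that("cognitive factor is delta^t, decreasing, and validated", {
  expect_equal(cognitive_factor(0.5, 1), 0.5)
  expect_equal(cognitive_factor(0.9, 2), 0.81)
  expect_lt(cognitive_factor(0.99, 5000), 1e-12)
  t_grid <- 1:50
  expect_true(all(diff(cognitive_factor(0.97, t_grid)) < 0))
  expect_error(cognitive_factor(1, 1), class = "capsonet_config_error")
  expect_error(cognitive_factor(0, 1), class = "capsonet_config_error")
})

test_that("position update obeys the accelerated rule and the box", {
  x <- c(1, -2, 0.5)
  g <- c(0, 0, 0)
  expect_equal(update_position(x, g, c1 = 0, c2 = 1, r = rep(0.3, 3)), g)
  expect_equal(update_position(x, g, c1 = 0, c2 = 0, r = rep(0.3, 3)), x)
  expect_equal(update_position(1, 3, c1 = 0.1, c2 = 0.5, r = 0.5), 2.05)
  expect_equal(update_position(1, 3, c1 = 0.1, c2 = 0.5, r = 0.5,
                               lower = 0, upper = 2), 2)
  expect_error(update_position(c(1, 2), 3, 0.1, 0.5, 0.5),
               class = "capsonet_contract_error")
})

test_that("swarm control validates its invariants", {
  expect_error(swarm_control(particles = 1), class = "capsonet_config_error")
  expect_error(swarm_control(delta = 1.1), class = "capsonet_config_error")
  expect_error(swarm_control(chaos_seed = 0.75), class = "capsonet_config_error")
  expect_error(swarm_control(chaos_seed = 0), class = "capsonet_config_error")
  expect_error(swarm_control(lower = 2, upper = -2), class = "capsonet_config_error")
  expect_s3_class(swarm_control(), "swarm_control")
})

test_that("capso handles constant objectives and zero-iteration budgets", {
  ctrl <- swarm_control(particles = 5, iterations = 20, seed = 1)
  res <- capso_optimize(function(x) 7, 3, ctrl)
  expect_equal(res$best_value, 7)
  res0 <- capso_optimize(sphere, 2, swarm_control(particles = 8, iterations = 0,
                                                  seed = 2))
  expect_equal(res0$iterations_run, 0L)
  expect_equal(res0$evaluations, 8L)
  expect_equal(nrow(res0$trace), 0L)
})

test_that("capso recovers a 1-D quadratic minimum", {
  res <- capso_optimize(function(x) (x - 2)^2, 1, swarm_control(seed = 3))
  expect_lt(abs(res$best_position - 2), 1e-2)
})

test_that("capso traces are monotone, bounded, deterministic and accounted", {
  ctrl <- swarm_control(particles = 10, iterations = 150, seed = 11,
                        lower = -4, upper = 4, min_error = 0)
  seen <- new.env()
  seen$rows <- list()
  probe <- function(x) {
    seen$rows[[length(seen$rows) + 1L]] <- x
    sum(x^2)
  }
  res <- capso_optimize(probe, 3, ctrl)
  expect_true(all(diff(res$trace$best_value) <= 0))
  pos <- do.call(rbind, seen$rows)
  expect_true(all(pos >= -4 & pos <= 4))
  expect_equal(res$evaluations, 10 * (res$iterations_run + 1))
  expect_equal(nrow(pos), res$evaluations)
  res2 <- capso_optimize(function(x) sum(x^2), 3, ctrl)
  expect_identical(res$best_position, res2$best_position)
  expect_identical(res$trace, res2$trace)
})

test_that("capso stops at the error floor and flags convergence", {
  res <- capso_optimize(sphere, 2, swarm_control(seed = 5, min_error = 1e-4))
  expect_true(res$converged_by_error)
  expect_lte(res$best_value, 1e-4)
  expect_lt(res$iterations_run, 2000)
})

test_that("non-finite objective values fail with the offending position", {
  expect_error(
    capso_optimize(function(x) NaN, 2, swarm_control(particles = 3, iterations = 5)),
    class = "capsonet_optim_error"
  )
})

test_that("standard PSO baseline shares the contract", {
  expect_equal(pso_optimize(function(x) 7, 2,
                            swarm_control(particles = 5, iterations = 10))$best_value, 7)
  ctrl <- swarm_control(particles = 20, iterations = 500, seed = 4)
  res <- pso_optimize(function(x) (x - 2)^2, 1, ctrl)
  expect_lt(abs(res$best_position - 2), 1e-2)
  res2 <- pso_optimize(function(x) (x - 2)^2, 1, ctrl)
  expect_identical(res$trace, res2$trace)
  expect_true(all(diff(res$trace$best_value) <= 0))
})

test_that("swarm results expose tidy, glance and autoplot", {
  res <- capso_optimize(sphere, 2, swarm_control(particles = 5, iterations = 30))
  expect_s3_class(tidy(res), "tbl_df")
  expect_named(tidy(res), c("iteration", "c1", "c2", "best_value"))
  g <- glance(res)
  expect_equal(g$best_value, res$best_value)
  expect_s3_class(autoplot(res), "ggplot")
})

test_that("YAML configuration round-trips into swarm_control", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("particles: 30", "iterations: 100", "delta: 0.95",
               "lower: -2", "upper: 2", "seed: 9"), path)
  ctrl <- read_swarm_control(path)
  expect_equal(ctrl$particles, 30L)
  expect_equal(ctrl$delta, 0.95)
  expect_equal(ctrl$chaos_seed, 0.7)
  writeLines("bogus_key: 1", path)
  expect_error(read_swarm_control(path), class = "capsonet_config_error")
})
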