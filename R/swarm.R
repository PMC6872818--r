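#' One step of the logistic map at full chaos
#'
#' The chaos variable driving the social coefficient evolves by
#' `x -> 4 x (1 - x)` on \[0, 1\], the logistic map at growth rate 4, which is
#' fully chaotic with the arcsine invariant density. The fixed points 0 and
#' 0.75 and the pre-images of 0 (0.5, then 0.25) are degenerate seeds and are
#' rejected by [swarm_control()].
#'
#' @param x Chaos value(s) in \[0, 1\]; vectorized.
#' @return `4 * x * (1 - x)`, again in \[0, 1\].
#' @examples
#' logistic_step(0.2)   # 0.64
#' logistic_step(0.75)  # fixed point
#' @export
logistic_step <- function(x) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    abort("Chaos value must lie in [0, 1].", class = "capsonet_domain_error")
  }
  4 * x * (1 - x)
}

#' Geometrically decaying cognitive coefficient
#'
#' `C1 = delta^t` weights the random exploration term of the position update;
#' it decays strictly in `t` so the swarm moves from global exploration to
#' local refinement.
#'
#' @param delta Base in (0, 1).
#' @param t Iteration index, starting at 1.
#' @return `delta^t`.
#' @export
cognitive_factor <- function(delta, t) {
  if (!is.numeric(delta) || any(delta <= 0) || any(delta >= 1)) {
    abort("`delta` must lie strictly inside (0, 1).", class = "capsonet_config_error")
  }
  if (any(t < 1)) {
    abort("Iteration index `t` starts at 1.", class = "capsonet_config_error")
  }
  delta^t
}

#' Accelerated position update
#'
#' Moves one particle by the accelerated rule
#' `x' = (1 - C2) x + C2 g + C1 r`, then clamps to the box. There is no
#' velocity and no personal best: the particle is pulled toward the global
#' best `g` with chaotic weight `C2` and perturbed by `C1 r`. The optimizer
#' supplies a zero-mean perturbation (uniform on (-1, 1)); see
#' [capso_optimize()].
#'
#' @param x Current position (d-vector).
#' @param global_best Global best position (same length).
#' @param c1,c2 Cognitive and social coefficients.
#' @param r Perturbation draws, one per dimension.
#' @param lower,upper Box bounds used for clamping.
#' @return The updated, clamped position.
#' @examples
#' update_position(1, 3, c1 = 0.1, c2 = 0.5, r = 0.5)  # 2.05
#' @export
update_position <- function(x, global_best, c1, c2, r,
                            lower = -Inf, upper = Inf) {
  if (length(x) != length(global_best) || length(r) != length(x)) {
    abort("`x`, `global_best` and `r` must have equal length.",
          class = "capsonet_contract_error")
  }
  pmin(pmax((1 - c2) * x + c2 * global_best + c1 * r, lower), upper)
}

eval_positions <- function(objective, X) {
  vals <- vapply(seq_len(nrow(X)), function(i) as.numeric(objective(X[i, ])),
                 numeric(1))
  if (any(!is.finite(vals))) {
    bad <- which(!is.finite(vals))[1]
    abort(
      sprintf("Objective returned a non-finite value at position (%s).",
              paste(signif(X[bad, ], 6), collapse = ", ")),
      class = "capsonet_optim_error"
    )
  }
  vals
}

new_swarm_result <- function(best_position, best_value, iterations_run,
                             converged, trace, evaluations, method, control) {
  structure(
    list(
      best_position = best_position, best_value = best_value,
      iterations_run = iterations_run, converged_by_error = converged,
      trace = trace, evaluations = evaluations, method = method,
      control = control
    ),
    class = "swarm_result"
  )
}

#' Minimize an objective with the chaos-enhanced accelerated swarm
#'
#' Runs CAPSO on a box-bounded real vector: positions start uniform in the
#' box; at iteration `t` the cognitive coefficient is `C1 = delta^t`, the
#' social coefficient `C2` is the next value of the logistic-map orbit
#' (shared by all particles and dimensions), and every particle moves by
#' [update_position()] with an independent uniform draw per particle and
#' dimension. Only the global best constrains the particles. The search stops
#' at the iteration cap or as soon as the best objective value reaches
#' `min_error`.
#'
#' The perturbation is centered: the uniform draw `u` in (0, 1) enters as
#' `2 u - 1`, so the exploration noise is zero-mean with amplitude `C1`. A
#' one-sided perturbation cannot reduce any coordinate once the swarm has
#' collapsed onto the global best, which destroys convergence; the centered
#' form preserves the annealing interpretation of the `delta^t` schedule.
#'
#' Runs are deterministic given `control$seed` and `control$chaos_seed`.
#'
#' @param objective Function mapping a numeric d-vector to a finite scalar.
#' @param dimension Number of search dimensions `d`.
#' @param control A [swarm_control()] object.
#' @param snapshot_every If positive, store a copy of the global best
#'   position every this many iterations (used by the trainer for
#'   checkpointed validation monitoring).
#' @return A `swarm_result` with elements `best_position`, `best_value`,
#'   `iterations_run`, `converged_by_error`, `trace` (a tibble with one row
#'   per iteration: `iteration`, `c1`, `c2`, `best_value`), `evaluations`
#'   and the control snapshot. The best-value trace is non-increasing.
#' @examples
#' res <- capso_optimize(function(x) sum((x - 2)^2), 1,
#'                       swarm_control(particles = 20, iterations = 300))
#' res$best_position
#' @export
capso_optimize <- function(objective, dimension, control = swarm_control(),
                           snapshot_every = 0L) {
  stopifnot(is.function(objective), dimension >= 1)
  m <- control$particles
  d <- as.integer(dimension)
  withr::local_seed(control$seed)

  X <- matrix(runif(m * d, control$lower, control$upper), m, d)
  vals <- eval_positions(objective, X)
  gi <- which.min(vals)
  g <- X[gi, ]
  gv <- vals[gi]
  chaos <- control$chaos_seed

  itmax <- control$iterations
  tr_c1 <- numeric(itmax)
  tr_c2 <- numeric(itmax)
  tr_best <- numeric(itmax)
  converged <- gv <= control$min_error
  t_run <- 0L
  snapshots <- list()

  if (!converged && itmax > 0L) {
    for (t in seq_len(itmax)) {
      c1 <- control$delta^t
      chaos <- 4 * chaos * (1 - chaos)
      c2 <- chaos
      R <- matrix(runif(m * d), m, d)
      X <- (1 - c2) * X + c2 * matrix(g, m, d, byrow = TRUE) +
        c1 * (2 * R - 1)
      X[X < control$lower] <- control$lower
      X[X > control$upper] <- control$upper
      vals <- eval_positions(objective, X)
      if (min(vals) < gv) {
        gi <- which.min(vals)
        g <- X[gi, ]
        gv <- vals[gi]
      }
      tr_c1[t] <- c1
      tr_c2[t] <- c2
      tr_best[t] <- gv
      t_run <- t
      if (snapshot_every > 0L && t %% snapshot_every == 0L) {
        snapshots[[length(snapshots) + 1L]] <-
          list(iteration = t, position = g)
      }
      if (control$verbose) {
        message(sprintf("iter %5d  C1 %.3e  C2 %.4f  best %.6e", t, c1, c2, gv))
      }
      if (gv <= control$min_error) {
        converged <- TRUE
        break
      }
    }
  }

  trace <- tibble(
    iteration = seq_len(t_run),
    c1 = tr_c1[seq_len(t_run)],
    c2 = tr_c2[seq_len(t_run)],
    best_value = tr_best[seq_len(t_run)]
  )
  out <- new_swarm_result(g, gv, t_run, converged, trace,
                          evaluations = m * (t_run + 1L),
                          method = "capso", control = control)
  out$snapshots <- snapshots
  out
}

#' Minimize an objective with classical inertia-weight PSO
#'
#' Baseline comparator for [capso_optimize()]: full particle swarm with
#' velocities, personal bests and the standard constriction-style
#' coefficients (inertia 0.7298, acceleration 1.49618). Shares the stopping
#' rules, box clamping, determinism contract and result layout of the CAPSO
#' driver.
#'
#' @inheritParams capso_optimize
#' @param inertia Inertia weight on the previous velocity.
#' @param accel_personal,accel_social Acceleration coefficients toward the
#'   personal and global bests.
#' @return A `swarm_result`; see [capso_optimize()].
#' @export
pso_optimize <- function(objective, dimension, control = swarm_control(),
                         inertia = 0.7298, accel_personal = 1.49618,
                         accel_social = 1.49618) {
  stopifnot(is.function(objective), dimension >= 1)
  m <- control$particles
  d <- as.integer(dimension)
  withr::local_seed(control$seed)

  X <- matrix(runif(m * d, control$lower, control$upper), m, d)
  V <- matrix(0, m, d)
  vals <- eval_positions(objective, X)
  P <- X
  pv <- vals
  gi <- which.min(vals)
  g <- X[gi, ]
  gv <- vals[gi]

  itmax <- control$iterations
  tr_best <- numeric(itmax)
  converged <- gv <= control$min_error
  t_run <- 0L

  if (!converged && itmax > 0L) {
    for (t in seq_len(itmax)) {
      R1 <- matrix(runif(m * d), m, d)
      R2 <- matrix(runif(m * d), m, d)
      V <- inertia * V + accel_personal * R1 * (P - X) +
        accel_social * R2 * (matrix(g, m, d, byrow = TRUE) - X)
      X <- X + V
      X[X < control$lower] <- control$lower
      X[X > control$upper] <- control$upper
      vals <- eval_positions(objective, X)
      better <- vals < pv
      P[better, ] <- X[better, , drop = FALSE]
      pv[better] <- vals[better]
      if (min(pv) < gv) {
        gi <- which.min(pv)
        g <- P[gi, ]
        gv <- pv[gi]
      }
      tr_best[t] <- gv
      t_run <- t
      if (gv <= control$min_error) {
        converged <- TRUE
        break
      }
    }
  }

  trace <- tibble(
    iteration = seq_len(t_run),
    c1 = rep(accel_personal, t_run),
    c2 = rep(accel_social, t_run),
    best_value = tr_best[seq_len(t_run)]
  )
  new_swarm_result(g, gv, t_run, converged, trace,
                   evaluations = m * (t_run + 1L),
                   method = "pso", control = control)
}

#' @export
print.swarm_result <- function(x, ...) {
  cat(sprintf("<swarm_result: %s>\n", x$method))
  cat(sprintf("  best value: %.6e after %d iterations (%d evaluations)\n",
              x$best_value, x$iterations_run, x$evaluations))
  cat(sprintf("  converged by error floor: %s\n", x$converged_by_error))
  invisible(x)
}

#' @rdname capso_optimize
#' @param x,object A `swarm_result`.
#' @param ... Unused.
#' @method tidy swarm_result
#' @export
tidy.swarm_result <- function(x, ...) x$trace

#' @rdname capso_optimize
#' @method glance swarm_result
#' @export
glance.swarm_result <- function(x, ...) {
  tibble(
    method = x$method,
    best_value = x$best_value,
    iterations_run = x$iterations_run,
    evaluations = x$evaluations,
    converged_by_error = x$converged_by_error
  )
}

#' @rdname capso_optimize
#' @method autoplot swarm_result
#' @export
autoplot.swarm_result <- function(object, ...) {
  ggplot2::ggplot(object$trace, ggplot2::aes(x = .data$iteration,
                                             y = .data$best_value)) +
    ggplot2::geom_line(colour = "#2c7fb8") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Iteration", y = "Best objective value",
                  title = sprintf("%s convergence", toupper(object$method))) +
    ggplot2::theme_minimal()
}
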