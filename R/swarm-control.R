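#' Configure the swarm optimizer
#'
#' Collects every tunable of the chaos-enhanced accelerated particle swarm
#' (CAPSO) in one validated object. The defaults follow the standard
#' configuration for this optimizer family: 60 particles, 2000 iterations and
#' an objective floor of 1e-7. The cognitive coefficient is `delta^t` at
#' iteration `t`; the social coefficient is the running value of the logistic
#' map at full chaos, seeded by `chaos_seed`.
#'
#' @param particles Number of particles `m` (at least 2).
#' @param iterations Iteration cap. Zero is allowed and returns the best
#'   particle of the random initialization unchanged.
#' @param min_error Non-negative objective floor; the search stops as soon as
#'   the global best value drops to or below it.
#' @param delta Base of the geometric cognitive schedule `C1 = delta^t`,
#'   strictly inside (0, 1). The default 0.99 matches the decay horizon to
#'   the default 2000-iteration budget (`0.99^2000` is about 2e-9); smaller
#'   values finish annealing long before the budget is spent.
#' @param lower,upper Scalar box bounds applied to every dimension.
#' @param chaos_seed Starting value of the logistic-map chaos variable, in
#'   (0, 1) and away from the absorbing / fixed values 0.25, 0.5 and 0.75
#'   where the orbit degenerates.
#' @param seed Integer seed for every pseudo-random draw of the run
#'   (initial positions and per-iteration exploration noise).
#' @param verbose If `TRUE`, print one log line per iteration with the
#'   iteration index, `C1`, `C2` and the best objective value.
#'
#' @return An object of class `swarm_control`.
#' @seealso [capso_optimize()], [read_swarm_control()]
#' @examples
#' swarm_control()
#' swarm_control(particles = 30, iterations = 500, lower = -3, upper = 3)
#' @export
swarm_control <- function(particles = 60L, iterations = 2000L,
                          min_error = 1e-7, delta = 0.99,
                          lower = -10, upper = 10,
                          chaos_seed = 0.7, seed = 0L,
                          verbose = FALSE) {
  particles <- as.integer(particles)
  iterations <- as.integer(iterations)
  if (is.na(particles) || particles < 2L) {
    abort("`particles` must be an integer >= 2.", class = "capsonet_config_error")
  }
  if (is.na(iterations) || iterations < 0L) {
    abort("`iterations` must be a non-negative integer.", class = "capsonet_config_error")
  }
  if (!is.numeric(min_error) || length(min_error) != 1L || min_error < 0) {
    abort("`min_error` must be a single non-negative number.", class = "capsonet_config_error")
  }
  if (!is.numeric(delta) || length(delta) != 1L || delta <= 0 || delta >= 1) {
    abort("`delta` must lie strictly inside (0, 1).", class = "capsonet_config_error")
  }
  if (!is.numeric(lower) || !is.numeric(upper) || lower >= upper) {
    abort("`lower` must be strictly less than `upper`.", class = "capsonet_config_error")
  }
  check_chaos_seed(chaos_seed)
  structure(
    list(
      particles = particles, iterations = iterations, min_error = min_error,
      delta = delta, lower = as.numeric(lower), upper = as.numeric(upper),
      chaos_seed = as.numeric(chaos_seed), seed = as.integer(seed),
      verbose = isTRUE(verbose)
    ),
    class = "swarm_control"
  )
}

check_chaos_seed <- function(x) {
  if (!is.numeric(x) || length(x) != 1L || x <= 0 || x >= 1) {
    abort("`chaos_seed` must lie strictly inside (0, 1).", class = "capsonet_config_error")
  }
  if (any(abs(x - c(0.25, 0.5, 0.75)) < 1e-12)) {
    abort(
      "`chaos_seed` must avoid 0.25, 0.5 and 0.75: the logistic orbit collapses or freezes there.",
      class = "capsonet_config_error"
    )
  }
  invisible(x)
}

#' Read a swarm configuration from a YAML file
#'
#' Accepts the flat key set `particles`, `iterations`, `min_error`, `delta`,
#' `lower`, `upper`, `chaos_seed`, `seed`; missing keys fall back to the
#' [swarm_control()] defaults and unknown keys are an error.
#'
#' @param path Path to a YAML file.
#' @return A `swarm_control` object.
#' @export
read_swarm_control <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(swarm_control))
  extra <- setdiff(names(vals), known)
  if (length(extra) > 0) {
    abort(paste0("Unknown swarm configuration key(s): ", paste(extra, collapse = ", ")),
          class = "capsonet_config_error")
  }
  do.call(swarm_control, vals)
}

#' @export
print.swarm_control <- function(x, ...) {
  cat("<swarm_control>\n")
  cat(sprintf("  particles: %d  iterations: %d  min_error: %g\n",
              x$particles, x$iterations, x$min_error))
  cat(sprintf("  delta: %g  box: [%g, %g]\n", x$delta, x$lower, x$upper))
  cat(sprintf("  chaos_seed: %g  seed: %d\n", x$chaos_seed, x$seed))
  invisible(x)
}
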