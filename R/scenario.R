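#' Initial conditions of the angiogenesis scenario
#'
#' Endothelial cells seeded at amplitude `C0` on \eqn{0 \le x \le a} (the node
#' at `x = a` is included, matching the closed seeding interval) and zero
#' beyond; uniform small positive levels \eqn{\xi_1, \xi_2, \xi_3} for
#' protease, inhibitor and matrix; oxygen
#' \eqn{O(x, 0) = O_0 e^{-\lambda x} + \xi_4}, the diffusion-limited profile
#' of a parent vessel at \eqn{x = 0}. Defaults are the physiological
#' angiogenesis scenario (`C0 = 1`, `a = 0.1`, \eqn{\xi = (0.1, 0.2, 1, 0.1)},
#' `O0 = 0.5`, `lambda = 5`).
#'
#' @param C0 Endothelial seeding amplitude, in `[0, 1]`.
#' @param a Seeding cutoff position, inside `(0, L_f)` (checked against the
#'   grid at build time).
#' @param xi1,xi2,xi3,xi4 Small positive offsets for `P`, `I`, `F`, `O`.
#' @param O0 Oxygen amplitude, positive.
#' @param lambda Oxygen decay rate, `>= 0`.
#' @return An object of class `"initial_conditions"`.
#' @export
initial_conditions <- function(C0 = 1, a = 0.1, xi1 = 0.1, xi2 = 0.2,
                               xi3 = 1, xi4 = 0.1, O0 = 0.5, lambda = 5) {
  stopifnot(C0 >= 0, C0 <= 1, a > 0,
            xi1 > 0, xi2 > 0, xi3 > 0, xi4 > 0, O0 > 0, lambda >= 0)
  structure(list(C0 = C0, a = a, xi1 = xi1, xi2 = xi2, xi3 = xi3, xi4 = xi4,
                 O0 = O0, lambda = lambda),
            class = "initial_conditions")
}

#' Sample the initial conditions on a grid
#'
#' @param ics An [initial_conditions()] object.
#' @param grid A [grid1d()].
#' @return A [system_state()] at `t = 0`.
#' @examples
#' s <- build_initial_state(initial_conditions(), grid1d(1, 16))
#' s$O[1]  # 0.5 + 0.1 at the parent vessel
#' @export
build_initial_state <- function(ics, grid) {
  .check_grid(grid)
  if (ics$a <= 0 || ics$a >= grid$L_f) {
    stop("seeding cutoff a must lie strictly inside (0, L_f)", call. = FALSE)
  }
  x <- grid$x
  n <- length(x)
  system_state(
    C = ifelse(x <= ics$a, ics$C0, 0),
    P = rep(ics$xi1, n),
    I = rep(ics$xi2, n),
    F = rep(ics$xi3, n),
    O = ics$O0 * exp(-ics$lambda * x) + ics$xi4,
    t = 0
  )
}

#' Run configuration
#'
#' Bundles everything one simulation needs: grid, time stepping, model
#' parameters, initial conditions, monitoring cadence and snapshot schedule.
#' Defaults reproduce the physiological angiogenesis scenario: `M = 256`,
#' `dt = 1e-5`, `t_final = 10`, reference parameters, snapshots at
#' `t = 0, 2, 5, 10`. All values are dimensionless.
#'
#' @param L_f Domain length.
#' @param M Number of grid intervals.
#' @param dt Time step.
#' @param t_final Final time.
#' @param params A [model_parameters()] object.
#' @param ics An [initial_conditions()] object.
#' @param monitor_every Bounds/energy recording cadence in steps.
#' @param snapshot_times Snapshot schedule.
#' @param scenario Scenario tag (`"test2_angiogenesis"` or `"custom"`).
#' @param output_dir Optional directory for snapshot/report files.
#' @return An object of class `"run_config"`.
#' @export
run_config <- function(L_f = 1, M = 256L, dt = 1e-5, t_final = 10,
                       params = model_parameters(L_f = L_f),
                       ics = initial_conditions(),
                       monitor_every = 1000L,
                       snapshot_times = c(0, 2, 5, 10),
                       scenario = c("test2_angiogenesis", "custom"),
                       output_dir = NULL) {
  scenario <- match.arg(scenario)
  stopifnot(dt > 0, t_final >= 0, monitor_every >= 0)
  if (abs(params$L_f - L_f) > 1e-12) {
    stop("params$L_f disagrees with the configured domain length", call. = FALSE)
  }
  structure(list(L_f = L_f, M = as.integer(M), dt = dt, t_final = t_final,
                 params = params, ics = ics,
                 monitor_every = as.integer(monitor_every),
                 snapshot_times = snapshot_times, scenario = scenario,
                 output_dir = output_dir),
            class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat(sprintf("<run_config> scenario = %s: M = %d on [0, %g], dt = %g, t_final = %g\n",
              x$scenario, x$M, x$L_f, x$dt, x$t_final))
  cat(sprintf("  monitor every %d steps; snapshots at %s\n",
              x$monitor_every, paste(x$snapshot_times, collapse = ", ")))
  invisible(x)
}

#' Position of the endothelial front
#'
#' The largest node coordinate where the endothelial density exceeds the
#' threshold (default 0.5, the mid-amplitude of the admissible `[0, 1]`
#' range). `NA` if no node exceeds it.
#'
#' @param state A [system_state()].
#' @param grid The grid the state lives on.
#' @param threshold Density threshold.
#' @return The front position, or `NA_real_`.
#' @export
front_position <- function(state, grid, threshold = 0.5) {
  idx <- which(state$C > threshold)
  if (!length(idx)) return(NA_real_)
  grid$x[max(idx)]
}

#' Run a named scenario with monitors attached
#'
#' Builds grid, operators, tumor profile and initial state from the
#' configuration, runs the simulation with invariant-region and energy
#' monitoring plus endothelial front tracking (arrival at `0.9 L_f`), checks
#' the recorded extrema against the invariant region, and optionally writes
#' snapshots and reports.
#'
#' @param config A [run_config()] (default: the physiological angiogenesis
#'   scenario).
#' @param engine Integration engine, passed to [run_simulation()].
#' @param output_dir Optional output directory (overrides the config's).
#' @param tol Region-check tolerance.
#' @return The [run_simulation()] result, augmented with `config`, `region`,
#'   `region_check` and `metrics` (front position, arrival time, oxygen
#'   range and endothelial mass at the final time).
#' @export
run_scenario <- function(config = run_config(), engine = "auto",
                         output_dir = config$output_dir, tol = 1e-10) {
  stopifnot(inherits(config, "run_config"))
  grid <- grid1d(config$L_f, config$M)
  ops <- operator_set(grid)
  profile <- tumor_factor(grid, config$params$epsilon, config$params$alpha4,
                          Dx = ops$Dx)
  init <- build_initial_state(config$ics, grid)
  result <- run_simulation(init, config$params, ops,
                           dt = config$dt, t_final = config$t_final,
                           profile = profile, engine = engine,
                           monitor_every = config$monitor_every,
                           snapshot_times = config$snapshot_times,
                           front_target = 0.9 * config$L_f,
                           ics = config$ics)
  region <- invariant_region(config$params, config$ics)
  result$config <- config
  result$region <- region
  result$region_check <- check_run(result, region, tol = tol)
  final <- result$states[[length(result$states)]]
  result$metrics <- data.frame(
    front_position = front_position(final, grid),
    arrival_time = result$front_arrival,
    O_min = min(final$O), O_max = max(final$O),
    ec_mass = trapezoid_integral(final$C, grid$dx)
  )
  if (!is.null(output_dir)) write_snapshots(result, output_dir)
  result
}

#' Sensitivity sweep over one model parameter
#'
#' Runs the scenario once per parameter value (in the given, deterministic
#' order) and tabulates summary metrics: final endothelial front position,
#' time for the front to reach `0.9 L_f` (`NA` if never), oxygen range at the
#' final time, and trapezoidal endothelial mass at the final time. These
#' metrics are package definitions chosen to quantify the qualitative
#' behaviors of interest (speed and extent of vascular advance, perfusion).
#' A failing value is recorded as a failed row; the sweep continues.
#'
#' @param config Base [run_config()].
#' @param param Name of a [model_parameters()] field.
#' @param values Values to sweep over (must respect the parameter's sign
#'   constraints).
#' @param engine Integration engine.
#' @return A data frame with one row per value: `value`, the metrics, and
#'   `status`.
#' @export
sensitivity_sweep <- function(config, param, values, engine = "auto") {
  stopifnot(inherits(config, "run_config"))
  if (!param %in% names(config$params)) {
    stop("unknown model parameter: ", param, call. = FALSE)
  }
  rows <- lapply(values, function(v) {
    out <- tryCatch({
      p <- config$params
      p[[param]] <- v
      p <- do.call(model_parameters,
                   c(unclass(p), list(strict = attr(config$params, "strict"))))
      cfg <- config
      cfg$params <- p
      res <- run_scenario(cfg, engine = engine, output_dir = NULL)
      cbind(data.frame(value = v), res$metrics, data.frame(status = "ok"))
    }, error = function(e) {
      data.frame(value = v, front_position = NA_real_, arrival_time = NA_real_,
                 O_min = NA_real_, O_max = NA_real_, ec_mass = NA_real_,
                 status = paste0("failed: ", conditionMessage(e)))
    })
    out
  })
  do.call(rbind, rows)
}
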