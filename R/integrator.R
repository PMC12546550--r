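#' One classical RK4 step
#'
#' Advances `y` by the four-stage fourth-order Runge-Kutta rule
#' \eqn{y^{n+1} = y^n + \frac{\Delta t}{6}(s_1 + 2 s_2 + 2 s_3 + s_4)}
#' with stages evaluated at times \eqn{t, t + \Delta t/2, t + \Delta t/2,
#' t + \Delta t} (the classical non-autonomous form, which reduces to the
#' autonomous four-stage rule when `rhs` ignores `t`). Works for any numeric
#' shape `y` (scalar, vector or matrix); `rhs(y, t)` must return the same
#' shape. The stage vectors are named `stage_1..stage_4` to avoid any clash
#' with the kinetic rates `k1..k6` of the model.
#'
#' @param rhs A function `rhs(y, t)`.
#' @param y Current value (numeric scalar, vector or matrix).
#' @param t Current time.
#' @param dt Step size, positive.
#' @return The updated value, same shape as `y`; the input is not modified.
#'   A non-finite stage aborts with the stage identified.
#' @examples
#' rk4_step(function(y, t) -y, 1, 0, 0.1)  # one step of linear decay
#' @export
rk4_step <- function(rhs, y, t, dt) {
  stopifnot(is.numeric(dt), length(dt) == 1L, dt > 0)
  stage_1 <- rhs(y, t)
  if (any(!is.finite(stage_1))) stop("non-finite RK4 stage 1 at t = ", t, call. = FALSE)
  stage_2 <- rhs(y + (dt / 2) * stage_1, t + dt / 2)
  if (any(!is.finite(stage_2))) stop("non-finite RK4 stage 2 at t = ", t, call. = FALSE)
  stage_3 <- rhs(y + (dt / 2) * stage_2, t + dt / 2)
  if (any(!is.finite(stage_3))) stop("non-finite RK4 stage 3 at t = ", t, call. = FALSE)
  stage_4 <- rhs(y + dt * stage_3, t + dt)
  if (any(!is.finite(stage_4))) stop("non-finite RK4 stage 4 at t = ", t, call. = FALSE)
  y + (dt / 6) * (stage_1 + 2 * stage_2 + 2 * stage_3 + stage_4)
}

## Numerical estimate of the Lipschitz constant of the local reaction map over
## the invariant region: max over a coarse sample of the region of the
## infinity-norm of a finite-difference Jacobian. The tumor factor is frozen at
## its worst case T = 1. The theory states this constant exists and can be
## computed; it is never printed, so it is estimated here and exposed in the
## stability report.
.estimate_reaction_lipschitz <- function(params, region, levels = 3L, h = 1e-6) {
  f <- function(u) {
    C <- u[1L]; P <- u[2L]; I <- u[3L]; Fm <- u[4L]; O <- u[5L]
    H <- O / (params$K_O + O)
    c(params$k1 * C * (1 - C) * H,
      -params$k3 * P * I + params$k4 * C + params$k5 - params$k6 * P,
      -params$k3 * P * I,
      -params$k2 * P * Fm,
      -params$gamma1 * C * O / (params$K_O + O) +
        params$gamma2 * (params$O_max - O) * params$beta * C)
  }
  axes <- lapply(.FIELDS, function(nm) {
    iv <- region[[nm]]
    seq(iv[1L], iv[2L], length.out = levels)
  })
  pts <- as.matrix(expand.grid(axes))
  L <- 0
  for (r in seq_len(nrow(pts))) {
    u <- pts[r, ]
    J <- matrix(0, 5L, 5L)
    for (k in seq_len(5L)) {
      up <- u; um <- u
      up[k] <- up[k] + h
      um[k] <- max(um[k] - h, 0)        # stay in the admissible orthant
      J[, k] <- (f(up) - f(um)) / (up[k] - um[k])
    }
    L <- max(L, max(rowSums(abs(J))))
  }
  L
}

#' Time-step limits for explicit integration
#'
#' Computes the explicit-integration bounds for the semi-discrete system:
#'
#' * `dt_diffusion`: \eqn{\Delta x^2 / (2 d_{\max})}, the Euler-derived
#'   diffusion constraint (conservative for RK4, whose real-axis stability
#'   interval extends to \eqn{-2.785});
#' * `dt_cfl`: \eqn{C_{CFL} \Delta x}, the advection bound. When a state and
#'   profile are supplied, \eqn{C_{CFL} = 1/v_{\max}} with \eqn{v_{\max}} the
#'   measured maximum taxis speed
#'   \eqn{\max_j |\alpha_1 (D_x F)_j - \alpha_2 (D_x I)_j + \alpha_3 (d\phi/dx)_j|};
#'   zero measured speed yields an `Inf` sentinel. Otherwise the configured
#'   constant `c_cfl` is used;
#' * `dt_region`: \eqn{\min\{\Delta x^2/(2 d_{\max}),\, 1/L_R,\,
#'   \Delta x/\alpha_{\max}\}}, the invariant-region preservation restriction,
#'   with the Lipschitz constant \eqn{L_R} of the reaction map over the region
#'   estimated numerically (finite-difference Jacobians over a coarse sample);
#' * `dt_recommended`: `safety` times the minimum of the applicable bounds.
#'
#' @param params A [model_parameters()] object.
#' @param grid A [grid1d()] object.
#' @param state Optional [system_state()] used to measure the advective speed.
#' @param profile Optional [tumor_factor()] profile (required with `state`).
#' @param c_cfl CFL constant used when no state is supplied (default 1).
#' @param safety Safety factor applied to the recommendation (default 0.9).
#' @param ics Initial conditions used to size the invariant region for the
#'   Lipschitz estimate; defaults to [initial_conditions()].
#' @return An object of class `"stability_limits"`: list with `dt_diffusion`,
#'   `dt_cfl`, `dt_region`, `dt_recommended`, `d_max`, `alpha_max`, `L_R`,
#'   `v_max`.
#' @examples
#' stability_limits(model_parameters(), grid1d(1, 64))
#' @export
stability_limits <- function(params, grid, state = NULL, profile = NULL,
                             c_cfl = 1, safety = 0.9,
                             ics = initial_conditions()) {
  .check_grid(grid)
  dm <- d_max(params)
  dt_diffusion <- grid$dx^2 / (2 * dm)
  alpha_max <- max(abs(params$alpha1), abs(params$alpha2), abs(params$alpha3))
  v_max <- NA_real_
  if (!is.null(state)) {
    if (is.null(profile)) stop("profile is required when a state is supplied", call. = FALSE)
    Dx <- gradient_matrix(grid)
    v <- params$alpha1 * as.vector(Dx %*% state$F) -
         params$alpha2 * as.vector(Dx %*% state$I) +
         params$alpha3 * profile$dphi_dx
    v_max <- max(abs(v))
    ## speeds at round-off level (uniform fields differentiated numerically)
    ## count as zero: the advection bound is then inactive
    dt_cfl <- if (v_max > 1e-12) grid$dx / v_max else Inf
  } else {
    dt_cfl <- c_cfl * grid$dx
  }
  region <- invariant_region(params, ics)
  L_R <- .estimate_reaction_lipschitz(params, region)
  dt_region <- min(dt_diffusion,
                   if (L_R > 0) 1 / L_R else Inf,
                   if (alpha_max > 0) grid$dx / alpha_max else Inf)
  structure(
    list(dt_diffusion = dt_diffusion, dt_cfl = dt_cfl, dt_region = dt_region,
         dt_recommended = safety * min(dt_diffusion, dt_cfl, dt_region),
         d_max = dm, alpha_max = alpha_max, L_R = L_R, v_max = v_max,
         safety = safety),
    class = "stability_limits"
  )
}

#' @export
print.stability_limits <- function(x, ...) {
  cat("<stability_limits>\n")
  cat(sprintf("  dt_diffusion   = %g   (dx^2 / (2 d_max), d_max = %g)\n",
              x$dt_diffusion, x$d_max))
  cat(sprintf("  dt_cfl         = %g   (advection bound%s)\n", x$dt_cfl,
              if (is.na(x$v_max)) "" else sprintf(", measured v_max = %g", x$v_max)))
  cat(sprintf("  dt_region      = %g   (invariant-region restriction, L_R ~ %g)\n",
              x$dt_region, x$L_R))
  cat(sprintf("  dt_recommended = %g   (safety factor %g)\n",
              x$dt_recommended, x$safety))
  invisible(x)
}

## Build the fixed-step plan: n_full steps of size dt plus an optional smaller
## final step hitting t_final exactly.
.step_plan <- function(dt, t_final) {
  stopifnot(dt > 0, t_final >= 0)
  if (t_final == 0) return(list(n_full = 0L, dt_last = 0, n_total = 0L))
  ratio <- t_final / dt
  n_full <- floor(ratio * (1 + 1e-12) + 1e-9)   # absorb 10/1e-5 = 999999.99...
  rem <- t_final - n_full * dt
  if (rem > dt * 1e-9) {
    list(n_full = as.integer(n_full), dt_last = rem,
         n_total = as.integer(n_full) + 1L)
  } else {
    list(n_full = as.integer(n_full), dt_last = 0,
         n_total = as.integer(n_full))
  }
}

.snapshot_steps <- function(snapshot_times, dt, n_total, t_final) {
  if (is.null(snapshot_times)) snapshot_times <- c(0, t_final)
  steps <- vapply(snapshot_times, function(s) {
    if (t_final > 0 && s >= t_final) n_total else as.integer(round(s / dt))
  }, integer(1L))
  sort(unique(pmin(pmax(steps, 0L), n_total)))
}

.step_time <- function(n, dt, n_total, t_final, dt_last) {
  if (n >= n_total && dt_last > 0) t_final else n * dt
}

#' Run the fully discrete simulation
#'
#' Advances the five-field system from `t = 0` to `t_final` with fixed-step
#' RK4 (a smaller final step is taken if `t_final` is not a multiple of `dt`).
#' Per-component global minima and maxima are tracked at every accepted step
#' (including the initial state); a bounds/energy series is recorded every
#' `monitor_every` steps; field snapshots are stored at `snapshot_times`. The
#' integration is fully deterministic: identical inputs give bit-identical
#' trajectories on one platform.
#'
#' Two engines are available. `"compiled"` runs the model right-hand side and
#' RK4 loop in C++ and is used automatically for the physical (source-free,
#' hook-free) model; `"reference"` is the plain-R loop built on
#' [rk4_step()]/[semi_discrete_rhs()] and supports manufactured-solution
#' sources and per-step hooks. Both implement the same scheme; they agree to
#' round-off.
#'
#' @param initial A [system_state()] at `t = 0`.
#' @param params A [model_parameters()] object.
#' @param ops An [operator_set()] for the grid the state lives on.
#' @param dt Time step, positive. Unless `allow_unstable = TRUE`, `dt` must
#'   not exceed the recommended stability limit ([stability_limits()]).
#' @param t_final Final time, `>= 0`.
#' @param profile Optional [tumor_factor()] profile; defaults to the profile
#'   implied by `params` on the grid.
#' @param sources Optional list of five source functions `f(x, t)`
#'   (manufactured-solution forcing); forces the reference engine.
#' @param engine `"auto"`, `"compiled"` or `"reference"`.
#' @param monitor_every Record the bounds/energy series every this many steps
#'   (0 disables the series; extrema are tracked regardless).
#' @param snapshot_times Times at which to store full field snapshots
#'   (default: initial and final).
#' @param hooks Optional list of functions `f(U, t, step)` called after every
#'   accepted step (reference engine only); `U` is the `(M+1) x 5` state
#'   matrix. Hooks observe and must not be relied on to mutate the state.
#' @param allow_unstable Permit `dt` above the recommended limit (a warning is
#'   issued).
#' @param front_threshold,front_target Optional endothelial front tracking:
#'   record the first time any node with `x >= front_target` has
#'   `C > front_threshold`.
#' @param ics Initial conditions used only to size the invariant region inside
#'   the stability check.
#' @return An object of class `"run_result"`: list with `times`, `states`
#'   (snapshots), `step_count`, `dt`, `extrema` (per-component global
#'   min/max), `bounds` (data frame series or `NULL`), `front_arrival`,
#'   `grid`, `engine`, `status`.
#' @export
run_simulation <- function(initial, params, ops, dt, t_final,
                           profile = NULL, sources = NULL,
                           engine = c("auto", "compiled", "reference"),
                           monitor_every = 0L, snapshot_times = NULL,
                           hooks = NULL, allow_unstable = FALSE,
                           front_threshold = 0.5, front_target = NULL,
                           ics = initial_conditions()) {
  engine <- match.arg(engine)
  stopifnot(inherits(initial, "system_state"), inherits(ops, "operator_set"))
  grid <- ops$grid
  if (length(initial$C) != length(grid$x)) {
    stop("initial state and operator set do not share a grid", call. = FALSE)
  }
  if (is.null(profile)) {
    profile <- tumor_factor(grid, params$epsilon, params$alpha4, Dx = ops$Dx)
  }
  stopifnot(t_final >= 0, dt > 0)

  lim <- stability_limits(params, grid, ics = ics)
  if (dt > lim$dt_recommended) {
    if (!allow_unstable) {
      stop(sprintf(paste0("dt = %g exceeds the recommended stability limit %g; ",
                          "pass allow_unstable = TRUE to override"),
                   dt, lim$dt_recommended), call. = FALSE)
    }
    warning(sprintf("dt = %g exceeds the recommended stability limit %g",
                    dt, lim$dt_recommended), call. = FALSE)
  }

  if (engine == "auto") {
    engine <- if (is.null(sources) && is.null(hooks)) "compiled" else "reference"
  }
  if (engine == "compiled" && (!is.null(sources) || !is.null(hooks))) {
    stop("the compiled engine supports neither sources nor hooks; use engine = 'reference'",
         call. = FALSE)
  }

  plan <- .step_plan(dt, t_final)
  snap_steps <- .snapshot_steps(snapshot_times, dt, plan$n_total, t_final)
  monitor_every <- as.integer(monitor_every)
  front_idx <- if (!is.null(front_target)) which(grid$x >= front_target)[1L] else NA_integer_
  energy_w <- 1 / (params$gamma2 * params$beta)

  raw <- if (engine == "compiled") {
    .simulate_compiled(initial, params, profile, grid, dt, plan, snap_steps,
                       monitor_every, front_idx, front_threshold, energy_w)
  } else {
    .simulate_reference(initial, params, profile, ops, dt, plan, snap_steps,
                        monitor_every, front_idx, front_threshold, energy_w,
                        sources, hooks)
  }

  snap_times <- vapply(snap_steps, .step_time, numeric(1L),
                       dt = dt, n_total = plan$n_total, t_final = t_final,
                       dt_last = plan$dt_last)
  states <- Map(function(U, tt) state_from_matrix(U, t = tt),
                raw$snapshots, snap_times)
  bounds <- NULL
  if (monitor_every > 0L && length(raw$monitor_times)) {
    bounds <- data.frame(time = raw$monitor_times)
    mm <- raw$monitor_minmax   # rows: records; cols: C_min, C_max, ..., O_max
    colnames(mm) <- as.vector(rbind(paste0(.FIELDS, "_min"), paste0(.FIELDS, "_max")))
    bounds <- cbind(bounds, as.data.frame(mm))
    bounds$energy <- raw$monitor_energy
  }
  structure(
    list(times = snap_times, states = states, step_count = plan$n_total,
         dt = dt, dt_last = plan$dt_last,
         extrema = data.frame(component = .FIELDS, min = raw$ext_min,
                              max = raw$ext_max, row.names = NULL),
         bounds = bounds, front_arrival = raw$front_arrival,
         grid = grid, engine = engine, stability = lim, status = "completed"),
    class = "run_result"
  )
}

#' @export
print.run_result <- function(x, ...) {
  cat(sprintf("<run_result> %d steps, dt = %g, t in [0, %g], engine = %s\n",
              x$step_count, x$dt, max(x$times), x$engine))
  cat("global extrema over the run:\n")
  print(x$extrema)
  invisible(x)
}

.simulate_compiled <- function(initial, params, profile, grid, dt, plan,
                               snap_steps, monitor_every, front_idx,
                               front_threshold, energy_w) {
  res <- rk4_core(state_matrix(initial), grid$dx, dt,
                  plan$n_full, plan$dt_last,
                  as.numeric(unlist(params[c("d_C", "d_P", "d_I", "d_O",
                                             "alpha1", "alpha2", "alpha3",
                                             "k1", "k2", "k3", "k4", "k5", "k6",
                                             "gamma1", "gamma2", "K_O", "O_max",
                                             "beta")])),
                  profile$T, profile$dphi_dx,
                  monitor_every, as.integer(snap_steps),
                  if (is.na(front_idx)) -1L else front_idx - 1L,
                  front_threshold, energy_w)
  res$front_arrival <- if (res$front_arrival < 0) NA_real_ else res$front_arrival
  res
}

.simulate_reference <- function(initial, params, profile, ops, dt, plan,
                                snap_steps, monitor_every, front_idx,
                                front_threshold, energy_w, sources, hooks) {
  U <- state_matrix(initial)
  x <- ops$grid$x
  dxh <- ops$grid$dx
  rhs <- function(U, t) .rhs_matrix(U, t, params, profile, ops, sources)

  col_min <- function(U) c(min(U[, 1L]), min(U[, 2L]), min(U[, 3L]),
                           min(U[, 4L]), min(U[, 5L]))
  col_max <- function(U) c(max(U[, 1L]), max(U[, 2L]), max(U[, 3L]),
                           max(U[, 4L]), max(U[, 5L]))
  energy_of <- function(U) {
    q <- U[, 1L]^2 + U[, 2L]^2 + U[, 3L]^2 + U[, 4L]^2 + energy_w * U[, 5L]^2
    0.5 * trapezoid_integral(q, dxh)
  }

  ext_min <- col_min(U); ext_max <- col_max(U)
  snapshots <- list(); snap_ptr <- 1L
  monitor_times <- numeric(0L); monitor_minmax <- NULL; monitor_energy <- numeric(0L)
  record_monitor <- function(t, mn, mx) {
    monitor_times <<- c(monitor_times, t)
    monitor_minmax <<- rbind(monitor_minmax, as.vector(rbind(mn, mx)))
    monitor_energy <<- c(monitor_energy, energy_of(U))
  }
  front_arrival <- NA_real_
  check_front <- function(t) {
    if (!is.na(front_idx) && is.na(front_arrival) &&
        any(U[front_idx:nrow(U), 1L] > front_threshold)) {
      front_arrival <<- t
    }
  }

  if (length(snap_steps) && snap_steps[snap_ptr] == 0L) {
    snapshots[[length(snapshots) + 1L]] <- U
    snap_ptr <- snap_ptr + 1L
  }
  if (monitor_every > 0L) record_monitor(0, ext_min, ext_max)
  check_front(0)

  t <- 0
  for (n in seq_len(plan$n_total)) {
    h <- if (n <= plan$n_full) dt else plan$dt_last
    U <- rk4_step(rhs, U, t, h)
    t <- if (n <= plan$n_full) n * dt else plan$n_full * dt + plan$dt_last
    mn <- col_min(U); mx <- col_max(U)
    if (any(!is.finite(mn)) || any(!is.finite(mx))) {
      bad <- .FIELDS[which(!is.finite(mn) | !is.finite(mx))[1L]]
      stop(sprintf("non-finite state in component %s at t = %g", bad, t),
           call. = FALSE)
    }
    ext_min <- pmin(ext_min, mn); ext_max <- pmax(ext_max, mx)
    if (monitor_every > 0L && n %% monitor_every == 0L) record_monitor(t, mn, mx)
    if (snap_ptr <= length(snap_steps) && snap_steps[snap_ptr] == n) {
      snapshots[[length(snapshots) + 1L]] <- U
      snap_ptr <- snap_ptr + 1L
    }
    check_front(t)
    if (!is.null(hooks)) for (hk in hooks) hk(U, t, n)
  }

  list(snapshots = snapshots, ext_min = ext_min, ext_max = ext_max,
       monitor_times = monitor_times, monitor_minmax = monitor_minmax,
       monitor_energy = monitor_energy, front_arrival = front_arrival)
}
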