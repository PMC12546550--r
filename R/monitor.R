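#' Invariant region of the five-field system
#'
#' The per-component box that the continuous solution provably never leaves
#' and that the discrete scheme is verified to preserve:
#' \eqn{C \in [0, 1]}, \eqn{P \in [0, P_{\max}]} with
#' \eqn{P_{\max} = \max\{\xi_1, (k_4 + k_5)/k_6\}}, \eqn{I \in [0, \xi_2]},
#' \eqn{F \in [0, \xi_3]} and \eqn{O \in [0, O_{upper}]} with
#' \eqn{O_{upper} = \max\{O_0 + \xi_4, O_{\max}\}}. Bounds are recomputed from
#' the supplied parameters and initial conditions on every call, never cached.
#'
#' @param params A [model_parameters()] object.
#' @param ics An [initial_conditions()] object.
#' @return An object of class `"invariant_region"`: named list of
#'   `c(lower, upper)` intervals for `C, P, I, F, O`.
#' @examples
#' invariant_region(model_parameters(), initial_conditions())
#' @export
invariant_region <- function(params, ics = initial_conditions()) {
  ## production/decay balance; a zeroed decay rate (admissible only in the
  ## relaxed verification mode, where production is zeroed too) contributes no
  ## production ceiling
  prod_ceiling <- if (params$k6 > 0) (params$k4 + params$k5) / params$k6 else 0
  P_max <- max(ics$xi1, prod_ceiling)
  O_upper <- max(ics$O0 + ics$xi4, params$O_max)
  region <- list(C = c(0, 1), P = c(0, P_max), I = c(0, ics$xi2),
                 F = c(0, ics$xi3), O = c(0, O_upper))
  for (nm in names(region)) {
    iv <- region[[nm]]
    stopifnot(all(is.finite(iv)), iv[1L] <= iv[2L])
  }
  structure(region, class = "invariant_region", P_max = P_max, O_upper = O_upper)
}

#' @export
print.invariant_region <- function(x, ...) {
  cat("<invariant_region>\n")
  for (nm in .FIELDS) cat(sprintf("  %s in [%g, %g]\n", nm, x[[nm]][1L], x[[nm]][2L]))
  invisible(x)
}

#' Check a state against the invariant region
#'
#' A component fails iff some node lies outside its closed interval by more
#' than `tol` (absolute). States are observed, never clipped or projected:
#' region preservation is a claim the scheme is verified against, not a
#' constraint it enforces.
#'
#' @param state A [system_state()].
#' @param region An [invariant_region()].
#' @param tol Absolute tolerance, `>= 0` (default `1e-10`, absorbing
#'   round-off).
#' @return A list with `pass` (logical scalar), `table` (per-component data
#'   frame with `min`, `max`, `excess`, `pass`) and `worst` (component, node
#'   and value of the worst offender, or `NULL` if everything passes).
#' @export
check_state <- function(state, region, tol = 1e-10) {
  stopifnot(tol >= 0)
  rows <- lapply(.FIELDS, function(nm) {
    v <- state[[nm]]
    iv <- region[[nm]]
    below <- iv[1L] - min(v)
    above <- max(v) - iv[2L]
    excess <- max(below, above, 0)
    node <- if (below >= above) which.min(v) else which.max(v)
    data.frame(component = nm, min = min(v), max = max(v),
               lower = iv[1L], upper = iv[2L], excess = excess,
               node = node, pass = excess <= tol, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  worst <- NULL
  if (!all(tab$pass)) {
    w <- tab[which.max(tab$excess), ]
    worst <- list(component = w$component, node = w$node,
                  value = state[[w$component]][w$node], excess = w$excess)
  }
  list(pass = all(tab$pass), table = tab, worst = worst)
}

#' Check the global extrema of a run against the invariant region
#'
#' Applies the region check to the per-component global minima/maxima that
#' [run_simulation()] tracked at every accepted step, and scans the recorded
#' bounds series (if any) for the first monitored violation.
#'
#' @param result A [run_simulation()] result.
#' @param region An [invariant_region()].
#' @param tol Absolute tolerance (default `1e-10`).
#' @return A list with `pass`, `table` (extrema vs intervals) and
#'   `first_violation` (time/component of the first monitored violation, or
#'   `NULL`).
#' @export
check_run <- function(result, region, tol = 1e-10) {
  stopifnot(tol >= 0)
  ex <- result$extrema
  rows <- lapply(seq_len(nrow(ex)), function(i) {
    nm <- ex$component[i]
    iv <- region[[nm]]
    excess <- max(iv[1L] - ex$min[i], ex$max[i] - iv[2L], 0)
    data.frame(component = nm, min = ex$min[i], max = ex$max[i],
               lower = iv[1L], upper = iv[2L], excess = excess,
               pass = excess <= tol, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  first_violation <- NULL
  if (!is.null(result$bounds)) {
    b <- result$bounds
    for (i in seq_len(nrow(b))) {
      for (nm in .FIELDS) {
        lo <- region[[nm]][1L]; hi <- region[[nm]][2L]
        if (b[[paste0(nm, "_min")]][i] < lo - tol ||
            b[[paste0(nm, "_max")]][i] > hi + tol) {
          first_violation <- list(time = b$time[i], component = nm)
          break
        }
      }
      if (!is.null(first_violation)) break
    }
  }
  list(pass = all(tab$pass), table = tab, first_violation = first_violation)
}

#' Energy functional of a state
#'
#' Trapezoidal quadrature of
#' \deqn{E = \frac{1}{2} \int_\Omega \left( C^2 + P^2 + I^2 + F^2 +
#'   \frac{1}{\gamma_2 \beta} O^2 \right) dx,}
#' the Lyapunov-type functional whose eventual boundedness expresses the
#' dissipativity of the system. Used as a diagnostic trace; always
#' nonnegative.
#'
#' @param state A [system_state()].
#' @param params A [model_parameters()] object (supplies \eqn{\gamma_2 \beta}).
#' @param dx Grid spacing.
#' @return The energy value (scalar, `>= 0`).
#' @examples
#' s <- system_state(C = rep(1, 5), P = rep(1, 5), I = rep(1, 5),
#'                   F = rep(1, 5), O = rep(1, 5))
#' energy(s, model_parameters(), dx = 0.25)  # 0.5 * (4 + 1/0.05) = 12
#' @export
energy <- function(state, params, dx) {
  stopifnot(params$gamma2 * params$beta > 0)
  q <- state$C^2 + state$P^2 + state$I^2 + state$F^2 +
       state$O^2 / (params$gamma2 * params$beta)
  0.5 * trapezoid_integral(q, dx)
}
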