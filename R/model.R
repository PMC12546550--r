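#' Michaelis-Menten saturation function
#'
#' \eqn{H(O) = O / (K_O + O)}: the saturating factor modulating
#' oxygen-dependent endothelial proliferation and oxygen consumption.
#' Monotone increasing in `O` and bounded below 1 for finite `O`. Negative
#' concentrations are reported with a warning but not clamped; positivity is a
#' property the scheme is verified to preserve, not one that is enforced.
#'
#' @param O Oxygen concentration(s), numeric vector.
#' @param K_O Half-saturation constant, positive scalar.
#' @return `O / (K_O + O)`, same length as `O`.
#' @examples
#' michaelis_menten(0.2, K_O = 0.2)  # 0.5 at half-saturation
#' @export
michaelis_menten <- function(O, K_O) {
  stopifnot(is.numeric(K_O), length(K_O) == 1L, K_O > 0)
  if (any(O < 0, na.rm = TRUE)) {
    warning("negative oxygen concentration passed to michaelis_menten(); ",
            "value computed without clamping", call. = FALSE)
  }
  O / (K_O + O)
}

#' Tumor angiogenic factor profile and its regularization
#'
#' Samples \eqn{T(x) = \exp(-\epsilon^{-1} (L_f - x)^2)} (a fixed field peaking
#' at the tumor edge \eqn{x = L_f}) and its logarithmic regularization
#' \eqn{\phi(x) = \alpha_4^{-1} \log(1 + \alpha_4 T(x))} on the grid.
#' `dphi_dx` is precomputed with the package's discrete gradient operator (not
#' the analytic derivative), so the advective flux in the semi-discrete system
#' uses exactly the discrete stencil throughout.
#'
#' @param grid A [grid1d()] object.
#' @param epsilon Transition width, positive.
#' @param alpha4 Regularization strength, positive.
#' @param Dx Optional precomputed gradient matrix for `grid`; built on the fly
#'   if omitted.
#' @return An object of class `"tumor_profile"`: list with `T`, `phi`,
#'   `dphi_dx` (grid functions), `epsilon`, `alpha4` and `grid`.
#' @examples
#' pr <- tumor_factor(grid1d(1, 16), epsilon = 0.01, alpha4 = 1)
#' pr$T[17]  # 1 at the tumor edge
#' @export
tumor_factor <- function(grid, epsilon = 0.01, alpha4 = 1, Dx = NULL) {
  .check_grid(grid)
  stopifnot(epsilon > 0, alpha4 > 0)
  Tx <- exp(-(grid$L_f - grid$x)^2 / epsilon)
  phi <- log1p(alpha4 * Tx) / alpha4
  if (is.null(Dx)) Dx <- gradient_matrix(grid)
  tumor_profile(T = Tx, phi = phi, dphi_dx = as.vector(Dx %*% phi),
                grid = grid, epsilon = epsilon, alpha4 = alpha4)
}

#' Low-level tumor-profile constructor
#'
#' Assembles a `"tumor_profile"` from explicitly supplied grid functions.
#' [tumor_factor()] is the standard entry point; this constructor exists for
#' verification workflows that need a non-standard profile (e.g. a profile that
#' is identically zero, which switches the angiogenic forcing off).
#'
#' @param T,phi,dphi_dx Grid functions (numeric vectors of equal length).
#' @param grid Optional [grid1d()] the profile lives on.
#' @param epsilon,alpha4 Optional parameters recorded for provenance.
#' @return An object of class `"tumor_profile"`.
#' @export
tumor_profile <- function(T, phi, dphi_dx, grid = NULL, epsilon = NA_real_,
                          alpha4 = NA_real_) {
  stopifnot(length(T) == length(phi), length(phi) == length(dphi_dx))
  structure(list(T = as.numeric(T), phi = as.numeric(phi),
                 dphi_dx = as.numeric(dphi_dx), grid = grid,
                 epsilon = epsilon, alpha4 = alpha4),
            class = "tumor_profile")
}

#' @export
print.tumor_profile <- function(x, ...) {
  cat(sprintf("<tumor_profile> %d nodes, T in [%g, %g], epsilon = %g, alpha4 = %g\n",
              length(x$T), min(x$T), max(x$T), x$epsilon, x$alpha4))
  invisible(x)
}

.check_shared_grid <- function(state, profile) {
  if (length(state$C) != length(profile$T)) {
    stop("state and tumor profile do not share a grid (lengths ",
         length(state$C), " vs ", length(profile$T), ")", call. = FALSE)
  }
  invisible(TRUE)
}

.check_state_finite <- function(state) {
  for (nm in .FIELDS) {
    if (anyNA(state[[nm]]) || any(!is.finite(state[[nm]]))) {
      stop("non-finite value in component ", nm, call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Local reaction terms of the five equations
#'
#' Elementwise evaluation of the reaction part of the model:
#' \deqn{\big(k_1 C (1-C) H(O);\;
#'   -k_3 P I + k_4 T C + k_5 T - k_6 P;\;
#'   -k_3 P I;\; -k_2 P F;\;
#'   -\gamma_1 C O/(K_O + O) + \gamma_2 (O_{max} - O) \beta C\big).}
#'
#' @param state A [system_state()].
#' @param params A [model_parameters()] object.
#' @param profile A [tumor_factor()] profile on the same grid.
#' @return Named list of five grid functions (`C`, `P`, `I`, `F`, `O`).
#' @export
reaction_terms <- function(state, params, profile) {
  .check_shared_grid(state, profile)
  .check_state_finite(state)
  C <- state$C; P <- state$P; I <- state$I; Fm <- state$F; O <- state$O
  H <- O / (params$K_O + O)
  list(
    C = params$k1 * C * (1 - C) * H,
    P = -params$k3 * P * I + params$k4 * profile$T * C +
        params$k5 * profile$T - params$k6 * P,
    I = -params$k3 * P * I,
    F = -params$k2 * P * Fm,
    O = -params$gamma1 * C * O / (params$K_O + O) +
        params$gamma2 * (params$O_max - O) * params$beta * C
  )
}

#' Divergence of the taxis flux in the endothelial equation
#'
#' Computes \eqn{D_x\big(C \odot (\alpha_1 D_x F - \alpha_2 D_x I +
#' \alpha_3\, d\phi/dx)\big)} with the discrete gradient applied twice. The
#' sign convention is that of the endothelial equation, where this quantity
#' enters with a leading minus sign. `alpha2` is used verbatim (negative by
#' default), so the term \eqn{-\alpha_2 D_x I} is an effective attraction up
#' inhibitor gradients under the reference parameterization.
#'
#' @inheritParams reaction_terms
#' @param ops An [operator_set()] on the shared grid.
#' @return A grid function (numeric vector).
#' @export
advective_flux_divergence <- function(state, profile, ops, params) {
  .check_shared_grid(state, profile)
  v <- params$alpha1 * as.vector(ops$Dx %*% state$F) -
       params$alpha2 * as.vector(ops$Dx %*% state$I) +
       params$alpha3 * profile$dphi_dx
  as.vector(ops$Dx %*% (state$C * v))
}

## Matrix-form right-hand side used by the integrators. U is (M+1) x 5 in the
## order C, P, I, F, O; sources (if given) is a list of five functions f(x, t).
## Returns a matrix of the same shape. Single source of truth for the R path;
## semi_discrete_rhs() is the user-facing wrapper.
.rhs_matrix <- function(U, t, params, profile, ops, sources = NULL) {
  C <- U[, 1L]; P <- U[, 2L]; I <- U[, 3L]; Fm <- U[, 4L]; O <- U[, 5L]
  Dx <- ops$Dx; Dxx <- ops$Dxx
  v <- params$alpha1 * as.vector(Dx %*% Fm) -
       params$alpha2 * as.vector(Dx %*% I) +
       params$alpha3 * profile$dphi_dx
  adv <- as.vector(Dx %*% (C * v))
  H <- O / (params$K_O + O)
  out <- U            # reuse shape
  out[, 1L] <- params$d_C * as.vector(Dxx %*% C) - adv +
               params$k1 * C * (1 - C) * H
  out[, 2L] <- params$d_P * as.vector(Dxx %*% P) -
               params$k3 * P * I + params$k4 * profile$T * C +
               params$k5 * profile$T - params$k6 * P
  out[, 3L] <- params$d_I * as.vector(Dxx %*% I) - params$k3 * P * I
  out[, 4L] <- -params$k2 * P * Fm
  out[, 5L] <- params$d_O * as.vector(Dxx %*% O) -
               params$gamma1 * C * O / (params$K_O + O) +
               params$gamma2 * (params$O_max - O) * params$beta * C
  if (!is.null(sources)) {
    x <- ops$grid$x
    for (k in seq_len(5L)) out[, k] <- out[, k] + sources[[k]](x, t)
  }
  out
}

#' Semi-discrete right-hand side of the method-of-lines system
#'
#' Assembles \eqn{dU/dt = L(U) + N(U)} where \eqn{L(U)} holds the linear
#' diffusion terms \eqn{(d_C D_{xx} C,\, d_P D_{xx} P,\, d_I D_{xx} I,\, 0,\,
#' d_O D_{xx} O)} and \eqn{N(U)} the taxis flux divergence (entering the
#' endothelial equation with a minus sign) plus the [reaction_terms()]. The
#' matrix equation has no spatial operator: its right-hand side is purely
#' local. Optional per-field `sources` (callables on `(x, t)`) support
#' manufactured-solution forcing; the physical model is autonomous and ignores
#' `t`.
#'
#' @inheritParams advective_flux_divergence
#' @param t Evaluation time (used only by time-dependent sources).
#' @param sources Optional named list of five vectorized functions `f(x, t)`
#'   in the order `C, P, I, F, O`.
#' @return Named list of five grid functions; a non-finite result aborts with
#'   the first offending field named.
#' @export
semi_discrete_rhs <- function(state, t = state$t, params, profile, ops,
                              sources = NULL) {
  .check_shared_grid(state, profile)
  .check_state_finite(state)
  out <- .rhs_matrix(state_matrix(state), t, params, profile, ops, sources)
  for (k in seq_len(5L)) {
    if (any(!is.finite(out[, k]))) {
      stop("non-finite right-hand side in component ", .FIELDS[k], call. = FALSE)
    }
  }
  setNames(lapply(seq_len(5L), function(k) out[, k]), .FIELDS)
}
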