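## Parameters of the five-field angiogenesis model. The "reference set" values
## (diffusivities, taxis sensitivities, kinetic rates, oxygen constants) follow
## the published physiological parameterization; the remaining defaults (k4, k5,
## beta, O_max, epsilon, alpha4) are package choices documented in the methods
## vignette and flagged as such by parameter_table().

.REFERENCE_PARAMS <- c("d_C", "d_P", "d_I", "d_O", "alpha1", "alpha2", "alpha3",
                       "k1", "k2", "k3", "k6", "gamma1", "gamma2", "K_O")
.PACKAGE_DEFAULT_PARAMS <- c("k4", "k5", "beta", "O_max", "epsilon", "alpha4")

.PARAM_MEANING <- c(
  d_C = "endothelial cell random motility",
  d_P = "protease diffusivity",
  d_I = "inhibitor diffusivity",
  d_O = "oxygen diffusion coefficient",
  alpha1 = "haptotaxis sensitivity (ECM gradient)",
  alpha2 = "chemotaxis sensitivity (inhibitor gradient)",
  alpha3 = "angiogenic-factor sensitivity",
  alpha4 = "TAF regularization strength",
  k1 = "endothelial proliferation rate",
  k2 = "ECM degradation by proteases",
  k3 = "protease-inhibitor binding rate",
  k4 = "TAF-driven protease production (cell-bound)",
  k5 = "TAF-driven protease production (constitutive)",
  k6 = "protease decay rate",
  gamma1 = "maximum oxygen consumption rate",
  gamma2 = "vascular oxygen supply rate",
  K_O = "oxygen half-saturation constant",
  O_max = "maximum oxygen concentration",
  beta = "vessel functionality coefficient",
  epsilon = "TAF transition width",
  L_f = "domain length"
)

#' Model parameters for the angiogenesis system
#'
#' Collects every rate and transport coefficient of the five-field model, with
#' defaults matching the published physiological reference set where one exists
#' (`d_C = 0.001`, `d_P = d_I = 0.01`, `d_O = 0.1`, `alpha1 = 0.1`,
#' `alpha2 = -0.1`, `alpha3 = 0.01`, `k1 = 0.1`, `k2 = 0.05`, `k3 = 0.5`,
#' `k6 = 0.2`, `gamma1 = 0.1`, `gamma2 = 0.05`, `K_O = 0.2`) and package
#' defaults elsewhere (`k4 = 0.1`, `k5 = 0.05`, `beta = 1`, `O_max = 1`,
#' `epsilon = 0.01`, `alpha4 = 1`); [parameter_table()] flags which is which.
#'
#' The chemotaxis sensitivity `alpha2` is stored as a negative number and used
#' verbatim in the flux term \eqn{-\alpha_2 \partial I/\partial x}; no sign
#' normalization is performed, so with the default the effective
#' inhibitor-gradient coefficient is +0.1.
#'
#' With `strict = TRUE` (the default) the sign constraints of the
#' well-posedness theory are enforced: all diffusivities and kinetic rates
#' positive, `alpha1, alpha3 > 0`, `alpha2 < 0`, and
#' `gamma1, gamma2, K_O, O_max, beta > 0`. `strict = FALSE` relaxes rates,
#' taxis sensitivities and diffusivities to "finite, diffusivities and rates
#' nonnegative", which verification workflows use to switch couplings off
#' (e.g. a pure-diffusion reduction).
#'
#' @param d_C,d_P,d_I,d_O Diffusivities.
#' @param alpha1,alpha2,alpha3 Haptotaxis, chemotaxis (negative) and
#'   angiogenic-factor sensitivities.
#' @param alpha4 Regularization strength of the tumor-factor profile.
#' @param k1,k2,k3,k4,k5,k6 Kinetic rates.
#' @param gamma1,gamma2 Maximum oxygen consumption and vascular supply rates.
#' @param K_O Oxygen half-saturation constant.
#' @param O_max Maximum oxygen concentration.
#' @param beta Vessel functionality coefficient.
#' @param epsilon Width of the tumor-factor transition zone.
#' @param L_f Domain length.
#' @param strict Enforce the full sign constraints (see Details).
#'
#' @return An object of class `"model_parameters"` (a named list).
#' @examples
#' p <- model_parameters()
#' d_max(p)
#' @export
model_parameters <- function(d_C = 0.001, d_P = 0.01, d_I = 0.01, d_O = 0.1,
                             alpha1 = 0.1, alpha2 = -0.1, alpha3 = 0.01,
                             alpha4 = 1,
                             k1 = 0.1, k2 = 0.05, k3 = 0.5,
                             k4 = 0.1, k5 = 0.05, k6 = 0.2,
                             gamma1 = 0.1, gamma2 = 0.05,
                             K_O = 0.2, O_max = 1, beta = 1,
                             epsilon = 0.01, L_f = 1,
                             strict = TRUE) {
  p <- list(d_C = d_C, d_P = d_P, d_I = d_I, d_O = d_O,
            alpha1 = alpha1, alpha2 = alpha2, alpha3 = alpha3, alpha4 = alpha4,
            k1 = k1, k2 = k2, k3 = k3, k4 = k4, k5 = k5, k6 = k6,
            gamma1 = gamma1, gamma2 = gamma2, K_O = K_O, O_max = O_max,
            beta = beta, epsilon = epsilon, L_f = L_f)
  bad <- names(p)[!vapply(p, function(v) is.numeric(v) && length(v) == 1L && is.finite(v),
                          logical(1L))]
  if (length(bad)) {
    stop("non-finite or non-scalar parameter value(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  .check_positive <- function(nms) {
    neg <- nms[vapply(nms, function(nm) p[[nm]] <= 0, logical(1L))]
    if (length(neg)) {
      stop("parameter(s) must be positive: ", paste(neg, collapse = ", "),
           call. = FALSE)
    }
  }
  ## always required (denominators / profile construction)
  .check_positive(c("K_O", "epsilon", "alpha4", "L_f"))
  if (strict) {
    .check_positive(c("d_C", "d_P", "d_I", "d_O", "alpha1", "alpha3",
                      "k1", "k2", "k3", "k4", "k5", "k6",
                      "gamma1", "gamma2", "O_max", "beta"))
    if (alpha2 >= 0) stop("alpha2 must be negative (chemotaxis sensitivity)", call. = FALSE)
  } else {
    nn <- c("d_C", "d_P", "d_I", "d_O", "k1", "k2", "k3", "k4", "k5", "k6",
            "gamma1", "gamma2")
    neg <- nn[vapply(nn, function(nm) p[[nm]] < 0, logical(1L))]
    if (length(neg)) {
      stop("diffusivities and rates must be nonnegative: ", paste(neg, collapse = ", "),
           call. = FALSE)
    }
  }
  structure(p, class = "model_parameters", strict = strict)
}

#' Largest diffusivity of a parameter set
#'
#' \eqn{d_{\max} = \max\{d_C, d_P, d_I, d_O\}}, the coefficient entering the
#' explicit-integration diffusion constraint.
#'
#' @param params A [model_parameters()] object.
#' @return A positive scalar.
#' @export
d_max <- function(params) {
  max(params$d_C, params$d_P, params$d_I, params$d_O)
}

#' Tabulate parameter values and their provenance
#'
#' @param params A [model_parameters()] object.
#' @return A data frame with columns `parameter`, `value`, `meaning` and
#'   `source` (`"reference set"` for values from the published physiological
#'   table, `"package default"` for values the package chooses itself,
#'   `"domain"` for the domain length).
#' @export
parameter_table <- function(params = model_parameters()) {
  nms <- names(.PARAM_MEANING)
  src <- ifelse(nms %in% .REFERENCE_PARAMS, "reference set",
                ifelse(nms %in% .PACKAGE_DEFAULT_PARAMS,
                       "package default (not from the reference set)", "domain"))
  data.frame(parameter = nms,
             value = vapply(nms, function(nm) params[[nm]], numeric(1L)),
             meaning = unname(.PARAM_MEANING[nms]),
             source = src,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' @export
print.model_parameters <- function(x, ...) {
  cat("<model_parameters>\n")
  tab <- parameter_table(x)
  print(tab, right = FALSE)
  invisible(x)
}
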