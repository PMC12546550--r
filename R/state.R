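#' System state: the five grid functions at one time
#'
#' Holds the grid samples of endothelial cell density `C`, protease `P`,
#' inhibitor `I`, extracellular matrix `F` and oxygen `O`, plus the current
#' time. All five fields must share one grid (equal lengths) and be finite:
#' NaN/Inf anywhere is rejected with the offending component named.
#'
#' @param C,P,I,F,O Numeric vectors of equal length (`M + 1` nodes).
#' @param t Current time (scalar, default 0).
#' @return An object of class `"system_state"`.
#' @examples
#' s <- system_state(C = rep(0, 9), P = rep(0.1, 9), I = rep(0.2, 9),
#'                   F = rep(1, 9), O = rep(0.5, 9))
#' @export
system_state <- function(C, P, I, F, O, t = 0) {
  fields <- list(C = as.numeric(C), P = as.numeric(P), I = as.numeric(I),
                 F = as.numeric(F), O = as.numeric(O))
  n <- unique(lengths(fields))
  if (length(n) != 1L) {
    stop("all five fields must share one grid (equal lengths); got lengths ",
         paste(lengths(fields), collapse = ", "), call. = FALSE)
  }
  for (nm in .FIELDS) {
    if (anyNA(fields[[nm]]) || any(!is.finite(fields[[nm]]))) {
      stop("non-finite value in component ", nm, call. = FALSE)
    }
  }
  stopifnot(is.numeric(t), length(t) == 1L, is.finite(t))
  structure(c(fields, list(t = t)), class = "system_state")
}

#' @export
print.system_state <- function(x, ...) {
  cat(sprintf("<system_state> %d nodes, t = %g\n", length(x$C), x$t))
  rng <- t(vapply(.FIELDS, function(nm) range(x[[nm]]), numeric(2L)))
  colnames(rng) <- c("min", "max")
  print(rng)
  invisible(x)
}

## (M+1) x 5 matrix view used by the integrators; column order C, P, I, F, O.
state_matrix <- function(state) {
  matrix(c(state$C, state$P, state$I, state$F, state$O),
         ncol = 5L, dimnames = list(NULL, .FIELDS))
}

state_from_matrix <- function(U, t = 0) {
  system_state(C = U[, 1L], P = U[, 2L], I = U[, 3L], F = U[, 4L], O = U[, 5L],
               t = t)
}

#' Convert a state to a data frame of columns x, C, P, I, F, O
#'
#' @param x A [system_state()] object.
#' @param grid The [grid1d()] the state lives on.
#' @param ... Unused.
#' @return A data frame with `M + 1` rows.
#' @export
as.data.frame.system_state <- function(x, grid = NULL, ...) {
  d <- data.frame(C = x$C, P = x$P, I = x$I, F = x$F, O = x$O)
  if (!is.null(grid)) {
    .check_grid(grid)
    stopifnot(length(grid$x) == nrow(d))
    d <- cbind(x = grid$x, d)
  }
  d
}
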