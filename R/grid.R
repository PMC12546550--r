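#' Uniform one-dimensional grid with inclusive endpoints
#'
#' Discretizes the domain \eqn{[0, L_f]} into `M` equal intervals, giving
#' `M + 1` nodes \eqn{x_j = j \Delta x}, \eqn{j = 0, \dots, M}, with
#' \eqn{\Delta x = L_f / M}. All finite-difference operators in the package
#' act on grid functions sampled at these nodes.
#'
#' @param L_f Domain length (dimensionless), positive scalar.
#' @param M Number of intervals; must be at least 4 so that the one-sided
#'   boundary stencils do not overlap.
#'
#' @return An object of class `"grid1d"`: a list with elements `L_f`, `M`,
#'   `dx` and `x` (the node coordinates, length `M + 1`).
#' @examples
#' g <- grid1d(L_f = 1, M = 8)
#' g$dx
#' @export
grid1d <- function(L_f = 1, M = 256L) {
  stopifnot(is.numeric(L_f), length(L_f) == 1L, is.finite(L_f), L_f > 0)
  M <- as.integer(M)
  if (length(M) != 1L || is.na(M) || M < 4L) {
    stop("M must be an integer >= 4: the one-sided boundary stencils at rows ",
         "0, 1, M-1, M would otherwise collide", call. = FALSE)
  }
  structure(
    list(L_f = L_f, M = M, dx = L_f / M,
         x = seq(0, L_f, length.out = M + 1L)),
    class = "grid1d"
  )
}

#' @export
print.grid1d <- function(x, ...) {
  cat(sprintf("<grid1d> [0, %g], M = %d intervals, dx = %g\n",
              x$L_f, x$M, x$dx))
  invisible(x)
}

.check_grid <- function(grid) {
  if (!inherits(grid, "grid1d")) stop("expected a 'grid1d' object", call. = FALSE)
  invisible(grid)
}

#' Discrete gradient operator with second-order one-sided boundary rows
#'
#' Builds the \eqn{(M+1) \times (M+1)} first-derivative matrix: central
#' differences \eqn{(-1, 0, 1)/(2\Delta x)} at interior rows and the
#' second-order one-sided stencils \eqn{(-3, 4, -1)/(2\Delta x)} (first row) and
#' \eqn{(1, -4, 3)/(2\Delta x)} (last row) at the boundaries, so the operator
#' retains \eqn{O(\Delta x^2)} accuracy up to and including the endpoints.
#'
#' @param grid A [grid1d()] object.
#' @return A sparse `Matrix::dgCMatrix` of dimension `(M+1) x (M+1)`.
#' @seealso [laplacian_matrix()], [operator_set()]
#' @export
gradient_matrix <- function(grid) {
  .check_grid(grid)
  M <- grid$M
  h <- grid$dx
  int <- 2:M                              # interior rows (1-based)
  i <- c(1L, 1L, 1L, rep(int, each = 2L), M + 1L, M + 1L, M + 1L)
  j <- c(1L, 2L, 3L, as.vector(rbind(int - 1L, int + 1L)), M - 1L, M, M + 1L)
  v <- c(-3, 4, -1, rep(c(-1, 1), times = M - 1L), 1, -4, 3) / (2 * h)
  Matrix::sparseMatrix(i = i, j = j, x = v, dims = c(M + 1L, M + 1L))
}

#' Discrete Laplacian with homogeneous-Neumann boundary rows
#'
#' Builds the \eqn{(M+1) \times (M+1)} tridiagonal second-derivative matrix
#' \eqn{(1, -2, 1)/\Delta x^2} whose boundary rows \eqn{(-2, 2)/\Delta x^2} and
#' \eqn{(2, -2)/\Delta x^2} encode the zero-flux (ghost-reflection
#' \eqn{u_{-1} = u_1}) Neumann condition. Every row sums to zero, and with
#' trapezoidal weights the operator conserves discrete mass exactly.
#'
#' @inheritParams gradient_matrix
#' @return A sparse `Matrix::dgCMatrix` of dimension `(M+1) x (M+1)`.
#' @export
laplacian_matrix <- function(grid) {
  .check_grid(grid)
  M <- grid$M
  h2 <- grid$dx^2
  int <- 2:M
  i <- c(1L, 1L, rep(int, each = 3L), M + 1L, M + 1L)
  j <- c(1L, 2L, as.vector(rbind(int - 1L, int, int + 1L)), M, M + 1L)
  v <- c(-2, 2, rep(c(1, -2, 1), times = M - 1L), 2, -2) / h2
  Matrix::sparseMatrix(i = i, j = j, x = v, dims = c(M + 1L, M + 1L))
}

#' Closed-form spectrum of the Neumann Laplacian
#'
#' Eigenvalues of [laplacian_matrix()] in closed form,
#' \deqn{\lambda_m = -\frac{4}{\Delta x^2} \sin^2\!\left(\frac{m \pi \Delta x}{2 L_f}\right),
#'   \quad m = 0, \dots, M,}
#' with eigenvectors \eqn{\cos(m \pi j / M)}. \eqn{\lambda_0 = 0} is the
#' constant mode; the most negative eigenvalue is \eqn{-4/\Delta x^2}. These
#' eigenvalues drive the explicit-integration diffusion constraint
#' \eqn{\Delta t \le \Delta x^2 / (2 d_{\max})}.
#'
#' @inheritParams gradient_matrix
#' @return Numeric vector of length `M + 1`, ordered by increasing mode number
#'   `m = 0..M` (hence decreasing eigenvalue).
#' @export
laplacian_spectrum <- function(grid) {
  .check_grid(grid)
  m <- 0:grid$M
  -(4 / grid$dx^2) * sin(m * pi / (2 * grid$M))^2
}

#' Bundle the discrete operators for a grid
#'
#' Convenience container holding a grid together with its gradient and
#' Laplacian matrices; built once per run and treated as immutable.
#'
#' @inheritParams gradient_matrix
#' @return An object of class `"operator_set"`: list with `grid`, `Dx`, `Dxx`.
#' @export
operator_set <- function(grid) {
  .check_grid(grid)
  structure(
    list(grid = grid, Dx = gradient_matrix(grid), Dxx = laplacian_matrix(grid)),
    class = "operator_set"
  )
}

#' @export
print.operator_set <- function(x, ...) {
  cat(sprintf("<operator_set> Dx, Dxx (%d x %d) on ", x$grid$M + 1L, x$grid$M + 1L))
  print(x$grid)
  invisible(x)
}

#' Trapezoidal quadrature on a uniform grid
#'
#' Weights \eqn{(1/2, 1, \dots, 1, 1/2) \Delta x}; this is the quadrature under
#' which the Neumann Laplacian conserves mass exactly (telescoping sums).
#'
#' @param values Grid function (numeric vector).
#' @param dx Grid spacing.
#' @return The quadrature value (scalar).
#' @export
trapezoid_integral <- function(values, dx) {
  n <- length(values)
  stopifnot(n >= 2L)
  dx * (sum(values) - 0.5 * (values[1L] + values[n]))
}
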