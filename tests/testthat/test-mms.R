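test_that("exact fields evaluate to their closed-form spot values", {
  sol <- manufactured_solution("paper")
  g <- grid1d(1, 8)
  s0 <- evaluate_exact(sol, g, 0)
  expect_equal(s0$C[which(g$x == 0.5)], 1)            # (1 + sin(pi/2))/2
  expect_equal(s0$O[1], 0.9)                          # 0.5 + 0.4 cos 0
  expect_equal(s0$P[1], 0.2)
  # matrix field decays to 1 pointwise as t grows
  far <- evaluate_exact(sol, g, 60)
  expect_equal(far$F, rep(1, 9), tolerance = 1e-9)
  expect_error(evaluate_exact(sol, g, -1))
})

test_that("the verbatim variant violates zero flux where the compatible one does not", {
  paper <- manufactured_solution("paper")
  compat <- manufactured_solution("neumann_compatible")
  expect_equal(paper$fields$C$fx(0, 0), pi / 2)        # nonzero boundary slope
  expect_equal(paper$fields$I$fx(0, 0), 0.4 * pi)
  for (nm in c("C", "P", "I", "F", "O")) {
    expect_equal(compat$fields[[nm]]$fx(c(0, 1), 0), c(0, 0), tolerance = 1e-12)
  }
})

test_that("compensating sources close the equations pointwise", {
  p <- model_parameters()
  sol <- manufactured_solution("paper")
  src <- mms_sources(sol, p)
  # F equation at (0.5, 0): P vanishes there, leaving only the time derivative
  expect_equal(src$F(0.5, 0), 0.08, tolerance = 1e-12)
  # residual identity at random points, both variants
  for (v in c("paper", "neumann_compatible")) {
    set.seed(42)
    x <- runif(100); t <- runif(100, 0, 2)
    res <- mms_residual(manufactured_solution(v), p, x, t)
    expect_lt(max(abs(res)), 1e-12)
  }
})

test_that("zeroed rates with constant fields give identically zero sources", {
  p0 <- model_parameters(alpha1 = 0, alpha2 = 0, alpha3 = 0,
                         k1 = 0, k2 = 0, k3 = 0, k4 = 0, k5 = 0, k6 = 0,
                         gamma1 = 0, gamma2 = 0, strict = FALSE)
  sol <- manufactured_solution("paper")
  # freeze every field to a constant: all derivatives vanish symbolically
  for (nm in c("C", "P", "I", "F", "O")) {
    e <- quote(0.3 + 0 * x + 0 * t)
    sol$fields[[nm]] <- list(expr = e,
                             f = angiomol:::.expr_fun(e),
                             ft = angiomol:::.expr_fun(D(e, "t")),
                             fx = angiomol:::.expr_fun(D(e, "x")),
                             fxx = angiomol:::.expr_fun(D(D(e, "x"), "x")))
  }
  src <- mms_sources(sol, p0)
  x <- seq(0, 1, by = 0.1)
  for (nm in c("C", "P", "I", "F", "O")) {
    expect_equal(src[[nm]](x, 0.7), rep(0, length(x)))
  }
})

test_that("discrete L2 error has the closed-form and homogeneity properties", {
  u <- runif(33)
  expect_identical(discrete_l2_error(u, u, 1 / 32), 0)
  cst <- u + 0.25
  expect_equal(discrete_l2_error(cst, u, 1 / 32), 0.25 * sqrt(33 / 32),
               tolerance = 1e-14)
  v <- runif(33)
  expect_equal(discrete_l2_error(u + 10 * (v - u), u, 1 / 32),
               10 * discrete_l2_error(v, u, 1 / 32), tolerance = 1e-12)
  expect_error(discrete_l2_error(u, u[-1], 1 / 32), "length")
})

test_that("observed_rate is the log2 error ratio and rejects bad input", {
  expect_identical(observed_rate(4, 1), 2)
  expect_equal(round(observed_rate(8.74e-3, 2.36e-3), 2), 1.89)
  expect_equal(round(observed_rate(6.54e-4, 1.74e-4), 2), 1.91)
  expect_equal(round(observed_rate(2.15e-5, 6.89e-6), 2), 1.64)
  expect_error(observed_rate(0, 1), "positive")
  expect_error(observed_rate(1, -1), "positive")
})

test_that("pure-diffusion reduction reproduces the textbook heat-equation orders", {
  # all couplings zero, oxygen carries a cosine: exact solution is the decaying
  # Neumann mode, the classical heat-equation verification problem
  p0 <- model_parameters(d_C = 0.05, d_P = 0.05, d_I = 0.05, d_O = 0.05,
                         alpha1 = 0, alpha2 = 0, alpha3 = 0,
                         k1 = 0, k2 = 0, k3 = 0, k4 = 0, k5 = 0, k6 = 0,
                         gamma1 = 0, gamma2 = 0, strict = FALSE)
  errs <- vapply(c(16L, 32L, 64L), function(M) {
    g <- grid1d(1, M)
    ops <- operator_set(g)
    n <- length(g$x)
    init <- system_state(C = rep(0, n), P = rep(0, n), I = rep(0, n),
                         F = rep(0, n), O = cos(pi * g$x))
    dt0 <- 0.25 * g$dx^2 / 0.05
    nstep <- ceiling(0.5 / dt0)
    res <- run_simulation(init, p0, ops, dt = 0.5 / nstep, t_final = 0.5,
                          profile = zero_profile(g), engine = "compiled")
    exact <- cos(pi * g$x) * exp(-0.05 * pi^2 * 0.5)
    discrete_l2_error(res$states[[length(res$states)]]$O, exact, g$dx)
  }, numeric(1L))
  rates <- log2(errs[-length(errs)] / errs[-1L])
  expect_true(all(rates > 1.9 & rates < 2.1))
})

test_that("evolved MMS errors match an independent stiff integrator", {
  p <- model_parameters()
  sol <- manufactured_solution("neumann_compatible")
  src <- mms_sources(sol, p)
  M <- 32L
  g <- grid1d(1, M)
  ops <- operator_set(g)
  prof <- tumor_factor(g, p$epsilon, p$alpha4, Dx = ops$Dx)
  fields <- c("C", "P", "I", "F", "O")
  # route 1: the package's RK4 loop with the step slaved to the grid
  dt0 <- 0.5 * g$dx^2 / (2 * d_max(p))
  dt <- 1 / ceiling(1 / dt0)
  init <- evaluate_exact(sol, g, 0)
  res <- run_simulation(init, p, ops, dt = dt, t_final = 1, sources = src,
                        engine = "reference", snapshot_times = 1)
  fin <- res$states[[length(res$states)]]
  # route 2: deSolve::lsoda on the same semi-discrete system at tight tolerance
  f <- function(t, y, parms) {
    U <- matrix(y, ncol = 5L)
    st <- system_state(U[, 1], U[, 2], U[, 3], U[, 4], U[, 5], t = t)
    list(unlist(semi_discrete_rhs(st, t, p, prof, ops, sources = src),
                use.names = FALSE))
  }
  out <- deSolve::ode(unlist(init[fields], use.names = FALSE), c(0, 1), f,
                      NULL, method = "lsoda", rtol = 1e-10, atol = 1e-12)
  U1 <- matrix(out[2L, -1L], ncol = 5L)
  ex <- evaluate_exact(sol, g, 1)
  for (k in seq_along(fields)) {
    e_rk4 <- discrete_l2_error(fin[[fields[k]]], ex[[fields[k]]], g$dx)
    e_ref <- discrete_l2_error(U1[, k], ex[[fields[k]]], g$dx)
    expect_equal(e_rk4, e_ref, tolerance = 5e-3)
  }
})

test_that("a single-grid study reports errors but no rates", {
  tab <- run_spatial_convergence(grids = 32L, t_final = 0.05)
  expect_equal(nrow(tab), 1L)
  expect_true(all(is.na(tab$C_rate)))
  expect_true(tab$C_error > 0)
})

test_that("exact-reference temporal errors plateau at the spatial floor", {
  # once the temporal error is below the fixed-grid spatial error, refining dt
  # cannot reduce the measured error: successive errors stop decreasing
  tab <- run_temporal_convergence(M_fixed = 32L, dts = c(2e-3, 1e-3, 5e-4),
                                  t_final = 0.5, reference_mode = "exact")
  errs <- tab$O_error
  expect_true(all(is.finite(errs)))
  expect_lt(max(abs(diff(errs))) / errs[1], 0.05)   # flat: spatial floor
})

test_that("convergence tables round-trip through their text format", {
  tab <- run_spatial_convergence(grids = 32L, t_final = 0.05)
  tmp <- file.path(tempdir(), "conv.tsv")
  write_convergence_table(tab, tmp)
  back <- read.table(tmp, header = TRUE, sep = "\t")
  expect_equal(back$C_error, tab$C_error, tolerance = 1e-12)
  meta <- yaml::read_yaml(file.path(tempdir(), "conv.meta.yaml"))
  expect_equal(meta$study, "spatial")
  expect_equal(meta$norm, "dx-weighted discrete L2")
})
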