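test_that("parameter validation enforces the well-posedness sign constraints", {
  p <- model_parameters()
  expect_s3_class(p, "model_parameters")
  expect_equal(d_max(p), 0.1)        # oxygen diffusion dominates
  expect_error(model_parameters(alpha2 = 0.1), "alpha2")
  expect_error(model_parameters(k3 = 0), "positive")
  expect_error(model_parameters(K_O = 0), "positive")
  expect_error(model_parameters(d_O = NA), "non-finite")
  # relaxed mode admits zeroed couplings but not negative rates
  expect_silent(model_parameters(k1 = 0, alpha1 = 0, alpha2 = 0, strict = FALSE))
  expect_error(model_parameters(k1 = -1, strict = FALSE), "nonnegative")
})

test_that("parameter table flags reference values and package defaults", {
  tab <- parameter_table(model_parameters())
  ref <- setNames(tab$value, tab$parameter)
  expect_equal(ref[["d_C"]], 0.001)
  expect_equal(ref[["d_P"]], 0.01)
  expect_equal(ref[["d_I"]], 0.01)
  expect_equal(ref[["d_O"]], 0.1)
  expect_equal(ref[["alpha1"]], 0.1)
  expect_equal(ref[["alpha2"]], -0.1)
  expect_equal(ref[["alpha3"]], 0.01)
  expect_equal(ref[["k1"]], 0.1)
  expect_equal(ref[["k2"]], 0.05)
  expect_equal(ref[["k3"]], 0.5)
  expect_equal(ref[["k6"]], 0.2)
  expect_equal(ref[["gamma1"]], 0.1)
  expect_equal(ref[["gamma2"]], 0.05)
  expect_equal(ref[["K_O"]], 0.2)
  expect_setequal(tab$parameter[tab$source == "reference set"],
                  c("d_C", "d_P", "d_I", "d_O", "alpha1", "alpha2", "alpha3",
                    "k1", "k2", "k3", "k6", "gamma1", "gamma2", "K_O"))
  expect_true(all(c("k4", "k5", "beta", "O_max", "epsilon", "alpha4") %in%
                    tab$parameter[grepl("package default", tab$source)]))
})

test_that("michaelis_menten has the saturation properties", {
  expect_identical(michaelis_menten(0, 0.2), 0)
  expect_equal(michaelis_menten(0.2, 0.2), 0.5)
  expect_equal(michaelis_menten(0.8, 0.2), 0.8)
  o <- seq(0, 10, by = 0.1)
  h <- michaelis_menten(o, 0.3)
  expect_true(all(diff(h) > 0))
  expect_true(all(h < 1))
  expect_warning(michaelis_menten(-0.1, 0.2), "negative")
})

test_that("tumor factor profile satisfies its bounds and monotonicity", {
  g <- grid1d(1, 64)
  pr <- tumor_factor(g, epsilon = 0.01, alpha4 = 1)
  expect_equal(pr$T[length(pr$T)], 1)            # exp(0) at the tumor edge
  expect_true(all(pr$T >= 0 & pr$T <= 1))
  expect_true(all(diff(pr$T) >= 0))
  expect_true(all(pr$phi >= 0 & pr$phi <= pr$T + 1e-15))
  # closed-form spot value at x = 0.9 (a node of the M = 20 grid)
  g20 <- grid1d(1, 20)
  pr20 <- tumor_factor(g20, epsilon = 0.01, alpha4 = 1)
  expect_equal(pr20$T[g20$x == 0.9], exp(-1), tolerance = 1e-12)
  expect_equal(log1p(1 * 1) / 1, log(2))          # phi at T = 1, alpha4 = 1
  expect_equal(pr$phi[length(pr$phi)], log(2), tolerance = 1e-12)
  expect_error(tumor_factor(g, epsilon = 0), "epsilon")
  expect_error(tumor_factor(g, alpha4 = -1))
})

test_that("reaction terms match a hand evaluation node by node", {
  p <- model_parameters()
  st <- system_state(C = 0.5, P = 0.1, I = 0.2, F = 1, O = 0.2)
  pr <- tumor_profile(T = 1, phi = 0, dphi_dx = 0)
  r <- reaction_terms(st, p, pr)
  expect_equal(unlist(r), c(C = 0.0125, P = 0.07, I = -0.01, F = -0.005,
                            O = -0.005))
})

test_that("reaction structure: constitutive protease source and logistic cap", {
  p <- model_parameters()
  g <- quick_grid()
  n <- length(g$x)
  pr <- tumor_factor(g)
  zero <- system_state(C = rep(0, n), P = rep(0, n), I = rep(0, n),
                       F = rep(0, n), O = rep(0, n))
  r <- reaction_terms(zero, p, pr)
  expect_equal(r$P, p$k5 * pr$T)       # only the constitutive source survives
  expect_true(all(r$C == 0) && all(r$I == 0) && all(r$F == 0) && all(r$O == 0))
  full <- system_state(C = rep(1, n), P = runif(n), I = runif(n),
                       F = runif(n), O = runif(n))
  expect_equal(reaction_terms(full, p, pr)$C, rep(0, n))   # (1 - C) = 0
})

test_that("advective flux divergence vanishes when it must and is exact on linears", {
  p <- model_parameters()
  g <- grid1d(1, 8)
  ops <- operator_set(g)
  n <- length(g$x)
  pr <- zero_profile(g)
  noC <- system_state(C = rep(0, n), P = rep(0, n), I = runif(n),
                      F = runif(n), O = rep(0, n))
  expect_equal(advective_flux_divergence(noC, pr, ops, p), rep(0, n))
  flat <- system_state(C = runif(n), P = rep(0, n), I = rep(0.3, n),
                       F = rep(0.7, n), O = rep(0, n))
  expect_lt(max(abs(advective_flux_divergence(flat, pr, ops, p))), 1e-12)
  # F = x, C = x, others flat: flux = alpha1 * x, divergence = alpha1
  lin <- system_state(C = g$x, P = rep(0, n), I = rep(0, n), F = g$x,
                      O = rep(0, n))
  expect_equal(advective_flux_divergence(lin, pr, ops, p),
               rep(p$alpha1, n), tolerance = 1e-12)
})

test_that("zero state with zero tumor factor is a fixed point of the RHS", {
  p <- model_parameters()
  g <- quick_grid()
  ops <- operator_set(g)
  n <- length(g$x)
  zero <- system_state(C = rep(0, n), P = rep(0, n), I = rep(0, n),
                       F = rep(0, n), O = rep(0, n))
  r <- semi_discrete_rhs(zero, 0, p, zero_profile(g), ops)
  expect_true(all(vapply(r, function(v) all(v == 0), logical(1L))))
})

test_that("RHS splits additively into diffusion and advection/reaction parts", {
  g <- quick_grid()
  ops <- operator_set(g)
  st <- random_state(g)
  pr <- tumor_factor(g)
  full <- model_parameters()
  diff_only <- model_parameters(alpha1 = 0, alpha2 = 0, alpha3 = 0,
                                k1 = 0, k2 = 0, k3 = 0, k4 = 0, k5 = 0, k6 = 0,
                                gamma1 = 0, gamma2 = 0, strict = FALSE)
  react_only <- model_parameters(d_C = 0, d_P = 0, d_I = 0, d_O = 0,
                                 strict = FALSE)
  r_full <- semi_discrete_rhs(st, 0, full, pr, ops)
  r_diff <- semi_discrete_rhs(st, 0, diff_only, pr, ops)
  r_react <- semi_discrete_rhs(st, 0, react_only, pr, ops)
  for (nm in c("C", "P", "I", "F", "O")) {
    expect_equal(r_full[[nm]], r_diff[[nm]] + r_react[[nm]], tolerance = 1e-14)
  }
})

test_that("matrix equation F is purely local and decoupled oxygen is pure diffusion", {
  p <- model_parameters()
  g <- quick_grid()
  ops <- operator_set(g)
  n <- length(g$x)
  st <- random_state(g)
  pr <- tumor_factor(g)
  r <- semi_discrete_rhs(st, 0, p, pr, ops)
  expect_equal(r$F, -p$k2 * st$P * st$F)     # no spatial operator in the F row
  # with C = 0 both oxygen consumption and supply vanish
  noC <- system_state(C = rep(0, n), P = st$P, I = st$I, F = st$F,
                      O = cos(pi * g$x))
  r2 <- semi_discrete_rhs(noC, 0, p, pr, ops)
  expect_equal(r2$O, p$d_O * as.vector(ops$Dxx %*% noC$O), tolerance = 1e-13)
})

test_that("oxygen row reproduces a hand matrix-vector product at M = 4", {
  p <- model_parameters()
  g <- grid1d(1, 4)
  ops <- operator_set(g)
  O <- cos(pi * g$x)
  st <- system_state(C = rep(0, 5), P = rep(0, 5), I = rep(0, 5),
                     F = rep(0, 5), O = O)
  r <- semi_discrete_rhs(st, 0, p, tumor_factor(g), ops)
  dense <- as.matrix(laplacian_matrix(g))
  expect_equal(r$O, 0.1 * as.vector(dense %*% O), tolerance = 1e-14)
})

test_that("semi-discrete RHS converges to the continuous RHS at second order", {
  p <- model_parameters()
  sol <- manufactured_solution("neumann_compatible")
  errs <- vapply(c(32L, 64L, 128L), function(M) {
    g <- grid1d(1, M)
    ops <- operator_set(g)
    st <- evaluate_exact(sol, g, 0.2)
    num <- semi_discrete_rhs(st, 0.2, p, tumor_factor(g, p$epsilon, p$alpha4), ops)
    cont <- angiomol:::.continuous_rhs_funs(sol, p)
    max(vapply(c("C", "P", "I", "O"), function(nm) {
      discrete_l2_error(num[[nm]], cont[[nm]](g$x, 0.2), g$dx)
    }, numeric(1L)))
  }, numeric(1L))
  rates <- log2(errs[-length(errs)] / errs[-1L])
  expect_true(all(abs(rates - 2) < 0.2))
})

test_that("reaction terms stay finite on states sampled inside the invariant region", {
  p <- model_parameters()
  reg <- invariant_region(p, initial_conditions())
  g <- quick_grid()
  pr <- tumor_factor(g)
  n <- length(g$x)
  set.seed(99)
  for (rep in 1:20) {
    st <- system_state(C = runif(n, reg$C[1], reg$C[2]),
                       P = runif(n, reg$P[1], reg$P[2]),
                       I = runif(n, reg$I[1], reg$I[2]),
                       F = runif(n, reg$F[1], reg$F[2]),
                       O = runif(n, reg$O[1], reg$O[2]))
    r <- reaction_terms(st, p, pr)
    expect_true(all(vapply(r, function(v) all(is.finite(v)), logical(1L))))
  }
})

test_that("non-finite inputs are rejected with the component named", {
  g <- quick_grid()
  ops <- operator_set(g)
  n <- length(g$x)
  expect_error(system_state(C = c(NaN, rep(0, n - 1L)), P = rep(0, n),
                            I = rep(0, n), F = rep(0, n), O = rep(0, n)),
               "component C")
  st <- random_state(g)
  st$I[3] <- Inf    # corrupt after construction
  expect_error(reaction_terms(st, model_parameters(), tumor_factor(g)),
               "component I")
})
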