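# Shared fixtures: small grids and parameter sets used across the suite.

quick_grid <- function(M = 16L, L_f = 1) grid1d(L_f, M)

# Reference parameters with every coupling switched off except diffusion;
# used for pure-diffusion oracles.
diffusion_only_parameters <- function(d = 0.1) {
  model_parameters(d_C = d, d_P = d, d_I = d, d_O = d,
                   alpha1 = 0, alpha2 = 0, alpha3 = 0,
                   k1 = 0, k2 = 0, k3 = 0, k4 = 0, k5 = 0, k6 = 0,
                   gamma1 = 0, gamma2 = 0, strict = FALSE)
}

# A profile that is identically zero: switches the angiogenic forcing off.
zero_profile <- function(grid) {
  n <- length(grid$x)
  tumor_profile(T = rep(0, n), phi = rep(0, n), dphi_dx = rep(0, n),
                grid = grid)
}

random_state <- function(grid, seed = 1) {
  set.seed(seed)
  n <- length(grid$x)
  system_state(C = runif(n), P = runif(n, 0, 0.5), I = runif(n, 0, 0.2),
               F = runif(n, 0.5, 1), O = runif(n, 0, 1))
}

test2_config_small <- function(M = 32L, t_final = 0.5, dt = 5e-4,
                               monitor_every = 50L) {
  run_config(M = M, dt = dt, t_final = t_final,
             monitor_every = monitor_every,
             snapshot_times = seq(0, t_final, length.out = 3L))
}
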