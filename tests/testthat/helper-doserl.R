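# shared fixtures, all generated in code

# group summary of exact (noise-free) data: large balanced groups with the
# group means equal to the curve values
gs_exact <- function(curve, n = rep(1000, 5), grid = dose_grid()) {
  group_summary(n, evaluate_curve(curve, as.numeric(grid)), 0, grid)
}

# group summary of one simulated balanced trial
gs_simulate <- function(curve, n_per = 30, sigma2 = 4.5, seed = 1,
                        grid = dose_grid()) {
  set.seed(seed)
  mu <- evaluate_curve(curve, as.numeric(grid))
  y <- vapply(mu, function(m) stats::rnorm(n_per, m, sqrt(sigma2)),
              numeric(n_per))
  group_summary(rep(n_per, length(mu)), colMeans(y),
                sum(scale(y, scale = FALSE)^2), grid)
}

# degenerate one-step environment: a fixed state, reward 1 iff the good arm
# is chosen; used to sanity-check the policy-gradient machinery
bandit_env_factory <- function(good_arm = 3, sdim = 14, K = 5) {
  function(seed) {
    s0 <- rep(0, sdim)
    list(B = 1L, K = K, state_dim = sdim,
         reset = function() s0,
         step = function(a) list(state = s0,
                                 reward = as.numeric(a == good_arm),
                                 done = TRUE))
  }
}

# published reference geometry of the 16 scenarios (target doses and
# target-dose intervals, printed to 2 decimals)
reference_geometry <- function() {
  data.frame(
    id = 1:16,
    d_targ = c(6.30, 7.88, 5.25, 2.00, 6.83, 1.17, 5.06, 7.37, 4.47,
               3.24, 5.26, 2.48, 7.76, 7.98, 7.58, NA),
    lower = c(5.67, 7.09, 4.73, 1.44, 3.30, 0.92, 4.68, 5.75, 4.24,
              2.76, 3.98, 2.16, 7.66, 7.88, 7.47, NA),
    upper = c(6.93, 8.00, 5.78, 2.95, 8.00, 1.52, 5.58, 8.00, 4.74,
              3.81, 8.00, 2.84, 7.86, 8.00, 7.67, NA)
  )
}
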