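test_that("model gradients agree with numerical differentiation", {
  skip_if_not_installed("numDeriv")
  cand <- candidate_set()
  curried <- list(
    linear = function(th, d) th[1] + th[2] * d,
    emax = function(th, d) th[1] + th[2] * d / (th[3] + d),
    sigEmax = function(th, d) th[1] + th[2] * d^th[4] / (th[3]^th[4] + d^th[4])
  )
  for (fam in names(curried)) {
    cv <- cand$models[[fam]]
    th <- c(cv$e0, cv$scale, cv$ed50, cv$h)[seq_len(cand$kpar[fam])]
    g_an <- drop(model_gradient(cv, 4))
    g_num <- numDeriv::grad(function(t) curried[[fam]](t, 4), th)
    expect_lt(max(abs(g_an - g_num)), 1e-6)
  }
  expect_equal(unname(drop(model_gradient(cand$models$linear, 0))), c(1, 0))
  # Emax at d = ED50: the standardized shape is at half maximum
  expect_equal(model_gradient(cand$models$emax, 0.79)[2], 0.5,
               tolerance = 1e-12)
})

test_that("Fisher information has the expected structure", {
  cand <- candidate_set()
  # single-dose design: rank one
  w1 <- c(0, 0, 1, 0, 0)
  M1 <- fisher_information(cand$models$emax, w1)
  expect_equal(sum(eigen(M1, symmetric = TRUE)$values > 1e-10), 1)
  # equal weights, linear model: moment matrix of (1, d) over the grid / 5
  Me <- fisher_information(cand$models$linear, rep(0.2, 5))
  d <- c(0, 2, 4, 6, 8)
  expect_equal(Me, matrix(c(1, mean(d), mean(d), mean(d^2)), 2),
               tolerance = 1e-12, ignore_attr = TRUE)
  # symmetric in the (dose, weight) pairing
  perm <- c(3, 1, 5, 2, 4)
  g <- dose_grid()
  Ma <- fisher_information(cand$models$sigEmax, c(.1, .2, .3, .25, .15))
  Gp <- model_gradient(cand$models$sigEmax, d[perm])
  Mb <- crossprod(Gp * sqrt(c(.1, .2, .3, .25, .15)[perm]))
  expect_equal(Ma, Mb, tolerance = 1e-12)
})

test_that("design objectives: infeasibility, improvement, stability", {
  cand <- candidate_set()
  # fewer support points than the largest model's dimension: singular
  expect_identical(d_objective(c(0.5, 0.5, 0, 0, 0), cand), Inf)
  expect_identical(td_objective(c(1, 0, 0, 0, 0), cand), Inf)
  # the optimizer improves on equal weights
  oD <- optimize_design(cand, "D", n_restarts = 5)
  expect_lt(oD$value, d_objective(rep(0.2, 5), cand))
  oT <- optimize_design(cand, "TD", n_restarts = 5)
  expect_lt(oT$value, td_objective(rep(0.2, 5), cand))
  # independent restarts land on the same design
  oD2 <- optimize_design(cand, "D", n_restarts = 5, seed = 999L)
  expect_lt(max(abs(oD$w - oD2$w)), 1e-4)
  # constrained mode: an overwhelming history pins the effective weights
  oC <- optimize_design(cand, "D", n_old = c(4000, 3000, 1000, 1000, 1000),
                        n_new = 10, n_restarts = 2)
  expect_lt(max(abs(oC$effective - c(0.4, 0.3, 0.1, 0.1, 0.1))), 0.002)
})

test_that("target-dose variance: estimability and implicit-gradient oracle", {
  cand <- candidate_set()
  # all mass on placebo: the MED is not estimable
  expect_identical(td_variance(cand$models$emax, c(1, 0, 0, 0, 0), 1.3), Inf)
  # finite for a full design
  expect_true(is.finite(td_variance(cand$models$emax, rep(0.2, 5), 1.3)))

  # finite-difference check of b = d d_targ / d theta
  curve <- cand$models$emax
  b_an <- doserl:::td_theta_gradient(curve, 1.3)$b
  th <- c(curve$e0, curve$scale, curve$ed50)
  b_num <- vapply(1:3, function(j) {
    h <- 1e-6
    up <- th; up[j] <- up[j] + h
    dn <- th; dn[j] <- dn[j] - h
    cu <- drc("emax", e0 = up[1], scale = up[2], ed50 = up[3])
    cd <- drc("emax", e0 = dn[1], scale = dn[2], ed50 = dn[3])
    (target_dose(cu, 1.3) - target_dose(cd, 1.3)) / (2 * h)
  }, numeric(1))
  expect_lt(max(abs(b_an - b_num)), 1e-4)
})

test_that("efficient rounding matches the exhaustive apportionment oracle", {
  expect_equal(efficient_round(rep(0.2, 5), 150), rep(30L, 5))
  # enumeration oracle: the efficient apportionment maximizes min n_k / w_k
  compositions <- function(N, K) {
    if (K == 1) return(matrix(N, 1))
    out <- NULL
    for (i in 1:(N - K + 1))
      out <- rbind(out, cbind(i, compositions(N - i, K - 1)))
    out
  }
  set.seed(21)
  for (rep in 1:6) {
    K <- sample(2:4, 1); N <- sample(K:12, 1)
    w <- stats::rgamma(K, 2); w <- w / sum(w)
    n <- efficient_round(w, N)
    expect_equal(sum(n), N)
    best <- max(apply(compositions(N, K), 1,
                      function(nn) min(nn / w)))
    expect_equal(min(n / w), best, tolerance = 1e-12)
  }
  # zero-weight doses are excluded from the apportionment
  expect_equal(efficient_round(c(0.5, 0, 0.5), 9), c(5L, 0L, 4L))
})

test_that("model probabilities update toward the generating model", {
  cand <- candidate_set()
  expect_equal(update_model_probs(cand, NULL)$prior, cand$prior)
  # exact Emax data with huge n: the Emax model takes all the mass
  gs <- gs_exact(cand$models$emax, n = rep(2000, 5))
  gs$ss_within <- 0.1 * sum(gs$n)   # tiny noise
  post <- update_model_probs(cand, gs)$prior
  expect_gt(post[2], 0.99)
  expect_equal(sum(post), 1, tolerance = 1e-12)
  # probabilities stay normalized even when likelihoods are extreme
  gs2 <- gs_exact(cand$models$linear, n = rep(5000, 5))
  gs2$ss_within <- 1e-6
  expect_equal(sum(update_model_probs(cand, gs2)$prior), 1, tolerance = 1e-12)
})

test_that("adaptive D-optimal allocation is pulled toward the fixed D-optimal ratios", {
  cfg <- trial_config()
  tab <- scenario_table()
  ma <- mean_allocation(rule_doptimal(adaptive = TRUE), 4, n_sims = 200,
                        config = cfg, seed = 31)
  # D-optimal 1 puts extra subjects on the extreme doses and starves the
  # middle ones relative to equal allocation; the adaptive variant should
  # move in the same direction from its equal start
  expect_gt(ma[1, 1], 32)   # placebo above 30
  expect_gt(ma[1, 5], 32)   # top dose above 30
  expect_lt(ma[1, 3], 28)   # 4 mg below 30
  expect_lt(ma[1, 4], 28)   # 6 mg below 30
  expect_equal(sum(ma[1, ]), 150)
})
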