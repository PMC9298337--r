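test_that("optimal contrasts satisfy the constraints and maximize noncentrality", {
  # equal n, linear means: the centred dose scores
  C <- optimal_contrasts(matrix(0:4, ncol = 1), rep(10, 5))
  expect_equal(drop(C), c(-2, -1, 0, 1, 2) / sqrt(10), tolerance = 1e-12)
  # columns sum to zero and have unit length; scale invariance in n
  cand <- candidate_set()
  C1 <- optimal_contrasts(cand$mu, c(10, 20, 30, 10, 5))
  expect_true(all(abs(colSums(C1)) < 1e-10))
  expect_equal(unname(colSums(C1^2)), rep(1, 3))
  C2 <- optimal_contrasts(cand$mu, 2 * c(10, 20, 30, 10, 5))
  expect_equal(C1, C2, tolerance = 1e-12)
  expect_error(optimal_contrasts(matrix(1, 5, 1), rep(5, 5)), "constant")

  # oracle: no random zero-sum contrast beats the returned one
  set.seed(11)
  nc <- function(cc, mu, n) sum(cc * mu) / sqrt(sum(cc^2 / n))
  for (K in 4:6) {
    mu <- sort(stats::rnorm(K))
    n <- sample(5:40, K, replace = TRUE)
    copt <- drop(optimal_contrasts(matrix(mu, ncol = 1), n))
    Rc <- matrix(stats::rnorm(10000 * K), 10000)
    Rc <- Rc - rowMeans(Rc)
    ncs <- (Rc %*% mu) / sqrt((Rc^2 %*% (1 / n)))
    expect_gte(nc(copt, mu, n), max(abs(ncs)) - 1e-10)
  }
})

test_that("max-T test: degenerate single contrast and extreme signals", {
  grid <- dose_grid()
  one <- candidate_set()
  one$models <- one$models["linear"]; one$prior <- 1
  one$mu <- one$mu[, "linear", drop = FALSE]
  gs <- gs_simulate(drc("flat"), n_per = 30, seed = 2)
  tst <- mct_test(gs, one, alpha = 0.025, compute_crit = TRUE)
  expect_equal(tst$crit, stats::qt(0.975, gs$df), tolerance = 1e-6)

  # a huge clean signal is always detected
  cand <- candidate_set()
  gs2 <- group_summary(rep(30, 5), 100 * cand$mu[, "emax"], 1e-6, grid)
  expect_true(mct_test(gs2, cand)$significant)
  expect_lt(min(mct_test(gs2, cand)$pvalues), 1e-6)

  expect_error(mct_test(group_summary(rep(1, 5), rep(0, 5), 0, grid),
                        cand), "pooled variance")
})

test_that("candidate fits recover noise-free generating parameters", {
  truths <- list(
    linear = drc("linear", e0 = 0.3, scale = 1.65 / 8),
    emax = drc("emax", e0 = -0.2, scale = 1.8131, ed50 = 0.79),
    sigEmax = drc("sigEmax", e0 = 0.1, scale = 1.7016, ed50 = 4, h = 5)
  )
  for (fam in names(truths)) {
    fit <- fit_candidate(gs_exact(truths[[fam]]), fam)
    expect_lt(abs(fit$coefs["e0"] - truths[[fam]]$e0), 1e-4)
    expect_lt(abs(fit$coefs[2] - truths[[fam]]$scale), 1e-4)
    if (fam != "linear")
      expect_lt(abs(fit$coefs["ed50"] - truths[[fam]]$ed50), 1e-4)
    if (fam == "sigEmax")
      expect_lt(abs(fit$coefs["h"] - truths[[fam]]$h), 1e-4)
    expect_lt(fit$rss, 1e-6)
  }
  # on exactly linear data the AIC penalty ranks the simpler model first
  gs <- gs_exact(truths$linear, n = rep(50, 5))
  expect_lt(fit_candidate(gs, "linear")$aic, fit_candidate(gs, "sigEmax")$aic)
})

test_that("model selection follows AIC with deterministic tie-breaks", {
  mk <- function(aic, npar, fam) structure(
    list(family = fam, aic = aic, npar = as.integer(npar)), class = "drc_fit")
  fits <- list(mk(100, 2, "a"), mk(90, 3, "b"), mk(95, 4, "c"))
  expect_equal(select_model(fits)$family, "b")
  expect_equal(select_model(list(mk(50, 2, "only")))$family, "only")
  # equal AIC: fewer parameters wins; then input order
  expect_equal(select_model(list(mk(90, 3, "x"), mk(90, 2, "y")))$family, "y")
  expect_equal(select_model(list(mk(90, 2, "x"), mk(90, 2, "y")))$family, "x")
})

test_that("MAE is a placebo-shift-invariant curve distance", {
  s1 <- scenario_curves(scenario_table())[[1]]
  expect_equal(compute_mae(s1, s1), 0)
  shifted <- s1; shifted$e0 <- s1$e0 + 3.7
  expect_equal(compute_mae(shifted, s1), 0)
  # flat estimate against the linear truth: direct arithmetic
  expect_equal(compute_mae(drc("flat"), s1),
               mean(c(0.4125, 0.825, 1.2375, 1.65)), tolerance = 1e-9)
  # symmetry
  e <- scenario_curves(scenario_table())[[4]]
  expect_equal(compute_mae(e, s1), compute_mae(s1, e), tolerance = 1e-12)
})

test_that("analyze_trial produces a coherent end-of-trial result", {
  tab <- scenario_table()
  s4 <- get_scenario(tab, 4)
  gs <- gs_simulate(s4$curve, n_per = 30, seed = 5)
  an <- analyze_trial(gs, candidate_set(), truth = s4$curve)
  expect_type(an$significant, "logical")
  expect_true(an$selected %in% c("linear", "emax", "sigEmax"))
  expect_gte(an$mae, 0)
  expect_true(is.na(an$d_targ_hat) ||
                (an$d_targ_hat >= 0 && an$d_targ_hat <= 8))
  js <- analysis_to_json(an)
  expect_true(jsonlite::validate(js))

  # with noise-free data from scenario 1 the estimated MED hits the truth
  an0 <- analyze_trial(gs_exact(scenario_curves(tab)[[1]]), candidate_set(),
                       truth = scenario_curves(tab)[[1]])
  expect_lt(abs(an0$d_targ_hat - 6.30), 0.005)
  expect_lt(an0$mae, 1e-4)
})
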