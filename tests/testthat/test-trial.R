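test_that("initialization allocates equally and encodes the state correctly", {
  tab <- scenario_table()
  cfg <- trial_config()
  rng <- doserl:::make_rng(5L)
  st <- initialize_trial(cfg, get_scenario(tab, 1)$curve, rng)
  expect_equal(st$n, rep(10L, 5))
  s <- encode_state(st, cfg)
  expect_length(s, 14)
  expect_equal(unname(s[10:14]), rep(10 / 150, 5))

  # zero noise: means equal the curve, standard deviations are zero
  cfg0 <- trial_config(sigma2 = 0)
  st0 <- initialize_trial(cfg0, get_scenario(tab, 16)$curve,
                          doserl:::make_rng(1L))
  s0 <- encode_state(st0, cfg0)
  expect_equal(unname(s0[1:9]), rep(0, 9))

  # deterministic curve: the first K-1 entries are the placebo differences
  st1 <- initialize_trial(cfg0, get_scenario(tab, 1)$curve,
                          doserl:::make_rng(1L))
  mu <- evaluate_curve(get_scenario(tab, 1)$curve, c(0, 2, 4, 6, 8))
  expect_equal(unname(encode_state(st1, cfg0)[1:4]), mu[-1] - mu[1])

  # encoding requires at least two subjects per dose
  tiny <- doserl:::new_trial_state(cfg)
  doserl:::add_responses(tiny, 1, 0.5)
  expect_error(encode_state(tiny, cfg), "at least 2")
})

test_that("blocks accumulate correctly and every rule conserves subjects", {
  tab <- scenario_table()
  cfg <- trial_config()
  sc <- get_scenario(tab, 4)
  rng <- doserl:::make_rng(9L)
  st <- initialize_trial(cfg, sc$curve, rng)
  apply_block(st, c(10, 0, 0, 0, 0), sc$curve, cfg, rng)
  expect_equal(st$n, c(20L, 10L, 10L, 10L, 10L))
  # streaming summaries equal recomputation from the raw responses
  expect_equal(doserl:::state_means(st),
               vapply(st$responses, mean, numeric(1)))
  expect_equal(doserl:::state_sds(st),
               vapply(st$responses, stats::sd, numeric(1)))
  expect_error(apply_block(st, c(5, 5, 5, 0, 0), sc$curve, cfg, rng),
               "sum|N_block")

  net <- policy_network(14, 5, hidden = 8, seed = 42)
  rules <- list(rule_equal(), rule_doptimal(), rule_tdoptimal(),
                rule_rl(net), rule_fixed(c(50, 25, 25, 25, 25)))
  for (r in rules) {
    rec <- run_trial(r, sc, cfg, seed = 3)
    expect_equal(sum(rec$counts), 150)
    expect_true(all(rec$counts >= 0))
  }
})

test_that("fixed rules produce the published apportionments", {
  tab <- scenario_table()
  cfg <- trial_config()
  sc <- get_scenario(tab, 1)
  expect_equal(run_trial(rule_equal(), sc, cfg, seed = 1)$counts,
               rep(30L, 5))
  expect_equal(run_trial(rule_doptimal(), sc, cfg, seed = 1)$counts,
               c(44L, 30L, 18L, 14L, 44L))
  expect_equal(run_trial(rule_tdoptimal(), sc, cfg, seed = 1)$counts,
               c(46L, 39L, 17L, 27L, 21L))
})

test_that("terminal rewards follow the metric definitions", {
  tab <- scenario_table()
  s4 <- get_scenario(tab, 4)
  s16 <- get_scenario(tab, 16)
  an <- list(significant = TRUE, selected = "emax", d_targ_hat = 2.0,
             mae = 0)
  expect_equal(terminal_reward("power", an, s4), 1)
  expect_equal(terminal_reward("power", an, s16), 0)  # flat: never power
  expect_equal(terminal_reward("MS", an, s4), 1)
  expect_equal(terminal_reward("MS", an, get_scenario(tab, 1)), 0)
  # 2.0 mg sits inside scenario 4's target-dose interval (1.44, 2.95)
  expect_equal(terminal_reward("TD", an, s4), 1)
  an$d_targ_hat <- NA_real_
  expect_equal(terminal_reward("TD", an, s4), 0)
  expect_equal(terminal_reward("MAE", list(mae = 0), s4), 1)
  expect_equal(terminal_reward("MAE", list(mae = 0.5), s4), 0)
})

test_that("trial records are pure functions of (rule, scenario, config, seed)", {
  tab <- scenario_table()
  cfg <- trial_config()
  sc <- get_scenario(tab, 7)
  r1 <- run_trial(rule_equal(), sc, cfg, seed = 11)
  r2 <- run_trial(rule_equal(), sc, cfg, seed = 11)
  expect_identical(r1$metrics, r2$metrics)
  expect_identical(r1$counts, r2$counts)
  r3 <- run_trial(rule_equal(), sc, cfg, seed = 12)
  expect_false(identical(r1$metrics, r3$metrics))

  net <- policy_network(14, 5, hidden = 8, seed = 1)
  a1 <- run_trial(rule_rl(net), sc, cfg, seed = 11)
  a2 <- run_trial(rule_rl(net), sc, cfg, seed = 11)
  expect_identical(a1$counts, a2$counts)
  expect_identical(a1$metrics, a2$metrics)

  js <- record_to_json(r1)
  expect_true(jsonlite::validate(js))
})
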