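#' Trial configuration
#'
#' Defaults follow the reference phase II setting: 150 subjects in total, 50
#' allocated equally at start, ten blocks of ten, Gaussian noise with
#' variance 4.5, clinically relevant effect 1.3 and a one-sided 0.025-level
#' test.
#'
#' @param N total number of subjects.
#' @param N_ini subjects allocated equally at trial start (divisible by K).
#' @param N_block subjects per adaptive block ((N - N_ini) divisible by it).
#' @param sigma2 observation noise variance (response units squared).
#' @param delta clinically relevant effect.
#' @param alpha one-sided significance level.
#' @param eta relative band of the target-dose interval.
#' @param metric performance metric to optimize: `"power"`, `"MS"`, `"TD"`
#'   or `"MAE"`.
#' @param grid a [dose_grid].
#' @param cand a [candidate_set] used for testing, fitting and design.
#' @return object of class `trial_config`; `B` is the number of blocks.
#' @export
trial_config <- function(N = 150, N_ini = 50, N_block = 10, sigma2 = 4.5,
                         delta = 1.3, alpha = 0.025, eta = 0.1,
                         metric = c("MAE", "power", "MS", "TD"),
                         grid = dose_grid(), cand = candidate_set(grid)) {
  metric <- match.arg(metric)
  K <- length(grid)
  if (N_ini %% K != 0) stop("N_ini must be divisible by the number of doses")
  if ((N - N_ini) %% N_block != 0)
    stop("N - N_ini must be divisible by N_block")
  structure(list(N = N, N_ini = N_ini, N_block = N_block,
                 B = (N - N_ini) %/% N_block, sigma2 = sigma2, delta = delta,
                 alpha = alpha, eta = eta, metric = metric, grid = grid,
                 cand = cand, K = K),
            class = "trial_config")
}

# --- independent RNG substreams (L'Ecuyer-CMRG) -------------------------
# one master seed per trial spawns independent streams for scenario
# selection, response noise and allocation sampling

make_rng <- function(seed, names = c("scenario", "noise", "alloc")) {
  env <- new.env(parent = emptyenv())
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed, kind = "L'Ecuyer-CMRG")
  s <- get(".Random.seed", envir = globalenv())
  for (nm in names) {
    env[[nm]] <- s
    s <- parallel::nextRNGStream(s)
  }
  if (had) assign(".Random.seed", old, envir = globalenv())
  else rm(".Random.seed", envir = globalenv())
  env
}

with_stream <- function(rng, name, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  assign(".Random.seed", rng[[name]], envir = globalenv())
  on.exit({
    rng[[name]] <- get(".Random.seed", envir = globalenv())
    if (had) assign(".Random.seed", old, envir = globalenv())
    else rm(".Random.seed", envir = globalenv())
  })
  expr
}

# --- trial state ---------------------------------------------------------

new_trial_state <- function(config) {
  K <- config$K
  env <- new.env(parent = emptyenv())
  env$n <- integer(K)
  env$sum <- numeric(K)
  env$sumsq <- numeric(K)
  env$responses <- vector("list", K)  # raw responses, kept for the record
  env
}

state_means <- function(state) ifelse(state$n > 0, state$sum / pmax(state$n, 1), 0)

state_within_ss <- function(state) {
  pmax(state$sumsq - state$sum^2 / pmax(state$n, 1), 0)
}

state_sds <- function(state) {
  ss <- state_within_ss(state)
  ifelse(state$n >= 2, sqrt(ss / pmax(state$n - 1, 1)), NA_real_)
}

#' Group summary of a trial state
#'
#' @param state a trial state (from [initialize_trial()] / [apply_block()]).
#' @param config a [trial_config].
#' @return a [group_summary].
#' @export
state_summary <- function(state, config) {
  group_summary(state$n, state_means(state), sum(state_within_ss(state)),
                config$grid)
}

add_responses <- function(state, k, y) {
  state$n[k] <- state$n[k] + length(y)
  state$sum[k] <- state$sum[k] + sum(y)
  state$sumsq[k] <- state$sumsq[k] + sum(y^2)
  state$responses[[k]] <- c(state$responses[[k]], y)
  invisible(state)
}

#' Initialize a trial
#'
#' Allocates `N_ini` subjects equally over the doses and draws their
#' responses `Normal(mu(d_k), sigma2)`.
#'
#' @param config a [trial_config].
#' @param curve the true [drc].
#' @param rng RNG stream set (internal; created by [run_trial()]).
#' @return a trial state environment.
#' @export
initialize_trial <- function(config, curve, rng) {
  state <- new_trial_state(config)
  per <- config$N_ini %/% config$K
  mu <- evaluate_curve(curve, as.numeric(config$grid))
  with_stream(rng, "noise", {
    for (k in seq_len(config$K))
      add_responses(state, k, stats::rnorm(per, mu[k], sqrt(config$sigma2)))
  })
  state
}

#' Encode the MDP state vector
#'
#' `s = (Ybar_2 - Ybar_1, ..., Ybar_K - Ybar_1, sd_1, ..., sd_K,
#' n_1/N, ..., n_K/N)`, a vector of length 3K - 1.
#'
#' @param state a trial state.
#' @param config a [trial_config].
#' @return numeric vector of length `3K - 1`.
#' @export
encode_state <- function(state, config) {
  if (any(state$n < 2)) stop("state encoding requires at least 2 subjects per dose")
  ybar <- state_means(state)
  c(ybar[-1] - ybar[1], state_sds(state), state$n / config$N)
}

#' Apply one block of allocations
#'
#' @param state a trial state (modified in place and returned).
#' @param allocation per-dose counts summing to `N_block`.
#' @param curve the true [drc].
#' @param config a [trial_config].
#' @param rng RNG stream set.
#' @return the updated trial state.
#' @export
apply_block <- function(state, allocation, curve, config, rng) {
  stopifnot(length(allocation) == config$K, all(allocation >= 0),
            sum(allocation) == config$N_block)
  if (sum(state$n) + config$N_block > config$N) stop("over-allocation")
  mu <- evaluate_curve(curve, as.numeric(config$grid))
  with_stream(rng, "noise", {
    for (k in which(allocation > 0))
      add_responses(state, k,
                    stats::rnorm(allocation[k], mu[k], sqrt(config$sigma2)))
  })
  state
}

#' Terminal reward of a trial
#'
#' `r_power = 1` if the test is significant and the true curve is nonflat;
#' `r_MS = 1` if the selected family equals the true family; `r_TD = 1` if
#' the estimated target dose falls in the true target-dose interval
#' (undefined estimates score 0); `r_MAE = 1 - 2 MAE`.
#'
#' @param metric one of `"power"`, `"MS"`, `"TD"`, `"MAE"`.
#' @param analysis a `trial_analysis` (with `mae` computed for `"MAE"`).
#' @param scenario a scenario row (see [get_scenario()]).
#' @return scalar reward, approximately in \[0, 1\].
#' @export
terminal_reward <- function(metric, analysis, scenario) {
  switch(metric,
    power = as.numeric(analysis$significant && scenario$family != "flat"),
    MS    = as.numeric(identical(analysis$selected, scenario$family)),
    TD    = {
      d <- analysis$d_targ_hat
      as.numeric(!is.na(d) && !is.na(scenario$lower) &&
                   d >= scenario$lower && d <= scenario$upper)
    },
    MAE   = 1 - 2 * analysis$mae,
    stop("unknown metric: ", metric)
  )
}

#' Extract one scenario from the scenario table
#'
#' @param table output of [scenario_table()].
#' @param id scenario number (1..16).
#' @return list with `id`, `family`, `curve`, `max_effect`, `d_targ`,
#'   `lower`, `upper`.
#' @export
get_scenario <- function(table, id) {
  row <- table[table$id == id, ]
  if (nrow(row) != 1) stop("unknown scenario id: ", id)
  list(id = id, family = row$family, curve = scenario_curves(table)[[id]],
       max_effect = row$max_effect, d_targ = row$d_targ,
       lower = row$lower, upper = row$upper)
}

# all four metrics from one analysis
all_metrics <- function(analysis, scenario) {
  c(power = terminal_reward("power", analysis, scenario),
    MS = terminal_reward("MS", analysis, scenario),
    TD = terminal_reward("TD", analysis, scenario),
    MAE = analysis$mae)
}

#' Run one simulated trial
#'
#' Fixed rules allocate all `N` subjects up front; adaptive rules run the
#' equal initial allocation followed by `B` policy-driven blocks. The
#' end-of-trial MCP-Mod analysis and all four metrics are computed. Records
#' are a pure function of (rule, scenario, config, seed).
#'
#' @param rule an allocation rule (see [rule_equal()] and friends).
#' @param scenario a scenario (from [get_scenario()]).
#' @param config a [trial_config].
#' @param seed integer master seed for this trial.
#' @return object of class `trial_record`: `scenario`, `counts`,
#'   `analysis`, `metrics` (all four), `reward` (for `config$metric`),
#'   `seed`.
#' @export
run_trial <- function(rule, scenario, config = trial_config(), seed = 1L) {
  rng <- make_rng(seed)
  state <- new_trial_state(config)
  if (rule$kind == "fixed") {
    counts <- rule$counts(config)
    stopifnot(sum(counts) == config$N)
    mu <- evaluate_curve(scenario$curve, as.numeric(config$grid))
    with_stream(rng, "noise", {
      for (k in which(counts > 0))
        add_responses(state, k,
                      stats::rnorm(counts[k], mu[k], sqrt(config$sigma2)))
    })
  } else {
    state <- initialize_trial(config, scenario$curve, rng)
    rstate <- rule$init(config)
    for (b in seq_len(config$B)) {
      alloc <- rule$block(rstate, state, config, rng)
      apply_block(state, alloc, scenario$curve, config, rng)
    }
  }
  gs <- state_summary(state, config)
  analysis <- analyze_trial(gs, config$cand, alpha = config$alpha,
                            delta = config$delta, truth = scenario$curve)
  metrics <- all_metrics(analysis, scenario)
  structure(list(scenario = scenario$id, counts = state$n,
                 analysis = analysis, metrics = metrics,
                 reward = terminal_reward(config$metric, analysis, scenario),
                 seed = seed),
            class = "trial_record")
}

#' Serialize a trial record to one JSON line
#'
#' @param record a `trial_record`.
#' @return JSON string.
#' @export
record_to_json <- function(record) {
  jsonlite::toJSON(list(
    scenario = record$scenario, counts = record$counts,
    metrics = as.list(record$metrics), reward = record$reward,
    seed = record$seed, significant = record$analysis$significant,
    selected = record$analysis$selected,
    d_targ_hat = record$analysis$d_targ_hat
  ), auto_unbox = TRUE, digits = NA, na = "null")
}
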