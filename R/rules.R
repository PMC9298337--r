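#' Allocation rules
#'
#' An allocation rule is either *fixed* — the full-trial per-dose counts are
#' set before the first subject — or *adaptive* — the equal initial
#' allocation is followed by blockwise decisions from the interim data.
#'
#' * `rule_equal()`: equal split of all `N` subjects.
#' * `rule_fixed(counts)`: any prespecified apportionment.
#' * `rule_doptimal(adaptive = FALSE)`: model-averaged D-optimal weights,
#'   efficiently rounded. The adaptive variant re-optimizes each block given
#'   the subjects already allocated, with model probabilities re-weighted
#'   from the interim data.
#' * `rule_tdoptimal(adaptive = FALSE)`: same with the TD-criterion.
#' * `rule_rl(policy)`: a trained policy network; each block's subjects are
#'   drawn i.i.d. from pi(k | s) (`mode = "sample"`) or apportioned by
#'   efficient rounding of pi (`mode = "round"`).
#'
#' @param counts per-dose counts summing to the trial's `N`.
#' @param adaptive re-optimize every block instead of once up front.
#' @param delta clinically relevant effect for the TD-criterion.
#' @param policy a trained policy (see [train_policy()]) or a bare policy
#'   network.
#' @param mode `"sample"` or `"round"` deployment of the policy
#'   probabilities.
#' @return an object of class `alloc_rule`.
#' @name alloc_rules
NULL

new_rule <- function(kind, name, ...) {
  structure(c(list(kind = kind, name = name), list(...)), class = "alloc_rule")
}

#' @rdname alloc_rules
#' @export
rule_equal <- function() {
  new_rule("fixed", "equal", counts = function(config) {
    if (config$N %% config$K != 0) stop("N not divisible by K")
    rep(config$N %/% config$K, config$K)
  })
}

#' @rdname alloc_rules
#' @export
rule_fixed <- function(counts) {
  force(counts)
  new_rule("fixed", "fixed", counts = function(config) {
    stopifnot(length(counts) == config$K, sum(counts) == config$N)
    as.integer(counts)
  })
}

# one-off optimal design, cached per config
fixed_design_counts <- function(criterion) {
  cache <- new.env(parent = emptyenv())
  function(config) {
    key <- paste0(criterion, config$N, config$delta)
    if (is.null(cache[[key]])) {
      opt <- optimize_design(config$cand, criterion, delta = config$delta)
      cache[[key]] <- efficient_round(opt$w, config$N)
    }
    cache[[key]]
  }
}

adaptive_design_rule <- function(criterion, name) {
  new_rule("adaptive", name,
    init = function(config) new.env(parent = emptyenv()),
    block = function(rstate, state, config, rng) {
      cand <- update_model_probs(config$cand, state_summary(state, config))
      opt <- optimize_design(cand, criterion, delta = config$delta,
                             n_old = state$n, n_new = config$N_block,
                             n_restarts = 1, z0 = rstate$z,
                             maxit = 150, reltol = 1e-8)
      rstate$z <- opt$z
      efficient_round(opt$w, config$N_block)
    })
}

#' @rdname alloc_rules
#' @export
rule_doptimal <- function(adaptive = FALSE) {
  if (!adaptive)
    new_rule("fixed", "d_optimal", counts = fixed_design_counts("D"))
  else adaptive_design_rule("D", "d_optimal_adaptive")
}

#' @rdname alloc_rules
#' @export
rule_tdoptimal <- function(adaptive = FALSE, delta = 1.3) {
  if (!adaptive)
    new_rule("fixed", "td_optimal", counts = fixed_design_counts("TD"))
  else adaptive_design_rule("TD", "td_optimal_adaptive")
}

#' @rdname alloc_rules
#' @export
rule_rl <- function(policy, mode = c("sample", "round")) {
  mode <- match.arg(mode)
  net <- if (inherits(policy, "rl_policy")) policy$net else policy
  new_rule("adaptive", "rl",
    init = function(config) new.env(parent = emptyenv()),
    block = function(rstate, state, config, rng) {
      s <- encode_state(state, config)
      deploy_policy(net, s, config$N_block, rng = rng, mode = mode)
    })
}

#' @export
print.alloc_rule <- function(x, ...) {
  cat(sprintf("<alloc_rule> %s (%s)\n", x$name, x$kind))
  invisible(x)
}
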