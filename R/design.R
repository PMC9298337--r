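#' Gradient of the mean response in the model parameters
#'
#' Analytic gradient of mu(d; theta) at the curve's own parameters, in the
#' parameter order used throughout the design criteria: linear (e0, slope),
#' Emax (e0, scale, ED50), sigmoid Emax (e0, scale, ED50, h). Homoscedastic
#' Gaussian observations make the per-subject Fisher information the outer
#' product of this gradient (up to the constant 1/sigma^2, which cancels in
#' the criteria).
#'
#' @param curve a [drc] of a supported family.
#' @param d numeric vector of doses.
#' @return length(d) x k matrix of gradients (rows = doses).
#' @export
model_gradient <- function(curve, d) {
  switch(curve$family,
    linear = cbind(1, d),
    emax = {
      ed <- curve$ed50
      cbind(1, d / (ed + d), -curve$scale * d / (ed + d)^2)
    },
    sigEmax = {
      ed <- curve$ed50; h <- curve$h
      den <- (ed^h + d^h)^2
      dh <- ifelse(d == 0, 0,
                   curve$scale * d^h * ed^h * (log(pmax(d, 1e-300)) - log(ed)) / den)
      cbind(1, d^h / (ed^h + d^h),
            -curve$scale * d^h * h * ed^(h - 1) / den,
            dh)
    },
    stop("no design gradient for family: ", curve$family)
  )
}

#' Normalized Fisher information of a design
#'
#' `M = sum_k w_k g(d_k) g(d_k)'` with unit-variance normalization.
#'
#' @param curve a [drc].
#' @param w design weights on the grid (simplex vector).
#' @param grid a [dose_grid].
#' @return k x k symmetric matrix.
#' @export
fisher_information <- function(curve, w, grid = dose_grid()) {
  stopifnot(length(w) == length(grid), all(w >= -1e-12))
  G <- model_gradient(curve, as.numeric(grid))
  crossprod(G * sqrt(pmax(w, 0)))
}

# build a fast criterion closure: the per-model gradient matrices (and, for
# the TD criterion, the target-dose gradients) do not depend on the weights
# and are computed once
make_design_objective <- function(cand, criterion, delta = 1.3) {
  Gs <- lapply(cand$models, model_gradient, d = as.numeric(cand$grid))
  p <- cand$prior; k <- cand$kpar
  if (criterion == "D") {
    function(w) {
      val <- 0
      for (m in seq_along(Gs)) {
        M <- crossprod(Gs[[m]] * sqrt(pmax(w, 0)))
        dt <- determinant(M, logarithm = TRUE)
        if (dt$sign <= 0 || !is.finite(dt$modulus)) return(Inf)
        val <- val - p[m] / k[m] * as.numeric(dt$modulus)
      }
      val
    }
  } else {
    bs <- lapply(cand$models, function(cv)
      td_theta_gradient(cv, delta, cand$grid)$b)
    function(w) {
      val <- 0
      for (m in seq_along(Gs)) {
        M <- crossprod(Gs[[m]] * sqrt(pmax(w, 0)))
        b <- bs[[m]]
        # fast path: nonsingular information; generalized inverse otherwise
        x <- tryCatch(solve(M, b), error = function(e) NULL)
        if (is.null(x)) {
          Minv <- ginv_sym(M)
          if (is.null(Minv)) return(Inf)
          x <- Minv %*% b
          if (max(abs(M %*% x - b)) > 1e-6 * max(1, max(abs(b))))
            return(Inf)
        }
        v <- drop(crossprod(b, x))
        if (!is.finite(v) || v <= 0) return(Inf)
        val <- val + p[m] * log(v)
      }
      val
    }
  }
}

#' Model-averaged D-optimality objective
#'
#' `-sum_m (p_m / k_m) log det M_m(w)`; lower is better. Per-parameter
#' normalization makes models of different dimension commensurable. A design
#' that leaves any candidate's information singular scores `+Inf`.
#'
#' @param w design weights (simplex vector over the grid).
#' @param cand a [candidate_set].
#' @return scalar objective value.
#' @export
d_objective <- function(w, cand) make_design_objective(cand, "D")(w)

# gradient of the target dose in theta by implicit differentiation of
# mu(d; theta) - mu(0; theta) = delta; the sign is irrelevant to the
# quadratic form v = b' M^- b
td_theta_gradient <- function(curve, delta, grid = dose_grid()) {
  dt <- target_dose(curve, delta, grid)
  if (is.na(dt)) stop("target dose does not exist for this model")
  gtheta <- model_gradient(curve, dt) - model_gradient(curve, 0)
  dmu <- mu_prime(curve, dt)
  list(d_targ = dt, b = -as.numeric(gtheta) / dmu)
}

ginv_sym <- function(M, tol = 1e-10) {
  eg <- eigen(M, symmetric = TRUE)
  pos <- eg$values > tol * max(eg$values, 0)
  if (!any(pos)) return(NULL)
  V <- eg$vectors[, pos, drop = FALSE]
  V %*% (t(V) / eg$values[pos])
}

#' Asymptotic target-dose variance under one model
#'
#' `v = b' M(w)^- b` where `b` is the gradient of the target dose in the
#' model parameters (implicit differentiation) and `M^-` a generalized
#' inverse (eigendecomposition, 1e-10 relative cutoff). Returns `Inf` when
#' the target dose is not estimable under the design (b outside the range
#' of M).
#'
#' @param curve a [drc].
#' @param w design weights.
#' @param delta clinically relevant effect.
#' @param grid a [dose_grid].
#' @return scalar, possibly `Inf`.
#' @export
td_variance <- function(curve, w, delta, grid = dose_grid()) {
  b <- td_theta_gradient(curve, delta, grid)$b
  M <- fisher_information(curve, w, grid)
  Minv <- ginv_sym(M)
  if (is.null(Minv)) return(Inf)
  proj <- M %*% (Minv %*% b)
  if (max(abs(proj - b)) > 1e-6 * max(1, max(abs(b)))) return(Inf)
  drop(t(b) %*% Minv %*% b)
}

#' Model-averaged TD-optimality objective
#'
#' `sum_m p_m log v_m(w)`; lower is better.
#'
#' @inheritParams d_objective
#' @param delta clinically relevant effect.
#' @return scalar objective value.
#' @export
td_objective <- function(w, cand, delta = 1.3) {
  make_design_objective(cand, "TD", delta)(w)
}

softmax <- function(z) { e <- exp(z - max(z)); e / sum(e) }

#' Optimize a design criterion over the simplex
#'
#' Minimizes the D- or TD-criterion over allocation weights via a softmax
#' reparameterization and BFGS with seeded random restarts. In the adaptive
#' (constrained) mode the next block's weights `u` are optimized while the
#' already-allocated counts stay fixed: the criterion is evaluated at the
#' effective weights `(n_old + n_new u) / (sum(n_old) + n_new)`.
#'
#' @param cand a [candidate_set] (its `prior` carries the current model
#'   probabilities).
#' @param criterion `"D"` or `"TD"`.
#' @param delta clinically relevant effect (TD criterion).
#' @param n_old per-dose counts already allocated (adaptive mode), or `NULL`.
#' @param n_new number of subjects in the next block (adaptive mode).
#' @param n_restarts number of random restarts.
#' @param seed seed for the restart draws.
#' @param z0 optional warm-start logits (softmax parameters).
#' @param maxit,reltol optimizer budget and relative objective tolerance.
#' @return list with `w` (the optimized weights: full-trial weights in
#'   unconstrained mode, block weights `u` in adaptive mode), `value`
#'   (criterion at the optimum) and `effective` (effective full-trial
#'   weights).
#' @export
optimize_design <- function(cand, criterion = c("D", "TD"), delta = 1.3,
                            n_old = NULL, n_new = NULL, n_restarts = 20,
                            seed = 20201L, z0 = NULL, maxit = 500,
                            reltol = 1e-12) {
  criterion <- match.arg(criterion)
  obj_w <- make_design_objective(cand, criterion, delta)
  K <- length(cand$grid)
  constrained <- !is.null(n_old)
  if (constrained) {
    stopifnot(length(n_old) == K, !is.null(n_new), n_new >= 1)
    eff <- function(u) (n_old + n_new * u) / (sum(n_old) + n_new)
  } else eff <- identity
  f <- function(z) {
    v <- obj_w(eff(softmax(z)))
    if (!is.finite(v)) 1e10 else v
  }
  best <- NULL
  starts <- with_fixed_seed(
    replicate(max(n_restarts - 1, 0), stats::rnorm(K), simplify = FALSE),
    seed = seed)
  starts <- c(list(if (is.null(z0)) rep(0, K) else z0), starts)
  for (zs in starts) {
    op <- tryCatch(stats::optim(zs, f, method = "BFGS",
                                control = list(maxit = maxit, reltol = reltol)),
                   error = function(e) NULL)
    if (!is.null(op) && (is.null(best) || op$value < best$value)) best <- op
  }
  if (is.null(best)) stop("design optimization failed from every start")
  u <- softmax(best$par)
  list(w = u, value = best$value, effective = eff(u), z = best$par)
}

#' Efficient (Pukelsheim-Rieder) rounding
#'
#' Apportions `N` subjects to the support of the design weights: start from
#' `n_k = ceiling((N - S/2) w_k)` over the S support points, then decrement
#' the dose maximizing `(n_k - 1) / w_k` (or increment the dose minimizing
#' `n_k / w_k`) until the counts sum to `N`. The result maximizes
#' `min_k n_k / w_k` among all apportionments of `N`. Ties break at the
#' lowest dose index. Zero-weight doses receive zero subjects.
#'
#' @param w design weights (simplex vector).
#' @param N total number of subjects.
#' @return integer vector of per-dose counts summing to `N`.
#' @export
efficient_round <- function(w, N) {
  stopifnot(all(w >= 0), abs(sum(w) - 1) < 1e-6, N >= 1)
  idx <- which(w > 0)
  S <- length(idx)
  n <- integer(length(w))
  n[idx] <- as.integer(ceiling((N - S / 2) * w[idx] - 1e-12))
  while (sum(n) != N) {
    if (sum(n) > N) {
      j <- idx[which.max((n[idx] - 1) / w[idx])]
      n[j] <- n[j] - 1L
    } else {
      j <- idx[which.min(n[idx] / w[idx])]
      n[j] <- n[j] + 1L
    }
  }
  n
}

#' Update model probabilities from interim data
#'
#' Posterior-style reweighting of the candidate model probabilities: each
#' prior is multiplied by the maximized Gaussian likelihood of the interim
#' data under that model with only the placebo response and scale free (the
#' shape parameters stay fixed at their candidate values; the residual
#' variance is profiled out), then normalized in log space.
#'
#' @param cand a [candidate_set] whose `prior` holds the current
#'   probabilities.
#' @param gs a [group_summary] of the data so far (or `NULL` for no data).
#' @return a [candidate_set] with updated `prior`.
#' @export
update_model_probs <- function(cand, gs) {
  if (is.null(gs) || sum(gs$n) == 0) return(cand)
  d <- as.numeric(cand$grid)
  ntot <- sum(gs$n)
  loglik <- vapply(cand$models, function(cv) {
    f0 <- switch(cv$family,
      linear  = d,
      emax    = d / (cv$ed50 + d),
      sigEmax = d^cv$h / (cv$ed50^cv$h + d^cv$h),
      stop("unsupported candidate family"))
    rss <- profile_rss(gs, f0)$rss
    -ntot / 2 * log(max(rss, 1e-300) / ntot)
  }, numeric(1))
  lp <- log(cand$prior) + loglik
  lp <- lp - max(lp)
  cand$prior <- exp(lp) / sum(exp(lp))
  cand
}
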