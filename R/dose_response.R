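#' Dose grid
#'
#' An ordered set of dose amounts with the placebo dose first. The default is
#' the five-arm grid 0, 2, 4, 6, 8 mg used throughout the package.
#'
#' @param doses numeric vector of dose amounts (mg), strictly increasing,
#'   first element exactly 0 (placebo).
#' @return an object of class `dose_grid` (a numeric vector with class).
#' @export
dose_grid <- function(doses = c(0, 2, 4, 6, 8)) {
  doses <- as.numeric(doses)
  if (length(doses) < 2) stop("need at least two doses")
  if (doses[1] != 0) stop("first dose must be placebo (0)")
  if (any(diff(doses) <= 0)) stop("doses must be strictly increasing")
  structure(doses, class = "dose_grid")
}

#' Dose-response curve
#'
#' Constructs a parametric mean-response function mu(d). Six families are
#' supported; `scale` is the coefficient multiplying the standardized shape,
#' so that `mu(0) = e0` for every family:
#' \describe{
#'   \item{linear}{`e0 + scale * d`}
#'   \item{emax}{`e0 + scale * d / (ed50 + d)`}
#'   \item{sigEmax}{`e0 + scale * d^h / (ed50^h + d^h)`}
#'   \item{quadratic}{`e0 + scale * d - scale/(2*vertex) * d^2` (vertex =
#'     dose of maximum response)}
#'   \item{exponential}{`e0 + scale * (exp(d / rate) - 1)`}
#'   \item{flat}{`e0`}
#' }
#'
#' @param family one of `"linear"`, `"emax"`, `"sigEmax"`, `"quadratic"`,
#'   `"exponential"`, `"flat"`.
#' @param e0 placebo response.
#' @param scale slope/asymptote coefficient (response units).
#' @param ed50 dose giving half the asymptotic effect (emax, sigEmax).
#' @param h Hill exponent (sigEmax).
#' @param vertex dose at which the quadratic attains its maximum.
#' @param rate dose scale of the exponential rise.
#' @return an object of class `drc`.
#' @export
drc <- function(family, e0 = 0, scale = 1, ed50 = NULL, h = NULL,
                vertex = NULL, rate = 1) {
  family <- match.arg(family, c("linear", "emax", "sigEmax", "quadratic",
                                "exponential", "flat"))
  if (family %in% c("emax", "sigEmax")) {
    if (is.null(ed50) || ed50 <= 0) stop("ed50 must be positive")
  }
  if (family == "sigEmax") {
    if (is.null(h) || h <= 0) stop("Hill exponent h must be positive")
  }
  if (family == "quadratic") {
    if (is.null(vertex) || vertex <= 0) stop("vertex must be positive")
  }
  if (family == "exponential" && rate <= 0) stop("rate must be positive")
  structure(list(family = family, e0 = e0, scale = scale, ed50 = ed50,
                 h = h, vertex = vertex, rate = rate),
            class = "drc")
}

#' Evaluate a dose-response curve
#'
#' @param curve a [drc] object.
#' @param d numeric vector of doses.
#' @return mu(d), vectorized over `d`.
#' @export
evaluate_curve <- function(curve, d) {
  stopifnot(inherits(curve, "drc"))
  switch(curve$family,
    linear      = curve$e0 + curve$scale * d,
    emax        = curve$e0 + curve$scale * d / (curve$ed50 + d),
    sigEmax     = curve$e0 + curve$scale * d^curve$h /
                    (curve$ed50^curve$h + d^curve$h),
    quadratic   = curve$e0 + curve$scale * d -
                    curve$scale / (2 * curve$vertex) * d^2,
    exponential = curve$e0 + curve$scale * (exp(d / curve$rate) - 1),
    flat        = rep(curve$e0, length(d)),
    stop("unknown family: ", curve$family)
  )
}

#' @export
predict.drc <- function(object, d, ...) evaluate_curve(object, d)

#' @export
print.drc <- function(x, ...) {
  shp <- c(ed50 = x$ed50, h = x$h, vertex = x$vertex,
           rate = if (x$family == "exponential") x$rate else NULL)
  cat(sprintf("<drc> %s  e0=%.4g scale=%.6g%s\n", x$family, x$e0, x$scale,
              if (length(shp)) paste0("  ", paste(names(shp), signif(shp, 6),
                                                  sep = "=", collapse = " "))
              else ""))
  invisible(x)
}

# derivative d mu / d dose, used for implicit differentiation of the MED
mu_prime <- function(curve, d) {
  switch(curve$family,
    linear      = rep(curve$scale, length(d)),
    emax        = curve$scale * curve$ed50 / (curve$ed50 + d)^2,
    sigEmax     = {
      h <- curve$h; ed <- curve$ed50
      curve$scale * h * ed^h * d^(h - 1) / (ed^h + d^h)^2
    },
    quadratic   = curve$scale - curve$scale / curve$vertex * d,
    exponential = curve$scale / curve$rate * exp(d / curve$rate),
    flat        = rep(0, length(d))
  )
}

# dose at which the effect mu(d) - mu(0) is largest on [0, d_K]
peak_dose <- function(curve, grid) {
  dK <- max(grid)
  if (curve$family == "quadratic") min(curve$vertex, dK) else dK
}

#' Calibrate a curve to a maximum effect
#'
#' Solves for `scale` so that the maximum of mu(d) - mu(0) over the dose
#' range equals `max_effect` exactly. For the monotone families the maximum
#' sits at the top dose; for the quadratic it sits at the (interior) vertex.
#' The returned parameters are kept at full precision.
#'
#' @param family curve family (see [drc]).
#' @param max_effect target maximum effect over the dose range (>= 0).
#' @param grid a [dose_grid].
#' @param e0 placebo response.
#' @inheritParams drc
#' @return a calibrated [drc].
#' @export
calibrate_curve <- function(family, max_effect, grid = dose_grid(), e0 = 0,
                            ed50 = NULL, h = NULL, vertex = NULL, rate = 1) {
  if (max_effect < 0) stop("max_effect must be nonnegative")
  if (family == "flat") {
    if (max_effect != 0) stop("flat family cannot attain a nonzero effect")
    return(drc("flat", e0 = e0, scale = 0))
  }
  cv <- drc(family, e0 = e0, scale = 1, ed50 = ed50, h = h,
            vertex = vertex, rate = rate)
  dstar <- peak_dose(cv, grid)
  unit_eff <- evaluate_curve(cv, dstar) - e0
  if (unit_eff <= 0) stop("degenerate shape: no positive effect in range")
  cv$scale <- max_effect / unit_eff
  cv
}

#' Continuous target dose (minimum effective dose)
#'
#' The smallest dose in the range whose effect over placebo reaches the
#' clinically relevant effect `delta`:
#' `d_targ = argmin_{d in [d1, dK]} { mu(d) >= mu(d1) + delta }`.
#' Solved by bisection on the ascending branch to 1e-12 mg; returns `NA` when
#' no dose in range attains the effect.
#'
#' @param curve a [drc].
#' @param delta clinically relevant effect (> 0), response units.
#' @param grid a [dose_grid].
#' @return target dose (mg) or `NA_real_`.
#' @export
target_dose <- function(curve, delta, grid = dose_grid()) {
  stopifnot(delta > 0)
  if (curve$family == "flat") return(NA_real_)
  e0 <- evaluate_curve(curve, 0)
  hi <- peak_dose(curve, grid)
  g <- function(d) evaluate_curve(curve, d) - e0 - delta
  if (g(hi) < 0) return(NA_real_)
  lo <- 0
  if (g(lo) >= 0) return(lo)
  # all families are strictly increasing on [0, peak]: plain bisection
  while (hi - lo > 1e-12) {
    mid <- (lo + hi) / 2
    if (g(mid) >= 0) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

#' Target-dose interval
#'
#' Doses whose effects bracket the target effect band `delta * (1 +/- eta)`.
#' A missing upper end, or one beyond the top dose, is clipped to the top
#' dose; the interval is undefined (`NA`s) when even the lower target effect
#' is not reached in range.
#'
#' @inheritParams target_dose
#' @param eta half-width of the relative effect band, in (0, 1).
#' @return named numeric `c(lower=, upper=)`, possibly `NA`.
#' @export
target_dose_interval <- function(curve, delta, eta = 0.1, grid = dose_grid()) {
  stopifnot(eta > 0, eta < 1)
  lower <- target_dose(curve, delta * (1 - eta), grid)
  if (is.na(lower)) return(c(lower = NA_real_, upper = NA_real_))
  upper <- target_dose(curve, delta * (1 + eta), grid)
  if (is.na(upper)) upper <- max(grid)
  c(lower = lower, upper = min(upper, max(grid)))
}

# family + shape parameters of the 16 simulation scenarios; the effect
# multiplier column scales the reference maximum effect (1 / 0.8 / 1.2)
scenario_specs <- function() {
  fam <- c(rep("linear", 3), rep("emax", 3), rep("sigEmax", 3),
           rep("quadratic", 3), rep("exponential", 3), "flat")
  mult <- c(rep(c(1, 0.8, 1.2), 5), 0)
  list(family = fam, mult = mult)
}

#' The dose-response scenario table
#'
#' Builds the 16 simulation scenarios: linear, Emax (ED50 = 0.79),
#' sigmoid Emax (ED50 = 4, h = 5), quadratic (vertex at 6 mg) and
#' exponential (unit rate) families, each at maximum effects `max_effect`
#' times 1, 0.8 and 1.2, plus a flat scenario. Target doses and target-dose
#' intervals are computed from the calibrated full-precision curves.
#'
#' @param grid a [dose_grid].
#' @param delta clinically relevant effect.
#' @param eta relative band for the target-dose interval.
#' @param max_effect reference maximum effect over the dose range.
#' @return a `data.frame` with columns `id`, `family`, `max_effect`,
#'   `d_targ`, `lower`, `upper`, and the calibrated curves in the
#'   `"curves"` attribute (a list of [drc]).
#' @export
scenario_table <- function(grid = dose_grid(), delta = 1.3, eta = 0.1,
                           max_effect = 1.65) {
  sp <- scenario_specs()
  curves <- vector("list", 16)
  for (i in seq_len(16)) {
    curves[[i]] <- switch(sp$family[i],
      linear      = calibrate_curve("linear", max_effect * sp$mult[i], grid),
      emax        = calibrate_curve("emax", max_effect * sp$mult[i], grid,
                                    ed50 = 0.79),
      sigEmax     = calibrate_curve("sigEmax", max_effect * sp$mult[i], grid,
                                    ed50 = 4, h = 5),
      quadratic   = calibrate_curve("quadratic", max_effect * sp$mult[i],
                                    grid, vertex = 6),
      exponential = calibrate_curve("exponential", max_effect * sp$mult[i],
                                    grid, rate = 1),
      flat        = calibrate_curve("flat", 0, grid)
    )
  }
  dt <- vapply(curves, target_dose, numeric(1), delta = delta, grid = grid)
  iv <- t(vapply(curves, target_dose_interval, numeric(2), delta = delta,
                 eta = eta, grid = grid))
  out <- data.frame(id = seq_len(16), family = sp$family,
                    max_effect = max_effect * sp$mult,
                    d_targ = dt, lower = iv[, 1], upper = iv[, 2])
  attr(out, "curves") <- curves
  out
}

#' Curves of the scenario table
#'
#' @param table output of [scenario_table()].
#' @return list of [drc] objects, one per scenario.
#' @export
scenario_curves <- function(table) attr(table, "curves")

#' Export the scenario table as CSV
#'
#' @param table output of [scenario_table()].
#' @param path file path.
#' @export
write_scenario_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}
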