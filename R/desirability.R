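#' Define a desirability criterion for one response
#'
#' Derringer-style desirability maps a predicted response to a score in
#' \[0, 1\].  Supported goals:
#' \describe{
#'   \item{`minimize`}{d = 1 at `bound_low`, 0 at `bound_high`, linear ramp
#'     between, raised to `weight`.}
#'   \item{`maximize`}{mirror image of `minimize`.}
#'   \item{`upper_bound`}{a soft cap: d = 1 for responses at or below
#'     `bound_low` (the cap), ramping to 0 at `bound_high`.  Use this for
#'     "keep WL below 5"-type constraints where any value under the cap is
#'     fully acceptable.}
#'   \item{`target`}{d = 1 at `target`, ramping to 0 at both bounds.}
#' }
#' Bounds left `NA` are resolved by [optimize_desirability()] from the range
#' of the fitted surface over the experimental cube.
#'
#' @param response name of the response the criterion applies to.
#' @param goal one of `"minimize"`, `"maximize"`, `"upper_bound"`, `"target"`.
#' @param bound_low,bound_high ramp endpoints in response units
#'   (`bound_low < bound_high`); for `upper_bound`, `bound_low` is the cap.
#' @param target target value for goal `"target"`; defaults to the midpoint.
#' @param weight positive exponent applied to the ramp (default 1).
#' @return An object of class `criterion`.
#' @export
criterion <- function(response, goal = c("minimize", "maximize", "upper_bound",
                                         "target"),
                      bound_low = NA_real_, bound_high = NA_real_,
                      target = NA_real_, weight = 1) {
  goal <- match.arg(goal)
  if (!is.na(bound_low) && !is.na(bound_high) && bound_low >= bound_high)
    stop("bound_low must be strictly less than bound_high", call. = FALSE)
  if (!is.finite(weight) || weight <= 0)
    stop("weight must be a positive number", call. = FALSE)
  structure(list(response = response, goal = goal, bound_low = bound_low,
                 bound_high = bound_high, target = target, weight = weight),
            class = "criterion")
}

#' Individual desirability of response values
#'
#' @param y numeric vector of (predicted) response values; must be finite.
#' @param crit a [criterion()] with resolved (non-`NA`) bounds.
#' @return Desirability scores in \[0, 1\], same length as `y`.
#' @export
individual_desirability <- function(y, crit) {
  stopifnot(inherits(crit, "criterion"))
  if (any(!is.finite(y))) stop("response values must be finite", call. = FALSE)
  lo <- crit$bound_low; hi <- crit$bound_high
  if (is.na(lo) || is.na(hi))
    stop("criterion bounds are unresolved (NA); supply bounds or optimize first",
         call. = FALSE)
  ramp <- switch(crit$goal,
    minimize = (hi - y) / (hi - lo),
    upper_bound = (hi - y) / (hi - lo),   # cap at lo: values below clamp to 1
    maximize = (y - lo) / (hi - lo),
    target = {
      tg <- if (is.na(crit$target)) (lo + hi) / 2 else crit$target
      ifelse(y <= tg, (y - lo) / (tg - lo), (hi - y) / (hi - tg))
    }
  )
  pmin(1, pmax(0, ramp))^crit$weight
}

#' Composite (weighted geometric-mean) desirability
#'
#' @param d numeric vector of individual desirabilities in \[0, 1\].
#' @param weights positive weights, recycled to `length(d)`; default equal.
#' @return The weighted geometric mean; exactly 0 if any `d` is 0 and 1 only
#'   if all are 1.
#' @export
composite_desirability <- function(d, weights = NULL) {
  if (!length(d)) stop("no desirabilities supplied", call. = FALSE)
  if (any(!is.finite(d)) || any(d < 0) || any(d > 1))
    stop("individual desirabilities must lie in [0, 1]", call. = FALSE)
  w <- if (is.null(weights)) rep(1, length(d)) else rep_len(weights, length(d))
  if (any(w <= 0)) stop("weights must be positive", call. = FALSE)
  if (any(d == 0)) return(0)
  exp(sum(w * log(d)) / sum(w))
}

resolve_bounds <- function(crit, model, space, n = 51) {
  g <- cube_grid(space, n)
  ys <- predict(model, g)
  lo <- crit$bound_low; hi <- crit$bound_high
  if (crit$goal == "upper_bound") {
    if (is.na(lo)) stop("upper_bound criterion needs its cap in bound_low",
                        call. = FALSE)
    if (is.na(hi)) hi <- max(ys)
    if (hi <= lo) hi <- lo + abs(lo) + 1  # degenerate: surface never exceeds cap
  } else {
    if (is.na(lo)) lo <- min(ys)
    if (is.na(hi)) hi <- max(ys)
  }
  crit$bound_low <- lo; crit$bound_high <- hi
  crit
}

cube_grid <- function(space, n) {
  g <- expand.grid(
    seq(space$low[1], space$high[1], length.out = n),
    seq(space$low[2], space$high[2], length.out = n),
    seq(space$low[3], space$high[3], length.out = n)
  )
  names(g) <- space$name
  g
}

#' Multi-response desirability optimization over the experimental cube
#'
#' Maximizes the composite desirability of several fitted response surfaces by
#' a deterministic coarse grid search over the closed factor cube followed by
#' Nelder-Mead simplex refinement from the best grid cell (clamped to the
#' cube; no extrapolation).  Grid ties are broken towards the cheapest
#' process: lowest temperature, then shortest time, then lowest concentration.
#'
#' @param models named list of `quadratic_model`s (names = response names).
#' @param criteria list of [criterion()] objects; each must reference a model.
#' @param grid_n grid points per factor for the coarse search (>= 11).
#' @param refine run the simplex refinement step (default `TRUE`).
#' @return A `desirability_result` list: `optimum_actual`, `optimum_coded`,
#'   `d_individual` (named), `D_composite`, `predicted` responses at the
#'   optimum, and the resolved `criteria`.
#' @export
optimize_desirability <- function(models, criteria, grid_n = 21, refine = TRUE) {
  if (grid_n < 11) stop("grid_n must be >= 11", call. = FALSE)
  if (!length(criteria)) stop("no criteria supplied", call. = FALSE)
  space <- models[[1]]$factor_space
  crit_names <- vapply(criteria, `[[`, character(1), "response")
  if (!all(crit_names %in% names(models)))
    stop("criteria reference unknown response(s): ",
         paste(setdiff(crit_names, names(models)), collapse = ", "),
         call. = FALSE)
  criteria <- lapply(criteria, function(cr)
    resolve_bounds(cr, models[[cr$response]], space))

  d_at <- function(pts) {
    dm <- vapply(criteria, function(cr)
      individual_desirability(predict(models[[cr$response]], pts), cr),
      numeric(nrow(pts)))
    if (nrow(pts) == 1L) dm <- matrix(dm, nrow = 1)
    dm
  }
  D_of <- function(dm) {
    # criterion weights act as ramp exponents inside d; the composite is the
    # plain geometric mean across criteria
    out <- exp(rowMeans(log(pmax(dm, .Machine$double.xmin))))
    out[apply(dm == 0, 1, any)] <- 0
    out
  }

  g <- cube_grid(space, grid_n)
  dm <- d_at(g)
  D <- D_of(dm)
  if (max(D) == 0) {
    worst <- criteria[[which.min(apply(dm, 2, max))]]$response
    stop("infeasible criteria: composite desirability is zero everywhere; ",
         "binding criterion: ", worst, call. = FALSE)
  }
  cand <- which(D >= max(D) - 1e-12)
  cand <- cand[order(g[cand, 1], g[cand, 2], g[cand, 3])]
  best <- as.numeric(g[cand[1], ])

  if (refine) {
    clamp <- function(p) pmin(space$high, pmax(space$low, p))
    obj <- function(p) {
      pts <- matrix(clamp(p), nrow = 1, dimnames = list(NULL, space$name))
      -D_of(d_at(pts))
    }
    opt <- stats::optim(best, obj, method = "Nelder-Mead",
                        control = list(maxit = 500, reltol = 1e-12))
    refined <- clamp(opt$par)
    if (-opt$value >= max(D)) best <- refined
  }

  pts <- matrix(best, nrow = 1, dimnames = list(NULL, space$name))
  dm_best <- drop(d_at(pts))
  names(dm_best) <- crit_names
  preds <- vapply(models, function(m) predict(m, pts), numeric(1))
  structure(
    list(optimum_actual = stats::setNames(best, space$name),
         optimum_coded = code_factors(space, best, warn_extrapolation = FALSE),
         d_individual = dm_best,
         D_composite = composite_desirability(dm_best),
         predicted = preds,
         criteria = criteria),
    class = "desirability_result"
  )
}

#' @export
print.desirability_result <- function(x, ...) {
  cat("Desirability optimum (actual units):\n")
  print(round(x$optimum_actual, 3))
  cat("Individual desirabilities:\n")
  print(round(x$d_individual, 4))
  cat(sprintf("Composite desirability D = %.4f\n", x$D_composite))
  invisible(x)
}

#' Percent validation error of a prediction
#'
#' Signed percent deviation of a model prediction from an independent
#' experimental measurement, `100 * (experimental - predicted) /
#' experimental`.  Predictions with absolute error below 20% are
#' conventionally accepted.
#'
#' @param experimental measured value(s); must be nonzero.
#' @param predicted model prediction(s).
#' @return Signed percent error; attribute `"accepted"` flags |error| <= 20.
#' @export
validation_error <- function(experimental, predicted) {
  if (any(experimental == 0))
    stop("experimental value must be nonzero", call. = FALSE)
  err <- 100 * (experimental - predicted) / experimental
  attr(err, "accepted") <- abs(err) <= 20
  err
}
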