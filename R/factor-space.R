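#' Define the three-factor experimental space of an OD process
#'
#' A factor space holds, for each process factor, the low/center/high actual
#' levels and the affine map to dimensionless coded units (-1, 0, +1).  The
#' default levels are those of the cherry-tomato osmodehydration study the
#' package models: temperature 25/35/45 degC, immersion time 30/60/90 min,
#' glycerol concentration 50/60/70 % w/w.  Coding is defined by magnitude:
#' the smaller actual level maps to -1 and the larger to +1.
#'
#' @param temperature,time,glycerol numeric length-3 vectors
#'   `c(low, center, high)` in actual units (degC, min, % w/w).
#' @return An object of class `factor_space`: a data frame with one row per
#'   factor and columns `name`, `low`, `center`, `high`, `unit`.
#' @examples
#' fs <- od_factor_space()
#' code_factors(fs, c(36, 72, 61.5))   # 0.10 0.40 0.15
#' @export
od_factor_space <- function(temperature = c(25, 35, 45),
                            time = c(30, 60, 90),
                            glycerol = c(50, 60, 70)) {
  levels <- list(temperature = temperature, time = time, glycerol = glycerol)
  units <- c("degC", "min", "% w/w")
  for (nm in names(levels)) {
    lv <- levels[[nm]]
    if (length(lv) != 3L || any(!is.finite(lv)))
      stop("factor '", nm, "' needs finite c(low, center, high)", call. = FALSE)
    if (!(lv[1] < lv[2] && lv[2] < lv[3]))
      stop("factor '", nm, "' levels must satisfy low < center < high",
           call. = FALSE)
    if (abs(lv[2] - (lv[1] + lv[3]) / 2) > 1e-8 * diff(range(lv)))
      stop("factor '", nm, "' center must be the midpoint of low and high ",
           "for symmetric coding", call. = FALSE)
  }
  out <- data.frame(
    name = names(levels),
    low = vapply(levels, `[`, numeric(1), 1L),
    center = vapply(levels, `[`, numeric(1), 2L),
    high = vapply(levels, `[`, numeric(1), 3L),
    unit = units,
    row.names = NULL
  )
  class(out) <- c("factor_space", "data.frame")
  out
}

half_range <- function(space) (space$high - space$low) / 2

as_factor_matrix <- function(x, space) {
  if (is.data.frame(x)) {
    missing <- setdiff(space$name, names(x))
    if (length(missing))
      stop("missing factor column(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    x <- as.matrix(x[space$name])
  } else if (is.matrix(x)) {
    if (ncol(x) != nrow(space)) stop("need one column per factor", call. = FALSE)
  } else {
    if (length(x) != nrow(space)) stop("need one value per factor", call. = FALSE)
    x <- matrix(x, nrow = 1)
  }
  colnames(x) <- space$name
  x
}

#' Map actual factor settings to coded units and back
#'
#' Coded units are `(x - center) / half_range`, so the low, center and high
#' levels map to -1, 0 and +1.  `decode_factors()` is the exact inverse.
#' Values outside \[-1, +1\] are allowed (extrapolation) and flagged with a
#' warning.
#'
#' @param space a [od_factor_space()] object.
#' @param actual,coded numeric vector of length 3 (one setting), a matrix, or
#'   a data frame with columns named after the factors.
#' @param warn_extrapolation warn when a coded value falls outside \[-1, 1\].
#' @return Object of the same shape as the input, in the other unit system.
#' @export
code_factors <- function(space, actual, warn_extrapolation = TRUE) {
  x <- as_factor_matrix(actual, space)
  coded <- sweep(sweep(x, 2, space$center, "-"), 2, half_range(space), "/")
  if (warn_extrapolation && any(abs(coded) > 1 + 1e-8))
    warning("coded value(s) outside [-1, 1]: extrapolating beyond the design cube",
            call. = FALSE)
  reshape_like(coded, actual)
}

#' @rdname code_factors
#' @export
decode_factors <- function(space, coded) {
  x <- as_factor_matrix(coded, space)
  actual <- sweep(sweep(x, 2, half_range(space), "*"), 2, space$center, "+")
  reshape_like(actual, coded)
}

reshape_like <- function(m, template) {
  if (is.data.frame(template)) as.data.frame(m)
  else if (is.matrix(template)) m
  else stats::setNames(drop(m), colnames(m))
}

#' Generate a three-factor Box-Behnken design
#'
#' The Box-Behnken design for three factors places runs at the midpoints of
#' the twelve edges of the factor cube (all permutations of (+/-1, +/-1, 0))
#' plus replicated center runs.  With the default `n_center = 3` this is the
#' classical 15-run design.  Center replicates provide the pure-error degrees
#' of freedom used by the lack-of-fit test in [fit_quadratic()].
#'
#' @param space a [od_factor_space()]; must have exactly 3 factors.
#' @param n_center number of center-point replicates (>= 1).
#' @return A `bbd_design` data frame with columns `run_id`, coded `x1..x3`,
#'   and the actual factor settings.  The attached factor space is stored in
#'   attribute `"factor_space"`.
#' @examples
#' nrow(bbd_design(od_factor_space()))  # 15
#' @export
bbd_design <- function(space = od_factor_space(), n_center = 3) {
  if (nrow(space) != 3L)
    stop("unsupported design: Box-Behnken generator requires exactly 3 factors",
         call. = FALSE)
  if (n_center < 1) stop("n_center must be >= 1", call. = FALSE)
  pm <- as.matrix(expand.grid(c(-1, 1), c(-1, 1)))
  edges <- rbind(
    cbind(pm[, 1], pm[, 2], 0),
    cbind(pm[, 1], 0, pm[, 2]),
    cbind(0, pm[, 1], pm[, 2])
  )
  coded <- rbind(edges, matrix(0, nrow = n_center, ncol = 3))
  colnames(coded) <- c("x1", "x2", "x3")
  actual <- decode_factors(space, coded)
  out <- data.frame(run_id = seq_len(nrow(coded)), coded, actual)
  attr(out, "factor_space") <- space
  class(out) <- c("bbd_design", "data.frame")
  out
}
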