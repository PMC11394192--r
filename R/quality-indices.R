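#' Scalar quality and mass-transfer indices of osmotic dehydration
#'
#' Water loss and solid gain are the standard mass-transfer indices of an
#' osmotic dehydration (OD) run, both normalized by the sample's *initial dry
#' mass* (g water/g i.d.m. and g solids/g i.d.m.).  Note that many studies
#' normalize by initial *total* mass instead; the dry-mass convention used
#' here makes the indices directly comparable across samples of different
#' moisture content.
#'
#' `water_loss()` may be negative (net water uptake) and `solid_gain()` may be
#' negative down to -1 (total solids leaching); negative values are returned
#' as-is because they are physically meaningful and the response surface must
#' not be clipped.
#'
#' @param M0 total sample mass at OD time zero (g).
#' @param m0 dry mass at OD time zero (g); must be positive.
#' @param M total sample mass at OD time t (g).
#' @param m dry mass at OD time t (g).
#' @return Numeric vector of the index, in g per g initial dry mass.
#' @examples
#' water_loss(M0 = 10, m0 = 1, M = 8, m = 1.5)  # 2.5
#' solid_gain(m = 1.5, m0 = 1)                  # 0.5
#' @export
water_loss <- function(M0, m0, M, m) {
  check_masses(M0, m0, M, m)
  ((M0 - m0) - (M - m)) / m0
}

#' @rdname water_loss
#' @export
solid_gain <- function(m, m0) {
  if (any(!is.finite(m0)) || any(m0 <= 0))
    stop("zero initial dry mass: m0 must be positive", call. = FALSE)
  if (any(m < 0)) stop("dry mass m must be non-negative", call. = FALSE)
  (m - m0) / m0
}

check_masses <- function(M0, m0, M, m) {
  if (any(!is.finite(m0)) || any(m0 <= 0))
    stop("zero initial dry mass: m0 must be positive", call. = FALSE)
  if (any(M0 <= 0)) stop("initial total mass M0 must be positive", call. = FALSE)
  if (any(c(M, m) < 0)) stop("masses must be non-negative", call. = FALSE)
  if (any(m0 > M0)) stop("dry mass m0 cannot exceed total mass M0", call. = FALSE)
  if (any(m > M)) stop("dry mass m cannot exceed total mass M", call. = FALSE)
  invisible(TRUE)
}

#' CIELab total colour difference
#'
#' Euclidean distance in CIELab space between a reading and a reference
#' reading.  A difference larger than [DELTA_E_VISIBLE] (= 2) is commonly
#' taken as visible to the eye; use [is_visible_difference()] to apply that
#' threshold — it is deliberately not baked into the numeric return value.
#'
#' @param L,a,b colour reading at time t (CIELab; `L` in \[0, 100\]).
#' @param L0,a0,b0 reference reading (time zero).
#' @return Non-negative numeric vector of colour differences; symmetric in
#'   the two readings.
#' @examples
#' delta_e(30, 20, 13, 27, 16, 13)  # 5
#' @export
delta_e <- function(L, a, b, L0, a0, b0) {
  if (any(L < 0 | L > 100 | L0 < 0 | L0 > 100))
    stop("lightness L must lie in [0, 100]", call. = FALSE)
  sqrt((L - L0)^2 + (a - a0)^2 + (b - b0)^2)
}

#' @rdname delta_e
#' @export
DELTA_E_VISIBLE <- 2

#' @rdname delta_e
#' @param dE colour difference(s) as returned by `delta_e()`.
#' @export
is_visible_difference <- function(dE) dE > DELTA_E_VISIBLE

#' Drip loss on thawing
#'
#' Percent weight lost as exudate when a frozen sample is thawed, an index of
#' freeze damage to the tissue.
#'
#' @param w_before sample weight before thawing (g); must be positive.
#' @param w_after sample weight after thawing (g).
#' @return Percent drip loss, `100 * (w_before - w_after) / w_before`.
#'   At most 100 (only when `w_after` is 0); negative if the sample gained
#'   weight.
#' @export
drip_loss <- function(w_before, w_after) {
  if (any(!is.finite(w_before)) || any(w_before <= 0))
    stop("weight before thawing must be positive", call. = FALSE)
  if (any(w_after < 0))
    stop("weight after thawing must be non-negative", call. = FALSE)
  100 * (w_before - w_after) / w_before
}
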