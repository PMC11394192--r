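#' @keywords internal
GAS_CONSTANT <- 8.314        # J mol^-1 K^-1
KELVIN_OFFSET <- 273.15
T_REF_DEFAULT <- -18         # degC, reference storage temperature

to_kelvin <- function(T_C) T_C + KELVIN_OFFSET

#' Fit an isothermal degradation rate
#'
#' Quality loss during frozen storage is modelled as apparent first-order
#' decay for concentrations (vitamin C, lycopene: `C = C0 exp(-k t)`, fitted
#' as least squares of `log(value)` on time) or apparent zero-order decay for
#' sensory scores (`S = S0 - k t`, fitted as least squares of the value on
#' time).  The log-scale fit assumes homoscedastic multiplicative error,
#' the usual convention for concentration data.
#'
#' @param time storage times (days), strictly increasing, first >= 0.
#' @param value quality index at each time; strictly positive for
#'   `order = "first"`.
#' @param order kinetic order, `"first"` or `"zero"`.
#' @param temperature storage temperature (degC) recorded on the estimate.
#' @param quality optional quality-index name.
#' @return A `rate_estimate`: `k` (per day; positive when the index degrades),
#'   `intercept` (back-transformed `C0` for first order, `S0` for zero
#'   order), `order`, `temperature`, `r2`, `stderr_k` and `no_degradation`
#'   flag.  A non-negative fitted slope triggers a warning and the flag.
#' @examples
#' t <- seq(0, 90, 15)
#' fit_rate(t, 100 * exp(-0.02 * t), order = "first")$k  # 0.02
#' @export
fit_rate <- function(time, value, order = c("first", "zero"),
                     temperature = NA_real_, quality = NA_character_) {
  order <- match.arg(order)
  if (length(time) < 3L) stop("need at least 3 points", call. = FALSE)
  if (length(value) != length(time)) stop("time/value length mismatch", call. = FALSE)
  if (is.unsorted(time, strictly = TRUE) || time[1] < 0)
    stop("times must be strictly increasing and start at >= 0", call. = FALSE)
  resp <- if (order == "first") {
    if (any(value <= 0))
      stop("first-order fit requires strictly positive values", call. = FALSE)
    log(value)
  } else value
  fit <- stats::lm(resp ~ time)
  sl <- unname(stats::coef(fit)[2])
  ic <- unname(stats::coef(fit)[1])
  k <- -sl
  flag <- k <= 0
  if (flag) warning("no degradation detected: fitted rate is <= 0", call. = FALSE)
  structure(
    list(k = k,
         intercept = if (order == "first") exp(ic) else ic,
         order = order, temperature = temperature, quality = quality,
         r2 = summary(fit)$r.squared,
         stderr_k = unname(summary(fit)$coefficients[2, 2]),
         no_degradation = flag),
    class = "rate_estimate"
  )
}

#' Construct an Arrhenius model for a quality index
#'
#' The temperature dependence of a degradation rate is
#' `k(T) = k_ref * exp(-(E_a / R) * (1 / T_K - 1 / T_ref_K))`
#' with temperatures in Kelvin, so `k` increases with temperature when
#' `E_a > 0`.  `R` = 8.314 J mol^-1 K^-1; the reference temperature defaults
#' to -18 degC, the standard frozen-storage condition.
#'
#' @param k_ref rate at the reference temperature (per day, > 0).
#' @param E_a activation energy in J/mol (> 0 for degradation).
#' @param T_ref reference temperature (degC).
#' @param order kinetic order of the underlying decay, `"first"` or `"zero"`.
#' @param initial_value,limit_value initial level and acceptance limit of the
#'   quality index (used by [shelf_life()] and [predict_nonisothermal()]).
#' @return An object of class `arrhenius_model`.
#' @export
arrhenius_model <- function(k_ref, E_a, T_ref = T_REF_DEFAULT,
                            order = c("first", "zero"),
                            initial_value = NA_real_, limit_value = NA_real_) {
  order <- match.arg(order)
  if (!is.finite(k_ref) || k_ref <= 0) stop("k_ref must be positive", call. = FALSE)
  if (!is.finite(E_a) || E_a < 0) stop("E_a must be non-negative (J/mol)", call. = FALSE)
  structure(list(k_ref = k_ref, E_a = E_a, T_ref = T_ref, order = order,
                 initial_value = initial_value, limit_value = limit_value),
            class = "arrhenius_model")
}

#' @export
print.arrhenius_model <- function(x, ...) {
  cat(sprintf("Arrhenius model (%s order): k_ref = %.4g /d at %g degC, E_a = %.4g kJ/mol\n",
              x$order, x$k_ref, x$T_ref, x$E_a / 1000))
  invisible(x)
}

#' Fit the Arrhenius temperature dependence of degradation rates
#'
#' Least squares of `log(k)` on `(1/T_K - 1/T_ref_K)`: the slope is `-E_a/R`
#' and the intercept `log(k_ref)`.  With exactly two temperatures the fit is
#' exact.
#'
#' @param rates a list of `rate_estimate`s (from [fit_rate()]) or a data
#'   frame with columns `temperature` (degC) and `k` (per day).
#' @param T_ref reference temperature (degC) at which `k_ref` is anchored.
#' @param initial_value,limit_value passed to the resulting model.
#' @return An `arrhenius_model`; `E_a` in J/mol.
#' @export
fit_arrhenius <- function(rates, T_ref = T_REF_DEFAULT,
                          initial_value = NA_real_, limit_value = NA_real_) {
  if (is.data.frame(rates)) {
    temps <- rates$temperature; ks <- rates$k
    order <- attr(rates, "order") %||% "first"
  } else {
    stopifnot(all(vapply(rates, inherits, logical(1), "rate_estimate")))
    orders <- unique(vapply(rates, `[[`, character(1), "order"))
    if (length(orders) > 1L)
      stop("mixed kinetic orders cannot be pooled in one Arrhenius fit",
           call. = FALSE)
    order <- orders
    temps <- vapply(rates, `[[`, numeric(1), "temperature")
    ks <- vapply(rates, `[[`, numeric(1), "k")
  }
  keep <- is.finite(ks) & ks > 0
  if (sum(keep) < 2L || length(unique(temps[keep])) < 2L)
    stop("insufficient data: need rates k > 0 at >= 2 distinct temperatures",
         call. = FALSE)
  x <- 1 / to_kelvin(temps[keep]) - 1 / to_kelvin(T_ref)
  fit <- stats::lm(log(ks[keep]) ~ x)
  E_a <- -unname(stats::coef(fit)[2]) * GAS_CONSTANT
  k_ref <- exp(unname(stats::coef(fit)[1]))
  arrhenius_model(k_ref, E_a, T_ref, order, initial_value, limit_value)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Degradation rate at a storage temperature
#'
#' @param model an [arrhenius_model()].
#' @param temperature storage temperature(s), degC.
#' @return Rate(s) in per day; strictly increasing in temperature for
#'   `E_a > 0`, and exactly `k_ref` at the reference temperature.
#' @export
rate_at <- function(model, temperature) {
  stopifnot(inherits(model, "arrhenius_model"))
  model$k_ref * exp(-(model$E_a / GAS_CONSTANT) *
                      (1 / to_kelvin(temperature) - 1 / to_kelvin(model$T_ref)))
}

#' Shelf life at a constant storage temperature
#'
#' Time for the quality index to reach its acceptance limit: for first-order
#' decay `log(initial / limit) / k(T)` (with the common 50%-loss limit this is
#' `log(2) / k`), for zero-order decay `(initial - limit) / k(T)`.
#'
#' @param model an [arrhenius_model()].
#' @param temperature storage temperature(s), degC.
#' @param initial,limit initial level and acceptance limit; default to the
#'   values stored in the model.  Alternatively give `loss_fraction` (e.g.
#'   0.5 for 50% loss, first order only).
#' @param loss_fraction fraction of the initial level lost at the acceptance
#'   limit; overrides `limit` when supplied.
#' @return Shelf life in days; strictly decreasing in temperature for
#'   `E_a > 0`.
#' @examples
#' m <- arrhenius_model(k_ref = 0.0033, E_a = 88800, order = "first")
#' shelf_life(m, -18, loss_fraction = 0.5)  # log(2)/0.0033 = 210 d
#' @export
shelf_life <- function(model, temperature, initial = model$initial_value,
                       limit = model$limit_value, loss_fraction = NULL) {
  stopifnot(inherits(model, "arrhenius_model"))
  if (!is.null(loss_fraction)) {
    if (model$order != "first")
      stop("loss_fraction applies to first-order kinetics only", call. = FALSE)
    if (loss_fraction <= 0 || loss_fraction >= 1)
      stop("loss_fraction must be in (0, 1)", call. = FALSE)
    initial <- 1; limit <- 1 - loss_fraction
  }
  if (any(is.na(initial)) || any(is.na(limit)))
    stop("initial and limit values are required (not stored in the model)",
         call. = FALSE)
  if (model$order == "first" && (initial <= 0 || limit <= 0))
    stop("first-order shelf life needs positive initial and limit", call. = FALSE)
  if (limit >= initial)
    stop("acceptance limit must lie below the initial value ",
         "(zero or negative shelf life)", call. = FALSE)
  k <- rate_at(model, temperature)
  if (model$order == "first") log(initial / limit) / k else (initial - limit) / k
}

#' Piecewise-constant storage temperature profiles
#'
#' @param temperature segment temperatures (degC).
#' @param duration_h segment durations (hours, > 0), same length.
#' @return A `temperature_profile` data frame with columns `segment`,
#'   `duration_h`, `temperature`; total duration in attribute `"t_tot_h"`.
#' @export
temperature_profile <- function(temperature, duration_h) {
  if (length(temperature) != length(duration_h) || !length(temperature))
    stop("temperature and duration_h must be non-empty and equal length",
         call. = FALSE)
  if (any(!is.finite(duration_h)) || any(duration_h <= 0))
    stop("segment durations must be positive", call. = FALSE)
  out <- data.frame(segment = seq_along(temperature),
                    duration_h = duration_h, temperature = temperature)
  attr(out, "t_tot_h") <- sum(duration_h)
  class(out) <- c("temperature_profile", "data.frame")
  out
}

#' @rdname temperature_profile
#' @param repeats number of times the cycle is repeated (>= 1).
#' @examples
#' # the classic abuse scenario: three cycles of -12/-5/-8 degC, 24 h each
#' p <- make_cycle_profile(c(-12, -5, -8), c(24, 24, 24), repeats = 3)
#' attr(p, "t_tot_h")  # 216
#' @export
make_cycle_profile <- function(temperature, duration_h, repeats = 1) {
  if (repeats < 1) stop("repeats must be >= 1", call. = FALSE)
  temperature_profile(rep(temperature, repeats), rep(duration_h, repeats))
}

#' Effective temperature of a fluctuating storage profile
#'
#' The effective temperature is the constant temperature that produces the
#' same quality loss as the variable profile over the same total time.  It is
#' obtained from the time-weighted mean rate
#' `k_eff = sum(k(T_i) t_i) / t_tot` and the closed-form inversion of the
#' Arrhenius relation,
#' `1 / T_eff_K = 1 / T_ref_K - (R / E_a) log(k_eff / k_ref)`.
#' The result depends only on `E_a` (not on `k_ref`), always lies within the
#' range of the segment temperatures, and for a non-constant profile is
#' warmer than the time-weighted arithmetic mean temperature and increases
#' with `E_a`.
#'
#' @param profile a [temperature_profile()].
#' @param model an [arrhenius_model()], or a bare activation energy in J/mol.
#' @return Effective temperature in degC.  For `E_a = 0` the rate is
#'   temperature-independent and the time-weighted harmonic mean (in Kelvin)
#'   is returned with a warning.
#' @export
effective_temperature <- function(profile, model) {
  stopifnot(inherits(profile, "temperature_profile"))
  if (is.numeric(model)) model <- arrhenius_model(1, model)
  stopifnot(inherits(model, "arrhenius_model"))
  t_i <- profile$duration_h; T_i <- profile$temperature
  if (model$E_a == 0) {
    warning("E_a = 0: rate is temperature-independent; returning the ",
            "time-weighted harmonic-mean temperature", call. = FALSE)
    return(1 / (sum(t_i / to_kelvin(T_i)) / sum(t_i)) - KELVIN_OFFSET)
  }
  k_eff <- sum(rate_at(model, T_i) * t_i) / sum(t_i)
  inv_T <- 1 / to_kelvin(model$T_ref) -
    (GAS_CONSTANT / model$E_a) * log(k_eff / model$k_ref)
  1 / inv_T - KELVIN_OFFSET
}

#' Predict quality evolution under non-isothermal storage
#'
#' Integrates the kinetic model over a piecewise-constant temperature profile
#' in closed form segment by segment: first-order values multiply by
#' `exp(-k(T_i) t_i)` and zero-order values decrease by `k(T_i) t_i`
#' (durations converted from hours to days).  The trajectory is reported at
#' segment boundaries.  Zero-order predictions are not floored: values below
#' the acceptance limit (or scale minimum) are returned as computed and
#' flagged, so the caller sees how far past rejection the profile drives the
#' product.
#'
#' @param model an [arrhenius_model()].
#' @param profile a [temperature_profile()].
#' @param initial initial quality level; defaults to the model's stored value.
#' @return Data frame with `time_d` (0 at the profile start), `temperature`
#'   (`NA` for the initial row) and `value`; attribute `"below_limit"` is
#'   `TRUE` if any value undershot the model's `limit_value`.
#' @export
predict_nonisothermal <- function(model, profile, initial = model$initial_value) {
  stopifnot(inherits(model, "arrhenius_model"),
            inherits(profile, "temperature_profile"))
  if (is.na(initial)) stop("initial value required", call. = FALSE)
  t_d <- profile$duration_h / 24
  k <- rate_at(model, profile$temperature)
  value <- if (model$order == "first") {
    initial * exp(-cumsum(k * t_d))
  } else {
    initial - cumsum(k * t_d)
  }
  out <- data.frame(time_d = c(0, cumsum(t_d)),
                    temperature = c(NA_real_, profile$temperature),
                    value = c(initial, value))
  lim <- model$limit_value
  attr(out, "below_limit") <- !is.na(lim) && any(value < lim)
  out
}

#' Relative error between experimental and model-predicted rates
#'
#' `100 * (k_exp - k_fit) / k_exp`; predictions within 20% absolute relative
#' error are conventionally accepted when validating kinetic models.
#'
#' @param k_exp experimentally fitted rate(s); must be nonzero.
#' @param k_fit model-predicted rate(s).
#' @return Signed percent relative error with attribute `"accepted"`
#'   (|RE| <= 20).
#' @export
relative_error <- function(k_exp, k_fit) {
  if (any(k_exp == 0)) stop("experimental rate must be nonzero", call. = FALSE)
  re <- 100 * (k_exp - k_fit) / k_exp
  attr(re, "accepted") <- abs(re) <= 20
  re
}
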