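#' Specification of a synthetic OD response-surface experiment
#'
#' Bundles the generating surfaces (defaults: the published cherry-tomato
#' regression equations, see [od_surface_coefficients()]) with per-response
#' additive Gaussian noise standard deviations on the scale of the respective
#' instruments.
#'
#' @param coefficients 10 x k uncoded coefficient matrix (terms x responses).
#' @param noise_sd named numeric vector of noise standard deviations, one per
#'   response column; all >= 0.
#' @return An `od_surface_spec` list.
#' @export
od_surface_spec <- function(coefficients = od_surface_coefficients(),
                            noise_sd = c(aw = 0.005, WL = 0.3, SG = 0.05,
                                         dE = 0.5, firmness = 0.15)) {
  if (nrow(coefficients) != 10L)
    stop("coefficient matrix needs 10 rows (quadratic terms)", call. = FALSE)
  noise_sd <- noise_sd[colnames(coefficients)]
  if (any(is.na(noise_sd)) || any(noise_sd < 0))
    stop("noise_sd must supply a non-negative value per response", call. = FALSE)
  structure(list(coefficients = coefficients, noise_sd = noise_sd),
            class = "od_surface_spec")
}

#' Simulate responses of an OD design from known surfaces
#'
#' For every design run and every response, draws
#' `surface value + N(0, noise_sd^2)`.  Center replicates therefore differ
#' only by noise, and with `noise_sd = 0` the responses lie exactly on the
#' generating surfaces (so [fit_quadratic()] recovers the coefficients to
#' machine precision).
#'
#' @param design a [bbd_design()].
#' @param spec an [od_surface_spec()].
#' @param seed integer seed; the output is bit-reproducible given the seed.
#' @return The design data frame with one appended column per response.
#' @export
simulate_od_experiment <- function(design, spec = od_surface_spec(), seed = 1) {
  space <- attr(design, "factor_space")
  set.seed(seed)
  out <- as.data.frame(design)
  x <- as.matrix(design[, space$name])
  for (r in colnames(spec$coefficients)) {
    mu <- eval_quad(spec$coefficients[, r], x[, 1], x[, 2], x[, 3])
    out[[r]] <- mu + stats::rnorm(length(mu), sd = spec$noise_sd[[r]])
  }
  attr(out, "factor_space") <- space
  class(out) <- class(design)
  out
}

#' Specification of a synthetic frozen-storage study
#'
#' Defines the isothermal storage experiment the degradation simulator
#' emulates: which (quality, treatment) kinetic models generate the data
#' (defaults: [kinetic_presets()]), the storage temperatures, sampling days,
#' replication and noise.  Concentration-type qualities get multiplicative
#' lognormal noise; sensory scores get additive Gaussian noise and are
#' truncated at the scale floor of 1 (with a warning when truncation occurs).
#'
#' @param presets data frame in the shape of [kinetic_presets()].
#' @param temperatures storage temperatures (degC), within \[-40, 0\].
#' @param times sampling times (days).
#' @param replicates replicate measurements per time point.
#' @param sigma lognormal sigma for concentration noise (e.g. 0.05 = 5%).
#' @param sensory_sd additive noise SD for sensory scores (score units).
#' @return A `storage_study_spec` list.
#' @export
storage_study_spec <- function(presets = kinetic_presets(),
                               temperatures = c(-5, -8, -14, -23),
                               times = seq(0, 90, by = 15),
                               replicates = 2, sigma = 0.05,
                               sensory_sd = 0.3) {
  if (sigma < 0 || sensory_sd < 0) stop("noise must be >= 0", call. = FALSE)
  if (any(temperatures < -40 | temperatures > 0))
    stop("storage temperatures must lie in [-40, 0] degC", call. = FALSE)
  structure(list(presets = presets, temperatures = temperatures,
                 times = times, replicates = replicates, sigma = sigma,
                 sensory_sd = sensory_sd),
            class = "storage_study_spec")
}

#' Simulate isothermal degradation series
#'
#' Generates one series per (quality, treatment, temperature): first-order
#' qualities as `C0 * exp(-k(T) t) * exp(N(0, sigma^2))`, zero-order sensory
#' scores as `S0 - k(T) t + N(0, sensory_sd^2)` truncated at the 9-point-scale
#' floor of 1.  Rates come from the Arrhenius preset at each temperature.
#'
#' @param spec a [storage_study_spec()].
#' @param seed integer seed; bit-reproducible output.
#' @return Data frame with columns `quality`, `treatment`, `temperature`,
#'   `time_d`, `rep`, `value`, `unit`.
#' @export
simulate_degradation <- function(spec = storage_study_spec(), seed = 1) {
  set.seed(seed)
  p <- spec$presets
  rows <- vector("list", nrow(p) * length(spec$temperatures))
  i <- 0L
  truncated <- FALSE
  for (j in seq_len(nrow(p))) {
    model <- arrhenius_model(p$k_ref[j], p$E_a[j], order = p$order[j],
                             initial_value = p$initial[j],
                             limit_value = p$limit[j])
    unit <- if (p$order[j] == "first") "mg/100 g" else "score"
    for (T_C in spec$temperatures) {
      k <- rate_at(model, T_C)
      tt <- rep(spec$times, each = spec$replicates)
      mu <- if (p$order[j] == "first") p$initial[j] * exp(-k * tt)
            else p$initial[j] - k * tt
      value <- if (p$order[j] == "first") {
        mu * exp(stats::rnorm(length(tt), sd = spec$sigma))
      } else {
        v <- mu + stats::rnorm(length(tt), sd = spec$sensory_sd)
        if (any(v < 1)) truncated <- TRUE
        pmax(v, 1)
      }
      i <- i + 1L
      rows[[i]] <- data.frame(
        quality = p$quality[j], treatment = p$treatment[j], temperature = T_C,
        time_d = tt, rep = rep(seq_len(spec$replicates), length(spec$times)),
        value = value, unit = unit
      )
    }
  }
  if (truncated)
    warning("sensory scores truncated at the scale floor of 1; ",
            "shorten the sampling window to avoid censored fits", call. = FALSE)
  do.call(rbind, rows)
}

#' Fit rates for every series of a storage table
#'
#' Convenience wrapper: averages replicates per time point, then calls
#' [fit_rate()] for each (quality, treatment, temperature) group using the
#' kinetic order conventional for the quality (first order for
#' concentrations, zero order for sensory scores).
#'
#' @param data storage series data frame as produced by
#'   [simulate_degradation()] or read via [read_od_table()] (schema
#'   `storage_series`).
#' @param orders named character vector mapping quality -> kinetic order.
#' @return List of `rate_estimate`s, named `quality/treatment/temperature`.
#' @export
fit_storage_rates <- function(data,
                              orders = c(vitamin_c = "first",
                                         lycopene = "first",
                                         sensory = "zero")) {
  groups <- split(data, list(data$quality, data$treatment, data$temperature),
                  drop = TRUE)
  out <- lapply(groups, function(g) {
    ord <- orders[[as.character(g$quality[1])]]
    if (is.null(ord)) stop("no kinetic order known for quality '",
                           g$quality[1], "'", call. = FALSE)
    agg <- stats::aggregate(value ~ time_d, data = g, FUN = mean)
    fit_rate(agg$time_d, agg$value, order = ord,
             temperature = g$temperature[1], quality = as.character(g$quality[1]))
  })
  names(out) <- gsub("\\.", "/", names(groups))
  out
}
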