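#' Published response-surface coefficients for cherry-tomato osmotic dehydration
#'
#' Uncoded (actual-unit) coefficients of the second-order regression surfaces
#' reported for osmodehydrated cherry tomato: water activity (`aw`), water
#' loss (`WL`, g water/g initial dry mass), solid gain (`SG`, g solids/g
#' i.d.m.), total colour change (`dE`) and firmness (`firmness`, N), as
#' functions of temperature (degC), immersion time (min) and glycerol
#' concentration (% w/w).  Term order matches [quadratic_model()]:
#' `(a0, a1, a2, a3, a11, a22, a33, a12, a13, a23)`.
#'
#' The published solid-gain equation prints two temperature-by-concentration
#' interaction terms; the final one is read as the (otherwise missing)
#' time-by-concentration interaction.
#'
#' @return A 10 x 5 numeric matrix (rows = model terms, columns = responses).
#' @seealso [od_reference_models()] to wrap the columns as model objects.
#' @export
od_surface_coefficients <- function() {
  m <- cbind(
    aw = c(1.871, -0.014408, -0.001750, -0.02115,
           0.000232, 0.000017, 0.000185,
           -0.000007, -0.000032, -0.000003),
    WL = c(-95.8, 0.643, 0.044, 2.887,
           -0.00325, -0.000560, -0.02251,
           0.00133, -0.00602, -0.00022),
    SG = c(6.40, -0.262, 0.0183, -0.085,
           0.00394, -0.000061, 0.00086,
           0.000146, -0.00008, -0.000255),
    dE = c(-15.5, -0.278, -0.5008, 1.386,
           -0.00941, 0.003228, -0.01624,
           0.00109, 0.01511, 0.00110),
    firmness = c(12.90, -0.210, -0.3016, 0.016,
                 0.00374, 0.001656, -0.00055,
                 0.000572, -0.00076, 0.001300)
  )
  rownames(m) <- quad_terms
  m
}

#' @rdname od_surface_coefficients
#' @param space factor space used for the coded/uncoded mapping.
#' @return `od_reference_models()`: a named list of `quadratic_model`s, one
#'   per response column.
#' @export
od_reference_models <- function(space = od_factor_space()) {
  coefs <- od_surface_coefficients()
  stats::setNames(
    lapply(colnames(coefs), function(r)
      quadratic_model(coefs[, r], space, response = r, form = "uncoded")),
    colnames(coefs)
  )
}

#' Reference validation measurements at the optimal OD conditions
#'
#' Experimental values measured in an independent validation run at the
#' optimal process settings (36 degC, 72 min, 61.5% w/w glycerol), together
#' with the model predictions reported alongside them.
#'
#' @return Data frame with columns `response`, `experimental`, `predicted`.
#' @export
od_validation_reference <- function() {
  data.frame(
    response = c("WL", "SG", "aw", "dE", "firmness"),
    experimental = c(4.881, 0.130, 0.9105, 6.24, 2.08),
    predicted = c(4.890, 0.152, 0.9117, 7.49, 1.26)
  )
}

#' Kinetic parameter presets for frozen cherry tomato
#'
#' Arrhenius parameters of the degradation of vitamin C and lycopene
#' (first-order, acceptance limit 50% loss) and of the sensory overall score
#' (zero-order, 9-point scale) for untreated and osmodehydrated (OD) frozen
#' cherry tomato, anchored at the reference temperature -18 degC.
#'
#' @return Data frame with one row per (quality, treatment): `quality`,
#'   `treatment`, `order`, `E_a` (J/mol), `k_ref` (per day), `initial`
#'   (mg/100 g or score) and `limit` (acceptance limit in the same units).
#' @seealso [preset_model()] to turn one row into an [arrhenius_model()];
#'   [sensory_limits] for the alternative sensory cut-offs.
#' @export
kinetic_presets <- function() {
  data.frame(
    quality = rep(c("vitamin_c", "lycopene", "sensory"), each = 2),
    treatment = rep(c("untreated", "od"), 3),
    order = rep(c("first", "first", "zero"), c(2, 2, 2)),
    E_a = c(88.8, 115.6, 88.5, 86.1, 56.58, 57.10) * 1000,
    k_ref = c(0.0033, 0.0025, 0.0025, 0.0020, 0.017, 0.009),
    initial = c(38.79, 39.15, 10.35, 11.35, 7.1, 9.0),
    limit = c(38.79 / 2, 39.15 / 2, 10.35 / 2, 11.35 / 2, 4, 4)
  )
}

#' @rdname kinetic_presets
#' @param quality,treatment row selector for [kinetic_presets()].
#' @param T_ref reference temperature (degC).
#' @export
preset_model <- function(quality, treatment, T_ref = T_REF_DEFAULT) {
  p <- kinetic_presets()
  row <- p[p$quality == quality & p$treatment == treatment, ]
  if (nrow(row) != 1L)
    stop("no preset for quality '", quality, "', treatment '", treatment, "'",
         call. = FALSE)
  arrhenius_model(row$k_ref, row$E_a, T_ref, row$order,
                  initial_value = row$initial, limit_value = row$limit)
}

#' Named sensory acceptance limits (9-point hedonic scale)
#'
#' Two conventional cut-offs for the overall-impression score: the scale
#' midpoint 5 ("neither like nor dislike") and the stricter rejection score 4
#' used in the shelf-life tables.  The sensory limit is always an explicit
#' input to [shelf_life()]; these constants are provided so the choice is
#' named, not hidden.
#'
#' @export
sensory_limits <- c(midpoint = 5, rejection = 4)

#' Reported shelf lives of frozen cherry tomato
#'
#' Shelf lives (days) reported per storage temperature for each quality index
#' and treatment.  These were computed from per-temperature fitted rates on
#' the original raw data and are not exactly reproducible from the
#' [kinetic_presets()] parameters alone; they are shipped as reference data
#' for ratio-level comparisons (e.g. the OD/untreated sensory shelf-life
#' ratio).
#'
#' @return Data frame with columns `quality`, `treatment`, `temperature`
#'   (degC) and `days`.
#' @export
reported_shelf_lives <- function() {
  temps <- c(-5, -8, -14, -23)
  sl <- rbind(
    c("vitamin_c", "untreated", 20, 37, 87, 402),
    c("vitamin_c", "od", 15, 33, 102, 737),
    c("lycopene", "untreated", 44, 68, 130, 415),
    c("lycopene", "od", 46, 70, 131, 395),
    c("sensory", "untreated", 14, 19, 30, 67),
    c("sensory", "od", 50, 66, 100, 207)
  )
  data.frame(
    quality = rep(sl[, 1], each = 4),
    treatment = rep(sl[, 2], each = 4),
    temperature = rep(temps, nrow(sl)),
    days = as.numeric(t(sl[, 3:6]))
  )
}

#' Default optimization criteria for the OD process
#'
#' The canonical triple criterion: minimize water activity over its fitted
#' range on the cube, keep water loss at or below 5 g/g i.d.m. and colour
#' change at or below 8.  The caps are soft constraints (full desirability
#' below the cap); unset ramp endpoints are resolved from the fitted surface
#' ranges by [optimize_desirability()].
#'
#' @param wl_cap,de_cap upper caps for water loss and colour change.
#' @return List of three [criterion()] objects.
#' @export
od_default_criteria <- function(wl_cap = 5, de_cap = 8) {
  list(
    criterion("aw", "minimize"),
    criterion("WL", "upper_bound", bound_low = wl_cap),
    criterion("dE", "upper_bound", bound_low = de_cap)
  )
}
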