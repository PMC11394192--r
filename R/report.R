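#' End-to-end reproducibility report
#'
#' Drives the whole analysis from the shipped reference data: evaluates the
#' published response surfaces at the optimal conditions (36 degC, 72 min,
#' 61.5% w/w) and at the design center (35, 60, 60), recomputes the percent
#' validation errors from the stored experimental/predicted pairs, re-runs
#' the desirability optimization under the canonical criteria, tabulates
#' shelf lives from the kinetic presets at the studied storage temperatures,
#' computes the OD/untreated sensory shelf-life ratios from the reported
#' shelf-life table, and maps the effective temperature of the standard
#' three-cycle abuse profile (-12/-5/-8 degC, 24 h each, repeated 3 times)
#' over a grid of activation energies.  The computation is deterministic:
#' repeated calls return identical reports.
#'
#' @param grid_n grid resolution per factor for the desirability search.
#' @param ea_grid_kJ activation energies (kJ/mol) for the effective-
#'   temperature map.
#' @param path optional path; when given, the report is also written there as
#'   JSON.
#' @return A nested list (invisibly if `path` is given).
#' @export
reproduce_report <- function(grid_n = 41, ea_grid_kJ = seq(50, 150, by = 10),
                             path = NULL) {
  space <- od_factor_space()
  models <- od_reference_models(space)
  optimum <- c(temperature = 36, time = 72, glycerol = 61.5)
  center <- stats::setNames(space$center, space$name)

  predictions_at_optimum <- vapply(models, predict, numeric(1),
                                   newdata = optimum)
  predictions_at_center <- vapply(models, predict, numeric(1),
                                  newdata = center)

  val <- od_validation_reference()
  val$recomputed_pct_error <- as.numeric(validation_error(val$experimental,
                                                          val$predicted))
  val$accepted <- abs(val$recomputed_pct_error) <= 20

  opt <- optimize_desirability(models[c("aw", "WL", "dE")],
                               od_default_criteria(), grid_n = grid_n)

  presets <- kinetic_presets()
  temps <- c(-5, -8, -14, -23, -18)
  shelf <- do.call(rbind, lapply(seq_len(nrow(presets)), function(j) {
    m <- preset_model(presets$quality[j], presets$treatment[j])
    data.frame(quality = presets$quality[j], treatment = presets$treatment[j],
               temperature = temps,
               shelf_life_d = shelf_life(m, temps))
  }))

  sl <- reported_shelf_lives()
  sens <- sl[sl$quality == "sensory", ]
  ratio <- merge(sens[sens$treatment == "od", c("temperature", "days")],
                 sens[sens$treatment == "untreated", c("temperature", "days")],
                 by = "temperature", suffixes = c("_od", "_untreated"))
  ratio$ratio <- ratio$days_od / ratio$days_untreated

  profile <- make_cycle_profile(c(-12, -5, -8), c(24, 24, 24), repeats = 3)
  teff <- data.frame(
    E_a_kJ = ea_grid_kJ,
    T_eff = vapply(ea_grid_kJ * 1000, function(ea)
      effective_temperature(profile, ea), numeric(1))
  )

  report <- list(
    optimum_conditions = as.list(optimum),
    predictions_at_optimum = as.list(predictions_at_optimum),
    predictions_at_center = as.list(predictions_at_center),
    validation = val,
    desirability = list(
      optimum_actual = as.list(opt$optimum_actual),
      d_individual = as.list(opt$d_individual),
      D_composite = opt$D_composite
    ),
    shelf_life_table = shelf,
    sensory_shelf_life_ratio = ratio,
    max_sensory_sl_ratio = max(ratio$ratio),
    effective_temperature_map = teff,
    profile_total_hours = attr(profile, "t_tot_h")
  )
  if (!is.null(path)) {
    jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
    return(invisible(report))
  }
  report
}
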