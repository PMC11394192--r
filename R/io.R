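od_schemas <- list(
  od_raw = c(run_id = "integer", T_C = "numeric", t_min = "numeric",
             C_glyc_pct = "numeric", M0_g = "numeric", m0_g = "numeric",
             M_g = "numeric", m_g = "numeric", aw = "numeric", L = "numeric",
             a = "numeric", b = "numeric", Fmax_N = "numeric"),
  design = c(run_id = "integer", T_C = "numeric", t_min = "numeric",
             C_glyc_pct = "numeric", x1 = "numeric", x2 = "numeric",
             x3 = "numeric"),
  storage_series = c(quality = "character", treatment = "character",
                     T_C = "numeric", time_d = "numeric", value = "numeric",
                     unit = "character"),
  profile = c(segment = "integer", duration_h = "numeric", T_C = "numeric")
)

#' Read and validate a delimited data file
#'
#' Reads a comma-separated, dot-decimal, UTF-8 file with a header row and
#' validates it against one of the package's fixed schemas.  A missing column
#' raises a schema error naming the column; unparseable numeric cells raise a
#' row error reporting the 1-based file line numbers (header = line 1).
#'
#' @param path path to the CSV file.
#' @param schema one of `"od_raw"` (raw OD runs), `"design"` (design table),
#'   `"storage_series"` (isothermal storage measurements), `"profile"`
#'   (piecewise-constant temperature profile).
#' @return A data frame with typed columns in schema order.
#' @export
read_od_table <- function(path, schema = names(od_schemas)) {
  schema <- match.arg(schema)
  cols <- od_schemas[[schema]]
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         fileEncoding = "UTF-8")
  missing <- setdiff(names(cols), names(raw))
  if (length(missing))
    stop("schema '", schema, "': missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  out <- raw[names(cols)]
  bad <- character(0)
  for (nm in names(cols)) {
    if (cols[[nm]] == "character") next
    v <- suppressWarnings(as.numeric(out[[nm]]))
    fail <- which(is.na(v) & !is.na(out[[nm]]) & nzchar(trimws(out[[nm]])))
    miss <- which(is.na(out[[nm]]) | !nzchar(trimws(out[[nm]])))
    fail <- sort(unique(c(fail, miss)))
    if (length(fail))
      bad <- c(bad, paste0("column '", nm, "', line(s) ",
                           paste(fail + 1L, collapse = ", ")))
    out[[nm]] <- if (cols[[nm]] == "integer") as.integer(v) else v
  }
  if (length(bad))
    stop("unparseable numeric value(s): ", paste(bad, collapse = "; "),
         call. = FALSE)
  out
}

#' Convert a read profile table to a temperature profile object
#'
#' @param df data frame with columns `duration_h` and `T_C`, e.g. from
#'   `read_od_table(path, "profile")`.
#' @return A [temperature_profile()].
#' @export
as_temperature_profile <- function(df) {
  temperature_profile(df$T_C, df$duration_h)
}
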