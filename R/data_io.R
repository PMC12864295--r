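# Measurement and covariate table input/output.
#
# Canonical long (tidy) layout: one row per egg pool x analyte, with the
# censoring metadata (MLOD, MLOQ, detect flag) carried on every row because
# detection limits vary by analyte and year. Censored rows have a null
# concentration: a value below the detection limit is never carried as truth.

measurement_cols <- c(colony_id = "colony_id", region = "region",
                      year = "year", pool_id = "pool_id", n_eggs = "n_eggs",
                      analyte = "analyte", conc = "conc_ng_g_ww",
                      mlod = "mlod_ng_g", mloq = "mloq_ng_g",
                      detected = "detected")

covariate_cols <- c(colony_id = "colony_id", year = "year",
                    egg_mass = "egg_mass_g", length = "length_cm",
                    breadth = "breadth_cm", pct_lipid = "pct_lipid")

#' Read a long-format measurement table
#'
#' Reads `measurements.csv` (columns `colony_id, region, year, pool_id,
#' n_eggs, analyte, conc_ng_g_ww, mlod_ng_g, mloq_ng_g, detected`) and
#' validates every row: known analyte and region, positive MLOD, MLOQ >=
#' MLOD, pool size 2-15 eggs, non-negative concentration for detected rows
#' and a null (or `"<MLOD"`-style) concentration for censored rows.
#' Validation never drops rows silently; the first offending rows are named
#' with their line number and field.
#'
#' @param path CSV file path. Lines starting with `#` are ignored.
#' @param config a [study_config()] (reserved for panel overrides).
#' @return data.frame with internal column names `colony_id, region, year,
#'   pool_id, n_eggs, analyte, conc, mlod, mloq, detected`; censored rows
#'   have `conc = NA`.
#' @export
read_measurements <- function(path, config = study_config()) {
  if (!file.exists(path)) abort("measurement file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#",
                        colClasses = "character")
  missing <- setdiff(unname(measurement_cols), names(df))
  if (length(missing))
    abort("measurement file is missing column(s): ",
          paste(missing, collapse = ", "))
  df <- df[, unname(measurement_cols)]
  names(df) <- names(measurement_cols)

  # "<MLOD"-style entries mean censored; parse to NA before numeric coercion
  below <- grepl("^\\s*<", df$conc)
  df$conc[below] <- NA
  df$conc[df$conc == ""] <- NA

  num <- function(col) suppressWarnings(as.numeric(df[[col]]))
  df$year <- num("year"); df$n_eggs <- num("n_eggs")
  df$conc <- num("conc"); df$mlod <- num("mlod"); df$mloq <- num("mloq")
  df$detected <- toupper(trimws(df$detected)) %in% c("TRUE", "T", "1", "YES")

  validate_measurements(df, panel = hfr_panel())
  df$year <- as.integer(df$year)
  df$n_eggs <- as.integer(df$n_eggs)
  df$conc[!df$detected] <- NA_real_
  df
}

# row-level invariant checks; errors name the offending line and field
validate_measurements <- function(df, panel = hfr_panel()) {
  line <- seq_len(nrow(df)) + 1L  # +1 for the header line
  fail <- function(rows, field, why) {
    if (any(rows, na.rm = TRUE)) {
      i <- which(rows)[1]
      abort(sprintf("invalid measurement row (line %d, field '%s'): %s",
                    line[i], field, why))
    }
  }
  fail(!(df$analyte %in% panel), "analyte",
       paste0("unknown analyte '", df$analyte[which(!(df$analyte %in% panel))[1]],
              "'; panel is: ", paste(panel, collapse = ", ")))
  fail(!(df$region %in% region_levels()), "region",
       paste0("region must be one of: ", paste(region_levels(), collapse = ", ")))
  fail(is.na(df$year) | df$year != floor(df$year), "year",
       "year must be an integer calendar year")
  fail(is.na(df$n_eggs) | df$n_eggs < 2 | df$n_eggs > 15, "n_eggs",
       "pool size must be an integer between 2 and 15 eggs")
  fail(is.na(df$mlod) | df$mlod <= 0, "mlod", "MLOD must be > 0")
  fail(is.na(df$mloq) | df$mloq < df$mlod, "mloq", "MLOQ must be >= MLOD")
  fail(df$detected & (is.na(df$conc) | df$conc < 0), "conc",
       "detected rows need a non-negative concentration")
  fail(!df$detected & !is.na(df$conc), "conc",
       "censored rows must not carry a numeric concentration")
  invisible(df)
}

#' Write a measurement table
#'
#' Inverse of [read_measurements()]: values are printed at 10 significant
#' digits so that a write/read cycle is lossless at the printed precision,
#' and censored rows are written with an empty concentration field.
#'
#' @param records measurement data.frame (internal column names).
#' @param path output CSV path.
#' @param comments optional character vector written as `#` header lines.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(records, path, comments = character()) {
  out <- data.frame(
    colony_id = records$colony_id, region = records$region,
    year = records$year, pool_id = records$pool_id, n_eggs = records$n_eggs,
    analyte = records$analyte, conc_ng_g_ww = fmt_num(records$conc),
    mlod_ng_g = fmt_num(records$mlod), mloq_ng_g = fmt_num(records$mloq),
    detected = records$detected, stringsAsFactors = FALSE)
  write_csv_commented(out, path, comments)
  invisible(path)
}

#' Read or write an egg morphometry / lipid covariate table
#'
#' Columns `colony_id, year, egg_mass_g, length_cm, breadth_cm, pct_lipid`.
#' All values must be strictly positive where present; missing values are
#' allowed (egg measurements were only recorded in part of the programme).
#'
#' @param path CSV file path.
#' @return data.frame with internal names `colony_id, year, egg_mass, length,
#'   breadth, pct_lipid`.
#' @export
read_covariates <- function(path) {
  if (!file.exists(path)) abort("covariate file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  missing <- setdiff(unname(covariate_cols), names(df))
  if (length(missing))
    abort("covariate file is missing column(s): ", paste(missing, collapse = ", "))
  df <- df[, unname(covariate_cols)]
  names(df) <- names(covariate_cols)
  for (col in c("egg_mass", "length", "breadth", "pct_lipid")) {
    bad <- !is.na(df[[col]]) & df[[col]] <= 0
    if (any(bad))
      abort(sprintf("invalid covariate row (line %d, field '%s'): %s",
                    which(bad)[1] + 1L, covariate_cols[[col]],
                    "values must be strictly positive when present"))
  }
  df$year <- as.integer(df$year)
  df
}

#' @rdname read_covariates
#' @param records covariate data.frame (internal column names).
#' @param comments optional `#` header lines.
#' @export
write_covariates <- function(records, path, comments = character()) {
  out <- data.frame(
    colony_id = records$colony_id, year = records$year,
    egg_mass_g = fmt_num(records$egg_mass), length_cm = fmt_num(records$length),
    breadth_cm = fmt_num(records$breadth), pct_lipid = fmt_num(records$pct_lipid),
    stringsAsFactors = FALSE)
  write_csv_commented(out, path, comments)
  invisible(path)
}
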