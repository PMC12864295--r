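#' Round half away from zero
#'
#' Integer rounding where exact halves move away from zero (2.5 -> 3,
#' -2.5 -> -3), the convention used when reporting percent annual change.
#' Base `round()` rounds half to even and is not what printed percentages use.
#'
#' @param x numeric vector.
#' @return numeric vector of rounded values.
#' @export
#' @examples
#' round_half_away(c(2.5, -2.5, 120.33))
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

# stop() with call. = FALSE everywhere; keeps error messages user-facing
abort <- function(...) stop(..., call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

# stage-prefixed, timestamped log line (pipeline reporting)
log_stage <- function(stage, ...) {
  message(sprintf("[%s] %s %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  stage, paste0(..., collapse = "")))
}

# deterministic 31-bit sub-seed from a base seed and a character key, so
# per-colony draws do not depend on the order colonies appear in a design
derive_seed <- function(seed, key) {
  h <- 0
  for (k in utf8ToInt(key)) h <- (h * 31 + k) %% 2147483647
  as.integer((h + seed) %% 2147483647)
}

# write a data.frame as CSV with '#'-prefixed header comment lines
write_csv_commented <- function(df, path, comments = character()) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  if (length(comments)) writeLines(paste0("# ", comments), con)
  utils::write.table(df, con, sep = ",", row.names = FALSE, quote = FALSE,
                     na = "")
  invisible(path)
}

# numeric formatting used by the writers: up to 10 significant digits keeps
# one write/read cycle lossless at the precision we print
fmt_num <- function(x) {
  out <- ifelse(is.na(x), "", sprintf("%.10g", x))
  out
}
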