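#' Study configuration
#'
#' Central configuration object shared by all pipeline stages. All arguments
#' have the programme defaults; any subset may be overridden.
#'
#' @param alpha significance cutoff for all tests (default 0.05).
#' @param detection_threshold_colony minimum detection fraction at a colony
#'   for non-detects of an analyte to receive maximum-likelihood replacement
#'   values; below it censored observations are set to zero (default 0.50,
#'   inclusive: exactly 50 percent detection imputes).
#' @param detection_threshold_sum minimum study-wide detection fraction for a
#'   lower-brominated congener to enter the PBDE sum (default 0.03).
#' @param min_years_breakpoint minimum number of monitored years for a
#'   breakpoint model to be attempted (default 6).
#' @param min_seg_points minimum number of observed years strictly on each
#'   side of an admissible breakpoint (default 2).
#' @param grid_fallback logical; rescue a non-convergent breakpoint
#'   iteration with an exhaustive profile-grid search (default FALSE:
#'   non-convergence means no breakpoint model, and the linear fit is
#'   reported, which keeps the slope-change test calibrated).
#' @param seed integer seed governing all simulation draws.
#' @param impute_by_year logical; group the detection policy by colony x
#'   analyte x year instead of colony x analyte pooled over years
#'   (default FALSE: a colony's detection rate is computed across all years).
#' @param select_use_aic,select_use_delta components of the breakpoint
#'   selection criterion: the segmented model replaces the linear one when its
#'   AIC is lower (`select_use_aic`) and the slope-change test is significant
#'   at `alpha` (`select_use_delta`). Both on by default.
#' @param class_sig which p value gates trend-model classification for fitted
#'   series: `"t_value"` (the reported first-segment slope test, the printed
#'   convention) or `"delta"` (the slope-change test).
#' @param milestones milestone registry data.frame (see
#'   [default_milestones()]) or path to a CSV.
#' @param half_min_offset logical; replace zero class means by half the
#'   minimum positive mean before log transform instead of excluding them
#'   (default FALSE: zero-mean colony-years are flagged and excluded from
#'   trend fitting).
#' @return list of class `study_config`.
#' @export
#' @examples
#' cfg <- study_config(alpha = 0.01)
#' cfg$alpha
study_config <- function(alpha = 0.05,
                         detection_threshold_colony = 0.50,
                         detection_threshold_sum = 0.03,
                         min_years_breakpoint = 6L,
                         min_seg_points = 2L,
                         grid_fallback = FALSE,
                         seed = 1L,
                         impute_by_year = FALSE,
                         select_use_aic = TRUE,
                         select_use_delta = TRUE,
                         class_sig = c("t_value", "delta"),
                         milestones = NULL,
                         half_min_offset = FALSE) {
  class_sig <- match.arg(class_sig)
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha >= 1)
    abort("alpha must be a single number in (0, 1)")
  for (nm in c("detection_threshold_colony", "detection_threshold_sum")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || v <= 0 || v >= 1)
      abort(nm, " must be a single number in (0, 1)")
  }
  if (min_years_breakpoint < 4) abort("min_years_breakpoint must be at least 4")
  if (min_seg_points < 1) abort("min_seg_points must be at least 1")
  if (is.character(milestones)) milestones <- default_milestones(milestones)
  if (is.null(milestones)) milestones <- default_milestones()
  cfg <- list(alpha = alpha,
              detection_threshold_colony = detection_threshold_colony,
              detection_threshold_sum = detection_threshold_sum,
              min_years_breakpoint = as.integer(min_years_breakpoint),
              min_seg_points = as.integer(min_seg_points),
              grid_fallback = isTRUE(grid_fallback),
              seed = as.integer(seed),
              impute_by_year = isTRUE(impute_by_year),
              select_use_aic = isTRUE(select_use_aic),
              select_use_delta = isTRUE(select_use_delta),
              class_sig = class_sig,
              milestones = milestones,
              half_min_offset = isTRUE(half_min_offset))
  class(cfg) <- "study_config"
  cfg
}

#' Read and validate a pipeline configuration file
#'
#' Reads a YAML file whose keys are the arguments of [study_config()]
#' (`milestones` may be a path to a milestone CSV), fills defaults for absent
#' keys and rejects unknown keys.
#'
#' @param path YAML file path, or `NULL` for all defaults.
#' @return a validated `study_config` object.
#' @export
validate_config <- function(path = NULL) {
  if (is.null(path)) return(study_config())
  if (!file.exists(path)) abort("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) abort("config file must contain a YAML mapping")
  known <- names(formals(study_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    abort("unknown config key(s): ", paste(unknown, collapse = ", "),
          "; known keys: ", paste(known, collapse = ", "))
  do.call(study_config, raw)
}

#' @export
print.study_config <- function(x, ...) {
  cat("Study configuration\n")
  cat(sprintf("  alpha: %g\n", x$alpha))
  cat(sprintf("  detection thresholds: colony %.2f, congener-sum %.2f\n",
              x$detection_threshold_colony, x$detection_threshold_sum))
  cat(sprintf("  breakpoint: min %d years, min %d points per segment\n",
              x$min_years_breakpoint, x$min_seg_points))
  cat(sprintf("  selection: AIC=%s, delta-test=%s; classification gate: %s\n",
              x$select_use_aic, x$select_use_delta, x$class_sig))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}

# one-line config snapshot embedded in output CSV headers
config_snapshot <- function(cfg) {
  sprintf(paste0("config: alpha=%g colony_thresh=%g sum_thresh=%g ",
                 "min_years=%d min_seg=%d grid_fb=%s seed=%d by_year=%s aic=%s delta=%s sig=%s"),
          cfg$alpha, cfg$detection_threshold_colony, cfg$detection_threshold_sum,
          cfg$min_years_breakpoint, cfg$min_seg_points, cfg$grid_fallback, cfg$seed,
          cfg$impute_by_year, cfg$select_use_aic, cfg$select_use_delta,
          cfg$class_sig)
}
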