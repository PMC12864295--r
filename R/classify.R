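# Trend-model classification against Stockholm Convention milestones.
#
# Five trend models describe a colony x HFR-class series: IT (increasing
# after a breakpoint), LI (declining after a breakpoint later than the
# listing year), NI (declining after a breakpoint between nomination and
# listing), EI (declining after a breakpoint earlier than nomination) and
# CT (no breakpoint; significant monotone linear trend). Non-significant
# fits are labelled NS.

#' Classify a trend fit against the milestone registry
#'
#' A significant segmented fit with a positive post-breakpoint slope is IT;
#' with a negative post-breakpoint slope the breakpoint year decides LI
#' (after listing), NI (nomination year through listing year, both ends
#' inclusive) or EI (before nomination). A significant linear fit is CT;
#' anything non-significant is NS. The breakpoint is compared as its point
#' estimate; its SE is reported but never used here.
#'
#' @param fit an `hfr_trend` object, or `NULL` when raw fields are supplied.
#' @param hfr_class HFR class of the series (must appear in `milestones`).
#' @param milestones registry data.frame (see [default_milestones()]).
#' @param alpha significance cutoff.
#' @param p significance p value; defaults to the fit's gating p value (the
#'   reported slope t test). Supply explicitly when classifying published
#'   table rows.
#' @param fit_type,psi,slope_after raw fields, used when `fit` is `NULL`.
#' @return character label: `"IT"`, `"LI"`, `"NI"`, `"EI"`, `"CT"` or `"NS"`.
#' @export
#' @examples
#' classify_trend(NULL, "HBCDD", fit_type = "segmented", psi = 2011,
#'                slope_after = -0.07, p = 0.025)  # "NI"
classify_trend <- function(fit = NULL, hfr_class, milestones = default_milestones(),
                           alpha = 0.05, p = NULL, fit_type = NULL,
                           psi = NULL, slope_after = NULL) {
  if (!is.null(fit)) {
    stopifnot(inherits(fit, "hfr_trend"))
    fit_type <- fit$fit_type
    psi <- fit$psi
    slope_after <- if (fit_type == "segmented") fit$slope_after else fit$slope
    if (is.null(p)) p <- fit$p_value
  }
  row <- milestones[milestones$hfr_class == hfr_class, ]
  if (nrow(row) != 1)
    abort("no milestone entry for class '", hfr_class, "'")
  if (identical(fit_type, "failed")) return("NS")
  if (is.null(p) || is.na(p) || p > alpha) return("NS")
  if (fit_type == "linear") return("CT")
  if (slope_after > 0) return("IT")
  if (psi > row$listing_year) return("LI")
  if (psi >= row$nomination_year) return("NI")
  "EI"
}

#' Percent annual change implied by a ln-scale slope
#'
#' A slope of `beta` ln-units per year corresponds to a multiplicative
#' change of `exp(beta)` per year, i.e. a signed percent annual change of
#' `(exp(beta) - 1) * 100`. Reported magnitudes are rounded half away from
#' zero to whole percent (see [format_percent_change()]).
#'
#' @param beta ln-scale slope(s), per year.
#' @return signed percent annual change, unrounded.
#' @export
#' @examples
#' percent_annual_change(0.79)   # +120.3%/yr
#' percent_annual_change(-0.42)  # -34.3%/yr
percent_annual_change <- function(beta) {
  (exp(beta) - 1) * 100
}

#' @rdname percent_annual_change
#' @return `format_percent_change()`: character, e.g. `"120% annual increase"`.
#' @export
format_percent_change <- function(beta) {
  pct <- percent_annual_change(beta)
  word <- ifelse(pct > 0, "increase", ifelse(pct < 0, "decrease", "change"))
  sprintf("%d%% annual %s", as.integer(round_half_away(abs(pct))), word)
}

#' Classify and tally a table of trend fits
#'
#' Takes one fitted row per colony x HFR class (the shape of the packaged
#' published table, or of [pipeline][run_pipeline()] output): columns
#' `hfr_class, colony, fit_type` (or `psi` = NA for linear), `psi,
#' slope_before, slope_after, p_value`. Labels every row and returns the
#' labelled table plus the summary tallies: total comparisons,
#' non-significant count, counts per label, and per-class counts of
#' consistent significant declines.
#'
#' @param fits data.frame as described.
#' @param milestones milestone registry.
#' @param alpha significance cutoff.
#' @return list with `table` (input plus `label` column) and `tallies`.
#' @export
#' @examples
#' res <- tabulate_trends(hfr_trend_table())
#' res$tallies$n_ns
tabulate_trends <- function(fits, milestones = default_milestones(),
                            alpha = 0.05) {
  if (!"fit_type" %in% names(fits))
    fits$fit_type <- ifelse(is.na(fits$psi), "linear", "segmented")
  key <- paste(fits$hfr_class, fits$colony)
  if (anyDuplicated(key))
    abort("duplicate colony x class row: ", key[duplicated(key)][1])
  n <- nrow(fits)
  labels <- character(n)
  for (i in seq_len(n)) {
    labels[i] <- classify_trend(
      NULL, hfr_class = fits$hfr_class[i], milestones = milestones,
      alpha = alpha, p = fits$p_value[i], fit_type = fits$fit_type[i],
      psi = fits$psi[i], slope_after = fits$slope_after[i])
  }
  fits$label <- labels
  ct_decline <- labels == "CT" & fits$slope_before < 0
  per_class_ct <- if (n) table(factor(fits$hfr_class[ct_decline],
                                      levels = unique(fits$hfr_class))) else
    table(character())
  tallies <- list(
    n_comparisons = n,
    n_ns = sum(labels == "NS"),
    n_significant = sum(labels != "NS"),
    n_ct_decline = sum(ct_decline),
    per_label = table(factor(labels, levels = c("IT", "LI", "NI", "EI",
                                                "CT", "NS"))),
    ct_decline_by_class = per_class_ct)
  list(table = fits, tallies = tallies)
}
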