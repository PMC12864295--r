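#' Analyte panel, HFR classes, regions and reference-analyte map
#'
#' The monitoring panel holds 13 PBDE congeners (BDE-17 through BDE-209),
#' alpha-HBCDD (total HBCDD is quantified as the alpha diastereomer because the
#' beta and gamma forms thermally isomerize during GC analysis) and the two
#' Dechlorane Plus isomers. Downstream analyses work on four HFR classes:
#' the sum of lower-brominated congeners (`Sum11PBDE`, a proxy for the
#' commercial penta- and octa-BDE mixtures), `BDE209` (proxy for the
#' commercial deca-BDE mixture, analyzed separately), `HBCDD` and `SumDP`
#' (syn + anti isomers).
#'
#' @return `hfr_panel()`: character vector of analyte codes.
#' @export
hfr_panel <- function() {
  c(pbde_congeners(), "BDE-209", "alpha-HBCDD", "syn-DP", "anti-DP")
}

#' @rdname hfr_panel
#' @param include_209 logical; include BDE-209 in the congener list.
#' @export
pbde_congeners <- function(include_209 = FALSE) {
  lower <- c("BDE-17", "BDE-28", "BDE-47", "BDE-49", "BDE-66", "BDE-85",
             "BDE-99", "BDE-100", "BDE-138", "BDE-153", "BDE-183", "BDE-190")
  if (include_209) c(lower, "BDE-209") else lower
}

#' @rdname hfr_panel
#' @export
hfr_classes <- function() {
  c("Sum11PBDE", "BDE209", "HBCDD", "SumDP")
}

#' @rdname hfr_panel
#' @export
region_levels <- function() {
  c("GreatLakesNiagara", "StLawrence", "Atlantic", "Arctic")
}

#' Reference-analyte map for non-detect replacement ranking
#'
#' Replacement values for censored observations are rank-ordered by the
#' concentration of a frequently detected reference analyte measured on the
#' same pools: BDE-99 for the PBDE congeners (including BDE-209) and syn-DP
#' for HBCDD and anti-DP. The two reference analytes cross-reference each
#' other so the map is total and never self-referential.
#'
#' @return named character vector: `map[analyte]` is its reference analyte.
#' @export
reference_map <- function() {
  dep_pbde <- setdiff(pbde_congeners(include_209 = TRUE), "BDE-99")
  m <- c(
    stats::setNames(rep("BDE-99", length(dep_pbde)), dep_pbde),
    "alpha-HBCDD" = "syn-DP",
    "anti-DP"     = "syn-DP",
    "BDE-99"      = "syn-DP",
    "syn-DP"      = "BDE-99"
  )
  stopifnot(!any(names(m) == m))
  m
}

# analyte -> HFR class membership used when summing pools into classes
analyte_class_map <- function(sum_congeners = setdiff(pbde_congeners(), "BDE-190")) {
  m <- c(
    stats::setNames(rep("Sum11PBDE", length(sum_congeners)), sum_congeners),
    "BDE-209"     = "BDE209",
    "alpha-HBCDD" = "HBCDD",
    "syn-DP"      = "SumDP",
    "anti-DP"     = "SumDP"
  )
  m
}

#' Stockholm Convention milestone registry
#'
#' Nomination and listing years under Annex A of the Stockholm Convention for
#' each HFR class. The penta- and octa-BDE commercial mixtures were nominated
#' separately in 2005 and 2006 and listed together in 2009; the registry keeps
#' the earliest nomination year. HBCDD: nominated 2008, listed 2013. Deca-BDE
#' (BDE-209): nominated 2013, listed 2017. Dechlorane Plus: nominated 2019,
#' listed 2023.
#'
#' @param path optional CSV with columns `hfr_class, nomination_year,
#'   listing_year` overriding the defaults.
#' @return data.frame with columns `hfr_class`, `nomination_year`,
#'   `listing_year`.
#' @export
#' @examples
#' default_milestones()
default_milestones <- function(path = NULL) {
  if (is.null(path)) {
    df <- data.frame(
      hfr_class       = c("Sum11PBDE", "HBCDD", "BDE209", "SumDP"),
      nomination_year = c(2005L, 2008L, 2013L, 2019L),
      listing_year    = c(2009L, 2013L, 2017L, 2023L),
      stringsAsFactors = FALSE
    )
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
    need <- c("hfr_class", "nomination_year", "listing_year")
    if (!all(need %in% names(df)))
      abort("milestone table must have columns: ", paste(need, collapse = ", "))
  }
  if (any(df$nomination_year > df$listing_year))
    abort("milestone registry invalid: nomination_year must not exceed listing_year")
  df
}

#' Published segmented-trend table for the 2008-2023 gull egg programme
#'
#' Loads the packaged reference table of breakpoint-regression results for the
#' four HFR classes at 17 Canadian herring gull colonies (2008-2023): number
#' of years analyzed, breakpoint year and SE (NA where no breakpoint model
#' could be fitted and a plain linear regression is reported), segment slopes
#' (ln ng/g per year) with SEs, the reported t statistic and p value, and the
#' published trend-model label for significant fits. This table is the
#' classification fixture: it lets the milestone classifier and the summary
#' tallies be exercised against published results without the underlying
#' concentration data.
#'
#' @return data.frame, one row per colony x HFR class (68 rows).
#' @export
#' @examples
#' tab <- hfr_trend_table()
#' table(tab$hfr_class)
hfr_trend_table <- function() {
  path <- system.file("extdata", "hfr_gull_trends_2008_2023.csv",
                      package = "hfrtrends", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  df$fit_type <- ifelse(is.na(df$psi), "linear", "segmented")
  df
}
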