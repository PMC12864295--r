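# Regional linear mixed model:
#   y_ijk = b0 + b_Region(i) + u_ij + v_k + e_ijk
# for ln concentration of colony j in region i during year k, with Region a
# fixed effect under sum-to-zero contrasts (the intercept is the overall
# mean across regions), random intercepts for colony (nested within region)
# and year, REML estimation, Satterthwaite denominator degrees of freedom
# for the Region F test, an ML likelihood-ratio test against the no-Region
# null, variance-component percentages and back-transformed marginal means.

#' Fit the regional linear mixed model for one HFR class
#'
#' @param data class series (output of [annual_means()], one HFR class):
#'   columns `colony_id, region, year, ln_mean`. Rows with missing `ln_mean`
#'   are dropped.
#' @param hfr_class optional class to subset on when `data` holds several.
#' @param reml fit by REML (default) or ML.
#' @return object of class `region_lmm` wrapping the `lmerModLmerTest` fit.
#' @export
fit_region_lmm <- function(data, hfr_class = NULL, reml = TRUE) {
  if (!is.null(hfr_class)) data <- data[data$hfr_class == hfr_class, ]
  data <- data[!is.na(data$ln_mean), ]
  if (length(unique(data$region)) < 2)
    abort("the regional model needs at least 2 regions")
  if (length(unique(data$year)) < 2)
    abort("the regional model needs at least 2 years")
  d <- data.frame(ln_mean = data$ln_mean,
                  region = factor(data$region,
                                  levels = intersect(region_levels(),
                                                     unique(data$region))),
                  colony = factor(data$colony_id),
                  year_f = factor(data$year))
  fit <- lmerTest::lmer(
    ln_mean ~ region + (1 | colony) + (1 | year_f), data = d, REML = reml,
    contrasts = list(region = "contr.sum"),
    control = lme4::lmerControl(check.conv.singular = lme4::.makeCC(
      action = "message", tol = 1e-4)))
  structure(list(model = fit, data = d, hfr_class = hfr_class,
                 reml = reml, singular = lme4::isSingular(fit)),
            class = "region_lmm")
}

#' @export
print.region_lmm <- function(x, ...) {
  cat(sprintf("Regional LMM%s (%s)\n",
              if (is.null(x$hfr_class)) "" else paste0(" for ", x$hfr_class),
              if (x$reml) "REML" else "ML"))
  print(x$model)
  invisible(x)
}

#' @export
summary.region_lmm <- function(object, ...) summary(object$model, ...)

#' @export
coef.region_lmm <- function(object, ...) lme4::fixef(object$model)

#' @export
logLik.region_lmm <- function(object, ...) stats::logLik(object$model)

#' Likelihood-ratio test for the Region effect
#'
#' Refits the full model and the no-Region null by maximum likelihood (REML
#' log-likelihoods are not comparable across fixed-effect structures) and
#' compares twice the log-likelihood difference to a chi-square with
#' (number of regions - 1) degrees of freedom.
#'
#' @param fit a `region_lmm`.
#' @return list `chi2`, `df`, `p`, plus both ML log-likelihoods.
#' @export
lrt_region <- function(fit) {
  full_ml <- update_ml(fit$model)
  # the null drops the region term; its unused contrast spec draws a warning
  null_ml <- suppressWarnings(stats::update(full_ml, . ~ . - region))
  lrt_nested(full_ml, null_ml, df = nlevels(fit$data$region) - 1L)
}

# shared nested-model LRT (also serves fixed-covariate comparisons such as
# full-with-lipid vs reduced): both fits must be ML on the same data
lrt_nested <- function(full, null, df = NULL) {
  ll_full <- as.numeric(stats::logLik(full))
  ll_null <- as.numeric(stats::logLik(null))
  if (is.null(df))
    df <- attr(stats::logLik(full), "df") - attr(stats::logLik(null), "df")
  if (df < 1) abort("models are not nested (no fixed-effect difference)")
  chi2 <- max(2 * (ll_full - ll_null), 0)
  list(chi2 = chi2, df = df, p = stats::pchisq(chi2, df, lower.tail = FALSE),
       logLik_full = ll_full, logLik_null = ll_null)
}

update_ml <- function(model) {
  if (lme4::isREML(model)) lme4::refitML(model) else model
}

#' Wald F test of the Region effect with Satterthwaite df
#'
#' @param fit a `region_lmm`.
#' @return list `F`, `ndf`, `ddf` (Satterthwaite), `p`, and a flag when a
#'   variance component sits on the boundary (the approximation is then
#'   only indicative).
#' @export
anova_region <- function(fit) {
  an <- stats::anova(fit$model, type = 3, ddf = "Satterthwaite")
  row <- an["region", ]
  list(F = row[["F value"]], ndf = row[["NumDF"]], ddf = row[["DenDF"]],
       p = row[["Pr(>F)"]], boundary = fit$singular)
}

#' Variance-component percentages
#'
#' Each random component (colony within region, year, residual) as a
#' percentage of their summed variance. Fixed effects describe the mean
#' structure and are not part of this total.
#'
#' @param fit a `region_lmm`.
#' @return list `colony_pct`, `year_pct`, `residual_pct`, and the raw
#'   variances in `components`.
#' @export
variance_pct <- function(fit) {
  vc <- as.data.frame(lme4::VarCorr(fit$model))
  v <- stats::setNames(vc$vcov, vc$grp)
  comps <- c(colony = unname(v["colony"]), year = unname(v["year_f"]),
             residual = unname(v["Residual"]))
  if (all(comps == 0)) abort("all variance components are zero")
  pct <- 100 * comps / sum(comps)
  list(colony_pct = unname(pct["colony"]), year_pct = unname(pct["year"]),
       residual_pct = unname(pct["residual"]), components = comps)
}

#' Region marginal means, back-transformed to ng/g
#'
#' Estimated marginal means per region on the ln scale with Wald intervals,
#' back-transformed by exponentiation (the interval of the median on the
#' raw scale). Under sum-to-zero contrasts the region effect is the
#' deviation from the overall mean, so the effect-vs-overall comparison is
#' the test of each region effect against zero; p values are reported both
#' unadjusted and Holm-adjusted.
#'
#' @param fit a `region_lmm`.
#' @param level confidence level.
#' @return data.frame: region, ln-scale mean and SE and df, back-transformed
#'   mean and interval (ng/g), effect vs overall mean, p values.
#' @export
region_emmeans <- function(fit, level = 0.95) {
  emm <- emmeans::emmeans(fit$model, ~region, lmer.df = "satterthwaite")
  s <- as.data.frame(summary(emm, level = level))
  eff <- as.data.frame(summary(emmeans::contrast(emm, method = "eff",
                                                 adjust = "none")))
  holm <- as.data.frame(summary(emmeans::contrast(emm, method = "eff",
                                                  adjust = "holm")))
  data.frame(
    region = as.character(s$region),
    emmean_ln = s$emmean, se_ln = s$SE, df = s$df,
    mean_ng_g = exp(s$emmean),
    lower_ng_g = exp(s$lower.CL), upper_ng_g = exp(s$upper.CL),
    effect_ln = eff$estimate,
    p_vs_overall = eff$p.value, p_vs_overall_holm = holm$p.value,
    stringsAsFactors = FALSE)
}
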