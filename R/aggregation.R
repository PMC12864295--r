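# Analysis-ready class series: congener selection and summation, annual
# arithmetic means, natural-log transform, egg volume and covariate
# screening.

#' Select the congeners entering the PBDE sum
#'
#' Retains each lower-brominated congener (BDE-17 through BDE-183, and
#' BDE-190) whose study-wide detection fraction reaches `threshold`;
#' BDE-209 is always analyzed separately and never enters the sum. With the
#' default 3 percent rule and typical monitoring data BDE-190 drops out, leaving
#' the 11-congener sum.
#'
#' @param measurements measurement data.frame spanning the full study.
#' @param threshold minimum detection fraction (default from config, 0.03).
#' @return character vector of included congener codes.
#' @export
select_sum_congeners <- function(measurements, threshold = 0.03) {
  cands <- pbde_congeners()
  present <- intersect(cands, unique(measurements$analyte))
  if (length(present) == 0) abort("no PBDE congeners present in the data")
  keep <- vapply(present, function(a) {
    detection_rate(measurements$detected[measurements$analyte == a]) >= threshold
  }, logical(1))
  present[keep]
}

#' Per-pool HFR class values
#'
#' Sums completed (imputed) analyte concentrations into the four HFR
#' classes for every pool: `Sum11PBDE` = sum of the selected congeners,
#' `SumDP` = syn + anti isomers, `BDE209` and `HBCDD` pass through.
#'
#' @param measurements completed measurement data.frame (no missing
#'   concentrations; run [apply_detection_policy()] first).
#' @param sum_congeners congeners entering the PBDE sum, from
#'   [select_sum_congeners()].
#' @return data.frame `colony_id, region, year, pool_id, hfr_class, conc`.
#' @export
class_sums <- function(measurements,
                       sum_congeners = setdiff(pbde_congeners(), "BDE-190")) {
  if (anyNA(measurements$conc))
    abort("class_sums requires completed data: run apply_detection_policy() first")
  cmap <- analyte_class_map(sum_congeners)
  m <- measurements[measurements$analyte %in% names(cmap), ]
  m$hfr_class <- unname(cmap[m$analyte])
  # every pool must carry every analyte of its class sum
  pkey <- paste(m$colony_id, m$year, m$pool_id, sep = "|")
  for (cls in unique(m$hfr_class)) {
    members <- names(cmap)[cmap == cls]
    sub_i <- m$hfr_class == cls
    counts <- table(pkey[sub_i])
    short <- names(counts)[counts < length(members)]
    if (length(short)) {
      have <- m$analyte[sub_i & pkey == short[1]]
      abort(sprintf("pool '%s' is missing analyte(s) %s for class %s",
                    short[1],
                    paste(setdiff(members, have), collapse = ", "), cls))
    }
  }
  agg <- stats::aggregate(conc ~ colony_id + region + year + pool_id + hfr_class,
                          data = m, FUN = sum)
  agg[order(agg$hfr_class, agg$colony_id, agg$year, agg$pool_id), ]
}

#' Annual arithmetic means of class values
#'
#' Arithmetic mean over the pools of each colony-year (the single pool value
#' when only one pool was analyzed), with the natural-log transform applied
#' to the mean. Colony-years whose mean is exactly zero (all non-detects
#' zeroed under the detection policy) have no defined log and are flagged
#' `zero_mean` for exclusion from trend fitting; optionally they are
#' replaced by half the minimum positive mean of the same series.
#'
#' @param pool_values output of [class_sums()].
#' @param half_min_offset logical; apply the half-minimum replacement
#'   instead of flagging (default FALSE).
#' @return data.frame `colony_id, region, hfr_class, year, mean_conc,
#'   ln_mean, n_pools, flag`.
#' @export
annual_means <- function(pool_values, half_min_offset = FALSE) {
  agg <- stats::aggregate(conc ~ colony_id + region + hfr_class + year,
                          data = pool_values,
                          FUN = function(v) c(mean = mean(v), n = length(v)))
  out <- data.frame(colony_id = agg$colony_id, region = agg$region,
                    hfr_class = agg$hfr_class, year = agg$year,
                    mean_conc = agg$conc[, "mean"],
                    n_pools = as.integer(agg$conc[, "n"]),
                    stringsAsFactors = FALSE)
  out$flag <- ifelse(out$mean_conc == 0, "zero_mean", "")
  if (half_min_offset) {
    for (i in which(out$mean_conc == 0)) {
      same <- out$hfr_class == out$hfr_class[i] & out$colony_id == out$colony_id[i]
      pos <- out$mean_conc[same & out$mean_conc > 0]
      if (length(pos)) {
        out$mean_conc[i] <- min(pos) / 2
        out$flag[i] <- "half_min"
      }
    }
  }
  out$ln_mean <- ifelse(out$mean_conc > 0, log(out$mean_conc), NA_real_)
  out <- out[order(out$hfr_class, out$colony_id, out$year),
             c("colony_id", "region", "hfr_class", "year", "mean_conc",
               "ln_mean", "n_pools", "flag")]
  rownames(out) <- NULL
  out
}

#' Egg volume from length and breadth
#'
#' Ryder's formula `volume = k * l * d^2` with `k = 0.489`.
#'
#' @param l egg length (cm).
#' @param d egg breadth (cm).
#' @param k dimensionless shape constant.
#' @return volume in cm^3.
#' @export
#' @examples
#' egg_volume(7.2, 5.0)  # 88.02
egg_volume <- function(l, d, k = 0.489) {
  if (any(l <= 0) || any(d <= 0)) abort("egg dimensions must be > 0")
  k * l * d^2
}

#' Screen a covariate against a colony's class series
#'
#' Pearson correlation between ln mean concentration and the covariate
#' (colony-year means), falling back to a Spearman rank correlation when the
#' residuals of the linear fit fail a Shapiro-Wilk normality check at
#' `alpha`. The decision is a pure function of the data and is recorded in
#' the result. Screening is reported only; covariates are never fed into
#' the trend models.
#'
#' @param ln_mean ln mean concentrations.
#' @param covariate matched covariate means (egg mass, volume, or percent lipid).
#' @param alpha normality-test cutoff (default 0.05).
#' @return list: `method` ("pearson" / "spearman"), `estimate`, `p.value`,
#'   `n`, `normality_p`, `flag`.
#' @export
covariate_screen <- function(ln_mean, covariate, alpha = 0.05) {
  ok <- stats::complete.cases(ln_mean, covariate)
  x <- covariate[ok]; y <- ln_mean[ok]
  n <- length(x)
  if (n < 4) abort("covariate screening needs at least 4 paired values")
  if (stats::sd(x) == 0)
    return(list(method = "none", estimate = NA_real_, p.value = NA_real_,
                n = n, normality_p = NA_real_, flag = "constant_covariate"))
  res <- stats::resid(stats::lm(y ~ x))
  norm_p <- tryCatch(stats::shapiro.test(res)$p.value, error = function(e) NA)
  # an (essentially) exact linear fit leaves degenerate residuals: the
  # normality condition is not violated, keep Pearson
  normal <- is.na(norm_p) || norm_p >= alpha || stats::sd(res) < 1e-10
  method <- if (normal) "pearson" else "spearman"
  ct <- suppressWarnings(stats::cor.test(x, y, method = method, exact = FALSE))
  list(method = method, estimate = unname(ct$estimate), p.value = ct$p.value,
       n = n, normality_p = norm_p, flag = "")
}
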