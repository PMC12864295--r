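# Non-detect policy: left-censored log-normal maximum likelihood with
# quantile-normal replacement values, rank-ordered by a reference analyte.
#
# Per colony and analyte: when at least half of the samples have reportable
# concentrations, a log-normal distribution is fitted by ML (detected values
# contribute density terms; censored values contribute the cumulative
# probability at their detection limit) and the censored observations receive
# the smallest plotting-position quantiles of the fitted distribution,
# assigned in ascending order of a frequently-detected reference analyte
# measured on the same pools. Below 50% detection no replacement is
# generated and censored observations are set to zero.

#' Detection rate of a record group
#'
#' @param detected logical vector (or a measurement data.frame with a
#'   `detected` column): one colony x analyte group.
#' @return fraction of records with reportable concentrations, in `[0, 1]`.
#' @export
detection_rate <- function(detected) {
  if (is.data.frame(detected)) detected <- detected$detected
  if (length(detected) == 0) abort("detection_rate: empty record group")
  mean(detected)
}

#' Fit a left-censored log-normal distribution by maximum likelihood
#'
#' Detected concentrations contribute log-normal density terms; censored
#' records contribute the log-normal CDF evaluated at their own detection
#' limit. With no censored records the fit reduces to the closed-form
#' maximum-likelihood moments of the log values (mean, and SD with the 1/n
#' divisor).
#'
#' @param values detected concentrations (ng/g), all > 0; at least 3.
#' @param limits detection limits (ng/g) of the censored records, one per
#'   censored record (may be empty).
#' @return object of class `cenlnorm`: `mu`, `sigma` (ln-scale mean and SD),
#'   `n_total`, `n_censored`, `log_likelihood`, `converged`, `degenerate`.
#' @export
#' @examples
#' x <- exp(rnorm(50, 1, 0.5))
#' fit_censored_lognormal(x[x > 1], rep(1, sum(x <= 1)))
fit_censored_lognormal <- function(values, limits = numeric()) {
  if (length(values) < 3)
    abort("censored log-normal fit needs at least 3 detected values")
  if (any(values <= 0) || any(limits <= 0))
    abort("concentrations and limits must be > 0")
  lx <- log(values)
  mu0 <- mean(lx)
  s0 <- sqrt(mean((lx - mu0)^2))
  out <- list(n_total = length(values) + length(limits),
              n_censored = length(limits))

  if (s0 < 1e-10 && length(limits) == 0) {
    # all detected values identical: sigma at its lower bound
    out <- c(out, list(mu = mu0, sigma = 1e-6, converged = TRUE,
                       degenerate = TRUE))
    out$log_likelihood <- sum(stats::dlnorm(values, mu0, 1e-6, log = TRUE))
    class(out) <- "cenlnorm"
    return(out)
  }

  if (length(limits) == 0) {
    # uncensored ML has the closed form
    out <- c(out, list(mu = mu0, sigma = s0, converged = TRUE,
                       degenerate = FALSE))
    out$log_likelihood <- sum(stats::dlnorm(values, mu0, s0, log = TRUE))
    class(out) <- "cenlnorm"
    return(out)
  }

  nll <- function(par) {
    mu <- par[1]; sigma <- exp(par[2])
    ll <- sum(stats::dlnorm(values, mu, sigma, log = TRUE)) +
      sum(stats::plnorm(limits, mu, sigma, log.p = TRUE))
    if (!is.finite(ll)) return(1e10)
    -ll
  }
  # censoring pulls the naive moments up; start slightly wide
  start <- c(mu0, log(max(s0, 0.1)))
  opt <- stats::optim(start, nll, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  converged <- opt$convergence == 0 && is.finite(opt$value)
  out <- c(out, list(mu = opt$par[1], sigma = exp(opt$par[2]),
                     converged = converged,
                     degenerate = exp(opt$par[2]) < 1e-6))
  out$log_likelihood <- -opt$value
  class(out) <- "cenlnorm"
  out
}

#' @export
print.cenlnorm <- function(x, ...) {
  cat(sprintf("Left-censored log-normal ML fit: mu = %.4f, sigma = %.4f\n",
              x$mu, x$sigma))
  cat(sprintf("  n = %d (%d censored), logLik = %.3f, converged: %s%s\n",
              x$n_total, x$n_censored, x$log_likelihood, x$converged,
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' @export
coef.cenlnorm <- function(object, ...) c(mu = object$mu, sigma = object$sigma)

#' @export
logLik.cenlnorm <- function(object, ...) {
  structure(object$log_likelihood, df = 2, class = "logLik")
}

#' Impute non-detects in one colony x analyte group
#'
#' The `m` censored records receive the `m` smallest plotting-position
#' quantiles of the fitted log-normal, `exp(mu + sigma * qnorm(i/(n+1)))`
#' for `i = 1..m` with `n` the group size, so the completed sample lies on
#' the fitted quantile-normal line. Replacements are assigned in ascending
#' order of the reference-analyte concentration on the same pools (ties and
#' missing references fall back to year/pool order, flagged). Every
#' replacement is kept at or below its record's MLOD (clamped and flagged
#' if a fitted quantile exceeds it) and replacements are unique.
#'
#' @param records measurement data.frame: one colony x analyte group.
#' @param fit a `cenlnorm` fit for the group.
#' @param reference measurement data.frame of the mapped reference analyte
#'   for the same colony (completed or raw), or `NULL`.
#' @return `records` with censored rows filled in, plus a `source` column
#'   (`observed` / `imputed`) and a `flag` column.
#' @export
impute_nondetects <- function(records, fit, reference = NULL) {
  if (!"source" %in% names(records))
    records$source <- ifelse(records$detected, "observed", NA_character_)
  if (!"flag" %in% names(records)) records$flag <- ""
  cens <- which(!records$detected)
  m <- length(cens)
  if (m == 0) return(records)
  stopifnot(inherits(fit, "cenlnorm"))
  n <- nrow(records)
  p <- seq_len(m) / (n + 1)
  repl <- exp(fit$mu + fit$sigma * stats::qnorm(p))  # ascending

  # rank the censored records by reference concentration on the same pools
  key <- paste(records$colony_id, records$year, records$pool_id)
  ref_ok <- FALSE
  if (!is.null(reference) && nrow(reference) > 0) {
    rkey <- paste(reference$colony_id, reference$year, reference$pool_id)
    rconc <- reference$conc[match(key[cens], rkey)]
    ref_ok <- !anyNA(rconc)
  }
  if (ref_ok) {
    ord <- cens[order(rconc, records$year[cens], records$pool_id[cens])]
  } else {
    ord <- cens[order(records$year[cens], records$pool_id[cens])]
    records$flag[cens] <- paste0(records$flag[cens], "ref_fallback;")
  }

  mlods <- records$mlod[ord]
  clamped <- repl > mlods
  repl[clamped] <- mlods[clamped]
  if (any(clamped))
    records$flag[ord[clamped]] <- paste0(records$flag[ord[clamped]], "clamped;")
  # clamping can collapse values onto a shared MLOD; restore strict uniqueness
  if (m > 1) {
    for (i in (m - 1):1) {
      if (repl[i] >= repl[i + 1]) repl[i] <- repl[i + 1] * (1 - 1e-9)
    }
  }
  records$conc[ord] <- repl
  records$source[ord] <- "imputed"
  records
}

#' Apply the colony-level detection policy to a full measurement table
#'
#' Groups records by colony x analyte (or colony x analyte x year when
#' `config$impute_by_year`), computes the detection rate of each group and
#' completes it: groups at or above the colony detection threshold get
#' ML-fitted replacement values ranked by their reference analyte; groups
#' below it have censored records set to zero. Groups whose ML fit cannot be
#' attempted (fewer than 3 detected values) or does not converge also fall
#' back to the zero policy, flagged. Reference analytes (BDE-99, syn-DP) are
#' completed first so dependents can rank against their completed values.
#'
#' @param measurements measurement data.frame.
#' @param config a [study_config()].
#' @return completed measurements with `source` (`observed` / `imputed` /
#'   `zeroed`) and `flag` columns; the per-group audit table (colony,
#'   analyte, n, n_censored, rate, mu, sigma, action) is attached as
#'   attribute `"audit"`.
#' @export
apply_detection_policy <- function(measurements, config = study_config()) {
  m <- measurements
  m$source <- ifelse(m$detected, "observed", NA_character_)
  m$flag <- ""
  refmap <- reference_map()
  # complete the reference analytes first, then their dependents
  analyte_order <- c(intersect(c("BDE-99", "syn-DP"), unique(m$analyte)),
                     setdiff(unique(m$analyte), c("BDE-99", "syn-DP")))
  audit <- list()
  for (analyte in analyte_order) {
    for (colony in unique(m$colony_id[m$analyte == analyte])) {
      sel_colony <- m$colony_id == colony & m$analyte == analyte
      year_groups <- if (config$impute_by_year)
        split(which(sel_colony), m$year[sel_colony]) else
        list(all = which(sel_colony))
      for (rows in year_groups) {
        g <- m[rows, ]
        rate <- detection_rate(g$detected)
        n_cens <- sum(!g$detected)
        fit_mu <- NA_real_; fit_sigma <- NA_real_
        if (n_cens == 0) {
          action <- "complete"
        } else if (rate >= config$detection_threshold_colony &&
                   sum(g$detected) >= 3) {
          fit <- fit_censored_lognormal(g$conc[g$detected],
                                        g$mlod[!g$detected])
          if (fit$converged && !fit$degenerate) {
            ref_analyte <- refmap[[analyte]]
            ref <- m[m$colony_id == colony & m$analyte == ref_analyte, ]
            g <- impute_nondetects(g, fit, reference = ref)
            m[rows, ] <- g
            fit_mu <- fit$mu; fit_sigma <- fit$sigma
            action <- "imputed"
          } else {
            m$conc[rows][!g$detected] <- 0
            m$source[rows][!g$detected] <- "zeroed"
            m$flag[rows][!g$detected] <- "fit_failed;"
            action <- "zeroed_fit_failed"
          }
        } else {
          m$conc[rows][!g$detected] <- 0
          m$source[rows][!g$detected] <- "zeroed"
          action <- if (rate < config$detection_threshold_colony)
            "zeroed_low_detection" else "zeroed_too_few_detects"
        }
        audit[[length(audit) + 1]] <- data.frame(
          colony_id = colony, analyte = analyte, n = nrow(g),
          n_censored = n_cens, detection_rate = rate,
          mu = fit_mu, sigma = fit_sigma, action = action,
          stringsAsFactors = FALSE)
      }
    }
  }
  attr(m, "audit") <- do.call(rbind, audit)
  m
}
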