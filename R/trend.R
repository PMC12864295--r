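# Segmented (breakpoint) trend regression of ln mean concentration on year.
#
# Model: y = b0 + b1 * year + delta * (year - psi)_+  with Gaussian errors
# (a Gaussian identity-link GLM, i.e. least squares). psi is estimated by
# iterative linearization: at a working breakpoint the model is refitted
# with the extra working covariate V = -1[year > psi] and psi is updated by
# gamma_hat / delta_hat, restarted from the observed-year tertiles; when no
# start converges to an admissible breakpoint, an exhaustive profile grid
# over admissible psi values is used instead. Slope tests use n - 4 residual
# degrees of freedom (the breakpoint is an estimated parameter).

as_trend_series <- function(series, y = NULL) {
  if (is.data.frame(series)) {
    if (!all(c("year", "ln_mean") %in% names(series)))
      abort("a trend series needs columns 'year' and 'ln_mean'")
    x <- series$year; yy <- series$ln_mean
  } else {
    x <- series; yy <- y
  }
  ok <- stats::complete.cases(x, yy)
  o <- order(x[ok])
  list(x = as.numeric(x[ok][o]), y = as.numeric(yy[ok][o]))
}

new_hfr_trend <- function(...) structure(list(...), class = "hfr_trend")

#' Linear trend fit (fallback model)
#'
#' Ordinary least squares of ln mean concentration on calendar year with a
#' two-sided t test of the slope. Used when a breakpoint model cannot be
#' fitted or is not selected.
#'
#' @param series data.frame with columns `year`, `ln_mean` (rows with
#'   missing values are dropped), or a numeric year vector.
#' @param y ln mean concentrations when `series` is a vector.
#' @return object of class `hfr_trend` with `fit_type = "linear"`.
#' @export
trend_linear <- function(series, y = NULL) {
  d <- as_trend_series(series, y)
  n <- length(d$x)
  if (n < 3) abort("linear trend fit needs at least 3 years")
  fit <- stats::lm(d$y ~ d$x)
  # degenerate (exactly collinear) data draw a "perfect fit" warning from
  # summary.lm; the zero-RSS case is handled explicitly by the callers
  sm <- suppressWarnings(summary(fit))$coefficients
  rss <- sum(stats::resid(fit)^2)
  ll <- -n / 2 * (log(2 * pi) + log(rss / n) + 1)
  new_hfr_trend(
    fit_type = "linear", n_years = n, x = d$x, y = d$y,
    coefficients = c(intercept = unname(stats::coef(fit)[1]),
                     slope = unname(stats::coef(fit)[2])),
    slope = unname(stats::coef(fit)[2]), slope_se = sm[2, 2],
    t_value = sm[2, 3], p_value = sm[2, 4],
    psi = NA_real_, psi_se = NA_real_,
    slope_before = unname(stats::coef(fit)[2]), se_before = sm[2, 2],
    slope_after = NA_real_, se_after = NA_real_,
    delta = NA_real_, se_delta = NA_real_,
    t_delta = NA_real_, p_delta = NA_real_,
    df_residual = n - 2, rss = rss, log_likelihood = ll, n_par = 3,
    fitted = stats::fitted(fit), converged = TRUE, method = "ols")
}

# least-squares refit at a fixed breakpoint; returns coefficient table with
# df = n - 4 (psi counts as an estimated parameter) and the rss
refit_at_psi <- function(x, y, psi) {
  U <- pmax(x - psi, 0)
  X <- cbind(1, x, U)
  qr_ <- qr(X)
  if (qr_$rank < 3) return(NULL)
  beta <- unname(qr.coef(qr_, y))
  res <- y - X %*% beta
  rss <- sum(res^2)
  n <- length(y)
  df <- n - 4
  sigma2 <- rss / max(df, 1)
  xtx_inv <- chol2inv(qr.R(qr_))
  se <- sqrt(diag(xtx_inv) * sigma2)
  list(beta = beta, se = se, rss = rss, df = df, vcov = xtx_inv * sigma2,
       fitted = as.vector(X %*% beta))
}

psi_admissible <- function(x, psi, min_seg_points) {
  is.finite(psi) &&
    sum(x < psi) >= min_seg_points && sum(x > psi) >= min_seg_points
}

# working-model least squares at a fixed breakpoint: the extra covariate
# V = -1[x > psi] carries the linearized breakpoint uncertainty, so its
# vcov is the one slope inference must use (dropping V understates slope
# SEs because psi is estimated)
work_fit <- function(x, y, psi) {
  U <- pmax(x - psi, 0)
  V <- -(x > psi)
  X <- cbind(1, x, U, V)
  qr_ <- qr(X)
  if (qr_$rank < 4) return(NULL)
  beta <- unname(qr.coef(qr_, y))
  rss <- sum((y - X %*% beta)^2)
  df <- length(y) - 4
  list(beta = beta, vcov = chol2inv(qr.R(qr_)) * rss / max(df, 1),
       rss = rss, df = df)
}

# one run of the iterative linearization from a starting breakpoint.
# The update is psi <- psi + h * gamma/delta with h halved whenever the
# step changes sign without shrinking (the least-squares optimum can sit at
# an observed-year kink of the RSS profile, where the undamped update
# oscillates forever); a proposed step leaving the observed range means the
# working model has no interior breakpoint to find, and the run fails --
# that non-convergence is the method's own "no breakpoint" signal.
segment_iterate <- function(x, y, psi0, min_seg_points, max_iter = 100,
                            tol = 1e-9) {
  psi <- psi0
  h <- 1
  prev_step <- NA_real_
  for (it in seq_len(max_iter)) {
    w <- work_fit(x, y, psi)
    if (is.null(w) || anyNA(w$beta)) return(NULL)
    delta <- w$beta[3]; gamma <- w$beta[4]
    if (!is.finite(delta) || abs(delta) < 1e-12) return(NULL)
    step <- gamma / delta
    if (!is.finite(step)) return(NULL)
    if (!is.na(prev_step) && sign(step) * sign(prev_step) < 0 &&
        abs(step) >= 0.5 * abs(prev_step)) {
      h <- h / 2
    } else {
      h <- min(1, h * 1.5)
    }
    prev_step <- step
    psi_new <- psi + h * step
    if (psi_new <= min(x) || psi_new >= max(x)) return(NULL)
    if (abs(psi_new - psi) < tol) {
      psi_se <- if (w$vcov[4, 4] > 0) sqrt(w$vcov[4, 4]) / abs(delta)
                else NA_real_
      return(list(psi = psi_new, psi_se = psi_se, iterations = it))
    }
    psi <- psi_new
  }
  NULL
}

#' Segmented (one-breakpoint) trend fit
#'
#' Estimates `y = b0 + b1*year + delta*(year - psi)_+` by Gaussian maximum
#' likelihood via damped iterative linearization from deterministic
#' starting breakpoints (the observed-year tertiles). Non-convergence from
#' every start is the method's "no breakpoint" outcome (`fit_type =
#' "failed"`, the caller then reports the linear fit) unless
#' `config$grid_fallback` switches on an exhaustive profile-grid rescue;
#' the rescue is off by default because a breakpoint taken at the global
#' profile optimum of an uninformative series makes the slope-change test
#' strongly anti-conservative. An admissible breakpoint has at least
#' `min_seg_points` observed years strictly on each side. The breakpoint SE
#' comes from the delta method on the working model, and slope SEs and
#' tests use the working-model covariance (which propagates breakpoint
#' uncertainty) on `n - 4` residual degrees of freedom.
#'
#' @inheritParams trend_linear
#' @param config a [study_config()] (uses `min_years_breakpoint`,
#'   `min_seg_points`, `grid_fallback`).
#' @return object of class `hfr_trend` with `fit_type` `"segmented"` or
#'   `"failed"` (no admissible breakpoint).
#' @export
#' @examples
#' yrs <- 2008:2021
#' y <- 1 + 0.3 * pmin(yrs - 2008, 7) - 0.2 * pmax(yrs - 2015, 0)
#' trend_segmented(data.frame(year = yrs, ln_mean = y))
trend_segmented <- function(series, y = NULL, config = study_config()) {
  d <- as_trend_series(series, y)
  x <- d$x; yy <- d$y
  n <- length(x)
  if (n < config$min_years_breakpoint)
    abort(sprintf("breakpoint fit needs at least %d years (got %d)",
                  config$min_years_breakpoint, n))
  msp <- config$min_seg_points

  # deterministic starts at the observed-year tertiles. Convergence from at
  # least one start is the evidence that a breakpoint model is supportable
  # (non-convergence from every start is the method's "no breakpoint"
  # outcome); once supported, the converged solution is checked against an
  # exhaustive profile grid -- iterating once more from the grid optimum
  # and keeping whichever candidate has the lowest RSS -- so the reported
  # breakpoint sits at the least-squares optimum, including optima at
  # observed-year kinks of the RSS profile.
  starts <- unique(stats::quantile(x, c(1 / 3, 2 / 3), names = FALSE))
  try_start <- function(psi0, sols) {
    sol <- segment_iterate(x, yy, psi0, msp)
    if (is.null(sol) || !psi_admissible(x, sol$psi, msp)) return(sols)
    ref <- refit_at_psi(x, yy, sol$psi)
    if (is.null(ref)) return(sols)
    sol$rss <- ref$rss
    sol$method <- "iterative"
    c(sols, list(sol))
  }
  sols <- list()
  for (psi0 in starts) sols <- try_start(psi0, sols)
  grid_best <- NULL
  xs <- sort(unique(x))
  if (length(xs) >= 2 * msp + 1 && xs[length(xs) - msp + 1] > xs[msp]) {
    grid <- seq(xs[msp], xs[length(xs) - msp + 1], length.out = 201)
    grid <- grid[vapply(grid, function(p) psi_admissible(x, p, msp),
                        logical(1))]
    if (length(grid)) {
      rsss <- vapply(grid, function(p) refit_at_psi(x, yy, p)$rss,
                     numeric(1))
      grid_best <- list(psi = grid[which.min(rsss)], rss = min(rsss),
                        psi_se = NA_real_, iterations = NA_integer_,
                        method = "grid")
    }
  }
  if (length(sols) > 0 && !is.null(grid_best)) {
    sols <- try_start(grid_best$psi, sols)
    sols <- c(sols, list(grid_best))
  } else if (length(sols) == 0 && isTRUE(config$grid_fallback) &&
             !is.null(grid_best)) {
    sols <- list(grid_best)
  }
  sol <- NULL
  if (length(sols)) {
    rsss <- vapply(sols, `[[`, numeric(1), "rss")
    psis <- vapply(sols, `[[`, numeric(1), "psi")
    best <- which(rsss <= min(rsss) + 1e-12)
    sol <- sols[[best[which.min(psis[best])]]]  # ties toward earlier psi
  }
  if (is.null(sol))
    return(new_hfr_trend(fit_type = "failed", n_years = n, x = x, y = yy,
                         converged = FALSE, method = "none",
                         log_likelihood = NA_real_, psi = NA_real_))

  ref <- refit_at_psi(x, yy, sol$psi)
  w <- work_fit(x, yy, sol$psi)
  if (is.null(w))
    w <- list(vcov = rbind(cbind(ref$vcov, 0), 0), beta = c(ref$beta, 0))
  b0 <- ref$beta[1]; b1 <- ref$beta[2]; delta <- ref$beta[3]
  # slope inference from the working model: its V column propagates the
  # breakpoint uncertainty into the slope variances
  se_b1 <- sqrt(w$vcov[2, 2]); se_delta <- sqrt(w$vcov[3, 3])
  slope_after <- b1 + delta
  se_after <- sqrt(w$vcov[2, 2] + w$vcov[3, 3] + 2 * w$vcov[2, 3])
  if (is.na(sol$psi_se) && w$vcov[4, 4] > 0 && abs(w$beta[3]) > 1e-12)
    sol$psi_se <- sqrt(w$vcov[4, 4]) / abs(w$beta[3])
  df <- ref$df
  tstat <- function(est, se) if (se > 0) est / se else Inf * sign(est)
  t1 <- tstat(b1, se_b1); td <- tstat(delta, se_delta)
  pt2 <- function(t) 2 * stats::pt(-abs(t), df)
  ll <- -n / 2 * (log(2 * pi) + log(ref$rss / n) + 1)
  new_hfr_trend(
    fit_type = "segmented", n_years = n, x = x, y = yy,
    coefficients = c(intercept = unname(b0), slope_before = unname(b1),
                     delta = unname(delta), psi = sol$psi),
    psi = sol$psi, psi_se = sol$psi_se,
    slope_before = unname(b1), se_before = se_b1,
    slope_after = unname(slope_after), se_after = se_after,
    delta = unname(delta), se_delta = se_delta,
    t_value = t1, p_value = pt2(t1),
    t_delta = td, p_delta = pt2(td),
    df_residual = df, rss = ref$rss, log_likelihood = ll, n_par = 5,
    fitted = ref$fitted, converged = TRUE, method = sol$method,
    iterations = sol$iterations)
}

#' Profile-grid breakpoint fit (exhaustive oracle)
#'
#' Exhaustive least squares over a user-supplied grid of candidate
#' breakpoints. Intended as an independent check on [trend_segmented()]:
#' the iterative fit's residual sum of squares should never exceed the grid
#' optimum's by more than the grid resolution allows.
#'
#' @inheritParams trend_segmented
#' @param grid numeric vector of candidate breakpoint years.
#' @return object of class `hfr_trend` (`method = "grid"`).
#' @export
trend_profile <- function(series, grid, y = NULL, config = study_config()) {
  d <- as_trend_series(series, y)
  if (length(grid) == 0) abort("empty breakpoint grid")
  grid <- grid[vapply(grid, function(p)
    psi_admissible(d$x, p, config$min_seg_points), logical(1))]
  if (length(grid) == 0) abort("no admissible breakpoint in the grid")
  rsss <- vapply(grid, function(p) refit_at_psi(d$x, d$y, p)$rss, numeric(1))
  psi <- grid[which.min(rsss)]
  out <- trend_segmented_at(d$x, d$y, psi)
  out$method <- "grid"
  out
}

# segmented-fit object at a fixed, known psi (shared by trend_profile)
trend_segmented_at <- function(x, y, psi) {
  ref <- refit_at_psi(x, y, psi)
  n <- length(x)
  b1 <- ref$beta[2]; delta <- ref$beta[3]
  slope_after <- b1 + delta
  se_after <- sqrt(ref$vcov[2, 2] + ref$vcov[3, 3] + 2 * ref$vcov[2, 3])
  pt2 <- function(t) 2 * stats::pt(-abs(t), ref$df)
  t1 <- b1 / ref$se[2]; td <- delta / ref$se[3]
  ll <- -n / 2 * (log(2 * pi) + log(ref$rss / n) + 1)
  new_hfr_trend(
    fit_type = "segmented", n_years = n, x = x, y = y,
    coefficients = c(intercept = unname(ref$beta[1]),
                     slope_before = unname(b1), delta = unname(delta),
                     psi = psi),
    psi = psi, psi_se = NA_real_,
    slope_before = unname(b1), se_before = ref$se[2],
    slope_after = unname(slope_after), se_after = se_after,
    delta = unname(delta), se_delta = ref$se[3],
    t_value = t1, p_value = pt2(t1), t_delta = td, p_delta = pt2(td),
    df_residual = ref$df, rss = ref$rss, log_likelihood = ll, n_par = 5,
    fitted = ref$fitted, converged = TRUE, method = "fixed")
}

#' Fit and select the trend model for one colony series
#'
#' Fits the breakpoint model when the series is long enough
#' (`min_years_breakpoint`) and keeps it when it is admissible and improves
#' on the plain linear fit under the configured criterion (by default:
#' lower AIC than the linear fit *and* a significant slope-change test at
#' `alpha`); otherwise the linear fit is returned. The selection decision
#' is recorded in the returned object's `selection` element.
#'
#' @inheritParams trend_segmented
#' @return an `hfr_trend` object, with `$selection` documenting the
#'   decision trace.
#' @export
fit_trend <- function(series, y = NULL, config = study_config()) {
  d <- as_trend_series(series, y)
  lin <- trend_linear(d$x, d$y)
  trace <- list(n_years = lin$n_years)
  if (lin$n_years < config$min_years_breakpoint) {
    trace$decision <- "linear_short_series"
    lin$selection <- trace
    return(lin)
  }
  # a (numerically) exact straight line leaves nothing for a breakpoint to
  # explain; comparing zero residual variances is meaningless
  if (lin$rss <= 1e-12 * max(1, sum(d$y^2))) {
    trace$decision <- "linear_perfect_fit"
    lin$selection <- trace
    return(lin)
  }
  seg <- trend_segmented(d$x, d$y, config = config)
  if (seg$fit_type == "failed") {
    trace$decision <- "linear_breakpoint_failed"
    lin$selection <- trace
    return(lin)
  }
  aic_ok <- !config$select_use_aic || AIC(seg) < AIC(lin)
  delta_ok <- !config$select_use_delta ||
    (is.finite(seg$p_delta) && seg$p_delta <= config$alpha)
  trace$aic_segmented <- AIC(seg); trace$aic_linear <- AIC(lin)
  trace$p_delta <- seg$p_delta
  if (aic_ok && delta_ok) {
    trace$decision <- "segmented"
    seg$selection <- trace
    seg
  } else {
    trace$decision <- paste0("linear",
                             if (!aic_ok) "_aic" else "",
                             if (!delta_ok) "_delta" else "")
    lin$selection <- trace
    lin
  }
}

#' @export
print.hfr_trend <- function(x, digits = 4, ...) {
  cat(sprintf("Trend fit (%s), %d years\n", x$fit_type, x$n_years))
  if (x$fit_type == "segmented") {
    cat(sprintf("  breakpoint: %.4g (SE %.3g)\n", x$psi, x$psi_se))
    cat(sprintf("  slope before: %.4g (SE %.3g)   slope after: %.4g (SE %.3g)\n",
                x$slope_before, x$se_before, x$slope_after, x$se_after))
    cat(sprintf("  t = %.3g (p = %.3g); slope-change t = %.3g (p = %.3g)\n",
                x$t_value, x$p_value, x$t_delta, x$p_delta))
  } else if (x$fit_type == "linear") {
    cat(sprintf("  slope: %.4g (SE %.3g), t = %.3g, p = %.3g\n",
                x$slope, x$slope_se, x$t_value, x$p_value))
  } else {
    cat("  no admissible breakpoint\n")
  }
  invisible(x)
}

#' @export
summary.hfr_trend <- function(object, ...) {
  print(object)
  if (object$fit_type != "failed") {
    cat(sprintf("  residual df = %d, logLik = %.4g, AIC = %.4g\n",
                object$df_residual, object$log_likelihood, AIC(object)))
    pct <- percent_annual_change(if (object$fit_type == "segmented")
      object$slope_after else object$slope)
    cat(sprintf("  terminal percent annual change: %+.1f%%\n", pct))
  }
  invisible(object)
}

#' @export
coef.hfr_trend <- function(object, ...) object$coefficients

#' @export
logLik.hfr_trend <- function(object, ...) {
  structure(object$log_likelihood, df = object$n_par,
            nobs = object$n_years, class = "logLik")
}

#' @export
residuals.hfr_trend <- function(object, ...) object$y - object$fitted

#' @export
fitted.hfr_trend <- function(object, ...) object$fitted

#' @export
predict.hfr_trend <- function(object, newdata = NULL, ...) {
  xx <- if (is.null(newdata)) object$x
        else if (is.data.frame(newdata)) newdata$year else newdata
  if (object$fit_type == "segmented") {
    cf <- object$coefficients
    cf[["intercept"]] + cf[["slope_before"]] * xx +
      cf[["delta"]] * pmax(xx - object$psi, 0)
  } else if (object$fit_type == "linear") {
    object$coefficients[["intercept"]] + object$coefficients[["slope"]] * xx
  } else {
    rep(NA_real_, length(xx))
  }
}

#' @export
confint.hfr_trend <- function(object, parm = NULL, level = 0.95, ...) {
  if (object$fit_type == "failed") abort("no fit to form intervals from")
  z <- stats::qt(1 - (1 - level) / 2, object$df_residual)
  if (object$fit_type == "linear") {
    est <- c(slope = object$slope)
    se <- c(slope = object$slope_se)
  } else {
    est <- c(slope_before = object$slope_before,
             slope_after = object$slope_after, delta = object$delta,
             psi = object$psi)
    se <- c(slope_before = object$se_before, slope_after = object$se_after,
            delta = object$se_delta, psi = object$psi_se)
  }
  out <- cbind(lower = est - z * se, upper = est + z * se)
  if (!is.null(parm)) out <- out[parm, , drop = FALSE]
  out
}

#' @export
plot.hfr_trend <- function(x, xlab = "Year",
                           ylab = "ln concentration (ng/g ww)", ...) {
  graphics::plot(x$x, x$y, pch = 19, xlab = xlab, ylab = ylab, ...)
  xx <- seq(min(x$x), max(x$x), length.out = 200)
  graphics::lines(xx, predict(x, xx), col = "steelblue", lwd = 2)
  if (x$fit_type == "segmented")
    graphics::abline(v = x$psi, lty = 3, col = "grey40")
  invisible(x)
}
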