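test_that("detection_rate is the detected fraction and rejects empty groups", {
  expect_equal(detection_rate(rep(TRUE, 10)), 1.0)
  expect_equal(detection_rate(c(rep(TRUE, 4), rep(FALSE, 6))), 0.4)
  expect_error(detection_rate(logical(0)), "empty")
})

test_that("uncensored fit equals the closed-form log-moment MLE", {
  set.seed(21)
  x <- rlnorm(40, 0.5, 0.8)
  f <- fit_censored_lognormal(x)
  lx <- log(x)
  expect_equal(f$mu, mean(lx))
  expect_equal(f$sigma, sqrt(mean((lx - mean(lx))^2)))
  expect_true(f$converged)
  expect_equal(f$log_likelihood, sum(dlnorm(x, f$mu, f$sigma, log = TRUE)))
})

test_that("identical detected values give a degenerate flagged fit", {
  f <- fit_censored_lognormal(rep(2.5, 5))
  expect_true(f$degenerate)
  expect_lte(f$sigma, 1e-6)
})

test_that("censored ML recovers known parameters and matches fitdistrplus", {
  set.seed(5)
  x <- rlnorm(1000, 1.0, 0.5)
  lim <- qlnorm(0.30, 1.0, 0.5)
  f <- fit_censored_lognormal(x[x >= lim], rep(lim, sum(x < lim)))
  expect_lt(abs(f$mu - 1.0), 0.05)
  expect_lt(abs(f$sigma - 0.5), 0.05)
  # independent oracle: interval-censored ML from fitdistrplus
  cd <- data.frame(left = ifelse(x < lim, NA, x),
                   right = ifelse(x < lim, lim, x))
  o <- fitdistrplus::fitdistcens(cd, "lnorm")
  expect_lt(abs(f$mu - unname(o$estimate["meanlog"])), 1e-3)
  expect_lt(abs(f$sigma - unname(o$estimate["sdlog"])), 1e-3)
})

test_that("estimator bias shrinks with sample size on censored data", {
  set.seed(77)
  err <- sapply(c(50, 200, 1000), function(n) {
    mus <- replicate(40, {
      x <- rlnorm(n, 1.0, 0.5)
      lim <- qlnorm(0.30, 1.0, 0.5)
      fit_censored_lognormal(x[x >= lim], rep(lim, sum(x < lim)))$mu
    })
    abs(mean(mus) - 1.0)
  })
  expect_lt(err[3], err[1] + 0.02)
  expect_lt(err[3], 0.02)
})

make_group <- function(n, n_cens, conc, mlod = 1.0) {
  data.frame(colony_id = "C", region = "Atlantic", year = 2010,
             pool_id = sprintf("P%02d", seq_len(n)), n_eggs = 10,
             analyte = "alpha-HBCDD", conc = conc, mlod = mlod,
             mloq = mlod * 10 / 3,
             detected = c(rep(TRUE, n - n_cens), rep(FALSE, n_cens)),
             stringsAsFactors = FALSE)
}

test_that("replacements are the closed-form plotting-position quantiles", {
  # n = 9, 2 censored: p = 0.1, 0.2 under i/(n+1); standard log-normal fit
  g <- make_group(9, 2, c(exp(rnorm(7)), NA, NA))
  fit <- structure(list(mu = 0, sigma = 1, n_total = 9, n_censored = 2,
                        converged = TRUE, degenerate = FALSE,
                        log_likelihood = 0), class = "cenlnorm")
  # reference concentrations reverse the natural pool order
  ref <- g
  ref$analyte <- "syn-DP"
  ref$detected <- TRUE
  ref$conc <- seq(9, 1)  # P08 has higher reference conc than P09
  out <- impute_nondetects(g, fit, reference = ref)
  expect_equal(sort(out$conc[8:9]),
               c(exp(qnorm(0.1)), exp(qnorm(0.2))), tolerance = 1e-10)
  expect_equal(round(sort(out$conc[8:9]), 4), c(0.2776, 0.4310))
  # ascending reference order: P09 (ref 1) gets the smaller replacement
  expect_lt(out$conc[9], out$conc[8])
  expect_equal(out$source[8:9], c("imputed", "imputed"))
})

test_that("imputation never alters detected values; replacements unique and below MLOD", {
  set.seed(8)
  g <- make_group(12, 5, c(rlnorm(7, 0, 1), rep(NA, 5)), mlod = 0.8)
  fit <- fit_censored_lognormal(g$conc[g$detected], g$mlod[!g$detected])
  out <- impute_nondetects(g, fit, reference = NULL)
  expect_identical(out$conc[1:7], g$conc[1:7])
  repl <- out$conc[8:12]
  expect_true(all(repl > 0 & repl <= 0.8))
  expect_equal(length(unique(repl)), 5)
  expect_true(all(grepl("ref_fallback", out$flag[8:12])))
  # zero censored records: identity
  g2 <- make_group(5, 0, rlnorm(5))
  expect_equal(impute_nondetects(g2, fit)$conc, g2$conc)
})

test_that("detection policy imputes at >= 50 percent and zeroes below", {
  cfg <- study_config()
  below <- make_group(10, 6, c(rlnorm(4, 0, 0.5), rep(NA, 6)))
  out <- apply_detection_policy(below, cfg)
  expect_true(all(out$conc[!below$detected] == 0))
  expect_true(all(out$source[!below$detected] == "zeroed"))
  at50 <- make_group(10, 5, c(rlnorm(5, 0, 0.5), rep(NA, 5)))
  out50 <- apply_detection_policy(at50, cfg)
  expect_true(all(out50$conc[!at50$detected] > 0))
  expect_true(all(out50$source[!at50$detected] == "imputed"))
  full <- make_group(10, 0, rlnorm(10))
  outf <- apply_detection_policy(full, cfg)
  expect_identical(outf$conc, full$conc)
  audit <- attr(out50, "audit")
  expect_equal(audit$action, "imputed")
  expect_equal(audit$n_censored, 5)
})

test_that("policy completes a censored synthetic study without NAs", {
  des <- small_design(years = 2008:2015)
  st <- simulate_study(des, flat_scenarios(des, classes = hfr_classes()),
                       seed = 19)
  out <- apply_detection_policy(st$measurements, study_config())
  expect_false(anyNA(out$conc))
  expect_true(all(out$source %in% c("observed", "imputed", "zeroed")))
  # detected values untouched
  det <- st$measurements$detected
  expect_identical(out$conc[det], st$measurements$conc[det])
})
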