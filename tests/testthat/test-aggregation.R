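cong_records <- function(rates, n = 200) {
  # one record set per congener with the requested detection rate
  do.call(rbind, lapply(names(rates), function(a) {
    k <- round(rates[[a]] * n)
    data.frame(colony_id = "C", region = "Atlantic", year = 2010,
               pool_id = sprintf("P%d", seq_len(n)), n_eggs = 10, analyte = a,
               conc = c(rep(1, k), rep(NA, n - k)), mlod = 0.05, mloq = 0.17,
               detected = c(rep(TRUE, k), rep(FALSE, n - k)),
               stringsAsFactors = FALSE)
  }))
}

test_that("congener selection applies the detection-fraction rule", {
  full <- setNames(rep(1, 12), pbde_congeners())
  expect_setequal(select_sum_congeners(cong_records(full)), pbde_congeners())
  rates <- full
  rates["BDE-190"] <- 0.029  # below the 3 percent rule
  kept <- select_sum_congeners(cong_records(rates, n = 1000))
  expect_length(kept, 11)
  expect_false("BDE-190" %in% kept)
  expect_setequal(select_sum_congeners(cong_records(rates, n = 1000),
                                       threshold = 1e-9),
                  pbde_congeners())
})

test_that("class sums add the right analytes", {
  pools <- expand.grid(pool_id = c("P1", "P2"),
                       analyte = c(setdiff(pbde_congeners(), "BDE-190"),
                                   "BDE-209", "alpha-HBCDD", "syn-DP", "anti-DP"),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  m <- data.frame(colony_id = "C", region = "Arctic", year = 2012,
                  pools, n_eggs = 5, conc = 1.0, mlod = 0.01, mloq = 0.04,
                  detected = TRUE, stringsAsFactors = FALSE)
  m$conc[m$analyte == "syn-DP"] <- 0.2
  m$conc[m$analyte == "anti-DP"] <- 0.8
  cs <- class_sums(m)
  expect_equal(cs$conc[cs$hfr_class == "Sum11PBDE"], c(11, 11))
  expect_equal(cs$conc[cs$hfr_class == "SumDP"], c(1, 1))
  expect_equal(cs$conc[cs$hfr_class == "BDE209"], c(1, 1))
  # missing congener names the pool and analyte
  expect_error(class_sums(m[-1, ]), "P1.*BDE-17")
  # incomplete (non-imputed) data is refused
  m2 <- m; m2$conc[1] <- NA
  expect_error(class_sums(m2), "apply_detection_policy")
})

test_that("class sums are linear in the underlying records", {
  des <- small_design(years = 2010:2013)
  st <- simulate_study(des, flat_scenarios(des), seed = 4, censor = FALSE)
  m <- st$measurements
  doubled <- m; doubled$conc <- 2 * m$conc
  expect_equal(class_sums(doubled)$conc, 2 * class_sums(m)$conc)
  # generator bookkeeping: sums equal exp of the truth pool values
  cs <- class_sums(m)
  key <- paste(cs$colony_id, cs$year, cs$pool_id)
  tr <- st$truth$pools
  expect_equal(cs$conc,
               exp(tr$ln_sum[match(key, paste(tr$colony_id, tr$year, tr$pool_id))]),
               tolerance = 1e-10)
})

test_that("annual means average pools and flag zero means", {
  pv <- data.frame(colony_id = "C", region = "Arctic", year = c(2010, 2010, 2011, 2012),
                   pool_id = c("P1", "P2", "P1", "P1"), hfr_class = "HBCDD",
                   conc = c(2, 4, 5, 0), stringsAsFactors = FALSE)
  am <- annual_means(pv)
  expect_equal(am$mean_conc, c(3, 5, 0))
  expect_equal(am$ln_mean, c(log(3), log(5), NA))
  expect_equal(am$n_pools, c(2L, 1L, 1L))
  expect_equal(am$flag, c("", "", "zero_mean"))
  # invariant to pool ordering
  am2 <- annual_means(pv[c(3, 1, 4, 2), ])
  expect_equal(am, am2)
  # optional half-minimum offset
  am3 <- annual_means(pv, half_min_offset = TRUE)
  expect_equal(am3$mean_conc[3], 1.5)
  expect_equal(am3$flag[3], "half_min")
})

test_that("egg volume follows the Ryder formula", {
  expect_equal(egg_volume(7.2, 5.0), 88.02)
  expect_equal(egg_volume(1e-9, 5.0), 0.489 * 1e-9 * 25)
  expect_equal(egg_volume(7.2, 10.0), 4 * egg_volume(7.2, 5.0))
  expect_error(egg_volume(0, 5), "> 0")
})

test_that("covariate screening picks Pearson or Spearman from residual normality", {
  x <- seq(1, 3, length.out = 16)
  lin <- covariate_screen(2 + 0.5 * x, x)
  expect_equal(lin$method, "pearson")
  expect_equal(lin$estimate, 1.0)
  expect_lt(lin$p.value, 0.05)
  # monotone but sharply nonlinear: residual normality fails, ranks agree
  curve <- covariate_screen(exp(3 * x), x)
  expect_equal(curve$method, "spearman")
  expect_equal(curve$estimate, 1.0)
  const <- covariate_screen(rnorm(10), rep(2, 10))
  expect_equal(const$flag, "constant_covariate")
  expect_true(is.na(const$estimate))
  expect_error(covariate_screen(1:3, 1:3), "at least 4")
})

test_that("screening keeps its nominal type-I error on independent noise", {
  set.seed(55)
  hits <- replicate(500, {
    covariate_screen(rnorm(16), rnorm(16))$p.value <= 0.05
  })
  rate <- mean(hits)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / 500) + 0.01)
})
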