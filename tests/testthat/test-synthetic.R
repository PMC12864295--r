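test_that("zero-noise study reproduces the deterministic piecewise line", {
  des <- small_design(years = 2008:2019, year_effect_sd = 0)
  sc <- flat_scenarios(des, residual_sd = 1e-9, pool_sd = 0)
  sc$slope_before <- 0.3
  sc$breakpoint_year <- 2014L
  sc$slope_after <- -0.2
  st <- simulate_study(des, sc, seed = 1, censor = FALSE)
  pools <- class_sums(st$measurements)
  for (i in seq_len(nrow(des$colonies))) {
    cid <- des$colonies$colony_id[i]
    off <- des$region_offsets[[des$colonies$region[i]]]
    sub <- pools[pools$colony_id == cid, ]
    expected <- 1.5 + off + 0.3 * (pmin(sub$year, 2014) - 2008) -
      0.2 * pmax(sub$year - 2014, 0)
    expect_equal(log(sub$conc), expected, tolerance = 1e-6)
  }
})

test_that("a fixed seed reproduces the study exactly; seeds differ", {
  des <- small_design(years = 2010:2014)
  sc <- flat_scenarios(des)
  a <- simulate_study(des, sc, seed = 42)
  b <- simulate_study(des, sc, seed = 42)
  expect_identical(a$measurements, b$measurements)
  expect_identical(a$covariates, b$covariates)
  c <- simulate_study(des, sc, seed = 43)
  expect_false(identical(a$measurements$conc, c$measurements$conc))
})

test_that("colony draws do not depend on design order", {
  cols <- small_colonies()
  des1 <- small_design(years = 2010:2014, colonies = cols)
  des2 <- small_design(years = 2010:2014, colonies = cols[rev(seq_len(nrow(cols))), ])
  sc <- flat_scenarios(des1)
  a <- simulate_study(des1, sc, seed = 5, censor = FALSE)$measurements
  b <- simulate_study(des2, sc, seed = 5, censor = FALSE)$measurements
  a1 <- a[a$colony_id == "B1", ]
  b1 <- b[b$colony_id == "B1", ]
  expect_equal(a1$conc, b1$conc)
})

test_that("breakpoint outside a colony's sampled years is rejected", {
  des <- small_design(years = 2010:2014)
  sc <- flat_scenarios(des)
  sc$breakpoint_year[1] <- 2014L  # boundary year: not strictly inside
  sc$slope_after[1] <- -0.1
  expect_error(simulate_study(des, sc, seed = 1), "strictly inside")
})

test_that("censoring thresholds behave and match known quantiles", {
  des <- small_design(years = 2010:2014)
  st <- simulate_study(des, flat_scenarios(des), seed = 9, censor = FALSE)
  m <- st$measurements
  sched0 <- data.frame(analyte = "alpha-HBCDD",
                       year = sort(unique(m$year)), mlod = 1e-12)
  sched0$mloq <- sched0$mlod * 10 / 3
  none <- apply_censoring(m, sched0)
  expect_equal(sum(!none$detected), 0)
  schedInf <- sched0; schedInf$mlod <- 1e6; schedInf$mloq <- 4e6
  all_c <- apply_censoring(m, schedInf)
  expect_equal(sum(!all_c$detected), nrow(m))
  expect_true(all(is.na(all_c$conc)))
  # missing schedule entry
  expect_error(apply_censoring(m, sched0[-1, ]), "missing")
})

test_that("censoring at a known quantile censors the expected fraction", {
  # ln concentrations ~ N(mu_total, sd_total): cut at the 40th percentile
  des <- small_design(years = 2008:2019, year_effect_sd = 0,
                      pools_range = c(4L, 5L))
  sc <- flat_scenarios(des, residual_sd = 0.3, pool_sd = 0.2)
  st <- simulate_study(des, sc, seed = 31, censor = FALSE)
  m <- st$measurements
  # empirical 40th percentile as the scheduled limit for every year
  q40 <- unname(stats::quantile(m$conc, 0.40))
  sched <- data.frame(analyte = "alpha-HBCDD", year = sort(unique(m$year)),
                      mlod = q40)
  sched$mloq <- sched$mlod * 10 / 3
  cen <- apply_censoring(m, sched)
  n <- nrow(m)
  mc_err <- 3 * sqrt(0.4 * 0.6 / n)
  expect_gt(n, 400)
  expect_lt(abs(mean(!cen$detected) - 0.40), mc_err + 1 / n)
  ds <- attr(cen, "detection_summary")
  expect_equal(ds$detection_rate[ds$analyte == "alpha-HBCDD"],
               mean(cen$detected))
})

test_that("pool deviations match the scenario pool_sd (generator bookkeeping)", {
  des <- small_design(years = 2008:2019, year_effect_sd = 0)
  sc <- flat_scenarios(des, residual_sd = 0.25, pool_sd = 0.2)
  st <- simulate_study(des, sc, seed = 13, censor = FALSE)
  dev <- st$truth$pools$ln_sum -
    st$truth$colony_year$mean_ln[match(
      paste(st$truth$pools$colony_id, st$truth$pools$year),
      paste(st$truth$colony_year$colony_id, st$truth$colony_year$year))]
  n <- length(dev)
  expect_lt(abs(mean(dev)), 3 * 0.2 / sqrt(n))
  expect_lt(abs(stats::sd(dev) - 0.2), 0.05)
})
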