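test_that("published example fits map to their trend models", {
  ms <- default_milestones()
  # HBCDD breakpoint in 2011 (between nomination 2008 and listing 2013),
  # declining after: nomination improvement
  expect_equal(classify_trend(NULL, "HBCDD", ms, fit_type = "segmented",
                              psi = 2011, slope_after = -0.07, p = 0.025),
               "NI")
  # BDE-209 breakpoint 2016 with rising post-breakpoint slope: increase
  expect_equal(classify_trend(NULL, "BDE209", ms, fit_type = "segmented",
                              psi = 2016, slope_after = 0.23, p = 0.041),
               "IT")
  # DP breakpoint 2014, five years before nomination, declining: early
  expect_equal(classify_trend(NULL, "SumDP", ms, fit_type = "segmented",
                              psi = 2014, slope_after = -0.21, p = 0.039),
               "EI")
  # significant linear decline: consistent trend
  expect_equal(classify_trend(NULL, "HBCDD", ms, fit_type = "linear",
                              psi = NA, slope_after = -0.08, p = 0.026),
               "CT")
  # non-significant anything: NS
  expect_equal(classify_trend(NULL, "HBCDD", ms, fit_type = "segmented",
                              psi = 2015, slope_after = -0.21, p = 0.15),
               "NS")
  expect_equal(classify_trend(NULL, "HBCDD", ms, fit_type = "failed",
                              psi = NA, slope_after = NA, p = NA), "NS")
  expect_error(classify_trend(NULL, "PCB", ms, fit_type = "linear",
                              psi = NA, slope_after = -1, p = 0.01),
               "milestone")
})

test_that("milestone-year boundaries are inclusive for NI", {
  ms <- default_milestones()
  lab <- function(psi) classify_trend(NULL, "HBCDD", ms, fit_type = "segmented",
                                      psi = psi, slope_after = -0.1, p = 0.01)
  expect_equal(lab(2013), "NI")        # breakpoint at the listing year
  expect_equal(lab(2008), "NI")        # breakpoint at the nomination year
  expect_equal(lab(2013.5), "LI")
  expect_equal(lab(2007.9), "EI")
})

test_that("classification responds to a milestone registry override", {
  alt <- default_milestones()
  alt$nomination_year[alt$hfr_class == "SumDP"] <- 2013L
  expect_equal(classify_trend(NULL, "SumDP", alt, fit_type = "segmented",
                              psi = 2014, slope_after = -0.21, p = 0.039),
               "NI")  # EI under the default registry
})

test_that("percent annual change converts and inverts cleanly", {
  expect_equal(percent_annual_change(0), 0)
  expect_equal(round_half_away(percent_annual_change(0.79)), 120)
  expect_equal(round_half_away(percent_annual_change(-0.42)), -34)
  expect_equal(round_half_away(abs(percent_annual_change(-0.95))), 61)
  # inversion: beta = ln(1 + pct/100)
  for (b in c(-0.5, -0.1, 0, 0.2, 0.8)) {
    expect_equal(log(1 + percent_annual_change(b) / 100), b)
  }
  # monotone
  b <- seq(-1, 1, by = 0.1)
  expect_true(all(diff(percent_annual_change(b)) > 0))
  expect_equal(format_percent_change(0.79), "120% annual increase")
  expect_equal(format_percent_change(-0.07), "7% annual decrease")
  expect_equal(round_half_away(c(2.5, -2.5, 0.49)), c(3, -3, 0))
})

test_that("tabulate reproduces the published labels and tallies", {
  tab <- hfr_trend_table()
  expect_equal(nrow(tab), 68)
  res <- tabulate_trends(tab)
  sig <- tab$significant
  expect_equal(res$table$label[sig], tab$label[sig])
  expect_true(all(res$table$label[!sig] == "NS"))
  expect_equal(res$tallies$n_ns, 51)
  expect_equal(res$tallies$n_significant, 17)
  expect_equal(res$tallies$n_ct_decline, 9)
  expect_equal(unname(res$tallies$ct_decline_by_class[["Sum11PBDE"]]), 3)
})

test_that("tabulate handles empty input and rejects duplicates", {
  empty <- hfr_trend_table()[0, ]
  res <- tabulate_trends(empty)
  expect_equal(res$tallies$n_comparisons, 0)
  expect_equal(res$tallies$n_ns, 0)
  dup <- hfr_trend_table()[c(1, 1), ]
  expect_error(tabulate_trends(dup), "duplicate")
})
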