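# Shared fixtures: small deterministic designs so individual tests stay fast.

small_colonies <- function() {
  data.frame(
    colony_id = c("A1", "A2", "B1", "B2", "C1", "C2", "D1", "D2"),
    region = rep(c("GreatLakesNiagara", "StLawrence", "Atlantic", "Arctic"),
                 each = 2),
    stringsAsFactors = FALSE)
}

small_design <- function(years = 2008:2019, colonies = small_colonies(), ...) {
  ys <- stats::setNames(rep(list(years), nrow(colonies)), colonies$colony_id)
  study_design(colonies = colonies, years = ys, ...)
}

# scenario table with a single archetype for every colony x class
flat_scenarios <- function(design, classes = "HBCDD", intercept = 1.5,
                           slope = 0, residual_sd = 0.25, pool_sd = 0.2) {
  grid <- expand.grid(colony_id = design$colonies$colony_id,
                      hfr_class = classes, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  data.frame(grid, intercept_ln = intercept, slope_before = slope,
             breakpoint_year = NA_integer_, slope_after = NA_real_,
             residual_sd = residual_sd, pool_sd = pool_sd,
             stringsAsFactors = FALSE)
}

make_series <- function(years, y) data.frame(year = years, ln_mean = y)

# piecewise-linear mean used across the breakpoint recovery tests
vshape <- function(years, b1 = 0.3, b2 = -0.2, psi = 2015, y0 = 1) {
  y0 + b1 * (pmin(years, psi) - min(years)) + b2 * pmax(years - psi, 0)
}

# design for variance-component recovery: 17 colonies, 12 years, one pool,
# no region effects, year and residual variance set by the caller
lmm_design <- function(year_var = 0.10) {
  cols <- default_colonies()
  ys <- stats::setNames(rep(list(2008:2019), nrow(cols)), cols$colony_id)
  study_design(colonies = cols, years = ys, pools_range = c(1L, 1L),
               region_offsets = c(GreatLakesNiagara = 0, StLawrence = 0,
                                  Atlantic = 0, Arctic = 0),
               year_effect_sd = sqrt(year_var))
}

# scenarios with colony intercepts drawn from N(mu, colony_var): the colony
# variance component of the regional mixed model
lmm_scenarios <- function(design, colony_var = 0.20, resid_var = 0.70,
                          mu = 1.5, seed = 1) {
  set.seed(seed + 900000L)
  data.frame(colony_id = design$colonies$colony_id, hfr_class = "HBCDD",
             intercept_ln = mu + stats::rnorm(nrow(design$colonies), 0,
                                              sqrt(colony_var)),
             slope_before = 0, breakpoint_year = NA_integer_,
             slope_after = NA_real_, residual_sd = sqrt(resid_var),
             pool_sd = 0, stringsAsFactors = FALSE)
}

lmm_series <- function(seed, design = lmm_design(), colony_var = 0.20,
                       resid_var = 0.70) {
  sc <- lmm_scenarios(design, colony_var = colony_var,
                      resid_var = resid_var, seed = seed)
  st <- simulate_study(design, sc, seed = seed, censor = FALSE)
  annual_means(class_sums(st$measurements))
}
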