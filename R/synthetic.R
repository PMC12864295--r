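# Synthetic study generator.
#
# Emulates the statistical structure the downstream analysis assumes: 17
# colonies in 4 regions monitored 2008-2023 (Arctic colonies from 2010, the
# chemical-surveillance colonies on an alternate-year schedule after 2012),
# 1-5 egg pools per colony-year of 2-15 eggs each, log-normal pool
# concentrations around piecewise-linear ln-scale colony trends with region
# offsets and shared year effects, congener composition within class sums,
# and analyte/year-specific detection limits. Every drawn parameter is
# recorded in a ground-truth object so recovery can be tested exactly.

#' Define a synthetic monitoring study design
#'
#' @param colonies data.frame with columns `colony_id`, `region`.
#' @param years named list: `years[[colony_id]]` = integer vector of sampled
#'   years.
#' @param pools_range integer range (min, max) of pools per colony-year,
#'   drawn uniformly.
#' @param eggs_range integer range of eggs per pool, drawn uniformly.
#' @param region_offsets named ln-scale additive offsets, one per region.
#' @param year_effect_sd SD (ln-units) of the year random effect shared by
#'   all colonies within an HFR class.
#' @param rho loading in `[-1, 1]` of the common factor in within-pool
#'   congener-composition noise; it controls how tightly the reference
#'   analyte (BDE-99, syn-DP) tracks its dependent analytes beyond the
#'   shared pool value.
#' @param composition_sd SD (ln-units) of congener-composition noise within
#'   a pool (compositions are renormalized so class sums are exact).
#' @param congener_props named proportions of the 11 summed PBDE congeners
#'   (must sum to 1).
#' @param dp_split named proportions for `syn-DP` and `anti-DP`.
#' @param bde190_frac BDE-190 concentration as a fraction of the PBDE class
#'   sum; kept tiny so BDE-190 falls below its detection limit in nearly all
#'   pools, as observed in the monitoring programme.
#' @param mlod_schedule data.frame `analyte, year, mlod, mloq`; defaults to
#'   [default_mlod_schedule()] over the design years.
#' @return list of class `study_design`.
#' @export
study_design <- function(colonies = default_colonies(),
                         years = default_year_schedule(colonies),
                         pools_range = c(1L, 5L),
                         eggs_range = c(2L, 15L),
                         region_offsets = c(GreatLakesNiagara = 0.6,
                                            StLawrence = 0.8,
                                            Atlantic = -0.5,
                                            Arctic = -0.9),
                         year_effect_sd = 0.30,
                         rho = 0.8,
                         composition_sd = 0.15,
                         congener_props = default_congener_props(),
                         dp_split = c("syn-DP" = 0.25, "anti-DP" = 0.75),
                         bde190_frac = 2e-4,
                         mlod_schedule = NULL) {
  if (!all(c("colony_id", "region") %in% names(colonies)))
    abort("colonies must have columns colony_id, region")
  if (!all(colonies$region %in% region_levels()))
    abort("regions must be in: ", paste(region_levels(), collapse = ", "))
  if (length(unique(colonies$region)) < 2)
    abort("a study design needs at least 2 regions")
  if (!all(colonies$colony_id %in% names(years)))
    abort("every colony needs a sampled-year vector in `years`")
  if (abs(rho) > 1) abort("rho must be in [-1, 1]")
  if (abs(sum(congener_props) - 1) > 1e-8)
    abort("congener_props must sum to 1")
  if (abs(sum(dp_split) - 1) > 1e-8) abort("dp_split must sum to 1")
  if (year_effect_sd < 0) abort("year_effect_sd must be >= 0")
  all_years <- sort(unique(unlist(years)))
  if (is.null(mlod_schedule))
    mlod_schedule <- default_mlod_schedule(all_years)
  d <- list(colonies = colonies, years = years,
            pools_range = as.integer(pools_range),
            eggs_range = as.integer(eggs_range),
            region_offsets = region_offsets,
            year_effect_sd = year_effect_sd, rho = rho,
            composition_sd = composition_sd,
            congener_props = congener_props, dp_split = dp_split,
            bde190_frac = bde190_frac, mlod_schedule = mlod_schedule,
            all_years = all_years)
  class(d) <- "study_design"
  d
}

#' @rdname study_design
#' @export
default_colonies <- function() {
  data.frame(
    colony_id = c("East Bay", "Great Slave Lake",
                  "Gull Is", "Kent Is",
                  "Middle Is", "Port Colborne", "Chantry Is", "Double Is",
                  "Hamilton H", "Snake Is", "Toronto H", "Agawa Rocks",
                  "Granite Is", "Weseloh Rocks",
                  "Ile Bellechasse", "Ile Deslauriers", "Strachan Is"),
    region = c("Arctic", "Arctic", "Atlantic", "Atlantic",
               rep("GreatLakesNiagara", 10),
               "StLawrence", "StLawrence", "StLawrence"),
    stringsAsFactors = FALSE)
}

#' @rdname study_design
#' @export
default_year_schedule <- function(colonies = default_colonies()) {
  annual <- function(from, to) seq.int(from, to)
  # surveillance-plan colonies: annual 2008-2012, alternate years after
  cmp <- c(2008:2012, seq.int(2014, 2022, 2))
  sched <- list(
    "East Bay"         = c(2010:2012, seq.int(2014, 2022, 2)),
    "Great Slave Lake" = c(2010, 2012, 2014, 2016, 2018, 2022),
    "Gull Is"          = cmp,
    "Kent Is"          = setdiff(cmp, 2020),
    "Middle Is"        = annual(2008, 2022),
    "Port Colborne"    = annual(2008, 2021),
    "Chantry Is"       = annual(2008, 2021),
    "Double Is"        = annual(2008, 2021),
    "Hamilton H"       = annual(2008, 2021),
    "Snake Is"         = annual(2008, 2022),
    "Toronto H"        = annual(2008, 2020),
    "Agawa Rocks"      = annual(2008, 2022),
    "Granite Is"       = annual(2008, 2023),
    "Weseloh Rocks"    = c(2008:2015, 2018, 2019),
    "Ile Bellechasse"  = cmp,
    "Ile Deslauriers"  = setdiff(cmp, 2020),
    "Strachan Is"      = annual(2008, 2021))
  sched[colonies$colony_id]
}

#' @rdname study_design
#' @export
default_congener_props <- function() {
  # typical gull-egg profile: BDE-47/-99/-100/-153 dominate
  p <- c("BDE-17" = 0.01, "BDE-28" = 0.02, "BDE-47" = 0.45, "BDE-49" = 0.02,
         "BDE-66" = 0.01, "BDE-85" = 0.02, "BDE-99" = 0.25, "BDE-100" = 0.12,
         "BDE-138" = 0.01, "BDE-153" = 0.06, "BDE-183" = 0.03)
  p / sum(p)
}

#' Default analyte x year detection-limit schedule
#'
#' Base MLODs between 0.01 and 1.0 ng/g varying deterministically by year
#' (a fixed multiplier cycle), except BDE-209 whose MLOD is 5.0 ng/g in
#' three analysis years; MLOQ is set at MLOD x 10/3, mirroring the
#' signal-to-noise 3 vs 10 definitions of the two limits.
#'
#' @param years integer vector of calendar years to cover.
#' @param analytes analyte codes to cover.
#' @return data.frame `analyte, year, mlod, mloq`.
#' @export
default_mlod_schedule <- function(years, analytes = hfr_panel()) {
  base <- c("BDE-17" = 0.02, "BDE-28" = 0.02, "BDE-47" = 0.05,
            "BDE-49" = 0.02, "BDE-66" = 0.02, "BDE-85" = 0.02,
            "BDE-99" = 0.05, "BDE-100" = 0.03, "BDE-138" = 0.02,
            "BDE-153" = 0.03, "BDE-183" = 0.03, "BDE-190" = 0.20,
            "BDE-209" = 0.50, "alpha-HBCDD" = 0.05, "syn-DP" = 0.10,
            "anti-DP" = 0.05)
  cycle <- c(1, 1.4, 0.8, 1.1, 0.9, 1.25)
  grid <- expand.grid(analyte = analytes, year = years,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  mult <- cycle[(grid$year - min(years)) %% length(cycle) + 1]
  grid$mlod <- pmin(pmax(base[grid$analyte] * mult, 0.01), 1.0)
  high209 <- grid$analyte == "BDE-209" &
    grid$year %in% (min(years) + c(2, 6, 10))
  grid$mlod[high209] <- 5.0
  grid$mloq <- grid$mlod * 10 / 3
  grid
}

#' Ground-truth trend scenarios for a design
#'
#' One scenario per colony x HFR class: ln-scale intercept at the colony's
#' first sampled year, slope before the breakpoint, optional breakpoint year
#' (strictly inside the colony's sampled range) and slope after, plus the
#' colony-year (`residual_sd`) and within-colony-year (`pool_sd`) noise SDs.
#' Defaults cycle deterministically through four archetypes seen in field
#' data: rise-then-fall breakpoint, monotone decline, flat, fall-then-rise
#' breakpoint.
#'
#' @param design a [study_design()].
#' @param residual_sd colony-year deviation SD (ln-units).
#' @param pool_sd within colony-year pool deviation SD (ln-units).
#' @param classes HFR classes to cover.
#' @return data.frame of class scenarios.
#' @export
trend_scenarios <- function(design, residual_sd = 0.25, pool_sd = 0.20,
                            classes = hfr_classes()) {
  if (residual_sd <= 0) abort("residual_sd must be > 0")
  if (pool_sd < 0) abort("pool_sd must be >= 0")
  base_ln <- c(Sum11PBDE = 4.0, BDE209 = 1.0, HBCDD = 1.5, SumDP = 0.3)
  rows <- list()
  for (ci in seq_len(nrow(design$colonies))) {
    cid <- design$colonies$colony_id[ci]
    ys <- sort(design$years[[cid]])
    mid <- ys[ceiling(length(ys) / 2)]
    for (ki in seq_along(classes)) {
      cls <- classes[ki]
      arch <- (ci + ki) %% 4
      jitter <- (((ci * 7 + ki * 3) %% 11) - 5) / 10  # deterministic +-0.5
      sc <- switch(as.character(arch),
        "0" = list(b1 = 0.12,  psi = mid, b2 = -0.10),
        "1" = list(b1 = -0.06, psi = NA_integer_, b2 = NA_real_),
        "2" = list(b1 = 0.01,  psi = NA_integer_, b2 = NA_real_),
        "3" = list(b1 = -0.15, psi = mid, b2 = 0.08))
      rows[[length(rows) + 1]] <- data.frame(
        colony_id = cid, hfr_class = cls,
        intercept_ln = base_ln[[cls]] + jitter,
        slope_before = sc$b1, breakpoint_year = sc$psi,
        slope_after = sc$b2, residual_sd = residual_sd, pool_sd = pool_sd,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# piecewise-linear ln-scale mean for one scenario at years `t`
scenario_mean <- function(sc, t, t0) {
  m <- sc$intercept_ln + sc$slope_before * (t - t0)
  if (!is.na(sc$breakpoint_year)) {
    delta <- sc$slope_after - sc$slope_before
    m <- m + delta * pmax(t - sc$breakpoint_year, 0)
  }
  m
}

#' Simulate a monitoring study with known ground truth
#'
#' Pool-level ln class-sum concentration = piecewise-linear colony trend +
#' region offset + shared year effect + colony-year deviate + pool deviate.
#' Class sums are then split into analyte concentrations (congener
#' composition with common-factor noise, renormalized so sums are exact) and
#' the detection-limit schedule applied. A single seed governs all draws;
#' per-colony sub-seeds are derived from the colony id so colonies are
#' independent of design order.
#'
#' @param design a [study_design()].
#' @param scenarios scenario table from [trend_scenarios()]; must cover
#'   every colony x class.
#' @param seed integer seed.
#' @param censor apply the MLOD schedule (default TRUE).
#' @return list of class `hfr_study` with elements `measurements`,
#'   `covariates` and `truth` (every drawn parameter and latent mean).
#' @export
#' @examples
#' des <- study_design()
#' study <- simulate_study(des, trend_scenarios(des), seed = 42)
#' head(study$measurements)
simulate_study <- function(design, scenarios = trend_scenarios(design),
                           seed = 1L, censor = TRUE) {
  stopifnot(inherits(design, "study_design"))
  classes <- sort(unique(scenarios$hfr_class))
  key <- paste(scenarios$colony_id, scenarios$hfr_class)
  need <- as.vector(outer(design$colonies$colony_id, classes, paste))
  if (!all(need %in% key))
    abort("scenarios must cover every colony x class in the design")
  # breakpoints must be strictly inside each colony's sampled years
  for (i in seq_len(nrow(scenarios))) {
    sc <- scenarios[i, ]
    if (is.na(sc$breakpoint_year)) next
    ys <- design$years[[sc$colony_id]]
    if (sc$breakpoint_year <= min(ys) || sc$breakpoint_year >= max(ys))
      abort(sprintf("breakpoint %d for %s/%s is not strictly inside its sampled years",
                    sc$breakpoint_year, sc$colony_id, sc$hfr_class))
  }

  # shared draws (year effects) come from the master seed
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  year_eff <- matrix(stats::rnorm(length(classes) * length(design$all_years),
                                  0, design$year_effect_sd),
                     nrow = length(classes),
                     dimnames = list(classes, as.character(design$all_years)))

  meas <- list(); covs <- list(); cy_truth <- list(); pool_truth <- list()
  congeners <- names(design$congener_props)

  for (ci in seq_len(nrow(design$colonies))) {
    cid <- design$colonies$colony_id[ci]
    region <- design$colonies$region[ci]
    off <- design$region_offsets[[region]]
    ys <- sort(design$years[[cid]])
    t0 <- min(ys)
    set.seed(derive_seed(seed, cid))
    n_pools <- sample(seq.int(design$pools_range[1], design$pools_range[2]),
                      length(ys), replace = TRUE)
    for (yi in seq_along(ys)) {
      yr <- ys[yi]
      np <- n_pools[yi]
      pool_ids <- sprintf("%s-%d-P%d", gsub("\\s+", "", cid), yr, seq_len(np))
      n_eggs <- sample(seq.int(design$eggs_range[1], design$eggs_range[2]),
                       np, replace = TRUE)
      # covariates at the colony-year level
      covs[[length(covs) + 1]] <- data.frame(
        colony_id = cid, year = yr,
        egg_mass = max(stats::rnorm(1, 92, 4), 1),
        length = max(stats::rnorm(1, 7.2, 0.15), 0.1),
        breadth = max(stats::rnorm(1, 5.0, 0.10), 0.1),
        pct_lipid = max(stats::rnorm(1, 9.5, 1.2), 0.5),
        stringsAsFactors = FALSE)
      for (cls in classes) {
        sc <- scenarios[scenarios$colony_id == cid & scenarios$hfr_class == cls, ]
        det_mean <- scenario_mean(sc, yr, t0) + off
        cy_mean <- det_mean + year_eff[cls, as.character(yr)]
        a <- stats::rnorm(1, 0, sc$residual_sd)
        s_pool <- cy_mean + a + stats::rnorm(np, 0, sc$pool_sd)
        cy_truth[[length(cy_truth) + 1]] <- data.frame(
          colony_id = cid, region = region, hfr_class = cls, year = yr,
          mean_ln_det = det_mean, mean_ln = cy_mean + a, n_pools = np,
          stringsAsFactors = FALSE)
        pool_truth[[length(pool_truth) + 1]] <- data.frame(
          colony_id = cid, hfr_class = cls, year = yr, pool_id = pool_ids,
          ln_sum = s_pool, stringsAsFactors = FALSE)
        # split the class sum into analyte concentrations
        total <- exp(s_pool)
        an_rows <- switch(cls,
          HBCDD  = data.frame(analyte = "alpha-HBCDD",
                              conc = total, pool = seq_len(np)),
          BDE209 = data.frame(analyte = "BDE-209",
                              conc = total, pool = seq_len(np)),
          SumDP  = split_composition(total, design$dp_split,
                                     design$composition_sd, design$rho),
          Sum11PBDE = {
            main <- split_composition(total, design$congener_props,
                                      design$composition_sd, design$rho)
            b190 <- data.frame(analyte = "BDE-190",
                               conc = design$bde190_frac * total,
                               pool = seq_len(np))
            rbind(main, b190)
          })
        meas[[length(meas) + 1]] <- data.frame(
          colony_id = cid, region = region, year = yr,
          pool_id = pool_ids[an_rows$pool], n_eggs = n_eggs[an_rows$pool],
          analyte = an_rows$analyte, conc = an_rows$conc,
          stringsAsFactors = FALSE)
      }
    }
  }
  measurements <- do.call(rbind, meas)
  rownames(measurements) <- NULL
  sched <- design$mlod_schedule
  idx <- match(paste(measurements$analyte, measurements$year),
               paste(sched$analyte, sched$year))
  if (anyNA(idx))
    abort("MLOD schedule does not cover every analyte-year in the study")
  measurements$mlod <- sched$mlod[idx]
  measurements$mloq <- sched$mloq[idx]
  measurements$detected <- TRUE
  truth <- list(design = design, scenarios = scenarios, seed = seed,
                region_offsets = design$region_offsets, year_effects = year_eff,
                colony_year = do.call(rbind, cy_truth),
                pools = do.call(rbind, pool_truth))
  if (censor) {
    measurements <- apply_censoring(measurements, sched)
    truth$detection_summary <- attr(measurements, "detection_summary")
  }
  covariates <- do.call(rbind, covs)
  structure(list(measurements = measurements, covariates = covariates,
                 truth = truth), class = "hfr_study")
}

# split pool totals into analyte concentrations: composition noise with a
# common factor loading rho, renormalized so each pool's sum is exact
split_composition <- function(total, props, sd, rho) {
  np <- length(total)
  k <- length(props)
  z <- stats::rnorm(np)                     # common factor per pool
  eps <- matrix(stats::rnorm(np * k), np, k)
  eta <- sd * (rho * z + sqrt(1 - rho^2) * eps)
  w <- matrix(props, np, k, byrow = TRUE) * exp(eta)
  w <- w / rowSums(w) * total
  data.frame(analyte = rep(names(props), each = np),
             conc = as.vector(w), pool = rep(seq_len(np), k),
             stringsAsFactors = FALSE)
}

#' Apply a detection-limit schedule to measurements
#'
#' Rows whose concentration falls below the scheduled MLOD for their analyte
#' and year are marked censored: the detect flag is cleared and the numeric
#' concentration nulled. Detection fractions per analyte are recorded in the
#' `detection_summary` attribute.
#'
#' @param measurements measurement data.frame (internal column names).
#' @param schedule data.frame `analyte, year, mlod, mloq` covering every
#'   analyte-year present.
#' @return the measurements with censoring applied.
#' @export
apply_censoring <- function(measurements, schedule) {
  idx <- match(paste(measurements$analyte, measurements$year),
               paste(schedule$analyte, schedule$year))
  if (anyNA(idx)) {
    miss <- unique(paste(measurements$analyte, measurements$year)[is.na(idx)])
    abort("MLOD schedule missing entries for: ",
          paste(utils::head(miss, 5), collapse = "; "))
  }
  measurements$mlod <- schedule$mlod[idx]
  measurements$mloq <- schedule$mloq[idx]
  cens <- !is.na(measurements$conc) & measurements$conc < measurements$mlod
  measurements$detected <- !cens & measurements$detected
  measurements$conc[!measurements$detected] <- NA_real_
  det <- stats::aggregate(detected ~ analyte, data = measurements,
                          FUN = function(v) c(n = length(v), rate = mean(v)))
  summary <- data.frame(analyte = det$analyte,
                        n = det$detected[, "n"],
                        detection_rate = det$detected[, "rate"],
                        stringsAsFactors = FALSE)
  attr(measurements, "detection_summary") <- summary
  measurements
}

#' @export
print.hfr_study <- function(x, ...) {
  m <- x$measurements
  cat("Synthetic HFR monitoring study\n")
  cat(sprintf("  %d colonies, years %d-%d, %d measurement rows (%d analytes)\n",
              length(unique(m$colony_id)), min(m$year), max(m$year),
              nrow(m), length(unique(m$analyte))))
  cat(sprintf("  censored rows: %d (%.1f%%)\n", sum(!m$detected),
              100 * mean(!m$detected)))
  invisible(x)
}
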