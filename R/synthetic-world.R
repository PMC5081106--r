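#' Configuration for a synthetic world
#'
#' Defines the hierarchy sizes and the generative parameters of a synthetic
#' "world": a known ground-truth diabetes-prevalence surface for every
#' country, year, sex and age group, plus covariates and populations. The
#' defaults emulate the conditions the estimation pipeline is designed for:
#' a rising global trend on the probit scale, nested country/region/
#' super-region deviations in level and slope, a smooth non-linear wiggle,
#' an age profile that steepens where prevalence is higher, covariate
#' effects, and a constant rural-urban gap.
#'
#' @param n_super_regions,n_regions_per_super,n_countries_per_region hierarchy
#'   sizes (all >= 1).
#' @param years simulation years (calendar, length >= 2).
#' @param sexes subset of `c("female", "male")`.
#' @param intercept global probit prevalence at the reference age (50),
#'   mid-period, average covariates.
#' @param slope_decade global linear trend, probit units per decade.
#' @param sd_super_level,sd_super_slope,sd_region_level,sd_region_slope,sd_country_level,sd_country_slope
#'   SDs of the nested level and slope deviations (probit / probit per decade).
#' @param sd_wiggle_global,sd_wiggle_country SDs of the smooth non-linear
#'   year-deviation coefficients.
#' @param age_slope,age_curv linear and quadratic coefficients of the base
#'   probit age profile around the reference age of 50 years.
#' @param steepness_gamma exponential steepness coefficient: the age profile
#'   is multiplied by exp(gamma * (level - intercept)), so countries/years at
#'   higher prevalence have steeper age gradients.
#' @param sex_effect named probit offsets by sex.
#' @param covariate_effects named probit effects of the z-scored country
#'   covariates (education years, urban fraction, food availability score,
#'   mean BMI).
#' @param rural_urban_gap probit difference between the urban and rural
#'   sub-surfaces (constant over age).
#' @param definition_offsets named probit offsets of the alternative
#'   diabetes definitions relative to the primary outcome (fasting plasma
#'   glucose >= 7.0 mmol/L, or diagnosis, or medication).
#' @param fpg_cutoff_per_unit probit shift per mmol/L by which a non-standard
#'   fasting-glucose cutoff exceeds 7.0.
#' @param mean_fpg_map two-parameter map `c(a, b)`: probit(primary prevalence)
#'   = a + b * (population mean fasting plasma glucose, mmol/L).
#' @param pop_base_log,pop_base_sd log-scale mean and SD of country adult
#'   population size.
#' @param pop_growth annual population growth rate.
#' @param age_decay_start,age_decay_end exponential age-structure decay rates
#'   at the first and last simulated year; the decline from start to end
#'   produces population ageing.
#' @return A list of class `WorldConfig`.
#' @export
worldConfig <- function(n_super_regions = 2,
                        n_regions_per_super = 2,
                        n_countries_per_region = 3,
                        years = 1980:2014,
                        sexes = c("female", "male"),
                        intercept = -1.6,
                        slope_decade = 0.11,
                        sd_super_level = 0.15, sd_super_slope = 0.05,
                        sd_region_level = 0.12, sd_region_slope = 0.04,
                        sd_country_level = 0.10, sd_country_slope = 0.04,
                        sd_wiggle_global = 0.05, sd_wiggle_country = 0.04,
                        age_slope = 0.030, age_curv = -2e-4,
                        steepness_gamma = 0.25,
                        sex_effect = c(female = 0, male = 0.05),
                        covariate_effects = c(education = -0.03,
                                              urbanisation = 0.06,
                                              food = 0.03,
                                              bmi = 0.12),
                        rural_urban_gap = 0.15,
                        definition_offsets = c(OGTT_11_1 = 0.20,
                                               HBA1C_6_5 = 0.10),
                        fpg_cutoff_per_unit = -0.45,
                        mean_fpg_map = c(a = -7.5, b = 1.1),
                        pop_base_log = log(5e6), pop_base_sd = 1,
                        pop_growth = 0.015,
                        age_decay_start = 0.030, age_decay_end = 0.018) {
  cfg <- as.list(environment())
  if (cfg$n_super_regions < 1 || cfg$n_regions_per_super < 1 ||
      cfg$n_countries_per_region < 1) {
    stop("hierarchy must contain at least one super-region, region and country")
  }
  if (length(cfg$years) < 2) stop("year span must cover at least 2 years")
  if (!all(cfg$sexes %in% c("female", "male")) || length(cfg$sexes) < 1) {
    stop("sexes must be a non-empty subset of c('female', 'male')")
  }
  structure(cfg, class = "WorldConfig")
}

# smooth non-linear basis over years, orthogonalised against intercept and
# linear trend so wiggles do not alias level or slope
wiggleBasis <- function(years) {
  tc <- (years - mean(years)) / 10
  B <- splines::ns(years, df = 3)
  B <- apply(B, 2, function(col) stats::residuals(stats::lm(col ~ tc)))
  unname(B)
}

#' Build a synthetic ground-truth world
#'
#' Draws a complete ground truth from the hierarchical generative process in
#' [worldConfig()]: true prevalence surfaces for every country, year, sex and
#' standard age group, country covariate series, and populations. All
#' generating parameters (including the realised hierarchical deviations) are
#' retained in the returned object so that recovery tests can compare
#' estimates against known truth.
#'
#' @param config a [worldConfig()] object.
#' @param seed integer seed; the same (config, seed) pair reproduces the
#'   world exactly.
#' @return An object of class `WorldTruth` with elements `hierarchy` (country
#'   -> region -> super-region table), `years`, `sexes`, `age_groups`,
#'   `prev` (array country x year x sex x age of true proportions), `mu`
#'   (probit level surface at the reference age), `covariates` (data.frame),
#'   `cov_scaling`, `population` (array country x year x sex x age),
#'   `params`, `seed`.
#' @export
buildWorld <- function(config = worldConfig(), seed = 1L) {
  stopifnot(inherits(config, "WorldConfig"))
  ag <- ageGroupTable()
  years <- config$years
  tc <- (years - mean(years)) / 10
  nS <- config$n_super_regions
  nR <- nS * config$n_regions_per_super
  nC <- nR * config$n_countries_per_region

  region_of <- rep(seq_len(nR), each = config$n_countries_per_region)
  super_of_region <- rep(seq_len(nS), each = config$n_regions_per_super)
  hierarchy <- data.frame(
    country_id = sprintf("C%02d", seq_len(nC)),
    region_id = sprintf("R%02d", region_of),
    super_region_id = sprintf("S%02d", super_of_region[region_of]),
    stringsAsFactors = FALSE
  )

  set.seed(substreamSeed(seed, 0))
  dev <- list(
    super_level = stats::rnorm(nS, 0, config$sd_super_level),
    super_slope = stats::rnorm(nS, 0, config$sd_super_slope),
    region_level = stats::rnorm(nR, 0, config$sd_region_level),
    region_slope = stats::rnorm(nR, 0, config$sd_region_slope),
    country_level = stats::rnorm(nC, 0, config$sd_country_level),
    country_slope = stats::rnorm(nC, 0, config$sd_country_slope)
  )
  B <- wiggleBasis(years)
  wig_global <- stats::rnorm(ncol(B), 0, config$sd_wiggle_global)
  wig_country <- matrix(stats::rnorm(nC * ncol(B), 0, config$sd_wiggle_country),
                        nrow = nC)

  # covariates: country series with country-specific trends and smooth
  # AR(1) fluctuations, so no covariate is a pure linear function of time
  smoothAR <- function(sd) {
    as.numeric(stats::filter(stats::rnorm(length(years), 0, sd), 0.85,
                             "recursive"))
  }
  covariates <- do.call(rbind, lapply(seq_len(nC), function(c) {
    data.frame(
      country_id = hierarchy$country_id[c],
      year = years,
      education = stats::runif(1, 4, 12) +
        stats::runif(1, 0.02, 0.10) * (years - years[1]) + smoothAR(0.08),
      urbanisation = stats::plogis(stats::runif(1, -1, 1) +
        stats::runif(1, 0.01, 0.06) * (years - mean(years)) + smoothAR(0.02)),
      food = stats::rnorm(1, 0, 1) +
        stats::runif(1, -0.01, 0.03) * (years - mean(years)) + smoothAR(0.05),
      bmi = stats::runif(1, 23, 27) +
        stats::runif(1, 0.01, 0.07) * (years - years[1]) + smoothAR(0.04),
      stringsAsFactors = FALSE
    )
  }))

  cov_names <- names(config$covariate_effects)
  Zraw <- as.matrix(covariates[, cov_names])
  cov_scaling <- list(center = colMeans(Zraw), scale = apply(Zraw, 2, stats::sd))
  cov_scaling$scale[cov_scaling$scale == 0] <- 1
  Z <- sweep(sweep(Zraw, 2, cov_scaling$center), 2, cov_scaling$scale, "/")
  cov_term <- as.numeric(Z %*% config$covariate_effects)

  # probit level surface mu[country, year, sex] at the reference age
  sr_of <- super_of_region[region_of]
  mu <- array(NA_real_, dim = c(nC, length(years), length(config$sexes)),
              dimnames = list(hierarchy$country_id, years, config$sexes))
  covariates$cov_term <- cov_term
  for (c in seq_len(nC)) {
    r <- region_of[c]; s <- sr_of[c]
    base <- config$intercept +
      (config$slope_decade + dev$super_slope[s] + dev$region_slope[r] +
         dev$country_slope[c]) * tc +
      dev$super_level[s] + dev$region_level[r] + dev$country_level[c] +
      as.numeric(B %*% (wig_global + wig_country[c, ]))
    ct <- cov_term[covariates$country_id == hierarchy$country_id[c]]
    for (x in seq_along(config$sexes)) {
      mu[c, , x] <- base + ct + config$sex_effect[[config$sexes[x]]]
    }
  }

  # age profile, steepened with the country-year level
  f0 <- config$age_slope * (ag$mid - 50) + config$age_curv * (ag$mid - 50)^2
  prev <- array(NA_real_,
                dim = c(nC, length(years), length(config$sexes), nrow(ag)),
                dimnames = list(hierarchy$country_id, years, config$sexes,
                                ag$label))
  for (a in seq_len(nrow(ag))) {
    prev[, , , a] <- stats::pnorm(
      mu + f0[a] * exp(config$steepness_gamma * (mu - config$intercept)))
  }

  # populations: growing totals with an ageing age structure
  base_pop <- exp(stats::rnorm(nC, config$pop_base_log, config$pop_base_sd))
  decay <- seq(config$age_decay_start, config$age_decay_end,
               length.out = length(years))
  population <- array(NA_real_,
                      dim = dim(prev), dimnames = dimnames(prev))
  for (t in seq_along(years)) {
    w <- exp(-decay[t] * (ag$mid - 18))
    w <- w / sum(w)
    tot <- base_pop * (1 + config$pop_growth)^(years[t] - years[1])
    for (x in seq_along(config$sexes)) {
      population[, t, x, ] <- outer(tot / length(config$sexes), w)
    }
  }

  structure(list(
    hierarchy = hierarchy, years = years, sexes = config$sexes,
    age_groups = ag, prev = prev, mu = mu,
    covariates = covariates[, c("country_id", "year", cov_names)],
    cov_scaling = cov_scaling, population = population,
    params = c(config, list(deviations = dev, wiggle_global = wig_global,
                            wiggle_country = wig_country)),
    seed = seed
  ), class = "WorldTruth")
}

#' @export
print.WorldTruth <- function(x, ...) {
  cat("WorldTruth:", nrow(x$hierarchy), "countries in",
      length(unique(x$hierarchy$region_id)), "regions /",
      length(unique(x$hierarchy$super_region_id)), "super-regions;",
      min(x$years), "-", max(x$years), ";",
      paste(x$sexes, collapse = "/"), "; seed", x$seed, "\n")
  invisible(x)
}

# true age-group prevalences for one country/year/sex on the requested
# sub-surface (mixed, urban-only or rural-only)
trueGroupPrev <- function(world, country, year, sex, urbanicity = "mixed") {
  ci <- match(country, world$hierarchy$country_id)
  ti <- match(year, world$years)
  xi <- match(sex, world$sexes)
  if (is.na(ci)) stop("unknown country: ", country)
  if (is.na(ti)) stop("year ", year, " outside the world's support")
  if (is.na(xi)) stop("sex ", sex, " not simulated in this world")
  p <- world$prev[ci, ti, xi, ]
  if (urbanicity == "mixed") return(p)
  urb <- world$covariates$urbanisation[
    world$covariates$country_id == country & world$covariates$year == year]
  gap <- world$params$rural_urban_gap
  shift <- if (urbanicity == "urban_only") gap * (1 - urb) else -gap * urb
  stats::pnorm(stats::qnorm(p) + shift)
}

#' Age-standardised true prevalence
#'
#' Exact weighted sum of the true age-specific prevalences of a world; the
#' oracle against which model estimates are scored in recovery tests.
#'
#' @param world a [buildWorld()] result.
#' @param country,year,sex the cell to summarise.
#' @param weights a `StandardPopulation`.
#' @return A proportion.
#' @export
trueSummary <- function(world, country, year, sex,
                        weights = whoStandardPopulation()) {
  p <- trueGroupPrev(world, country, year, sex)
  sum(unclass(weights) * p)
}

#' Survey simulation plan
#'
#' Bundles a study table with the global bias parameters that the trend
#' model is later asked to undo: probit-scale offsets for subnational and
#' community studies and scope-specific non-sampling noise SDs.
#'
#' @param studies data.frame with one row per study: `study_id`,
#'   `country_id`, `mid_year`, `sex`, `scope` (national/subnational/
#'   community), `urbanicity` (mixed/urban_only/rural_only),
#'   `study_urban_fraction`, `definition`, `fpg_cutoff` (mmol/L, used when
#'   definition is FPG_CUTOFF), `n_per_stratum`, `age_scheme` ("decade" or
#'   "fine").
#' @param offsets named probit offsets by scope.
#' @param urban_offset,rural_offset additional probit offsets for urban-only
#'   and rural-only studies on top of sampling the urban/rural sub-surface.
#' @param noise_sd named non-sampling (study-level) noise SDs by scope.
#' @return A list of class `SurveyPlan`.
#' @export
surveyPlan <- function(studies,
                       offsets = c(national = 0, subnational = 0.05,
                                   community = 0.2),
                       urban_offset = 0, rural_offset = 0,
                       noise_sd = c(national = 0, subnational = 0.06,
                                    community = 0.12)) {
  stopifnot(all(noise_sd >= 0))
  if (nrow(studies) > 0) {
    stopifnot(all(studies$n_per_stratum >= 1))
    stopifnot(all(studies$scope %in% names(offsets)))
  }
  structure(list(studies = studies,
                 bias = list(offsets = offsets, urban_offset = urban_offset,
                             rural_offset = rural_offset,
                             noise_sd = noise_sd)),
            class = "SurveyPlan")
}

#' Draw a random survey plan for a world
#'
#' Convenience generator of a realistic study mix: mostly national surveys,
#' with subnational and community studies (the latter carrying the plan's
#' bias offsets), log-uniform per-stratum sample sizes and decadal age
#' reporting.
#'
#' @param world a `WorldTruth`.
#' @param n_studies number of studies.
#' @param seed integer seed.
#' @param scope_probs sampling probabilities of the three scopes.
#' @param definition_probs named sampling probabilities over definitions.
#' @param countries optional subset of countries to draw studies from (e.g.
#'   to leave a country data-free).
#' @param n_range range of per-stratum sample sizes (log-uniform).
#' @param sexes subset of the world's sexes to survey.
#' @param ... passed to [surveyPlan()] (bias offsets and noise SDs).
#' @return A `SurveyPlan`.
#' @export
makeSurveyPlan <- function(world, n_studies, seed = 1L,
                           scope_probs = c(national = 0.6, subnational = 0.2,
                                           community = 0.2),
                           definition_probs = c(PRIMARY_FPG7 = 1),
                           countries = NULL, n_range = c(150, 3000),
                           sexes = world$sexes, ...) {
  if (is.null(countries)) countries <- world$hierarchy$country_id
  set.seed(substreamSeed(seed, 999))
  if (n_studies == 0) {
    studies <- data.frame(study_id = character(), country_id = character(),
                          mid_year = integer(), sex = character(),
                          scope = character(), urbanicity = character(),
                          study_urban_fraction = numeric(),
                          definition = character(), fpg_cutoff = numeric(),
                          n_per_stratum = integer(), age_scheme = character(),
                          stringsAsFactors = FALSE)
    return(surveyPlan(studies, ...))
  }
  scope <- sample(names(scope_probs), n_studies, TRUE, prob = scope_probs)
  urbanicity <- ifelse(scope == "national", "mixed",
                       sample(c("mixed", "urban_only", "rural_only"),
                              n_studies, TRUE, prob = c(0.6, 0.25, 0.15)))
  country <- sample(countries, n_studies, TRUE)
  year <- sample(world$years, n_studies, TRUE)
  definition <- sample(names(definition_probs), n_studies, TRUE,
                       prob = definition_probs)
  studies <- data.frame(
    study_id = sprintf("study%04d", seq_len(n_studies)),
    country_id = country, mid_year = year,
    sex = sample(sexes, n_studies, TRUE),
    scope = scope, urbanicity = urbanicity,
    study_urban_fraction = NA_real_,
    definition = definition,
    fpg_cutoff = ifelse(definition == "FPG_CUTOFF",
                        sample(c(7.8, 6.7), n_studies, TRUE), NA_real_),
    n_per_stratum = round(exp(stats::runif(n_studies, log(n_range[1]),
                                           log(n_range[2])))),
    age_scheme = "decade", stringsAsFactors = FALSE
  )
  urb <- mapply(function(c, y) {
    world$covariates$urbanisation[world$covariates$country_id == c &
                                    world$covariates$year == y]
  }, studies$country_id, studies$mid_year)
  studies$study_urban_fraction <- ifelse(
    studies$urbanicity == "urban_only", 1,
    ifelse(studies$urbanicity == "rural_only", 0, urb))
  surveyPlan(studies, ...)
}

# decadal reporting bands aligned with the standard groups
decadeBands <- function() {
  data.frame(age_lo = c(18, seq(20, 70, 10), 80),
             age_hi = c(20, seq(30, 80, 10), Inf))
}

#' Simulate survey datapoints from a world
#'
#' Draws one prevalence observation per sex-age stratum of every planned
#' study. Each stratum's true prevalence is the population-weighted mean of
#' the world's age-group prevalences over the reported band (on the urban or
#' rural sub-surface for urban-only/rural-only studies), shifted on the
#' probit scale by the plan's scope offset and a study-level non-sampling
#' error, then observed with binomial sampling error. Alternative-definition
#' studies report prevalence under their own definition (or, for MEAN_FPG
#' sources, the population mean fasting glucose) and must be cross-walked
#' before model fitting.
#'
#' Each study consumes its own random substream derived from `(seed,
#' study index)`, so output does not depend on iteration order.
#'
#' @param world a `WorldTruth`.
#' @param plan a `SurveyPlan`; strata must lie inside the world's support
#'   (out-of-range years/countries are an error, never clipped).
#' @param seed integer seed.
#' @return A data.frame of survey datapoints (columns: `study_id`,
#'   `country_id`, `mid_year`, `sex`, `age_lo`, `age_hi`, `n_examined`,
#'   `prevalence`, `se`, `definition`, `fpg_cutoff`, `mean_fpg`, `scope`,
#'   `urbanicity`, `study_urban_fraction`).
#' @export
simulateSurveys <- function(world, plan, seed = 1L) {
  stopifnot(inherits(world, "WorldTruth"), inherits(plan, "SurveyPlan"))
  st <- plan$studies
  out <- vector("list", nrow(st))
  for (i in seq_len(nrow(st))) {
    s <- st[i, ]
    if (!s$country_id %in% world$hierarchy$country_id) {
      stop("study ", s$study_id, ": unknown country ", s$country_id)
    }
    if (!s$mid_year %in% world$years) {
      stop("study ", s$study_id, ": year ", s$mid_year,
           " outside the world's support")
    }
    set.seed(substreamSeed(seed, i))
    bands <- if (identical(s$age_scheme, "fine")) {
      world$age_groups[, c("age_lo", "age_hi")]
    } else decadeBands()
    study_eff <- stats::rnorm(1, 0, plan$bias$noise_sd[[s$scope]])
    offset <- plan$bias$offsets[[s$scope]] +
      switch(s$urbanicity, urban_only = plan$bias$urban_offset,
             rural_only = plan$bias$rural_offset, 0)
    pgrp <- trueGroupPrev(world, s$country_id, s$mid_year, s$sex,
                          s$urbanicity)
    pop <- world$population[s$country_id, as.character(s$mid_year), s$sex, ]
    rows <- lapply(seq_len(nrow(bands)), function(b) {
      idx <- ageGroupIndices(bands$age_lo[b], bands$age_hi[b])
      p_true <- sum(pop[idx] * pgrp[idx]) / sum(pop[idx])
      q <- stats::qnorm(p_true) + offset + study_eff
      n <- s$n_per_stratum
      if (identical(s$definition, "MEAN_FPG")) {
        a <- world$params$mean_fpg_map[["a"]]
        b2 <- world$params$mean_fpg_map[["b"]]
        mfpg <- (q - a) / b2 + stats::rnorm(1, 0, 1.2 / sqrt(n))
        prevalence <- NA_real_; se <- 1.2 / sqrt(n); mean_fpg <- mfpg
      } else {
        q_def <- q + definitionShift(world, s$definition, s$fpg_cutoff)
        x <- stats::rbinom(1, n, stats::pnorm(q_def))
        prevalence <- x / n
        pc <- correctedPrevalence(prevalence, n)
        se <- sqrt(pc * (1 - pc) / n)
        mean_fpg <- NA_real_
      }
      data.frame(study_id = s$study_id, country_id = s$country_id,
                 mid_year = s$mid_year, sex = s$sex,
                 age_lo = bands$age_lo[b], age_hi = bands$age_hi[b],
                 n_examined = n, prevalence = prevalence, se = se,
                 definition = s$definition, fpg_cutoff = s$fpg_cutoff,
                 mean_fpg = mean_fpg, scope = s$scope,
                 urbanicity = s$urbanicity,
                 study_urban_fraction = s$study_urban_fraction,
                 stringsAsFactors = FALSE)
    })
    out[[i]] <- do.call(rbind, rows)
  }
  if (length(out) == 0) {
    return(data.frame(study_id = character(), country_id = character(),
                      mid_year = integer(), sex = character(),
                      age_lo = numeric(), age_hi = numeric(),
                      n_examined = integer(), prevalence = numeric(),
                      se = numeric(), definition = character(),
                      fpg_cutoff = numeric(), mean_fpg = numeric(),
                      scope = character(), urbanicity = character(),
                      study_urban_fraction = numeric(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

# probit shift of an alternative definition relative to the primary outcome
definitionShift <- function(world, definition, fpg_cutoff = NA) {
  switch(definition,
         PRIMARY_FPG7 = 0,
         OGTT_11_1 = world$params$definition_offsets[["OGTT_11_1"]],
         HBA1C_6_5 = world$params$definition_offsets[["HBA1C_6_5"]],
         FPG_CUTOFF = world$params$fpg_cutoff_per_unit * (fpg_cutoff - 7.0),
         stop("unknown definition: ", definition))
}

#' Simulate paired-definition observations
#'
#' Emulates data sources with individual-level data from which prevalence
#' can be computed under both the primary outcome and one alternative
#' definition on the same stratum; these pairs train the cross-walk
#' regressions. Each pair is a single standard age group of a national,
#' unbiased stratum; both prevalences are observed with binomial error at
#' the same sample size.
#'
#' @param world a `WorldTruth`.
#' @param n_pairs number of paired strata.
#' @param source_definition the alternative definition
#'   (`OGTT_11_1`, `HBA1C_6_5`, `FPG_CUTOFF`, `MEAN_FPG`).
#' @param seed integer seed.
#' @param n_range log-uniform range of sample sizes.
#' @param fpg_cutoff cutoff used when `source_definition = "FPG_CUTOFF"`.
#' @return A data.frame of paired observations with stratum metadata, the
#'   income stand-in covariate (country mean education years) and region id.
#' @export
simulatePairedSurveys <- function(world, n_pairs, source_definition,
                                  seed = 1L, n_range = c(30, 2000),
                                  fpg_cutoff = 7.8) {
  set.seed(substreamSeed(seed, 555))
  ag <- world$age_groups
  ci <- sample(nrow(world$hierarchy), n_pairs, TRUE)
  yi <- sample(world$years, n_pairs, TRUE)
  xi <- sample(world$sexes, n_pairs, TRUE)
  ai <- sample(nrow(ag), n_pairs, TRUE)
  n <- round(exp(stats::runif(n_pairs, log(n_range[1]), log(n_range[2]))))
  country <- world$hierarchy$country_id[ci]
  rows <- lapply(seq_len(n_pairs), function(i) {
    p <- trueGroupPrev(world, country[i], yi[i], xi[i])[ai[i]]
    q <- stats::qnorm(p)
    x_p <- stats::rbinom(1, n[i], p)
    if (identical(source_definition, "MEAN_FPG")) {
      a <- world$params$mean_fpg_map[["a"]]
      b <- world$params$mean_fpg_map[["b"]]
      src_prev <- NA_real_
      mfpg <- (q - a) / b + stats::rnorm(1, 0, 1.2 / sqrt(n[i]))
    } else {
      q_s <- q + definitionShift(world, source_definition, fpg_cutoff)
      src_prev <- stats::rbinom(1, n[i], stats::pnorm(q_s)) / n[i]
      mfpg <- NA_real_
    }
    inc <- world$covariates$education[
      world$covariates$country_id == country[i] &
        world$covariates$year == yi[i]]
    data.frame(country_id = country[i],
               region_id = world$hierarchy$region_id[ci[i]],
               mid_year = yi[i], sex = xi[i], age_mid = ag$mid[ai[i]],
               n_examined = n[i], prevalence_primary = x_p / n[i],
               prevalence_source = src_prev, mean_fpg = mfpg,
               income = inc, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write / read the delimited-text tables of a world
#'
#' `writeWorldTables()` writes the covariate and population tables of a
#' world as UTF-8 CSV with header rows (age intervals as two integer
#' columns, half-open); `writeSurveyTable()` / `readSurveyTable()` do the
#' same for survey datapoint tables.
#'
#' @param world a `WorldTruth`.
#' @param dir output directory (created if needed).
#' @return `writeWorldTables()` returns the paths written, invisibly.
#' @export
writeWorldTables <- function(world, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cov_path <- file.path(dir, "covariates.csv")
  utils::write.csv(world$covariates, cov_path, row.names = FALSE)
  ag <- world$age_groups
  pop <- as.data.frame.table(world$population, stringsAsFactors = FALSE,
                             responseName = "population")
  names(pop)[1:4] <- c("country_id", "year", "sex", "age_label")
  gi <- match(pop$age_label, ag$label)
  pop$year <- as.integer(pop$year)
  pop$age_lo <- ag$age_lo[gi]
  pop$age_hi <- ifelse(is.finite(ag$age_hi[gi]), ag$age_hi[gi], -1L)
  pop_path <- file.path(dir, "population.csv")
  utils::write.csv(pop[, c("country_id", "year", "sex", "age_lo", "age_hi",
                           "population")], pop_path, row.names = FALSE)
  invisible(c(covariates = cov_path, population = pop_path))
}

#' @rdname writeWorldTables
#' @param datapoints a survey datapoint data.frame.
#' @param path CSV path.
#' @export
writeSurveyTable <- function(datapoints, path) {
  utils::write.csv(datapoints, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeWorldTables
#' @export
readSurveyTable <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
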