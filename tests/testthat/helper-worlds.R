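# Shared fixtures, all generated in code. Expensive model fits are memoised
# so several test files can reuse the same run.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- force(expr)
  .fixture_cache[[name]]
}

whoWts <- function() whoStandardPopulation()

# a world whose surfaces are exactly flat at a known prevalence: no trend,
# no hierarchy variation, no age gradient, no covariate effects
flatWorldConfig <- function(p = 0.10, years = 2000:2014, ...) {
  worldConfig(
    intercept = qnorm(p), slope_decade = 0,
    sd_super_level = 0, sd_super_slope = 0, sd_region_level = 0,
    sd_region_slope = 0, sd_country_level = 0, sd_country_slope = 0,
    sd_wiggle_global = 0, sd_wiggle_country = 0,
    age_slope = 0, age_curv = 0, steepness_gamma = 0,
    sex_effect = c(female = 0, male = 0),
    covariate_effects = c(education = 0, urbanisation = 0, food = 0, bmi = 0),
    rural_urban_gap = 0, years = years, sexes = "female", ...
  )
}

# single-study survey plan builder
oneStudyPlan <- function(world, country, year, n, scope = "national",
                         urbanicity = "mixed", definition = "PRIMARY_FPG7",
                         age_scheme = "decade", ...) {
  urb <- world$covariates$urbanisation[
    world$covariates$country_id == country & world$covariates$year == year]
  frac <- switch(urbanicity, urban_only = 1, rural_only = 0, urb)
  surveyPlan(data.frame(
    study_id = "s0001", country_id = country, mid_year = year,
    sex = world$sexes[1], scope = scope, urbanicity = urbanicity,
    study_urban_fraction = frac, definition = definition,
    fpg_cutoff = NA_real_, n_per_stratum = n, age_scheme = age_scheme,
    stringsAsFactors = FALSE), ...)
}

# the reduced recovery world: 12 countries, 35 years, one sex, a steep
# programmed post-1980 rise, one data-free country (C12), community studies
# biased by +0.2 probit
recoveryWorld <- function() {
  memo("recovery_world",
       buildWorld(worldConfig(slope_decade = 0.35, sexes = "female"),
                  seed = 11))
}

recoveryData <- function() {
  memo("recovery_data", {
    w <- recoveryWorld()
    plan <- makeSurveyPlan(
      w, 110, seed = 12,
      scope_probs = c(national = 0.65, subnational = 0.15, community = 0.2),
      countries = w$hierarchy$country_id[-12], sexes = "female")
    simulateSurveys(w, plan, seed = 13)
  })
}

recoveryFit <- function() {
  memo("recovery_fit",
       suppressWarnings(fitTrendModel(recoveryData(),
                                      recoveryWorld()$covariates,
                                      recoveryWorld()$hierarchy,
                                      reducedModelConfig(seed = 5))))
}

# small flat world + fit, for the flat-trend arm of the target check
flatFit <- function() {
  memo("flat_fit", {
    w <- memo("flat_world",
              buildWorld(flatWorldConfig(
                p = 0.08, years = 1995:2014,
                n_super_regions = 1, n_regions_per_super = 2,
                n_countries_per_region = 2), seed = 21))
    plan <- makeSurveyPlan(w, 35, seed = 22,
                           scope_probs = c(national = 1, subnational = 0,
                                           community = 0),
                           sexes = "female")
    dp <- simulateSurveys(w, plan, seed = 23)
    suppressWarnings(fitTrendModel(
      dp, w$covariates, w$hierarchy,
      reducedModelConfig(years = w$years, draws = 400, burn = 600,
                         adapt = 300, thin = 3, seed = 24)))
  })
}

# hand-built PosteriorDraws whose age-standardised trajectory equals a given
# [draw, year] matrix exactly (prevalence constant over age)
fakeDraws <- function(asd, years, sexes = "female") {
  ag <- ageGroupTable()
  nd <- nrow(asd)
  prev <- array(NA_real_, dim = c(nd, 1, length(years), length(sexes),
                                  nrow(ag)),
                dimnames = list(NULL, "C01", years, sexes, ag$label))
  for (a in seq_len(nrow(ag))) prev[, 1, , 1, a] <- asd
  hierarchy <- data.frame(country_id = "C01", region_id = "R01",
                          super_region_id = "S01")
  structure(list(prev = prev, countries = "C01", years = years,
                 sexes = sexes, age_groups = ag, hierarchy = hierarchy,
                 coef = list(), diagnostics = list(), config = NULL),
            class = "PosteriorDraws")
}
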