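test_that("hierarchy sizes follow the configuration and worlds are reproducible", {
  cfg <- worldConfig(n_super_regions = 2, n_regions_per_super = 2,
                     n_countries_per_region = 3)
  w <- buildWorld(cfg, seed = 4)
  expect_equal(nrow(w$hierarchy), 12)
  expect_equal(length(unique(w$hierarchy$region_id)), 4)
  expect_equal(length(unique(w$hierarchy$super_region_id)), 2)
  # every country in exactly one region, every region in one super-region
  expect_true(all(table(w$hierarchy$country_id) == 1))
  expect_equal(anyDuplicated(unique(w$hierarchy[c("region_id",
                                                  "super_region_id")])$region_id), 0)

  w2 <- buildWorld(cfg, seed = 4)
  expect_identical(w$prev, w2$prev)
  expect_identical(w$population, w2$population)
  expect_identical(w$covariates, w2$covariates)
})

test_that("invalid world configurations are rejected", {
  expect_error(worldConfig(n_super_regions = 0), "at least one")
  expect_error(worldConfig(years = 1990), "2 years")
  expect_error(worldConfig(sexes = "other"), "subset")
})

test_that("zero hierarchical variance collapses every country onto the global surface", {
  cfg <- flatWorldConfig(p = 0.10)
  # reinstate an age gradient and trend but keep deviations at zero
  cfg$age_slope <- 0.03
  cfg$slope_decade <- 0.2
  w <- buildWorld(cfg, seed = 9)
  for (c in 2:nrow(w$hierarchy)) {
    expect_equal(w$prev[c, , , ], w$prev[1, , , ], tolerance = 1e-12)
  }
})

test_that("true surfaces, urbanisation and populations satisfy the domain invariants", {
  w <- buildWorld(worldConfig(), seed = 2)
  expect_true(all(w$prev >= 0 & w$prev <= 1))
  expect_true(all(w$covariates$urbanisation >= 0 &
                    w$covariates$urbanisation <= 1))
  expect_true(all(w$population >= 0))
  expect_equal(dim(w$prev)[2], length(1980:2014))
  expect_true(all(ageGroupTable()$age_lo >= 18))
})

test_that("an empty plan yields an empty, well-formed datapoint table", {
  w <- buildWorld(worldConfig(n_super_regions = 1, n_regions_per_super = 1,
                              n_countries_per_region = 2), seed = 3)
  plan <- makeSurveyPlan(w, 0, seed = 1)
  dp <- simulateSurveys(w, plan, seed = 1)
  expect_equal(nrow(dp), 0)
  expect_true(all(c("study_id", "prevalence", "n_examined", "definition",
                    "scope") %in% names(dp)))
})

test_that("an unbiased national stratum stays inside the exact binomial envelope", {
  w <- buildWorld(flatWorldConfig(p = 0.10), seed = 5)
  plan <- oneStudyPlan(w, "C01", 2005, n = 1e5,
                       offsets = c(national = 0, subnational = 0,
                                   community = 0),
                       noise_sd = c(national = 0, subnational = 0,
                                    community = 0))
  dp <- simulateSurveys(w, plan, seed = 6)
  # 99.9% binomial interval computed directly from the binomial distribution
  lo <- qbinom(5e-4, 1e5, 0.10) / 1e5
  hi <- qbinom(1 - 5e-4, 1e5, 0.10) / 1e5
  expect_true(all(dp$prevalence >= lo & dp$prevalence <= hi))
  expect_gte(lo, 0.094)
  expect_lte(hi, 0.106)
})

test_that("the community probit offset is recovered from replicate strata", {
  w <- buildWorld(flatWorldConfig(p = 0.10), seed = 7)
  studies <- do.call(rbind, lapply(1:25, function(i) {
    data.frame(study_id = sprintf("s%04d", i), country_id = "C01",
               mid_year = 2005, sex = "female", scope = "community",
               urbanicity = "mixed", study_urban_fraction = NA_real_,
               definition = "PRIMARY_FPG7", fpg_cutoff = NA_real_,
               n_per_stratum = 1e5, age_scheme = "decade")
  }))
  plan <- surveyPlan(studies,
                     offsets = c(national = 0, subnational = 0,
                                 community = 0.1),
                     noise_sd = c(national = 0, subnational = 0,
                                  community = 0))
  dp <- simulateSurveys(w, plan, seed = 8)
  expect_gte(nrow(dp), 200)
  gap <- probit(dp$prevalence) - probit(0.10)
  mc_se <- sd(gap) / sqrt(length(gap))
  expect_lt(abs(mean(gap) - 0.1), 3 * mc_se)
})

test_that("strata outside the world's support are an error, not clipped", {
  w <- buildWorld(flatWorldConfig(years = 2000:2010), seed = 1)
  plan_bad_year <- oneStudyPlan(w, "C01", 2000, n = 100)
  plan_bad_year$studies$mid_year <- 2015
  expect_error(simulateSurveys(w, plan_bad_year, seed = 1), "support")
  plan_bad_country <- oneStudyPlan(w, "C01", 2005, n = 100)
  plan_bad_country$studies$country_id <- "C99"
  expect_error(simulateSurveys(w, plan_bad_country, seed = 1), "country")
})

test_that("with no bias and huge n the observed prevalence converges to truth", {
  w <- buildWorld(worldConfig(sexes = "female"), seed = 14)
  plan <- oneStudyPlan(w, "C03", 2001, n = 1e6, age_scheme = "fine",
                       offsets = c(national = 0, subnational = 0,
                                   community = 0),
                       noise_sd = c(national = 0, subnational = 0,
                                    community = 0))
  dp <- simulateSurveys(w, plan, seed = 15)
  truth <- w$prev["C03", "2001", "female", ]
  se <- sqrt(truth * (1 - truth) / 1e6)
  expect_true(all(abs(dp$prevalence - truth) <= 3 * se + 1e-12))
  # probit transforms of every emitted datapoint are finite
  expect_true(all(is.finite(probit(correctedPrevalence(dp$prevalence,
                                                       dp$n_examined)))))
})

test_that("survey simulation is reproducible and independent of study order", {
  w <- buildWorld(worldConfig(sexes = "female"), seed = 16)
  plan <- makeSurveyPlan(w, 12, seed = 17, sexes = "female")
  dp1 <- simulateSurveys(w, plan, seed = 18)
  dp2 <- simulateSurveys(w, plan, seed = 18)
  expect_identical(dp1, dp2)
})

test_that("trueSummary equals the brute-force weighted sum for many random worlds", {
  wts <- whoWts()
  for (s in 1:50) {
    w <- buildWorld(worldConfig(n_super_regions = 1,
                                n_regions_per_super = 1,
                                n_countries_per_region = 2,
                                years = 2000:2005, sexes = "female"),
                    seed = s)
    yy <- sample(w$years, 1)
    got <- trueSummary(w, "C02", yy, "female", wts)
    # independent brute-force loop
    acc <- 0
    for (a in seq_len(nrow(w$age_groups))) {
      acc <- acc + unclass(wts)[[a]] * w$prev["C02", as.character(yy),
                                              "female", a]
    }
    expect_equal(got, acc, tolerance = 1e-12)
  }
})

test_that("trueSummary handles constant surfaces and rejects unknown cells", {
  w <- buildWorld(flatWorldConfig(p = 0.07), seed = 19)
  expect_equal(trueSummary(w, "C01", 2005, "female", whoWts()), 0.07,
               tolerance = 1e-9)
  two_group <- local({
    wts <- rep(0, 14)
    names(wts) <- ageGroupTable()$label
    wts[c("30-34", "60-64")] <- c(0.6, 0.4)
    standardPopulation(wts)
  })
  expect_equal(trueSummary(w, "C01", 2005, "female", two_group), 0.07,
               tolerance = 1e-9)
  expect_error(trueSummary(w, "C99", 2005, "female"), "unknown country")
  expect_error(trueSummary(w, "C01", 1890, "female"), "support")
})

test_that("world tables round-trip through the CSV dialect", {
  w <- buildWorld(worldConfig(n_super_regions = 1, n_regions_per_super = 1,
                              n_countries_per_region = 2,
                              years = 2000:2003, sexes = "female"), seed = 20)
  dir <- withr::local_tempdir()
  paths <- writeWorldTables(w, dir)
  expect_true(all(file.exists(paths)))
  pop <- read.csv(paths[["population"]])
  expect_equal(sum(pop$population), sum(w$population))
  plan <- makeSurveyPlan(w, 3, seed = 1, sexes = "female")
  dp <- simulateSurveys(w, plan, seed = 2)
  sp <- file.path(dir, "surveys.csv")
  writeSurveyTable(dp, sp)
  back <- readSurveyTable(sp)
  expect_equal(back$prevalence, dp$prevalence)
  expect_equal(back$age_lo, dp$age_lo)
})
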