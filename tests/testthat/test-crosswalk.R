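test_that("datapoints below the 25-person minimum are excluded, order preserved", {
  dp <- data.frame(study_id = letters[1:4], n_examined = c(10, 24, 25, 100))
  kept <- suppressMessages(filterMinSample(dp))
  expect_equal(kept$n_examined, c(25, 100))
  expect_equal(kept$study_id, c("c", "d"))
  all_big <- data.frame(n_examined = c(30, 400))
  expect_identical(filterMinSample(all_big, quiet = TRUE), all_big)
  expect_equal(nrow(filterMinSample(dp[0, ], quiet = TRUE)), 0)
})

test_that("retained count matches a brute-force recount on random data", {
  set.seed(42)
  dp <- data.frame(n_examined = sample(1:200, 1000, TRUE))
  expect_equal(nrow(filterMinSample(dp, quiet = TRUE)), sum(dp$n_examined >= 25))
})

test_that("regional random effects toggle on the 400-datapoint rule", {
  big <- fitCrosswalk(makePairs(500, seed = 2), "OGTT_11_1")
  expect_false(is.null(big$re_var))
  expect_gte(big$re_var, 0)
  small <- fitCrosswalk(makePairs(300, seed = 3), "OGTT_11_1")
  expect_null(small$re_var)
  expect_error(fitCrosswalk(makePairs(30, seed = 4), "OGTT_11_1"),
               "at least")
})

test_that("a known conversion slope is recovered and no spurious interaction selected", {
  m <- fitCrosswalk(makePairs(2000, a = 0.2, b = 0.9, noise = 0.05,
                              seed = 5), "OGTT_11_1")
  expect_gte(m$coefficients[["x"]], 0.85)
  expect_lte(m$coefficients[["x"]], 0.95)
  expect_length(m$interactions, 0)
  expect_gte(m$sigma2, 0)
})

test_that("BIC selection finds a real source-by-age interaction in most replicates", {
  hits <- vapply(1:50, function(r) {
    m <- fitCrosswalk(makePairs(500, b_age = 0.3, noise = 0.1, seed = 100 + r),
                      "OGTT_11_1")
    "x:age_c" %in% m$interactions
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("the selected model's BIC never exceeds the no-interaction model's", {
  for (s in 6:9) {
    m <- fitCrosswalk(makePairs(400, b_age = 0.15, noise = 0.1, seed = s),
                      "OGTT_11_1")
    expect_lte(min(m$bic), m$bic[["(none)"]])
    expect_equal(unname(min(m$bic)), unname(m$bic[[
      if (length(m$interactions)) paste(m$interactions, collapse = "+")
      else "(none)"]]))
  }
})

identityModel <- function() {
  coefs <- c("(Intercept)" = 0, x = 1, age_c = 0, sexmale = 0, year_c = 0,
             income_c = 0)
  structure(list(
    source_definition = "OGTT_11_1",
    fixed_formula = "~ x + age_c + sexmale + year_c + income_c",
    coefficients = coefs,
    vcov = matrix(0, 6, 6, dimnames = list(names(coefs), names(coefs))),
    sigma2 = 0, re_var = NULL, interactions = character(0), n_train = 1000,
    centers = list(year = 2000, income_center = 8, income_scale = 2),
    sex_levels = c("female", "male"), bic = c("(none)" = 0)
  ), class = "CrosswalkModel")
}

sampleDatapoint <- function(p = 0.12, n = 900) {
  data.frame(study_id = "s1", country_id = "C01", mid_year = 2004,
             sex = "female", age_lo = 40, age_hi = 50, n_examined = n,
             prevalence = p, se = sqrt(p * (1 - p) / n),
             definition = "OGTT_11_1", fpg_cutoff = NA_real_,
             mean_fpg = NA_real_, scope = "national", urbanicity = "mixed",
             study_urban_fraction = 0.5, income = 8)
}

test_that("an identity cross-walk leaves prevalence and uncertainty unchanged", {
  dp <- sampleDatapoint()
  out <- applyCrosswalk(identityModel(), dp)
  expect_equal(out$prevalence, dp$prevalence, tolerance = 1e-12)
  expect_equal(out$se, dp$se, tolerance = 1e-12)
  expect_equal(out$definition, "PRIMARY_FPG7")
  expect_equal(out$converted_from, "OGTT_11_1")
})

test_that("conversion output stays in [0,1] with uncertainty at least the sampling error", {
  m <- fitCrosswalk(makePairs(500, seed = 10), "OGTT_11_1")
  set.seed(11)
  for (i in 1:20) {
    dp <- sampleDatapoint(p = runif(1, 0.01, 0.6),
                          n = sample(50:5000, 1))
    out <- applyCrosswalk(m, dp)
    expect_gte(out$prevalence, 0)
    expect_lte(out$prevalence, 1)
    expect_gte(out$se, dp$se)
  }
})

test_that("definition mismatches are rejected", {
  dp <- sampleDatapoint()
  dp$definition <- "HBA1C_6_5"
  expect_error(applyCrosswalk(identityModel(), dp), "source definition")
})

test_that("propagated uncertainty matches a numerical delta-method oracle", {
  m <- identityModel()
  m$coefficients[["x"]] <- 0.8
  m$coefficients[["(Intercept)"]] <- 0.1
  m$sigma2 <- 0.1^2
  dp <- sampleDatapoint(p = 0.15, n = 2e6)   # tiny sampling error
  out <- applyCrosswalk(m, dp)
  # independent oracle: central-difference derivative of the full map
  # p -> pnorm(a + b probit(p)) plus the residual term
  f <- function(p) pnorm(0.1 + 0.8 * qnorm(p))
  h <- 1e-6
  dfdp <- (f(dp$prevalence + h) - f(dp$prevalence - h)) / (2 * h)
  q <- 0.1 + 0.8 * qnorm(dp$prevalence)
  se_oracle <- sqrt((dfdp * dp$se)^2 + (dnorm(q) * 0.1)^2)
  expect_lt(abs(out$se - se_oracle) / se_oracle, 0.02)
})

test_that("cross-walking biased-definition surveys reduces error against the primary truth", {
  w <- buildWorld(worldConfig(sexes = c("female", "male")), seed = 30)
  paired <- simulatePairedSurveys(w, 700, "OGTT_11_1", seed = 31)
  m <- fitCrosswalk(paired, "OGTT_11_1")
  test_pairs <- simulatePairedSurveys(w, 500, "OGTT_11_1", seed = 32)
  dp <- data.frame(study_id = sprintf("p%03d", seq_len(nrow(test_pairs))),
                   country_id = test_pairs$country_id,
                   mid_year = test_pairs$mid_year, sex = test_pairs$sex,
                   age_lo = NA, age_hi = NA,
                   n_examined = test_pairs$n_examined,
                   prevalence = test_pairs$prevalence_source,
                   se = NA, definition = "OGTT_11_1", fpg_cutoff = NA,
                   mean_fpg = NA, scope = "national", urbanicity = "mixed",
                   study_urban_fraction = NA, income = test_pairs$income)
  ag <- ageGroupTable()
  gi <- match(test_pairs$age_mid, ag$mid)
  dp$age_lo <- ag$age_lo[gi]
  dp$age_hi <- ag$age_hi[gi]
  pc <- correctedPrevalence(dp$prevalence, dp$n_examined)
  dp$se <- sqrt(pc * (1 - pc) / dp$n_examined)
  conv <- applyCrosswalk(m, dp)
  truth <- test_pairs$prevalence_primary
  mse_raw <- mean((dp$prevalence - truth)^2)
  mse_conv <- mean((conv$prevalence - truth)^2)
  expect_lt(mse_conv, mse_raw)
  # re-fitting converted against observed primary gives slope ~ 1
  refit <- lm(qnorm(correctedPrevalence(truth, dp$n_examined)) ~
                qnorm(conv$prevalence))
  slope <- coef(refit)[2]
  se_slope <- summary(refit)$coefficients[2, 2]
  expect_lt(abs(slope - 1), 3 * se_slope)
})

test_that("mean-FPG sources convert through the two-parameter map", {
  w <- buildWorld(worldConfig(sexes = "female"), seed = 33)
  paired <- simulatePairedSurveys(w, 500, "MEAN_FPG", seed = 34)
  m <- fitCrosswalk(paired, "MEAN_FPG")
  expect_named(m$coefficients, c("(Intercept)", "x"))
  # generator's map: probit(primary) = -7.5 + 1.1 * mean FPG
  expect_equal(unname(m$coefficients[["x"]]), 1.1, tolerance = 0.15)
  plan <- makeSurveyPlan(w, 6, seed = 35,
                         definition_probs = c(MEAN_FPG = 1),
                         sexes = "female")
  dp <- simulateSurveys(w, plan, seed = 36)
  conv <- applyCrosswalk(m, dp)
  expect_true(all(conv$prevalence > 0 & conv$prevalence < 1))
  expect_true(all(conv$definition == "PRIMARY_FPG7"))
  # converted prevalences track the true primary prevalence
  truth <- vapply(seq_len(nrow(dp)), function(i) {
    idx <- diabtrends:::ageGroupIndices(dp$age_lo[i], dp$age_hi[i])
    pop <- w$population[dp$country_id[i], as.character(dp$mid_year[i]),
                        dp$sex[i], ]
    pgrp <- w$prev[dp$country_id[i], as.character(dp$mid_year[i]),
                   dp$sex[i], ]
    sum(pop[idx] * pgrp[idx]) / sum(pop[idx])
  }, numeric(1))
  expect_lt(median(abs(conv$prevalence - truth)), 0.05)
})

test_that("cross-walk models survive a JSON round trip", {
  m <- fitCrosswalk(makePairs(500, seed = 40), "OGTT_11_1")
  path <- withr::local_tempfile(fileext = ".json")
  writeCrosswalkModel(m, path)
  back <- readCrosswalkModel(path)
  expect_equal(back$coefficients, m$coefficients)
  expect_equal(back$vcov, m$vcov, tolerance = 1e-12)
  expect_equal(back$sigma2, m$sigma2)
  expect_equal(back$interactions, m$interactions)
  dp <- sampleDatapoint()
  expect_equal(applyCrosswalk(back, dp)$prevalence,
               applyCrosswalk(m, dp)$prevalence, tolerance = 1e-10)
})
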