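test_that("age-standardisation reproduces hand-computed cases and the brute-force oracle", {
  expect_equal(ageStandardise(c(0.10, 0.20), c(0.6, 0.4)), 0.14)
  # constant prevalence is invariant to the weights
  wts <- whoWts()
  expect_equal(ageStandardise(rep(0.07, 14), wts), 0.07, tolerance = 1e-12)
  set.seed(1)
  for (i in 1:100) {
    k <- sample(2:14, 1)
    p <- runif(k)
    w <- runif(k); w <- w / sum(w)
    oracle <- 0
    for (a in seq_len(k)) oracle <- oracle + w[a] * p[a]
    expect_identical(ageStandardise(p, w), sum(w * p))
    expect_equal(ageStandardise(p, w), oracle, tolerance = 1e-15)
  }
  # matrix form applies per draw
  m <- matrix(runif(20), 4, 5)
  w5 <- rep(0.2, 5)
  expect_equal(ageStandardise(m, w5), as.numeric(m %*% w5))
})

test_that("age-standardisation rejects bad weights", {
  expect_error(ageStandardise(c(0.1, 0.2), c(0.5, 0.4)), "renormalised")
  p <- c("20-24" = 0.1, "25-29" = 0.2)
  w <- c("20-24" = 0.5, "30-34" = 0.5)
  expect_error(ageStandardise(p, w), "cover")
})

test_that("crude prevalence and counts follow the population structure", {
  expect_equal(crudeAndCounts(c(0, 0, 0), c(10, 20, 30)),
               list(crude = 0, count = 0))
  cc <- crudeAndCounts(0.25, 1000)
  expect_equal(cc$crude, 0.25)
  expect_equal(cc$count, 250)
  expect_error(crudeAndCounts(c(0.1, 0.2), c(0, 0)), "zero")
  # crude equals age-standardised when weights are population shares
  set.seed(2)
  for (i in 1:20) {
    p <- runif(6); pop <- runif(6, 100, 1e5)
    expect_equal(crudeAndCounts(p, pop)$crude,
                 ageStandardise(p, pop / sum(pop)), tolerance = 1e-12)
  }
})

test_that("age-standardised prevalence ignores population scale; crude does not", {
  p <- c(0.05, 0.10, 0.30)
  pop <- c(1000, 800, 200)
  wts <- c(0.3, 0.3, 0.4)
  expect_equal(ageStandardise(p, wts), ageStandardise(p, wts))
  expect_equal(crudeAndCounts(p, pop * 7)$crude, crudeAndCounts(p, pop)$crude)
  older <- c(200, 800, 1000)   # same total, older structure
  expect_gt(crudeAndCounts(p, older)$crude, crudeAndCounts(p, pop)$crude)
})

test_that("the decomposition identity is exact and degenerate cases collapse", {
  set.seed(3)
  for (i in 1:1000) {
    k <- sample(2:14, 1)
    p0 <- runif(k); p1 <- runif(k)
    n0 <- runif(k, 0, 1e7); n1 <- runif(k, 0, 1e7)
    d <- decomposeChange(p0, p1, n0, n1)
    total <- sum(n1 * p1) - sum(n0 * p0)
    expect_equal(d$total_change, total, tolerance = 1e-9)
    expect_equal(sum(d$shares), 100, tolerance = 1e-9)
  }
  # unchanged population: everything is attributed to prevalence change
  p0 <- c(0.1, 0.2); p1 <- c(0.15, 0.4); n <- c(1e6, 2e6)
  d <- decomposeChange(p0, p1, n, n)
  expect_equal(d$component_growth_ageing, 0)
  expect_equal(d$component_interaction, 0)
  expect_equal(d$component_prevalence, d$total_change)
  expect_error(decomposeChange(p0, p1[1], n, n), "mismatch")
})

test_that("reversing the two time points negates the total and remaps components", {
  set.seed(4)
  for (i in 1:50) {
    p0 <- runif(5); p1 <- runif(5)
    n0 <- runif(5, 1, 1e6); n1 <- runif(5, 1, 1e6)
    a <- decomposeChange(p0, p1, n0, n1)
    b <- decomposeChange(p1, p0, n1, n0)
    expect_equal(b$total_change, -a$total_change, tolerance = 1e-9)
    # under base-year weighting the interaction is direction-invariant and
    # each main component picks up the interaction when reversed
    expect_equal(b$component_interaction, a$component_interaction,
                 tolerance = 1e-6)
    expect_equal(b$component_growth_ageing,
                 -(a$component_growth_ageing + a$component_interaction),
                 tolerance = 1e-6)
    expect_equal(b$component_prevalence,
                 -(a$component_prevalence + a$component_interaction),
                 tolerance = 1e-6)
  }
})

test_that("flat trajectories project to themselves and linear probit trends extend exactly", {
  years <- 2000:2014
  flat <- fakeDraws(matrix(0.08, 10, length(years)), years)
  proj <- projectPost2000(flat, "female", unit = "C01", target_year = 2025)
  expect_equal(proj, rep(0.08, 10), tolerance = 1e-9)
  # exactly linear on the probit scale
  a <- -1.5; b <- 0.02
  lin <- fakeDraws(matrix(pnorm(a + b * (years - 2000)), 3, length(years),
                          byrow = TRUE), years)
  proj_lin <- projectPost2000(lin, "female", unit = "C01",
                              target_year = 2025)
  expect_equal(proj_lin, rep(pnorm(a + b * 25), 3), tolerance = 1e-10)
})

test_that("per-draw projection equals an independent least-squares oracle", {
  years <- 2000:2014
  set.seed(5)
  asd <- pnorm(matrix(rnorm(20 * length(years), -1.4, 0.2), 20))
  fd <- fakeDraws(asd, years)
  proj <- projectPost2000(fd, "female", unit = "C01", target_year = 2025)
  for (d in 1:20) {
    fit <- lm(qnorm(asd[d, ]) ~ years)
    expect_equal(proj[d],
                 pnorm(unname(coef(fit)[1] + coef(fit)[2] * 2025)),
                 tolerance = 1e-9)
  }
})

test_that("projection guards its window and support", {
  short <- fakeDraws(matrix(0.1, 5, 2), 2013:2014)
  expect_error(projectPost2000(short, "female", unit = "C01"),
               "at least 3")
  years <- 2000:2014
  fd <- fakeDraws(matrix(0.1, 5, length(years)), years)
  expect_error(projectPost2000(fd, "female", unit = "C01",
                               target_year = 2010), "beyond")
})

test_that("target probability follows the paired-draw convention", {
  flat <- rep(0.08, 400)
  expect_equal(targetProbability(flat, flat)$probability_met, 1)
  rising <- flat + 0.01
  expect_equal(targetProbability(rising, flat)$probability_met, 0)
  set.seed(6)
  n <- 4000
  noisy <- targetProbability(0.1 + rnorm(n, 0, 0.01),
                             0.1 + rnorm(n, 0, 0.01))
  expect_lt(abs(noisy$probability_met - 0.5), 3 * sqrt(0.25 / n))
  expect_error(targetProbability(flat, flat[-1]), "paired")
})

test_that("posterior probability of increase obeys its conventions", {
  years <- 2000:2014
  set.seed(7)
  up <- matrix(rep(seq(0.05, 0.12, length.out = length(years)), each = 50),
               50)
  fd <- fakeDraws(up, years)
  expect_equal(posteriorProbIncrease(fd, "female", 2000, 2014, unit = "C01"), 1)
  expect_equal(posteriorProbIncrease(fd, "female", 2005, 2005, unit = "C01"), 0)
  sym <- fakeDraws(pnorm(matrix(rnorm(2000 * 2, -1.5, 0.05), 2000)),
                   2013:2014)
  p <- posteriorProbIncrease(sym, "female", 2013, 2014, unit = "C01")
  expect_lt(abs(p - 0.5), 3 * sqrt(0.25 / 2000))
  expect_error(posteriorProbIncrease(fd, "female", 1990, 2014, unit = "C01"), "support")
  expect_error(posteriorProbIncrease(fd, "female", 2014, 2000, unit = "C01"), "exceed")
})
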