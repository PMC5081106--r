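# synthetic paired data with a known generative map on the probit scale:
# probit(primary) = a + b * probit(source) (+ optional source x age term)
makePairs <- function(n, a = 0.2, b = 0.9, b_age = 0, noise = 0.05,
                      seed = 1) {
  set.seed(seed)
  q_s <- qnorm(runif(n, 0.02, 0.30))
  age <- sample(ageGroupTable()$mid, n, TRUE)
  age_c <- (age - 50) / 10
  q_p <- a + b * q_s + b_age * q_s * age_c + rnorm(n, 0, noise)
  data.frame(
    prevalence_primary = pnorm(q_p), prevalence_source = pnorm(q_s),
    n_examined = 10000, age_mid = age,
    sex = sample(c("female", "male"), n, TRUE),
    mid_year = sample(1990:2014, n, TRUE),
    income = runif(n, 5, 12),
    region_id = sample(paste0("R0", 1:4), n, TRUE)
  )
}

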