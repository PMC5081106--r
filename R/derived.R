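#' Age-standardised prevalence
#'
#' Weighted sum of age-specific prevalences under a fixed standard age
#' distribution, removing the effect of differing population age
#' structures. Applied per posterior draw when given a draws matrix.
#'
#' @param age_specific numeric vector of prevalences by age group, or a
#'   matrix `[draw, age group]`; when named/colnamed, names must match the
#'   weight names.
#' @param weights a `StandardPopulation`, or a named non-negative numeric
#'   vector summing to 1 over exactly the age groups present.
#' @return A proportion, or a vector of proportions (one per draw).
#' @export
ageStandardise <- function(age_specific, weights) {
  w <- unclass(weights)
  nm <- if (is.matrix(age_specific)) colnames(age_specific) else
    names(age_specific)
  if (!is.null(nm) && !is.null(names(w))) {
    if (!setequal(nm, names(w))) {
      stop("weights do not cover exactly the age groups present")
    }
    w <- w[nm]
  } else if (length(w) != (if (is.matrix(age_specific)) ncol(age_specific)
                           else length(age_specific))) {
    stop("weights do not cover exactly the age groups present")
  }
  if (abs(sum(w) - 1) > 1e-8) stop("weights must be renormalised to sum to 1")
  if (is.matrix(age_specific)) as.numeric(age_specific %*% w)
  else sum(age_specific * w)
}

#' Crude prevalence and case counts
#'
#' Crude prevalence weights the age-specific prevalences by the actual
#' population age structure; the case count is the population-weighted sum
#' itself. Applied per posterior draw when given a draws matrix.
#'
#' @param age_specific vector or `[draw, age]` matrix of prevalences.
#' @param population non-negative population counts by age group (same age
#'   groups, same order).
#' @return A list with elements `crude` (proportion(s)) and `count`
#'   (person count(s)), each per draw.
#' @export
crudeAndCounts <- function(age_specific, population) {
  if (length(population) != (if (is.matrix(age_specific))
    ncol(age_specific) else length(age_specific))) {
    stop("population must cover exactly the age groups present")
  }
  tot <- sum(population)
  if (tot <= 0) stop("total population is zero")
  cnt <- if (is.matrix(age_specific)) {
    as.numeric(age_specific %*% population)
  } else sum(age_specific * population)
  list(crude = cnt / tot, count = cnt)
}

#' Construct a decomposition result
#'
#' Packages the three components of a change in case counts — population
#' growth and ageing, change in age-specific prevalence, and their
#' interaction — and computes each component's share of the summed
#' components, in percent.
#'
#' @param growth_ageing,prevalence,interaction component sizes in persons.
#' @return An object of class `DecompositionResult` with the components,
#'   `total_change` (their exact sum) and `shares` (percentages summing to
#'   100).
#' @export
decompositionResult <- function(growth_ageing, prevalence, interaction) {
  comp <- c(growth_ageing = growth_ageing, prevalence = prevalence,
            interaction = interaction)
  structure(list(
    total_change = sum(comp),
    component_growth_ageing = growth_ageing,
    component_prevalence = prevalence,
    component_interaction = interaction,
    shares = 100 * comp / sum(comp)
  ), class = "DecompositionResult")
}

#' @export
print.DecompositionResult <- function(x, ...) {
  cat("DecompositionResult: total change", format(x$total_change, big.mark = ","),
      "persons\n")
  comp <- c(x$component_growth_ageing, x$component_prevalence,
            x$component_interaction)
  lab <- c("population growth & ageing", "rise in prevalence", "interaction")
  for (i in 1:3) {
    cat(sprintf("  %-28s %14.1f  (%.1f%%)\n", lab[i], comp[i], x$shares[i]))
  }
  invisible(x)
}

#' Decompose a change in case counts
#'
#' Splits the change in the number of cases between two time points into
#' population growth and ageing (G), change in age-specific prevalence (P)
#' and their interaction (I), with base-year weighting for the two main
#' components so that G + P + I equals the total count change exactly:
#' G = sum (pop1 - pop0) * prev0; P = sum pop0 * (prev1 - prev0);
#' I = sum (pop1 - pop0) * (prev1 - prev0).
#'
#' @param prev_t0,prev_t1 age-specific prevalences at the two time points
#'   (same age groups, same order).
#' @param pop_t0,pop_t1 populations by age group at the two time points.
#' @return A [decompositionResult()].
#' @export
decomposeChange <- function(prev_t0, prev_t1, pop_t0, pop_t1) {
  k <- length(prev_t0)
  if (length(prev_t1) != k || length(pop_t0) != k || length(pop_t1) != k) {
    stop("age groups mismatch between the two time points")
  }
  G <- sum((pop_t1 - pop_t0) * prev_t0)
  P <- sum(pop_t0 * (prev_t1 - prev_t0))
  I <- sum((pop_t1 - pop_t0) * (prev_t1 - prev_t0))
  decompositionResult(G, P, I)
}

#' Project age-standardised prevalence beyond the fitted years
#'
#' For every posterior draw, fits an ordinary least-squares line on the
#' probit scale to the draw's age-standardised trajectory from
#' `window_start` to the end of the fitted period, and extrapolates it to
#' `target_year` — the "if recent trends continue" scenario used to assess
#' the global diabetes target.
#'
#' @param draws a `PosteriorDraws`.
#' @param sex sex to project.
#' @param unit country id or aggregate unit (see [ageStandardisedDraws()]).
#' @param target_year projection year (beyond the fitted support).
#' @param window_start first year of the trend window (default 2000); the
#'   window must contain at least 3 fitted years.
#' @param weights a `StandardPopulation`.
#' @param population population array, required for aggregate units.
#' @return Numeric vector of projected prevalence proportions, one per draw.
#' @export
projectPost2000 <- function(draws, sex, unit = NULL, target_year = 2025,
                            window_start = 2000,
                            weights = whoStandardPopulation(),
                            population = NULL) {
  yrs <- draws$years[draws$years >= window_start]
  if (length(yrs) < 3) stop("trend window must contain at least 3 fitted years")
  if (target_year <= max(draws$years)) {
    stop("target_year must lie beyond the fitted years; stored draws cover it")
  }
  asd <- ageStandardisedDraws(draws, sex, weights, unit, population)
  Q <- probit(asd[, as.character(yrs), drop = FALSE])
  X <- cbind(1, yrs)
  beta <- solve(crossprod(X), t(X) %*% t(Q))       # 2 x draws
  invProbit(beta[1, ] + beta[2, ] * target_year)
}

#' Probability of meeting the global diabetes target
#'
#' The global NCD target is to halt, by 2025, the rise in age-standardised
#' diabetes prevalence at its 2010 level. Given paired posterior draws of
#' the projected 2025 prevalence and the fitted 2010 baseline, the
#' probability of meeting the target is the fraction of draws in which the
#' projection does not exceed the baseline (ties count as met).
#'
#' @param projected draws of 2025 age-standardised prevalence.
#' @param baseline paired draws of the 2010 baseline (same length, same
#'   draw order).
#' @param unit,sex labels recorded in the result.
#' @return An object of class `TargetAssessment` with `probability_met`,
#'   the draws, and the labels.
#' @export
targetProbability <- function(projected, baseline, unit = "world",
                              sex = NA_character_) {
  if (length(projected) != length(baseline)) {
    stop("projected and baseline draws must be paired (equal length)")
  }
  structure(list(unit = unit, sex = sex,
                 probability_met = mean(projected <= baseline),
                 projected = projected, baseline = baseline),
            class = "TargetAssessment")
}

#' @export
print.TargetAssessment <- function(x, ...) {
  cat("TargetAssessment (", x$unit, ", ", x$sex, "): P(2025 <= 2010) = ",
      round(x$probability_met, 3), "\n", sep = "")
  cat("  projected 2025: ", round(mean(x$projected) * 100, 1), "% (",
      round(stats::quantile(x$projected, 0.025) * 100, 1), "-",
      round(stats::quantile(x$projected, 0.975) * 100, 1), "%)\n", sep = "")
  invisible(x)
}
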