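#' Split datapoints into training and held-out sets
#'
#' Three withholding schemes: `random_fraction` withholds a random fraction
#' of individual datapoints; `whole_study` withholds every datapoint of a
#' sampled fraction of studies; `whole_country` withholds every datapoint
#' of a sampled fraction of countries (the hardest test: those countries
#' are then estimated purely from the hierarchy and covariates).
#'
#' @param datapoints survey datapoint data.frame.
#' @param scheme one of `random_fraction`, `whole_study`, `whole_country`.
#' @param fraction fraction withheld, in (0, 1).
#' @param seed integer seed; the same seed reproduces the split.
#' @return A list with disjoint, exhaustive `train` and `test` data.frames.
#' @export
makeHoldoutSplit <- function(datapoints,
                             scheme = c("random_fraction", "whole_study",
                                        "whole_country"),
                             fraction = 0.2, seed = 1L) {
  scheme <- match.arg(scheme)
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)")
  n <- nrow(datapoints)
  set.seed(substreamSeed(seed, 77))
  test_idx <- switch(scheme,
    random_fraction = sample(n, round(fraction * n)),
    whole_study = {
      ids <- unique(datapoints$study_id)
      held <- sample(ids, max(1, round(fraction * length(ids))))
      which(datapoints$study_id %in% held)
    },
    whole_country = {
      ids <- unique(datapoints$country_id)
      held <- sample(ids, max(1, round(fraction * length(ids))))
      which(datapoints$country_id %in% held)
    })
  if (length(test_idx) >= n) stop("split would leave an empty training set")
  list(train = datapoints[-test_idx, , drop = FALSE],
       test = datapoints[test_idx, , drop = FALSE])
}

#' Score estimates against held-out observations
#'
#' For every withheld stratum, the residual is the estimated posterior-mean
#' prevalence (averaged over the stratum's age groups) minus the observed
#' prevalence, in percentage points. The report carries the median error
#' (bias), the median absolute error, and the share of observations falling
#' inside the stratum's 2.5-97.5 posterior percentile interval.
#'
#' @param estimates a `PosteriorDraws` (typically fitted on the training
#'   half of a [makeHoldoutSplit()]).
#' @param test withheld survey datapoints; every stratum must map to an
#'   estimated country-year-sex cell.
#' @param population optional population array used to weight age groups
#'   within a reported band; equal weights when `NULL`.
#' @return An object of class `ValidationReport`.
#' @export
evaluateHoldout <- function(estimates, test, population = NULL) {
  stopifnot(inherits(estimates, "PosteriorDraws"))
  if (nrow(test) == 0) stop("no held-out datapoints to score")
  res <- lapply(seq_len(nrow(test)), function(i) {
    d <- test[i, ]
    pr <- predictPrevalence(estimates, d$country_id, d$mid_year, d$sex)
    idx <- ageGroupIndices(d$age_lo, d$age_hi)
    w <- if (is.null(population)) rep(1, length(idx)) else
      population[d$country_id, as.character(d$mid_year), d$sex, idx]
    w <- w / sum(w)
    stratum <- as.numeric(pr[, idx, drop = FALSE] %*% w)
    ci <- stats::quantile(stratum, c(0.025, 0.975))
    data.frame(study_id = d$study_id, country_id = d$country_id,
               mid_year = d$mid_year, sex = d$sex, age_lo = d$age_lo,
               age_hi = d$age_hi, observed = d$prevalence,
               estimated = mean(stratum),
               residual_pp = (mean(stratum) - d$prevalence) * 100,
               in_cri = d$prevalence >= ci[1] & d$prevalence <= ci[2])
  })
  res <- do.call(rbind, res)
  structure(list(
    median_error = stats::median(res$residual_pp),
    median_absolute_error = stats::median(abs(res$residual_pp)),
    coverage = 100 * mean(res$in_cri),
    residuals = res
  ), class = "ValidationReport")
}

#' @export
print.ValidationReport <- function(x, ...) {
  cat("ValidationReport (", nrow(x$residuals), " held-out strata)\n", sep = "")
  cat("  median error:          ", round(x$median_error, 3), "pp\n")
  cat("  median absolute error: ", round(x$median_absolute_error, 3), "pp\n")
  cat("  95% CrI coverage:      ", round(x$coverage, 1), "%\n")
  invisible(x)
}

#' Write a validation report
#'
#' @param report a `ValidationReport`.
#' @param json_path,csv_path output paths for the summary JSON and the
#'   per-stratum residual table.
#' @return Paths written, invisibly.
#' @export
writeValidationReport <- function(report, json_path, csv_path) {
  jsonlite::write_json(list(median_error = report$median_error,
                            median_absolute_error = report$median_absolute_error,
                            coverage = report$coverage,
                            n_strata = nrow(report$residuals)),
                       json_path, auto_unbox = TRUE, digits = NA)
  utils::write.csv(report$residuals, csv_path, row.names = FALSE)
  invisible(c(json_path, csv_path))
}
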