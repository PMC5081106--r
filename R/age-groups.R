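#' Standard adult age groups
#'
#' All populations, truth surfaces and standardisation weights are discretised
#' on a fixed adult age grid: 18-19, then five-year groups 20-24 through
#' 75-79, then 80+. Intervals are half-open \[lo, hi); the open-ended top
#' group is treated as \[80, 85) for its midpoint. This matches conventional
#' survey reporting and the granularity of the WHO standard population.
#'
#' @return A data.frame with columns `age_lo`, `age_hi` (half-open bounds,
#'   `Inf` for the top group), `mid` (interval midpoint in years) and
#'   `label`.
#' @export
ageGroupTable <- function() {
  lo <- c(18, seq(20, 80, by = 5))
  hi <- c(lo[-1], Inf)
  mid <- ifelse(is.finite(hi), (lo + hi) / 2, lo + 2.5)
  label <- ifelse(is.finite(hi), paste0(lo, "-", hi - 1), paste0(lo, "+"))
  data.frame(age_lo = lo, age_hi = hi, mid = mid, label = label,
             stringsAsFactors = FALSE)
}

# indices of standard groups fully covered by [lo, hi); errors if the band
# does not align with group boundaries
ageGroupIndices <- function(age_lo, age_hi) {
  ag <- ageGroupTable()
  if (is.infinite(age_hi)) age_hi <- Inf
  idx <- which(ag$age_lo >= age_lo & (ag$age_hi <= age_hi))
  if (length(idx) == 0 || ag$age_lo[idx[1]] != age_lo ||
      (is.finite(age_hi) && utils::tail(ag$age_hi[idx], 1) != age_hi)) {
    stop("age band [", age_lo, ", ", age_hi,
         ") does not align with the standard age groups")
  }
  idx
}

#' WHO standard population weights for adults
#'
#' Reads the bundled WHO World Standard Population weights (Ahmad et al.
#' 2001 vintage), restricted to ages 18 and over and renormalised so the
#' adult weights sum to one. The 18-19 weight takes two fifths of the 15-19
#' standard weight; 80+ pools all standard groups from 80 upward.
#'
#' @param path optional path to an alternative weight table with columns
#'   `label` and `weight` matching [ageGroupTable()] labels.
#' @return An object of class `StandardPopulation`: a named numeric vector of
#'   weights (names are age-group labels, sum to 1) with a `provenance`
#'   attribute.
#' @export
whoStandardPopulation <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "who_standard_population.csv",
                        package = "diabtrends", mustWork = TRUE)
  }
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  standardPopulation(stats::setNames(tab$weight, tab$label),
                     provenance = "WHO World Standard Population (2000), adults 18+")
}

#' Construct a standard population
#'
#' @param weights named non-negative weights, one per standard age group
#'   (names must match [ageGroupTable()] labels); renormalised to sum to 1.
#' @param provenance short label recording where the weights come from.
#' @return A `StandardPopulation` object.
#' @export
standardPopulation <- function(weights, provenance = "user-supplied") {
  ag <- ageGroupTable()
  if (!setequal(names(weights), ag$label)) {
    stop("weights must be named by the standard age-group labels")
  }
  w <- weights[ag$label]
  if (any(w < 0) || sum(w) <= 0) stop("weights must be non-negative and not all zero")
  w <- w / sum(w)
  structure(w, provenance = provenance, class = "StandardPopulation")
}

#' @export
print.StandardPopulation <- function(x, ...) {
  cat("StandardPopulation (", attr(x, "provenance"), ")\n", sep = "")
  print(round(unclass(x), 4))
  invisible(x)
}
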