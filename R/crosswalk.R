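#' Drop datapoints below the minimum sample size
#'
#' Datapoints based on fewer than 25 examined people are excluded before any
#' cross-walk regression is fitted or applied.
#'
#' @param datapoints data.frame with an `n_examined` column (survey
#'   datapoints or paired observations).
#' @param min_n minimum sample size retained (default 25).
#' @param quiet suppress the removal message.
#' @return The retained rows, original order preserved.
#' @export
filterMinSample <- function(datapoints, min_n = 25, quiet = FALSE) {
  keep <- datapoints$n_examined >= min_n
  if (!quiet && any(!keep)) {
    message("filterMinSample: removed ", sum(!keep), " of ", length(keep),
            " datapoints with n < ", min_n)
  }
  datapoints[keep, , drop = FALSE]
}

# age/year/income standardisation shared by fitting and prediction
cwScale <- function(df, centers = NULL) {
  if (is.null(centers)) {
    centers <- list(year = mean(df$mid_year),
                    income_center = mean(df$income),
                    income_scale = max(stats::sd(df$income), 1e-8))
  }
  out <- data.frame(
    age_c = (df$age_mid - 50) / 10,
    year_c = (df$mid_year - centers$year) / 10,
    income_c = (df$income - centers$income_center) / centers$income_scale
  )
  list(covs = out, centers = centers)
}

#' Fit a definition cross-walk regression
#'
#' Regresses the probit of the primary-outcome prevalence on the probit of
#' the prevalence observed under an alternative definition, with terms for
#' age, sex, study year and an income covariate, from paired observations
#' (strata where both definitions were computed from the same individuals).
#' Candidate interactions of the source prevalence with age, sex and year
#' are enumerated exhaustively and the subset minimising the Bayesian
#' Information Criterion is retained. When more than 400 paired datapoints
#' are available the regression additionally carries regional random
#' intercepts (fitted with `lme4`, maximum likelihood); below that threshold
#' a fixed-effects regression is used. Sources reporting only the population
#' mean fasting plasma glucose are handled by a two-parameter linear map
#' from the mean (mmol/L) to the probit prevalence.
#'
#' @param paired data.frame of paired observations with columns
#'   `prevalence_primary`, `prevalence_source` (or `mean_fpg` for the
#'   MEAN_FPG source), `n_examined`, `age_mid`, `sex`, `mid_year`, `income`
#'   and (for the random-effect rule) `region_id`.
#' @param source_definition one of `OGTT_11_1`, `HBA1C_6_5`, `FPG_CUTOFF`,
#'   `MEAN_FPG`.
#' @param candidate_interactions subset of `c("age", "sex", "year")` whose
#'   interactions with the source term enter the BIC search.
#' @param min_paired minimum number of paired observations after the n >= 25
#'   filter.
#' @return An object of class `CrosswalkModel`.
#' @export
fitCrosswalk <- function(paired, source_definition,
                         candidate_interactions = c("age", "sex", "year"),
                         min_paired = 50) {
  paired <- filterMinSample(paired, quiet = TRUE)
  n_train <- nrow(paired)
  if (n_train < min_paired) {
    stop("only ", n_train, " paired observations with n >= 25; at least ",
         min_paired, " are required")
  }
  y <- probit(correctedPrevalence(paired$prevalence_primary,
                                  paired$n_examined))
  if (identical(source_definition, "MEAN_FPG")) {
    x <- paired$mean_fpg
  } else {
    x <- probit(correctedPrevalence(paired$prevalence_source,
                                    paired$n_examined))
  }
  sc <- cwScale(paired)
  dat <- cbind(data.frame(y = y, x = x), sc$covs)
  sex_levels <- sort(unique(paired$sex))
  has_sex <- length(sex_levels) > 1
  if (has_sex) dat$sexmale <- as.numeric(paired$sex == "male")
  use_re <- n_train > 400 && !identical(source_definition, "MEAN_FPG")
  if (use_re) {
    if (is.null(paired$region_id)) {
      stop("regional random effects require a region_id column")
    }
    dat$region_id <- paired$region_id
  }

  if (identical(source_definition, "MEAN_FPG")) {
    # two-parameter monotone map: probit(primary) = a + b * mean FPG
    base_terms <- "x"
    subsets <- list(character(0))
  } else {
    base_terms <- c("x", "age_c", if (has_sex) "sexmale", "year_c", "income_c")
    cand <- intersect(candidate_interactions, c("age", "sex", "year"))
    if (!has_sex) cand <- setdiff(cand, "sex")
    int_terms <- c(age = "x:age_c", sex = "x:sexmale", year = "x:year_c")[cand]
    subsets <- lapply(0:(2^length(int_terms) - 1), function(m) {
      int_terms[bitwAnd(m, 2^(seq_along(int_terms) - 1)) > 0]
    })
  }

  fitOne <- function(extra) {
    rhs <- paste(c(base_terms, extra), collapse = " + ")
    if (use_re) {
      fit <- lme4::lmer(stats::as.formula(paste("y ~", rhs, "+ (1 | region_id)")),
                        data = dat, REML = FALSE)
    } else {
      fit <- stats::lm(stats::as.formula(paste("y ~", rhs)), data = dat)
      if (any(is.na(stats::coef(fit)))) {
        stop("degenerate design matrix: collinear covariates (",
             paste(names(stats::coef(fit))[is.na(stats::coef(fit))],
                   collapse = ", "), ")")
      }
    }
    fit
  }
  fits <- lapply(subsets, fitOne)
  bics <- vapply(fits, stats::BIC, numeric(1))
  best <- which.min(bics)
  fit <- fits[[best]]
  selected <- unname(subsets[[best]])

  if (use_re) {
    vc <- lme4::VarCorr(fit)
    re_var <- as.numeric(vc$region_id[1, 1])
    sigma2 <- attr(vc, "sc")^2
    beta <- lme4::fixef(fit)
    V <- as.matrix(stats::vcov(fit))
  } else {
    re_var <- NULL
    sigma2 <- summary(fit)$sigma^2
    beta <- stats::coef(fit)
    V <- stats::vcov(fit)
  }
  rhs <- paste(c(base_terms, selected), collapse = " + ")
  structure(list(
    source_definition = source_definition,
    fixed_formula = paste("~", rhs),
    coefficients = beta, vcov = V, sigma2 = sigma2, re_var = re_var,
    interactions = selected, n_train = n_train,
    centers = sc$centers, sex_levels = sex_levels,
    bic = stats::setNames(bics, vapply(subsets, function(s) {
      if (length(s) == 0) "(none)" else paste(s, collapse = "+")
    }, character(1)))
  ), class = "CrosswalkModel")
}

#' @export
print.CrosswalkModel <- function(x, ...) {
  cat("CrosswalkModel:", x$source_definition, "-> PRIMARY_FPG7\n")
  cat("  n_train =", x$n_train,
      if (!is.null(x$re_var)) "(regional random intercepts)" else "", "\n")
  cat("  interactions:",
      if (length(x$interactions)) paste(x$interactions, collapse = ", ")
      else "(none)", "\n")
  cat("  residual SD =", round(sqrt(x$sigma2), 4), "\n")
  print(round(x$coefficients, 4))
  invisible(x)
}

# midpoint of a reported age band on the standard grid
bandMid <- function(age_lo, age_hi) {
  ag <- ageGroupTable()
  vapply(seq_along(age_lo), function(i) {
    mean(ag$mid[ageGroupIndices(age_lo[i], age_hi[i])])
  }, numeric(1))
}

#' Convert datapoints to the primary diabetes definition
#'
#' Applies a fitted cross-walk regression to survey datapoints observed
#' under the model's source definition, returning copies harmonised to the
#' primary outcome. The converted prevalence is the regression's point
#' prediction mapped back to \[0, 1\]; its standard error combines, by the
#' delta method on the probit scale, the datapoint's own sampling error
#' (propagated through the source-prevalence slope), the regression
#' coefficient uncertainty and the residual (plus any regional
#' random-effect) variance. The reported uncertainty never falls below the
#' input sampling error.
#'
#' @param model a `CrosswalkModel`.
#' @param datapoint data.frame of survey datapoints whose `definition`
#'   matches the model's source; must carry an `income` column (the income
#'   covariate at the study's country-year) unless the model is a MEAN_FPG
#'   map.
#' @return The datapoints with `definition = "PRIMARY_FPG7"`, converted
#'   `prevalence` and `se`, and the original definition recorded in
#'   `converted_from`.
#' @export
applyCrosswalk <- function(model, datapoint) {
  stopifnot(inherits(model, "CrosswalkModel"))
  if (nrow(datapoint) == 0) return(datapoint)
  if (!all(datapoint$definition == model$source_definition)) {
    stop("datapoint definition does not match the model's source definition (",
         model$source_definition, ")")
  }
  n <- datapoint$n_examined
  if (identical(model$source_definition, "MEAN_FPG")) {
    x <- datapoint$mean_fpg
    var_x <- ifelse(is.na(datapoint$se), 0, datapoint$se^2)
    se_in <- rep(NA_real_, nrow(datapoint))
  } else {
    pc <- correctedPrevalence(datapoint$prevalence, n)
    x <- probit(pc)
    se_in <- if (!is.null(datapoint$se)) datapoint$se else
      sqrt(pc * (1 - pc) / n)
    var_x <- (se_in / stats::dnorm(x))^2
  }
  need_cov <- !identical(model$source_definition, "MEAN_FPG")
  if (need_cov && is.null(datapoint$income)) {
    stop("datapoints must carry an 'income' column for cross-walk prediction")
  }
  nd <- data.frame(x = x)
  if (need_cov) {
    sc <- cwScale(data.frame(age_mid = bandMid(datapoint$age_lo,
                                               datapoint$age_hi),
                             mid_year = datapoint$mid_year,
                             income = datapoint$income),
                  centers = model$centers)
    nd <- cbind(nd, sc$covs)
    if ("sexmale" %in% names(model$coefficients) ||
        any(grepl("sexmale", names(model$coefficients)))) {
      nd$sexmale <- as.numeric(datapoint$sex == "male")
    }
  }
  X <- stats::model.matrix(stats::as.formula(model$fixed_formula), nd)
  X <- X[, names(model$coefficients), drop = FALSE]
  q_pred <- as.numeric(X %*% model$coefficients)
  var_coef <- rowSums((X %*% model$vcov) * X)
  # d q_pred / d x: the source slope plus its selected interactions
  dq_dx <- rep(model$coefficients[["x"]], nrow(nd))
  for (term in model$interactions) {
    covname <- sub("^x:", "", term)
    dq_dx <- dq_dx + model$coefficients[[term]] * nd[[covname]]
  }
  var_total <- var_coef + model$sigma2 +
    (if (!is.null(model$re_var)) model$re_var else 0) + dq_dx^2 * var_x
  p_out <- invProbit(q_pred)
  se_out <- stats::dnorm(q_pred) * sqrt(var_total)
  se_out <- pmax(se_out, se_in, na.rm = TRUE)
  out <- datapoint
  out$converted_from <- out$definition
  out$definition <- "PRIMARY_FPG7"
  out$prevalence <- p_out
  out$se <- se_out
  out$mean_fpg <- NA_real_
  out
}

#' Serialise a cross-walk model to JSON
#'
#' @param model a `CrosswalkModel`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
writeCrosswalkModel <- function(model, path) {
  obj <- unclass(model)
  obj$coefficients <- as.list(model$coefficients)
  obj$vcov <- list(names = colnames(model$vcov),
                   values = as.numeric(model$vcov))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname writeCrosswalkModel
#' @export
readCrosswalkModel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  k <- length(obj$vcov$names)
  obj$vcov <- matrix(obj$vcov$values, k, k,
                     dimnames = list(obj$vcov$names, obj$vcov$names))
  obj$coefficients <- unlist(obj$coefficients)
  obj$interactions <- as.character(obj$interactions)
  if (length(obj$re_var) == 0) obj$re_var <- NULL
  structure(obj, class = "CrosswalkModel")
}
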