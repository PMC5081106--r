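#' Pipeline run configuration
#'
#' Bundles everything a full synthetic-world run needs: output directory,
#' global seed, which stages to execute, and per-stage settings. The
#' `reduced` preset keeps MCMC at test scale; the full preset uses the
#' 5000-draw default schedule.
#'
#' @param outdir output directory.
#' @param seed global seed; every stage derives its own substream from it.
#' @param stages subset of `c("simulate", "crosswalk", "fit", "derive",
#'   "validate")`, executed in that order.
#' @param reduced logical; use the reduced MCMC preset.
#' @param world named list of [worldConfig()] overrides.
#' @param plan named list of [makeSurveyPlan()] overrides (e.g.
#'   `n_studies`, `definition_probs`).
#' @param model named list of [modelConfig()] overrides.
#' @param holdout list with `scheme` and `fraction` for the validate stage.
#' @param n_paired paired observations simulated per alternative definition
#'   for cross-walk training.
#' @return A list of class `RunConfig`.
#' @export
runConfig <- function(outdir = file.path(tempdir(), "diabtrends-run"),
                      seed = 1L,
                      stages = c("simulate", "crosswalk", "fit", "derive",
                                 "validate"),
                      reduced = TRUE,
                      world = list(),
                      plan = list(n_studies = 60),
                      model = list(),
                      holdout = list(scheme = "random_fraction",
                                     fraction = 0.2),
                      n_paired = 300) {
  known <- c("simulate", "crosswalk", "fit", "derive", "validate")
  if (!all(stages %in% known)) {
    stop("unknown stages: ", paste(setdiff(stages, known), collapse = ", "))
  }
  structure(list(outdir = outdir, seed = as.integer(seed),
                 stages = intersect(known, stages), reduced = reduced,
                 world = world, plan = plan, model = model,
                 holdout = holdout, n_paired = n_paired),
            class = "RunConfig")
}

#' Read a run configuration from YAML or JSON
#'
#' @param path configuration file; top-level keys as in [runConfig()].
#' @return A `RunConfig`.
#' @export
readRunConfig <- function(path) {
  raw <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  do.call(runConfig, raw)
}

configHash <- function(config) {
  obj <- unclass(config)
  obj <- obj[order(names(obj))]
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(as.character(jsonlite::toJSON(obj, auto_unbox = TRUE,
                                           digits = NA)), tf)
  unname(tools::md5sum(tf))
}

stageLog <- function(stage, ...) {
  message("[", stage, "] ", ...)
}

#' Run the estimation pipeline on a synthetic world
#'
#' Executes the enabled stages in order: `simulate` (build a ground-truth
#' world and survey datapoints), `crosswalk` (harmonise alternative
#' definitions to the primary outcome), `fit` (the hierarchical probit
#' model), `derive` (age-standardised/crude prevalence, counts,
#' decomposition, 2025 target assessment) and `validate` (hold-out refit
#' and scoring). Every run writes a manifest recording the seed, a hash of
#' the configuration, and each stage's declared outputs; rerunning with an
#' identical configuration reproduces identical outputs (the manifest's
#' `timestamp` field aside). A stage failure halts the run with an error
#' naming the stage.
#'
#' @param config a [runConfig()], or the path of a YAML/JSON file readable
#'   by [readRunConfig()].
#' @return The run manifest, invisibly, with the in-memory stage objects
#'   (world, datapoints, fit, ...) attached as the `"objects"` attribute.
#' @export
runPipeline <- function(config = runConfig()) {
  if (is.character(config)) config <- readRunConfig(config)
  stopifnot(inherits(config, "RunConfig"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package = "diabtrends",
                   version = as.character(utils::packageVersion("diabtrends")),
                   seed = config$seed, config_hash = configHash(config),
                   stages = list())
  obj <- new.env(parent = emptyenv())

  runStage <- function(name, fun) {
    if (!name %in% config$stages) return()
    stageLog(name, "started")
    t0 <- Sys.time()
    out <- tryCatch(fun(), error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e),
           " (see log above)", call. = FALSE)
    })
    stageLog(name, "done in ",
             format(round(difftime(Sys.time(), t0, units = "secs"), 1)))
    manifest$stages[[name]] <<- out
  }

  runStage("simulate", function() {
    wargs <- config$world
    obj$world <- buildWorld(do.call(worldConfig, wargs),
                            seed = substreamSeed(config$seed, 1))
    pargs <- config$plan
    pargs$world <- obj$world
    pargs$seed <- substreamSeed(config$seed, 2)
    obj$plan <- do.call(makeSurveyPlan, pargs)
    obj$datapoints <- simulateSurveys(obj$world, obj$plan,
                                      seed = substreamSeed(config$seed, 3))
    paths <- writeWorldTables(obj$world, config$outdir)
    sp <- file.path(config$outdir, "surveys.csv")
    writeSurveyTable(obj$datapoints, sp)
    list(outputs = c(unname(paths), sp),
         n_records = nrow(obj$datapoints),
         n_studies = nrow(obj$plan$studies))
  })

  runStage("crosswalk", function() {
    dp <- filterMinSample(obj$datapoints, quiet = TRUE)
    n_removed <- nrow(obj$datapoints) - nrow(dp)
    cov <- obj$world$covariates
    dp$income <- cov$education[match(paste(dp$country_id, dp$mid_year),
                                     paste(cov$country_id, cov$year))]
    defs <- setdiff(unique(dp$definition), "PRIMARY_FPG7")
    outputs <- character()
    harmonised <- dp[dp$definition == "PRIMARY_FPG7", , drop = FALSE]
    if (nrow(harmonised) > 0) harmonised$converted_from <- NA_character_
    for (def in defs) {
      paired <- simulatePairedSurveys(obj$world, config$n_paired, def,
                                      seed = substreamSeed(config$seed,
                                                           10 + match(def, defs)))
      cw <- fitCrosswalk(paired, def)
      mp <- file.path(config$outdir, paste0("crosswalk_", def, ".json"))
      writeCrosswalkModel(cw, mp)
      outputs <- c(outputs, mp)
      harmonised <- rbind(harmonised,
                          applyCrosswalk(cw, dp[dp$definition == def, ,
                                                drop = FALSE]))
    }
    obj$harmonised <- harmonised
    hp <- file.path(config$outdir, "harmonised.csv")
    writeSurveyTable(harmonised, hp)
    list(outputs = c(outputs, hp), n_records = nrow(harmonised),
         n_removed_small = n_removed, definitions_converted = defs)
  })

  runStage("fit", function() {
    margs <- config$model
    margs$years <- if (!is.null(margs$years)) margs$years else obj$world$years
    margs$seed <- substreamSeed(config$seed, 20)
    cfg <- if (config$reduced) do.call(reducedModelConfig, margs)
      else do.call(modelConfig, margs)
    dp <- if (!is.null(obj$harmonised)) obj$harmonised else obj$datapoints
    obj$fit <- fitTrendModel(dp, obj$world$covariates, obj$world$hierarchy,
                             cfg)
    sm <- posteriorSummaryTable(obj$fit)
    sp <- file.path(config$outdir, "posterior_summary.csv")
    utils::write.csv(sm, sp, row.names = FALSE)
    dpath <- file.path(config$outdir, "posterior_draws.rds")
    saveRDS(obj$fit, dpath)
    list(outputs = c(sp, dpath), draws = dim(obj$fit$prev)[1],
         converged = vapply(obj$fit$diagnostics, `[[`, TRUE, "converged"))
  })

  runStage("derive", function() {
    wts <- whoStandardPopulation()
    fit <- obj$fit
    pop <- obj$world$population
    rows <- list(); outputs <- character()
    for (sx in fit$sexes) {
      asd <- ageStandardisedDraws(fit, sx, wts, unit = "world",
                                  population = pop)
      agg <- aggregatePrevalence(fit, pop, sx)
      for (t in seq_along(fit$years)) {
        popw <- colSums(matrix(pop[, t, sx, ], nrow = length(fit$countries)))
        cc <- crudeAndCounts(agg[, t, ], popw)
        rows[[length(rows) + 1]] <- data.frame(
          sex = sx, year = fit$years[t],
          as_prev_mean = mean(asd[, t]),
          as_prev_lo = stats::quantile(asd[, t], 0.025),
          as_prev_hi = stats::quantile(asd[, t], 0.975),
          crude_prev_mean = mean(cc$crude),
          count_mean = mean(cc$count),
          count_lo = stats::quantile(cc$count, 0.025),
          count_hi = stats::quantile(cc$count, 0.975))
      }
      # decomposition of the count change over the estimation period
      t0 <- 1; t1 <- length(fit$years)
      prev0 <- colMeans(agg[, t0, ]); prev1 <- colMeans(agg[, t1, ])
      pop0 <- colSums(matrix(pop[, t0, sx, ], nrow = length(fit$countries)))
      pop1 <- colSums(matrix(pop[, t1, sx, ], nrow = length(fit$countries)))
      dec <- decomposeChange(prev0, prev1, pop0, pop1)
      dj <- file.path(config$outdir, paste0("decomposition_", sx, ".json"))
      jsonlite::write_json(unclass(dec), dj, auto_unbox = TRUE, digits = NA)
      outputs <- c(outputs, dj)
      # 2025 target under post-2000 trend continuation
      ws <- max(2000, min(fit$years))
      baseline_year <- if (2010 %in% fit$years) 2010 else
        fit$years[ceiling(length(fit$years) / 2)]
      proj <- projectPost2000(fit, sx, unit = "world", target_year = 2025,
                              window_start = ws, weights = wts,
                              population = pop)
      ta <- targetProbability(proj, asd[, as.character(baseline_year)],
                              unit = "world", sex = sx)
      tj <- file.path(config$outdir, paste0("target_", sx, ".json"))
      jsonlite::write_json(list(unit = ta$unit, sex = ta$sex,
                                baseline_year = baseline_year,
                                probability_met = ta$probability_met,
                                projected_2025_mean = mean(ta$projected)),
                           tj, auto_unbox = TRUE, digits = NA)
      outputs <- c(outputs, tj)
    }
    tab <- do.call(rbind, rows)
    tp <- file.path(config$outdir, "derived_trends.csv")
    utils::write.csv(tab, tp, row.names = FALSE)
    list(outputs = c(tp, outputs), n_records = nrow(tab))
  })

  runStage("validate", function() {
    dp <- if (!is.null(obj$harmonised)) obj$harmonised else obj$datapoints
    split <- makeHoldoutSplit(dp, config$holdout$scheme,
                              config$holdout$fraction,
                              seed = substreamSeed(config$seed, 30))
    margs <- config$model
    margs$years <- if (!is.null(margs$years)) margs$years else obj$world$years
    margs$seed <- substreamSeed(config$seed, 31)
    cfg <- if (config$reduced) do.call(reducedModelConfig, margs)
      else do.call(modelConfig, margs)
    refit <- fitTrendModel(split$train, obj$world$covariates,
                           obj$world$hierarchy, cfg)
    report <- evaluateHoldout(refit, split$test,
                              population = obj$world$population)
    obj$validation <- report
    jp <- file.path(config$outdir, "validation.json")
    cp <- file.path(config$outdir, "validation_residuals.csv")
    writeValidationReport(report, jp, cp)
    list(outputs = c(jp, cp), n_test = nrow(split$test),
         median_error = report$median_error,
         median_absolute_error = report$median_absolute_error)
  })

  manifest$timestamp <- format(Sys.time(), tz = "UTC")
  mp <- file.path(config$outdir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA)
  structure(invisible(manifest), objects = obj)
}

#' Posterior summary table
#'
#' Flat table of posterior mean and 2.5/97.5 percentiles of prevalence per
#' country, year, sex and age group.
#'
#' @param fit a `PosteriorDraws`.
#' @return A data.frame.
#' @export
posteriorSummaryTable <- function(fit) {
  stopifnot(inherits(fit, "PosteriorDraws"))
  pm <- apply(fit$prev, c(2, 3, 4, 5), mean)
  lo <- apply(fit$prev, c(2, 3, 4, 5), stats::quantile, 0.025)
  hi <- apply(fit$prev, c(2, 3, 4, 5), stats::quantile, 0.975)
  tab <- as.data.frame.table(pm, stringsAsFactors = FALSE,
                             responseName = "mean")
  names(tab)[1:4] <- c("country_id", "year", "sex", "age_group")
  tab$year <- as.integer(tab$year)
  tab$lo <- as.numeric(lo)
  tab$hi <- as.numeric(hi)
  tab
}
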