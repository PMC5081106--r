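#' Trend-model configuration
#'
#' Settings for the Bayesian hierarchical probit model: estimation years,
#' MCMC schedule, spline knots, prior scales and convergence thresholds.
#' Estimates are produced for every country in the supplied hierarchy and
#' every year in `years`, separately by sex.
#'
#' @param years estimation years (length >= 2; default 1980-2014).
#' @param draws total post-burn-in posterior draws retained (default 5000).
#' @param chains number of MCMC chains (>= 2, so convergence can be
#'   monitored).
#' @param burn,adapt burn-in and adaptation iterations per chain.
#' @param thin thinning interval.
#' @param knot_spacing spacing (years) of the knot grid carrying the
#'   second-order random-walk non-linear trend at each hierarchy level.
#' @param age_knots interior knots (years of age) of the cubic age spline.
#' @param covariates country-covariate column names entering the linear
#'   predictor (z-scored internally).
#' @param prior_sd_level,prior_sd_slope half-normal prior scales of the
#'   hierarchical level/slope deviation SDs (probit, probit per decade).
#' @param prior_sd_rw half-normal prior scale of the random-walk innovation
#'   SDs.
#' @param prior_sd_scope normal prior SD of the subnational/community/
#'   rural/urban fixed effects.
#' @param prior_sd_covariate normal prior SD of the covariate effects
#'   (probit per covariate SD).
#' @param prior_sd_study half-normal prior scale of the study random-effect
#'   SDs (subnational and community studies).
#' @param prior_sd_nonsampling half-normal prior scale of the
#'   scope-specific non-sampling SDs added to the sampling variance.
#' @param rhat_threshold potential-scale-reduction threshold above which a
#'   non-convergence warning is raised.
#' @param min_ess effective-sample-size floor per monitored parameter.
#' @param seed integer seed driving the MCMC random streams.
#' @return A list of class `ModelConfig`.
#' @export
modelConfig <- function(years = 1980:2014, draws = 5000, chains = 2,
                        burn = 2000, adapt = 1000, thin = 1,
                        knot_spacing = 5, age_knots = c(35, 50, 65),
                        covariates = c("education", "urbanisation", "food",
                                       "bmi"),
                        prior_sd_level = 0.3, prior_sd_slope = 0.15,
                        prior_sd_rw = 0.1, prior_sd_scope = 0.5,
                        prior_sd_covariate = 0.25,
                        prior_sd_study = 0.3, prior_sd_nonsampling = 0.15,
                        rhat_threshold = 1.1, min_ess = 50, seed = 1L) {
  cfg <- as.list(environment())
  if (length(cfg$years) < 2) stop("year range must cover at least 2 years")
  if (cfg$chains < 2) stop("at least 2 chains are required")
  if (cfg$draws < 1) stop("draws must be positive")
  structure(cfg, class = "ModelConfig")
}

#' Reduced-scale preset of a model configuration
#'
#' @param ... overrides passed to [modelConfig()].
#' @return A `ModelConfig` sized for test-scale runs (1000 retained draws).
#' @export
reducedModelConfig <- function(...) {
  args <- list(draws = 1000, chains = 2, burn = 2000, adapt = 500, thin = 8)
  override <- list(...)
  args[names(override)] <- override
  do.call(modelConfig, args)
}

yearKnots <- function(years, spacing) {
  ks <- unique(c(seq(min(years), max(years), by = spacing), max(years)))
  if (length(ks) < 3) ks <- seq(min(years), max(years), length.out = 3)
  ks
}

# linear interpolation weights from a knot grid to arbitrary year positions
knotInterpMatrix <- function(at, knots) {
  K <- length(knots)
  W <- matrix(0, length(at), K)
  j <- pmin(pmax(findInterval(at, knots), 1), K - 1)
  wr <- (at - knots[j]) / (knots[j + 1] - knots[j])
  for (i in seq_along(at)) {
    W[i, j[i]] <- 1 - wr[i]
    W[i, j[i] + 1] <- wr[i]
  }
  W
}

# cubic age-spline basis over the standard group midpoints, zeroed at the
# reference age of 50 so the level surface is probit prevalence at age 50
ageBasis <- function(age_knots) {
  ag <- ageGroupTable()
  b <- splines::ns(ag$mid, knots = age_knots,
                   Boundary.knots = range(ag$mid))
  ref <- stats::predict(b, 50)
  list(B = sweep(unclass(b), 2, as.numeric(ref)), basis = b)
}

trendModelCode <- "
model {
  for (i in 1:N) {
    fb[i] <- inprod(Ab[i, ], alpha[])
    theta[i] <- muct[cn[i], yr[i]]
      + fb[i] * exp(gamma * (muct[cn[i], yr[i]] - m0))
      + dsub * subi[i] + dcom * comi[i]
      + (durb * urbi[i] + drur * ruri[i]) * udiff[i]
      + est[sid[i]]
    y[i] ~ dnorm(theta[i], 1 / (v[i] + kap2[sci[i]]))
  }

  # probit prevalence level at the reference age, all countries and years
  for (c in 1:C) {
    for (t in 1:T) {
      muct[c, t] <- ac0[c] + ac1[c] * tcg[t]
        + inprod(Wy[t, ], gw[]) + inprod(Wy[t, ], gs[srx[c], ])
        + inprod(Wy[t, ], gr[rgx[c], ]) + inprod(Wy[t, ], gc[c, ])
        + inprod(Zg[c, t, ], bcov[])
    }
  }

  # nested levels and trends, hierarchically centred: country intercepts
  # and slopes are drawn around their region's, regions around their
  # super-region's, super-regions around the world's
  for (s in 1:S) {
    as0[s] ~ dnorm(b0, 1 / (sd_sr0 * sd_sr0))
    as1[s] ~ dnorm(b1, 1 / (sd_sr1 * sd_sr1))
  }
  for (r in 1:R) {
    ar0[r] ~ dnorm(as0[srofr[r]], 1 / (sd_rg0 * sd_rg0))
    ar1[r] ~ dnorm(as1[srofr[r]], 1 / (sd_rg1 * sd_rg1))
  }
  for (c in 1:C) {
    ac0[c] ~ dnorm(ar0[rgx[c]], 1 / (sd_cn0 * sd_cn0))
    ac1[c] ~ dnorm(ar1[rgx[c]], 1 / (sd_cn1 * sd_cn1))
  }

  # second-order random-walk non-linear trends on the knot grid, one series
  # per hierarchy level. Non-centred: innovations are standard normals
  # scaled by the level's innovation SD; the walk starts at (0, 0) and its
  # remaining level/slope component is projected out (those directions are
  # carried by the intercepts and linear trends above).
  for (k in 1:(K - 2)) { zw[k] ~ dnorm(0, 1) }
  rw[1] <- 0
  rw[2] <- 0
  for (k in 3:K) { rw[k] <- 2 * rw[k - 1] - rw[k - 2] + sd_rww * zw[k - 2] }
  mrw <- mean(rw[]); srw <- inprod(rw[], kcn[]) / kss
  for (k in 1:K) { gw[k] <- rw[k] - mrw - srw * kcn[k] }
  for (s in 1:S) {
    for (k in 1:(K - 2)) { zs[s, k] ~ dnorm(0, 1) }
    rs[s, 1] <- 0
    rs[s, 2] <- 0
    for (k in 3:K) {
      rs[s, k] <- 2 * rs[s, k - 1] - rs[s, k - 2] + sd_rws * zs[s, k - 2]
    }
    mrs[s] <- mean(rs[s, ]); srs[s] <- inprod(rs[s, ], kcn[]) / kss
    for (k in 1:K) { gs[s, k] <- rs[s, k] - mrs[s] - srs[s] * kcn[k] }
  }
  for (r in 1:R) {
    for (k in 1:(K - 2)) { zr[r, k] ~ dnorm(0, 1) }
    rr[r, 1] <- 0
    rr[r, 2] <- 0
    for (k in 3:K) {
      rr[r, k] <- 2 * rr[r, k - 1] - rr[r, k - 2] + sd_rwr * zr[r, k - 2]
    }
    mrr[r] <- mean(rr[r, ]); srr[r] <- inprod(rr[r, ], kcn[]) / kss
    for (k in 1:K) { gr[r, k] <- rr[r, k] - mrr[r] - srr[r] * kcn[k] }
  }
  for (c in 1:C) {
    for (k in 1:(K - 2)) { zc[c, k] ~ dnorm(0, 1) }
    rc[c, 1] <- 0
    rc[c, 2] <- 0
    for (k in 3:K) {
      rc[c, k] <- 2 * rc[c, k - 1] - rc[c, k - 2] + sd_rwc * zc[c, k - 2]
    }
    mrc[c] <- mean(rc[c, ]); src[c] <- inprod(rc[c, ], kcn[]) / kss
    for (k in 1:K) { gc[c, k] <- rc[c, k] - mrc[c] - src[c] * kcn[k] }
  }

  # study random effects: national studies are pinned at zero; subnational
  # and community studies get scope-specific variances
  for (j in 1:Sstud) { est[j] ~ dnorm(0, pstud[scst[j]]) }
  pstud[1] <- 1.0E8
  pstud[2] <- 1 / (tau_sub * tau_sub)
  pstud[3] <- 1 / (tau_com * tau_com)

  # age spline and level-dependent steepness
  for (j in 1:Pa) { alpha[j] ~ dnorm(0, 0.25) }
  gamma ~ dnorm(0, 1 / (0.5 * 0.5)) T(0, )

  # covariates and scope fixed effects
  for (p in 1:P) { bcov[p] ~ dnorm(0, pcov) }
  dsub ~ dnorm(0, pscope)
  dcom ~ dnorm(0, pscope)
  durb ~ dnorm(0, pscope)
  drur ~ dnorm(0, pscope)

  b0 ~ dnorm(0, 0.25)
  b1 ~ dnorm(0, 1)
  sd_sr0 ~ dnorm(0, plevel) T(0, )
  sd_rg0 ~ dnorm(0, plevel) T(0, )
  sd_cn0 ~ dnorm(0, plevel) T(0, )
  sd_sr1 ~ dnorm(0, pslope) T(0, )
  sd_rg1 ~ dnorm(0, pslope) T(0, )
  sd_cn1 ~ dnorm(0, pslope) T(0, )
  sd_rww ~ dnorm(0, prw0) T(0, )
  sd_rws ~ dnorm(0, prw0) T(0, )
  sd_rwr ~ dnorm(0, prw0) T(0, )
  sd_rwc ~ dnorm(0, prw0) T(0, )
  tau_sub ~ dnorm(0, pstudy0) T(0, )
  tau_com ~ dnorm(0, pstudy0) T(0, )
  kap2[1] <- kap_nat * kap_nat
  kap2[2] <- kap_sub * kap_sub
  kap2[3] <- kap_com * kap_com
  kap_nat ~ dnorm(0, pnons) T(0, )
  kap_sub ~ dnorm(0, pnons) T(0, )
  kap_com ~ dnorm(0, pnons) T(0, )
}
"

scopeIndex <- function(scope) match(scope, c("national", "subnational",
                                             "community"))

#' Fit the hierarchical probit trend model
#'
#' Fits, separately by sex, a Bayesian hierarchical probit model to
#' harmonised survey datapoints. On the probit scale the predictor combines
#' a global intercept and linear trend; nested super-region, region and
#' country deviations in level and slope; a second-order random-walk
#' non-linear year component at every hierarchy level; a cubic age spline
#' whose steepness increases exponentially with the country-year level;
#' z-scored country covariates; fixed offsets for subnational and community
#' studies; rural/urban fixed effects weighted by the difference between
#' study-level and country-level urbanisation; and study random effects with
#' scope-specific variances. The likelihood treats the probit-transformed
#' stratum prevalence as Gaussian with its delta-method sampling variance
#' plus a scope-specific non-sampling variance.
#'
#' Convergence is monitored through the potential scale reduction factor and
#' effective sample size of all variance parameters and fixed effects;
#' failures raise a warning and are flagged in the returned diagnostics,
#' never silently ignored.
#'
#' @param datapoints harmonised survey datapoints (every `definition` must
#'   be `PRIMARY_FPG7`).
#' @param covariates country-covariate table (`country_id`, `year`, one
#'   column per configured covariate; must include `urbanisation`).
#' @param hierarchy country/region/super-region table as in a `WorldTruth`.
#' @param config a [modelConfig()].
#' @return An object of class `PosteriorDraws`: element `prev` is an array
#'   `[draw, country, year, sex, age group]` of prevalence proportions
#'   (exactly `config$draws` draws); `coef` holds per-sex draws of the
#'   fixed effects and variance parameters; `diagnostics` the per-sex
#'   convergence table and flag.
#' @export
fitTrendModel <- function(datapoints, covariates, hierarchy,
                          config = modelConfig()) {
  stopifnot(inherits(config, "ModelConfig"))
  if (nrow(datapoints) == 0) stop("no datapoints to fit")
  if (!all(datapoints$definition == "PRIMARY_FPG7")) {
    stop("all datapoints must be harmonised to PRIMARY_FPG7 before fitting; ",
         "run the cross-walk first")
  }
  if (!all(datapoints$country_id %in% hierarchy$country_id)) {
    stop("datapoints reference countries absent from the hierarchy")
  }
  if (!all(datapoints$mid_year %in% config$years)) {
    stop("datapoints outside the configured year range")
  }
  # canonical ordering: results do not depend on input row order
  datapoints <- datapoints[order(datapoints$sex, datapoints$study_id,
                                 datapoints$age_lo), , drop = FALSE]

  years <- config$years
  ag <- ageGroupTable()
  C <- nrow(hierarchy)
  rg_levels <- unique(hierarchy$region_id)
  sr_levels <- unique(hierarchy$super_region_id)
  rgx <- match(hierarchy$region_id, rg_levels)
  srx <- match(hierarchy$super_region_id, sr_levels)
  tcg <- (years - mean(years)) / 10
  knots <- yearKnots(years, config$knot_spacing)
  Wy <- knotInterpMatrix(years, knots)
  K <- length(knots)
  kcn <- seq_len(K) - (K + 1) / 2
  ab <- ageBasis(config$age_knots)

  # covariate grid, z-scored across all country-years
  cov_names <- config$covariates
  key <- paste(covariates$country_id, covariates$year)
  Zraw <- as.matrix(covariates[, cov_names, drop = FALSE])
  z_center <- colMeans(Zraw)
  z_scale <- apply(Zraw, 2, stats::sd)
  z_scale[z_scale == 0] <- 1
  Zsc <- sweep(sweep(Zraw, 2, z_center), 2, z_scale, "/")
  Zg <- array(0, dim = c(C, length(years), length(cov_names)))
  urb_grid <- matrix(0, C, length(years))
  for (c in seq_len(C)) {
    idx <- match(paste(hierarchy$country_id[c], years), key)
    if (anyNA(idx)) stop("covariates missing for some country-years")
    Zg[c, , ] <- Zsc[idx, ]
    urb_grid[c, ] <- covariates$urbanisation[idx]
  }
  # orthogonalise each covariate against every country's linear trend.
  # Country-linear covariate components are absorbed exactly by the free
  # country intercepts and slopes, so the fitted surfaces are unchanged;
  # the projection keeps the covariate effects identified (from
  # within-country non-linear variation) and the sampler well-conditioned.
  H <- cbind(1, tcg)
  P_orth <- diag(length(years)) - H %*% solve(crossprod(H), t(H))
  for (p in seq_along(cov_names)) {
    Zg[, , p] <- Zg[, , p] %*% P_orth
  }

  sexes <- sort(unique(datapoints$sex))
  ndraw <- config$draws
  per_chain <- ceiling(ndraw / config$chains)
  prev <- array(NA_real_,
                dim = c(ndraw, C, length(years), length(sexes), nrow(ag)),
                dimnames = list(NULL, hierarchy$country_id, years, sexes,
                                ag$label))
  coef_draws <- list()
  diagnostics <- list()

  for (sx in sexes) {
    d <- datapoints[datapoints$sex == sx, , drop = FALSE]
    pc <- correctedPrevalence(d$prevalence, d$n_examined)
    y <- probit(pc)
    se <- if (!is.null(d$se)) d$se else sqrt(pc * (1 - pc) / d$n_examined)
    v <- (se / stats::dnorm(y))^2
    cn <- match(d$country_id, hierarchy$country_id)
    yr <- match(d$mid_year, years)
    Ab <- t(vapply(seq_len(nrow(d)), function(i) {
      idx <- ageGroupIndices(d$age_lo[i], d$age_hi[i])
      colMeans(ab$B[idx, , drop = FALSE])
    }, numeric(ncol(ab$B))))
    studies <- unique(d$study_id)
    sid <- match(d$study_id, studies)
    scst <- scopeIndex(d$scope[match(studies, d$study_id)])
    udiff <- ifelse(is.na(d$study_urban_fraction), 0,
                    d$study_urban_fraction - urb_grid[cbind(cn, yr)])
    m0 <- mean(y)

    jd <- list(
      N = nrow(d), C = C, T = length(years), S = length(sr_levels),
      R = length(rg_levels), K = K, Pa = ncol(ab$B), P = length(cov_names),
      Sstud = length(studies),
      y = y, v = v, cn = cn, yr = yr, Ab = Ab, sid = sid, scst = scst,
      sci = scopeIndex(d$scope),
      subi = as.numeric(d$scope == "subnational"),
      comi = as.numeric(d$scope == "community"),
      urbi = as.numeric(d$urbanicity == "urban_only"),
      ruri = as.numeric(d$urbanicity == "rural_only"),
      udiff = udiff,
      srx = srx, rgx = rgx, tcg = tcg, Wy = Wy, kcn = kcn,
      kss = sum(kcn^2), Zg = Zg, m0 = m0,
      srofr = match(hierarchy$super_region_id[match(rg_levels,
        hierarchy$region_id)], sr_levels),
      plevel = 1 / config$prior_sd_level^2,
      pslope = 1 / config$prior_sd_slope^2,
      prw0 = 1 / config$prior_sd_rw^2,
      pscope = 1 / config$prior_sd_scope^2,
      pcov = 1 / config$prior_sd_covariate^2,
      pstudy0 = 1 / config$prior_sd_study^2,
      pnons = 1 / config$prior_sd_nonsampling^2
    )
    inits <- lapply(seq_len(config$chains), function(ch) {
      list(.RNG.name = "base::Mersenne-Twister",
           .RNG.seed = substreamSeed(config$seed, 10 * match(sx, sexes) + ch))
    })
    monitors <- c("muct", "alpha", "gamma", "b0", "b1", "bcov",
                  "dsub", "dcom", "durb", "drur",
                  "sd_sr0", "sd_rg0", "sd_cn0", "sd_sr1", "sd_rg1", "sd_cn1",
                  "sd_rww", "sd_rws", "sd_rwr", "sd_rwc",
                  "tau_sub", "tau_com", "kap_nat", "kap_sub", "kap_com")
    jm <- rjags::jags.model(textConnection(trendModelCode), data = jd,
                            inits = inits, n.chains = config$chains,
                            n.adapt = config$adapt, quiet = TRUE)
    stats::update(jm, config$burn, progress.bar = "none")
    samp <- rjags::coda.samples(jm, monitors, per_chain * config$thin,
                                thin = config$thin, progress.bar = "none")

    diag_cols <- setdiff(colnames(samp[[1]]),
                         grep("^muct", colnames(samp[[1]]), value = TRUE))
    psrf <- tryCatch(
      coda::gelman.diag(samp[, diag_cols, drop = FALSE], autoburnin = FALSE,
                        multivariate = FALSE)$psrf[, 1],
      error = function(e) stats::setNames(rep(NA_real_, length(diag_cols)),
                                          diag_cols))
    ess <- coda::effectiveSize(samp[, diag_cols, drop = FALSE])
    # the convergence gate covers the variance parameters and the scope
    # bias terms; the remaining fixed effects are reported but individually
    # only weakly identified (the prevalence surface, their identified sum,
    # is what the draws carry)
    gate <- grep("^(sd_|tau_|kap_|gamma$|dsub$|dcom$|durb$|drur$)",
                 diag_cols, value = TRUE)
    converged <- all(psrf[gate] < config$rhat_threshold, na.rm = TRUE) &&
      all(ess[gate] >= config$min_ess)
    if (!converged) {
      warning("convergence diagnostics failed for sex '", sx, "': max Rhat = ",
              round(max(psrf, na.rm = TRUE), 3), ", min ESS = ",
              round(min(ess)), call. = FALSE)
    }
    diagnostics[[sx]] <- list(
      table = data.frame(parameter = diag_cols, psrf = unname(psrf[diag_cols]),
                         ess = unname(ess[diag_cols])),
      converged = converged)

    M <- do.call(rbind, lapply(samp, as.matrix))[seq_len(ndraw), ,
                                                 drop = FALSE]
    coef_draws[[sx]] <- M[, diag_cols, drop = FALSE]
    mu_cols <- outer(seq_len(C), seq_along(years),
                     function(c, t) sprintf("muct[%d,%d]", c, t))
    MU <- M[, as.vector(mu_cols), drop = FALSE]   # draws x (C*T)
    A <- M[, sprintf("alpha[%d]", seq_len(ncol(ab$B))), drop = FALSE]
    Fd <- A %*% t(ab$B)                           # draws x ages
    steep <- exp(M[, "gamma"] * (MU - m0))        # draws x (C*T)
    xi <- match(sx, sexes)
    for (a in seq_len(nrow(ag))) {
      eta <- MU + Fd[, a] * steep
      prev[, , , xi, a] <- stats::pnorm(eta)
    }
  }

  structure(list(
    prev = prev, countries = hierarchy$country_id, years = years,
    sexes = sexes, age_groups = ag, hierarchy = hierarchy,
    coef = coef_draws, diagnostics = diagnostics, config = config,
    cov_scaling = list(center = z_center, scale = z_scale)
  ), class = "PosteriorDraws")
}

#' @export
print.PosteriorDraws <- function(x, ...) {
  cat("PosteriorDraws:", dim(x$prev)[1], "draws x", length(x$countries),
      "countries x", length(x$years), "years x",
      paste(x$sexes, collapse = "/"), "x", nrow(x$age_groups),
      "age groups\n")
  for (sx in x$sexes) {
    cat("  ", sx, ": ",
        if (x$diagnostics[[sx]]$converged) "converged"
        else "CONVERGENCE FLAGGED", "\n", sep = "")
  }
  invisible(x)
}

#' Age-specific posterior prevalence draws for one cell
#'
#' Returns the stored draws for a country/year/sex; queries outside the
#' fitted support are an error (projection beyond the fitted years is a
#' separate, explicit operation).
#'
#' @param draws a `PosteriorDraws`.
#' @param country,year,sex the cell to extract.
#' @return Matrix `[draw, age group]` of prevalence proportions.
#' @export
predictPrevalence <- function(draws, country, year, sex) {
  stopifnot(inherits(draws, "PosteriorDraws"))
  ci <- match(country, draws$countries)
  ti <- match(year, draws$years)
  xi <- match(sex, draws$sexes)
  if (is.na(ci)) stop("country ", country, " not in the fitted hierarchy")
  if (is.na(ti)) stop("year ", year, " outside the fitted support")
  if (is.na(xi)) stop("sex ", sex, " was not fitted")
  draws$prev[, ci, ti, xi, ]
}

#' Population-weighted aggregation of posterior draws
#'
#' Aggregates age-specific prevalence draws across a set of countries using
#' age-specific population weights, per draw and year — the route from
#' country draws to regional and world draws.
#'
#' @param draws a `PosteriorDraws`.
#' @param population array `[country, year, sex, age]` with dimnames
#'   matching the draws (e.g. `world$population`).
#' @param sex which sex to aggregate.
#' @param countries countries to pool (default: all fitted).
#' @return Array `[draw, year, age group]` of pooled prevalences.
#' @export
aggregatePrevalence <- function(draws, population, sex,
                                countries = draws$countries) {
  stopifnot(inherits(draws, "PosteriorDraws"))
  ci <- match(countries, draws$countries)
  if (anyNA(ci)) stop("unknown countries in aggregation request")
  xi <- match(sex, draws$sexes)
  if (is.na(xi)) stop("sex ", sex, " was not fitted")
  pop <- population[countries, as.character(draws$years), sex, , drop = FALSE]
  nd <- dim(draws$prev)[1]
  out <- array(0, dim = c(nd, length(draws$years), nrow(draws$age_groups)),
               dimnames = list(NULL, draws$years, draws$age_groups$label))
  for (t in seq_along(draws$years)) {
    popmat <- matrix(pop[, t, 1, ], nrow = length(countries))
    ptot <- colSums(popmat)
    num <- matrix(0, nd, nrow(draws$age_groups))
    for (k in seq_along(ci)) {
      num <- num + sweep(draws$prev[, ci[k], t, xi, ], 2, popmat[k, ], "*")
    }
    out[, t, ] <- sweep(num, 2, ptot, "/")
  }
  out
}

#' Age-standardised posterior trajectories
#'
#' Applies standard-population weights to the age-specific draws of a
#' country (or of a population-weighted pool of countries), per draw and
#' year.
#'
#' @param draws a `PosteriorDraws`.
#' @param sex sex to summarise.
#' @param weights a `StandardPopulation`.
#' @param unit a country id, or `NULL`/`"world"`/a region or super-region id
#'   for aggregates (these require `population`).
#' @param population population array, required for aggregate units.
#' @return Matrix `[draw, year]` of age-standardised prevalence.
#' @export
ageStandardisedDraws <- function(draws, sex, weights = whoStandardPopulation(),
                                 unit = NULL, population = NULL) {
  stopifnot(inherits(draws, "PosteriorDraws"))
  w <- unclass(weights)
  if (!is.null(unit) && unit %in% draws$countries) {
    xi <- match(sex, draws$sexes)
    if (is.na(xi)) stop("sex ", sex, " was not fitted")
    ci <- match(unit, draws$countries)
    nd <- dim(draws$prev)[1]
    out <- matrix(0, nd, length(draws$years),
                  dimnames = list(NULL, draws$years))
    for (t in seq_along(draws$years)) {
      out[, t] <- draws$prev[, ci, t, xi, ] %*% w
    }
    return(out)
  }
  if (is.null(population)) {
    stop("aggregate units require a population array")
  }
  countries <- if (is.null(unit) || identical(unit, "world")) {
    draws$countries
  } else if (unit %in% draws$hierarchy$region_id) {
    draws$hierarchy$country_id[draws$hierarchy$region_id == unit]
  } else if (unit %in% draws$hierarchy$super_region_id) {
    draws$hierarchy$country_id[draws$hierarchy$super_region_id == unit]
  } else {
    stop("unknown unit: ", unit)
  }
  agg <- aggregatePrevalence(draws, population, sex, countries)
  out <- matrix(0, dim(agg)[1], length(draws$years),
                dimnames = list(NULL, draws$years))
  for (t in seq_along(draws$years)) out[, t] <- agg[, t, ] %*% w
  out
}

#' Posterior probability of an increase in prevalence
#'
#' Fraction of posterior draws in which the age-standardised prevalence at
#' `year1` exceeds that at `year0`. A value of 0.5 means an increase is
#' statistically indistinguishable from a decrease; `year0 == year1` gives
#' 0 under the strict ">" convention.
#'
#' @inheritParams ageStandardisedDraws
#' @param year0,year1 comparison years within the fitted support
#'   (`year0 <= year1`).
#' @return Probability in \[0, 1\].
#' @export
posteriorProbIncrease <- function(draws, sex, year0, year1,
                                  weights = whoStandardPopulation(),
                                  unit = NULL, population = NULL) {
  if (!year0 %in% draws$years || !year1 %in% draws$years) {
    stop("comparison years must lie within the fitted support")
  }
  if (year0 > year1) stop("year0 must not exceed year1")
  asd <- ageStandardisedDraws(draws, sex, weights, unit, population)
  mean(asd[, as.character(year1)] > asd[, as.character(year0)])
}
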