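## Report drivers tying the stages into the three analytical steps:
## step 1 univariate (un)conditional models, step 2 bivariate models with
## random-effect correlations, step 3 stratified cross-lag contrasts.

.resolveInput <- function(input, minWeeks, requireVariation, log) {
  if (is.character(input)) {
    digest <- unname(tools::md5sum(input))
    panel <- readPanel(input)
  } else if (methods::is(input, "GeneratorConfig")) {
    sim <- simulatePanel(input)
    panel <- sim$panel
    digest <- sprintf("generator(seed=%d,n=%d,T=%d)", input@seed, input@n,
                      input@nWeeks)
  } else if (methods::is(input, "MoodPanel")) {
    panel <- input
    tf <- tempfile(fileext = ".rds")
    on.exit(unlink(tf))
    saveRDS(SummarizedExperiment::assays(panel), tf)
    digest <- unname(tools::md5sum(tf))
  } else stop("input must be a file path, MoodPanel or GeneratorConfig")
  el <- applyEligibility(panel, minWeeks = minWeeks,
                         requireVariation = requireVariation)
  log(sprintf("input digest: %s", digest))
  log(sprintf("eligibility: %d of %d participants retained (%d excluded)",
              ncol(el$panel), ncol(panel), nrow(el$exclusions)))
  list(panel = el$panel, exclusions = el$exclusions, digest = digest)
}

.openRun <- function(outDir, config, seed) {
  if (!dir.exists(outDir)) {
    dir.create(outDir, recursive = TRUE)
  }
  logFile <- file.path(outDir, "run.log")
  cat(sprintf("[%s] run started\n", format(Sys.time())), file = logFile)
  log <- function(msg) {
    cat(sprintf("[%s] %s\n", format(Sys.time()), msg), file = logFile,
        append = TRUE)
  }
  log(sprintf("log created; master seed %d", seed))
  list(log = log, logFile = logFile,
       manifest = function(digest, extra = list()) {
         jsonlite::write_json(c(list(
           config = config, seed = seed,
           package = paste0("mooddsem ", as.character(packageVersion("mooddsem"))),
           inputDigest = digest), extra),
           file.path(outDir, "manifest.json"), auto_unbox = TRUE, digits = NA)
       })
}

.writeReport <- function(df, path, convergence) {
  con <- file(path, "w")
  if (!all(convergence))
    writeLines("# WARNING: convergence flag FALSE for at least one fit; interpret with caution", con)
  writeLines(paste0("# generated by mooddsem ",
                    as.character(packageVersion("mooddsem"))), con)
  write.csv(df, con, row.names = FALSE)
  close(con)
  path
}

#' Derive per-stage seeds from one master seed
#'
#' All randomness in a multi-stage run (simulation, calibration, each model
#' fit) flows from a single master seed, expanded deterministically into one
#' sub-seed per stage.
#'
#' @param seed master integer seed.
#' @param k number of stage seeds.
#' @return integer vector of length `k`.
#' @export
stageSeeds <- function(seed, k) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, k)
}

.stageSeeds <- stageSeeds

#' Step 1: univariate models, unconditional then covariate-conditional
#'
#' Fits an unconditional univariate model per outcome, then refits with the
#' four binary baseline covariates predicting every random effect jointly
#' (or one at a time with `oneAtATime = TRUE`), and writes a report table of
#' covariate effects on individual means, inertia and innovation (estimate,
#' 95% CI, one-tailed p) plus the unconditional fixed effects.
#'
#' @param input a CSV path, [MoodPanel-class] or [GeneratorConfig-class].
#' @param outDir output directory (created, with `manifest.json` and
#'   `run.log`, sufficient to reproduce the run).
#' @param outcomes outcomes to model.
#' @param chains,iterations,burnin,psrThreshold sampler settings.
#' @param minWeeks,requireVariation eligibility settings.
#' @param oneAtATime enter covariates singly instead of jointly.
#' @param seed master seed; all stage seeds are derived from it.
#' @return invisible list with the fits and the report data.frame.
#' @export
runStep1 <- function(input, outDir, outcomes = c("hypo", "dep", "ins"),
                     chains = 2L, iterations = 2000L, burnin = 2000L,
                     minWeeks = 20L, requireVariation = TRUE,
                     oneAtATime = FALSE, psrThreshold = 1.1, seed = 1L) {
  run <- .openRun(outDir, list(step = 1, outcomes = outcomes, chains = chains,
                               iterations = iterations, burnin = burnin,
                               minWeeks = minWeeks,
                               requireVariation = requireVariation,
                               oneAtATime = oneAtATime), seed)
  inp <- .resolveInput(input, minWeeks, requireVariation, run$log)
  outcomes <- intersect(outcomes, processNames(inp$panel))
  seeds <- .stageSeeds(seed, 2 * length(outcomes) * 5)
  si <- 0
  rows <- list()
  fits <- list()
  conv <- logical(0)
  parClass <- function(nm) {
    if (startsWith(nm, "mu_")) "individual mean"
    else if (startsWith(nm, "lnpi_")) "innovation"
    else if (startsWith(nm, "slope_")) "slope"
    else "inertia"
  }
  for (oc in outcomes) {
    uncond <- fitDsem(inp$panel, spec = defaultDsemSpec(oc),
                      covariates = FALSE, chains = chains,
                      iterations = iterations, burnin = burnin,
                      seed = seeds[si <- si + 1], psrThreshold = psrThreshold,
                      storePerson = FALSE)
    run$log(sprintf("step1 %s unconditional: convergence %s", oc,
                    uncond@diagnostics$convergence))
    dm <- posteriorDraws(uncond)
    for (g in grep("^gamma\\.", colnames(dm), value = TRUE)) {
      s <- posteriorSummary(dm[, g])
      rows[[length(rows) + 1]] <- data.frame(
        outcome = oc, model = "unconditional", covariate = "",
        parameter = parClass(sub("^gamma\\.", "", g)),
        estimate = s["mean"], lower = s["lower"], upper = s["upper"],
        pOneTailed = oneTailedP(dm[, g]), row.names = NULL)
    }
    covSets <- if (oneAtATime) as.list(COVARIATE_NAMES) else
      list(COVARIATE_NAMES)
    for (cs in covSets) {
      cond <- fitDsem(inp$panel, spec = defaultDsemSpec(oc),
                      covariates = TRUE, covariateSet = cs,
                      chains = chains, iterations = iterations,
                      burnin = burnin, seed = seeds[si <- si + 1],
                      psrThreshold = psrThreshold, storePerson = FALSE)
      run$log(sprintf("step1 %s conditional (%s): convergence %s", oc,
                      paste(cs, collapse = "+"),
                      cond@diagnostics$convergence))
      dm <- posteriorDraws(cond)
      for (b in grep("^beta\\.", colnames(dm), value = TRUE)) {
        parts <- strsplit(sub("^beta\\.", "", b), ".", fixed = TRUE)[[1]]
        par <- paste(parts[-length(parts)], collapse = ".")
        s <- posteriorSummary(dm[, b])
        rows[[length(rows) + 1]] <- data.frame(
          outcome = oc, model = "conditional",
          covariate = parts[length(parts)], parameter = parClass(par),
          estimate = s["mean"], lower = s["lower"], upper = s["upper"],
          pOneTailed = oneTailedP(dm[, b]), row.names = NULL)
      }
      fits[[paste0(oc, ".conditional")]] <- cond
      conv <- c(conv, cond@diagnostics$convergence)
    }
    fits[[paste0(oc, ".unconditional")]] <- uncond
    conv <- c(conv, uncond@diagnostics$convergence)
  }
  report <- do.call(rbind, rows)
  .writeReport(report, file.path(outDir, "step1_univariate.csv"), conv)
  run$manifest(inp$digest, list(convergence = all(conv)))
  write.csv(inp$exclusions, file.path(outDir, "exclusions.csv"),
            row.names = FALSE)
  invisible(list(fits = fits, report = report))
}

#' Step 2: unconditional bivariate model
#'
#' Fits the bivariate model for an outcome pair, writes the full
#' random-effect correlation matrix (raw, unstandardised effects), the
#' cross-lag fixed-effect summaries, and the averaged individually
#' standardised effects.
#'
#' @inheritParams runStep1
#' @param pair the two outcomes (default depression + insomnia).
#' @return invisible list with the fit, correlation matrix and reports.
#' @export
runStep2 <- function(input, outDir, pair = c("dep", "ins"),
                     chains = 2L, iterations = 2000L, burnin = 2000L,
                     minWeeks = 20L, requireVariation = TRUE,
                     psrThreshold = 1.1, seed = 1L) {
  run <- .openRun(outDir, list(step = 2, pair = pair, chains = chains,
                               iterations = iterations, burnin = burnin),
                  seed)
  inp <- .resolveInput(input, minWeeks, requireVariation, run$log)
  fit <- fitDsem(inp$panel, spec = defaultDsemSpec(pair),
                 chains = chains, iterations = iterations, burnin = burnin,
                 seed = .stageSeeds(seed, 1), psrThreshold = psrThreshold)
  run$log(sprintf("step2 %s: convergence %s", paste(pair, collapse = "+"),
                  fit@diagnostics$convergence))
  corr <- randomEffectCorrelations(fit)
  write.csv(round(corr, 4), file.path(outDir, "step2_correlations.csv"))
  std <- averageStandardisedEffects(fit)
  run$log(sprintf("step2 non-stationary person-draw fraction: %.4f",
                  std$excludedFraction))
  dm <- posteriorDraws(fit)
  cl <- grep("^gamma\\.phi_.*", colnames(dm), value = TRUE)
  fixef <- do.call(rbind, lapply(cl, function(g) {
    s <- posteriorSummary(dm[, g])
    data.frame(parameter = sub("^gamma\\.", "", g), estimate = s["mean"],
               lower = s["lower"], upper = s["upper"],
               pOneTailed = oneTailedP(dm[, g]), row.names = NULL)
  }))
  .writeReport(fixef, file.path(outDir, "step2_crosslag_fixef.csv"),
               fit@diagnostics$convergence)
  .writeReport(std$summary, file.path(outDir, "step2_standardised.csv"),
               fit@diagnostics$convergence)
  run$manifest(inp$digest, list(convergence = fit@diagnostics$convergence))
  invisible(list(fit = fit, correlations = corr, standardised = std,
                 fixef = fixef))
}

#' Step 3: bivariate models stratified by one baseline covariate
#'
#' Splits the eligible panel on a binary covariate, refits the bivariate
#' model in each stratum, and contrasts the averaged individually
#' standardised cross-lagged effects between strata (difference, SE, 95% CI,
#' two-tailed p) in both directions.
#'
#' @inheritParams runStep2
#' @param stratifyBy one of `bd2`, `female`, `age55`, `rapid`.
#' @param minStratum smallest stratum size accepted.
#' @return invisible list with both fits and the comparison table.
#' @export
runStep3 <- function(input, outDir, pair = c("dep", "ins"), stratifyBy,
                     chains = 2L, iterations = 2000L, burnin = 2000L,
                     minWeeks = 20L, requireVariation = TRUE,
                     minStratum = 10L, psrThreshold = 1.1, seed = 1L) {
  stopifnot(stratifyBy %in% COVARIATE_NAMES)
  run <- .openRun(outDir, list(step = 3, pair = pair,
                               stratifyBy = stratifyBy, chains = chains,
                               iterations = iterations, burnin = burnin),
                  seed)
  inp <- .resolveInput(input, minWeeks, requireVariation, run$log)
  g <- covariates(inp$panel)[[stratifyBy]]
  sizes <- table(factor(g, levels = 0:1))
  if (any(sizes < minStratum))
    stop(sprintf("stratum %s=%s has only %d participants (minimum %d)",
                 stratifyBy, names(sizes)[which.min(sizes)], min(sizes),
                 minStratum))
  seeds <- .stageSeeds(seed, 2)
  fit1 <- fitDsem(inp$panel[, g == 1], spec = defaultDsemSpec(pair),
                  chains = chains, iterations = iterations, burnin = burnin,
                  seed = seeds[1], psrThreshold = psrThreshold)
  fit0 <- fitDsem(inp$panel[, g == 0], spec = defaultDsemSpec(pair),
                  chains = chains, iterations = iterations, burnin = burnin,
                  seed = seeds[2], psrThreshold = psrThreshold)
  run$log(sprintf("step3 strata %s: convergence %s / %s", stratifyBy,
                  fit1@diagnostics$convergence, fit0@diagnostics$convergence))
  effects <- c(paste0("phi_", pair[1], "_", pair[2]),
               paste0("phi_", pair[2], "_", pair[1]))
  rows <- lapply(effects, function(e) {
    cmp <- stratifiedCompare(fit1, fit0, e,
                             labels = paste0(stratifyBy, c("=1", "=0")))
    data.frame(effect = e, stratum1 = cmp$estimateA["mean"],
               stratum1SE = cmp$estimateA["se"],
               stratum0 = cmp$estimateB["mean"],
               stratum0SE = cmp$estimateB["se"],
               difference = cmp$difference, se = cmp$se,
               lower = cmp$lower, upper = cmp$upper,
               pTwoTailed = cmp$pTwoTailed, row.names = NULL)
  })
  report <- do.call(rbind, rows)
  .writeReport(report, file.path(outDir,
                                 paste0("step3_", stratifyBy, ".csv")),
               c(fit1@diagnostics$convergence, fit0@diagnostics$convergence))
  run$manifest(inp$digest,
               list(convergence = fit1@diagnostics$convergence &&
                      fit0@diagnostics$convergence))
  invisible(list(fitStratum1 = fit1, fitStratum0 = fit0, report = report))
}
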