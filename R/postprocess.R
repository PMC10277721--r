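#' Average individually standardised lag effects
#'
#' For every posterior draw, each participant's lag matrix is standardised by
#' that person's own stationary within-person standard deviations
#' ([standardisePerson()]) and the standardised coefficients are averaged
#' across participants; the per-draw averages are then summarised over draws
#' (posterior mean, equal-tailed 95% credible interval, one-tailed p). This
#' is the "average individually standardised" effect: the within-person
#' effect size in which a cross-lag is read in the context of both processes'
#' within-person variances. Person-draws whose lag matrix is non-stationary
#' are excluded from that draw's average and counted.
#'
#' @param fit a [DsemFit-class] with stored person draws.
#' @param level credible level.
#' @return list with `summary` (data.frame: effect, mean, lower, upper,
#'   pOneTailed), `draws` (pooled per-draw averages, one column per ordered
#'   pair `phi_<to>_<from>`), and `excludedFraction` (share of person-draws
#'   dropped as non-stationary).
#' @export
averageStandardisedEffects <- function(fit, level = 0.95) {
  if (length(fit@personDraws) == 0)
    stop("fit was run with storePerson = FALSE; person draws are required")
  procs <- fit@spec@processes
  p <- length(procs)
  res <- lapply(fit@personDraws, avg_std_draws, p = p, trend = fit@spec@trend)
  draws <- do.call(rbind, lapply(res, `[[`, "draws"))
  excluded <- unlist(lapply(res, `[[`, "excluded"))
  nPerson <- length(fit@participants)
  exclFrac <- sum(excluded) / (length(excluded) * nPerson)
  if (exclFrac > 0.05)
    warning(sprintf("%.1f%% of person-draws were non-stationary and excluded from the standardised averages",
                    100 * exclFrac))
  labs <- as.vector(t(outer(procs, procs,
                            function(j, k) paste0("phi_", j, "_", k))))
  colnames(draws) <- labs
  summ <- do.call(rbind, lapply(labs, function(l) {
    s <- posteriorSummary(draws[, l], level)
    data.frame(effect = l, mean = s["mean"], lower = s["lower"],
               upper = s["upper"], pOneTailed = oneTailedP(draws[, l]),
               row.names = NULL)
  }))
  list(summary = summ, draws = draws, excludedFraction = exclFrac)
}

#' Compare an averaged standardised effect across two strata
#'
#' Pairs independent posterior draws of the averaged individually
#' standardised effect from two fits of the same model on disjoint strata and
#' summarises their difference: estimate, standard error (SD of the
#' difference draws), equal-tailed CI, and the two-tailed posterior p-value
#' `2 min(P(diff > 0), P(diff < 0))`.
#'
#' @param fitA,fitB [DsemFit-class] objects with identical specifications
#'   fitted on disjoint strata.
#' @param effect ordered-pair label, e.g. `"phi_ins_dep"` (effect of lagged
#'   depression on insomnia).
#' @param labels stratum labels for reporting.
#' @param level credible level.
#' @return list with per-stratum summaries (`estimateA`, `estimateB`: mean,
#'   se, lower, upper), `difference` (A minus B), `se`, `lower`, `upper`,
#'   `pTwoTailed`, and the labels.
#' @export
stratifiedCompare <- function(fitA, fitB, effect,
                              labels = c("A", "B"), level = 0.95) {
  if (!identical(fitA@spec@processes, fitB@spec@processes) ||
      !identical(fitA@spec@trend, fitB@spec@trend))
    stop("the two fits must share one model specification")
  dA <- averageStandardisedEffects(fitA, level)$draws
  dB <- averageStandardisedEffects(fitB, level)$draws
  if (!effect %in% colnames(dA))
    stop("unknown effect '", effect, "'; available: ",
         paste(colnames(dA), collapse = ", "))
  k <- min(nrow(dA), nrow(dB))
  a <- dA[seq_len(k), effect]
  b <- dB[seq_len(k), effect]
  delta <- a - b
  strat <- function(x) {
    s <- posteriorSummary(x, level)
    c(mean = unname(s["mean"]), se = sd(x), lower = unname(s["lower"]),
      upper = unname(s["upper"]))
  }
  qs <- quantile(delta, c((1 - level) / 2, 1 - (1 - level) / 2), names = FALSE)
  list(effect = effect, labels = labels,
       estimateA = strat(a), estimateB = strat(b),
       difference = mean(delta), se = sd(delta),
       lower = qs[1], upper = qs[2],
       pTwoTailed = min(1, 2 * min(mean(delta >= 0), mean(delta <= 0))))
}
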