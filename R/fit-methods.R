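#' @describeIn DsemFit pooled posterior draws, or per-chain when
#'   `pooled = FALSE`.
#' @param fit a `DsemFit`.
#' @param pooled logical; row-bind the chains.
#' @export
posteriorDraws <- function(fit, pooled = TRUE) {
  if (pooled) do.call(rbind, fit@draws) else fit@draws
}

#' @describeIn DsemFit person-level draws: list (per chain) of
#'   parameter x participant x iteration arrays.
#' @export
personDraws <- function(fit) fit@personDraws

#' @describeIn DsemFit sampler diagnostics (per-parameter PSR, effective
#'   sample sizes, convergence flag).
#' @export
convergenceDiagnostics <- function(fit) fit@diagnostics

setMethod("show", "DsemFit", function(object) {
  cat(sprintf("DsemFit: %s model (%s), %d participants\n",
              if (length(object@spec@processes) == 1) "univariate"
              else "bivariate",
              paste(object@spec@processes, collapse = " + "),
              length(object@participants)))
  cat(sprintf("%d chain(s) x %d iterations (burn-in %d), seed %d\n",
              object@chains, object@iterations, object@burnin, object@seed))
  if (length(object@covariateNames))
    cat("covariates:", paste(object@covariateNames, collapse = ", "), "\n")
  dg <- object@diagnostics
  cat(sprintf("convergence: %s (max PSR %s, threshold %.2f)\n",
              if (isTRUE(dg$convergence)) "yes"
              else if (isFALSE(dg$convergence)) "NO" else "not assessed",
              if (all(is.na(dg$psr))) "NA"
              else sprintf("%.3f", max(dg$psr, na.rm = TRUE)),
              dg$threshold))
  g <- grep("^gamma\\.", colnames(posteriorDraws(object)), value = TRUE)
  summ <- t(vapply(g, function(j) posteriorSummary(posteriorDraws(object)[, j]),
                   numeric(4)))
  print(round(summ, 3))
})

#' Posterior correlations between the random effects
#'
#' The posterior mean of the correlation matrix implied by each draw of the
#' between-person covariance `Omega` — correlations between the raw
#' (unstandardised) person-level effects of a bivariate model.
#'
#' @param fit a bivariate [DsemFit-class].
#' @return symmetric correlation matrix with unit diagonal, dimnames =
#'   parameter names.
#' @export
randomEffectCorrelations <- function(fit) {
  if (length(fit@spec@processes) < 2)
    stop("random-effect correlations between processes need a bivariate fit")
  dm <- posteriorDraws(fit)
  oc <- grep("^omega\\.", colnames(dm))
  nm <- dsemParamNames(fit@spec@processes, fit@spec@trend)
  d <- length(nm)
  acc <- matrix(0, d, d)
  for (r in seq_len(nrow(dm)))
    acc <- acc + cov2cor(matrix(dm[r, oc], d, d))
  out <- acc / nrow(dm)
  out <- (out + t(out)) / 2
  diag(out) <- 1
  dimnames(out) <- list(nm, nm)
  out
}

#' Persist a fit to disk
#'
#' Writes the pooled draws as a columnar CSV (one row per chain x iteration,
#' one column per parameter), a JSON sidecar naming the parameters and the
#' chain structure, and the diagnostics as JSON.
#'
#' @param fit a [DsemFit-class].
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return the directory, invisibly.
#' @export
writeFit <- function(fit, dir, prefix = "fit") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dm <- posteriorDraws(fit)
  write.csv(as.data.frame(dm), file.path(dir, paste0(prefix, "_draws.csv")),
            row.names = FALSE)
  jsonlite::write_json(list(
    parameters = colnames(dm), chains = fit@chains,
    iterations = fit@iterations, burnin = fit@burnin, seed = fit@seed,
    processes = fit@spec@processes, covariates = fit@covariateNames),
    file.path(dir, paste0(prefix, "_draws.json")), auto_unbox = TRUE)
  jsonlite::write_json(
    list(psr = as.list(fit@diagnostics$psr),
         ess = as.list(fit@diagnostics$ess),
         convergence = fit@diagnostics$convergence,
         accept = fit@accept),
    file.path(dir, paste0(prefix, "_diagnostics.json")),
    auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
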