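#' Create a DSEM parameterisation
#'
#' @param processes character vector of process labels (1 or 2 of `"dep"`,
#'   `"ins"`, `"hypo"`).
#' @param gamma named fixed-effect vector over [dsemParamNames()].
#' @param B covariate coefficient matrix (d x 4, columns `bd2`, `female`,
#'   `age55`, `rapid`); defaults to zero.
#' @param Omega random-effect covariance (d x d, symmetric PSD).
#' @param trend logical; model random linear slopes.
#' @return a validated [DsemSpec-class].
#' @export
dsemSpec <- function(processes, gamma, Omega, B = NULL, trend = TRUE) {
  nm <- dsemParamNames(processes, trend)
  d <- length(nm)
  gamma <- gamma[nm]
  names(gamma) <- nm
  if (is.null(B)) B <- matrix(0, d, 4)
  dimnames(B) <- list(nm, COVARIATE_NAMES)
  dimnames(Omega) <- list(nm, nm)
  methods::new("DsemSpec", processes = processes, gamma = gamma,
               B = B, Omega = Omega, trend = trend)
}

# per-process default calibration: population fixed effects and random-effect
# SDs emulating a large weekly mood-monitoring cohort of adults with bipolar
# disorder (individual means, their variances and the inertias are the
# cohort-level estimates; the remaining entries are documented package
# defaults chosen to be realistic and stationary)
.processDefaults <- data.frame(
  row.names = c("dep", "ins", "hypo"),
  mu = c(7.33, 3.29, 1.98),
  phi = c(0.47, 0.36, 0.40),
  lnpi = c(1.8, 0.4, 0.4),
  slope = c(-0.005, -0.005, -0.005),
  sdMu = sqrt(c(21.10, 3.71, 1.96)),
  sdPhi = c(0.15, 0.15, 0.15),
  sdLnpi = c(0.5, 0.5, 0.5),
  sdSlope = c(0.005, 0.005, 0.005))

.defaultCrossLag <- 0.02
.defaultSdCrossLag <- 0.10

#' Default calibrated DSEM specification
#'
#' Returns a [DsemSpec-class] whose individual-mean levels, individual-mean
#' variances and inertias match cohort-level estimates from weekly mood
#' monitoring of adults with bipolar disorder (depression scored 0-27,
#' insomnia 0-9, (hypo)mania 0-16), and whose remaining entries are documented
#' defaults: log innovation-variance means of 1.8 (depression) and 0.4
#' (insomnia, (hypo)mania), cross-lag means of 0.02, a slope mean of -0.005
#' points/week, random-effect SDs of 0.15 (inertia), 0.10 (cross-lag), 0.5
#' (log innovation variance) and 0.005 (slope), and a diagonal `Omega`.
#'
#' @param processes which processes to include (default the
#'   depression-insomnia pair).
#' @param trend logical; include random linear slopes.
#' @return a [DsemSpec-class].
#' @export
defaultDsemSpec <- function(processes = c("dep", "ins"), trend = TRUE) {
  stopifnot(all(processes %in% rownames(.processDefaults)))
  p <- length(processes)
  pd <- .processDefaults[processes, ]
  nm <- dsemParamNames(processes, trend)
  gamma <- setNames(numeric(length(nm)), nm)
  sdv <- setNames(numeric(length(nm)), nm)
  for (j in seq_len(p)) {
    pr <- processes[j]
    gamma[paste0("mu_", pr)] <- pd$mu[j]
    gamma[paste0("phi_", pr, "_", pr)] <- pd$phi[j]
    gamma[paste0("lnpi_", pr)] <- pd$lnpi[j]
    sdv[paste0("mu_", pr)] <- pd$sdMu[j]
    sdv[paste0("phi_", pr, "_", pr)] <- pd$sdPhi[j]
    sdv[paste0("lnpi_", pr)] <- pd$sdLnpi[j]
    if (trend) {
      gamma[paste0("slope_", pr)] <- pd$slope[j]
      sdv[paste0("slope_", pr)] <- pd$sdSlope[j]
    }
    for (k in seq_len(p)) if (k != j) {
      gamma[paste0("phi_", pr, "_", processes[k])] <- .defaultCrossLag
      sdv[paste0("phi_", pr, "_", processes[k])] <- .defaultSdCrossLag
    }
  }
  dsemSpec(processes, gamma, Omega = diag(sdv^2), trend = trend)
}

#' Set one between-person correlation in a specification
#'
#' Replaces the `Omega` entry for a pair of random effects by
#' `rho * sd1 * sd2`, keeping the variances fixed.
#'
#' @param spec a [DsemSpec-class].
#' @param par1,par2 parameter names (see [dsemParamNames()]).
#' @param rho correlation in `[-1, 1]`.
#' @return the modified, revalidated spec.
#' @export
setSpecCorrelation <- function(spec, par1, par2, rho) {
  stopifnot(abs(rho) <= 1)
  O <- spec@Omega
  stopifnot(par1 %in% rownames(O), par2 %in% rownames(O))
  O[par1, par2] <- O[par2, par1] <- rho * sqrt(O[par1, par1] * O[par2, par2])
  dsemSpec(spec@processes, spec@gamma, Omega = O, B = spec@B,
           trend = spec@trend)
}

#' Validate a DSEM specification
#'
#' Re-runs all class invariants (dimensions and naming, `Omega` symmetric
#' positive semidefinite, mean lag matrix stationary) and fails with a message
#' naming every violated invariant.
#'
#' @param spec a [DsemSpec-class].
#' @return the spec, invisibly, if valid.
#' @export
validateSpec <- function(spec) {
  methods::validObject(spec)
  invisible(spec)
}

setMethod("show", "DsemSpec", function(object) {
  cat(sprintf("DsemSpec: %s model (%s)%s\n",
              if (length(object@processes) == 1) "univariate" else "bivariate",
              paste(object@processes, collapse = " + "),
              if (object@trend) " with random linear trend" else ""))
  cat("fixed effects:\n")
  print(round(object@gamma, 4))
  cat("random-effect SDs:\n")
  print(round(sqrt(diag(object@Omega)), 4))
  if (any(object@B != 0)) {
    cat("covariate coefficients:\n")
    print(round(object@B, 4))
  }
})

#' Serialise a DSEM specification to structured text
#'
#' Writes the spec as a YAML document (key/value with nested sections) so the
#' generator and the fitter can share one format; [readDsemSpec()] inverts it.
#'
#' @param spec a [DsemSpec-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeDsemSpec <- function(spec, path) {
  yaml::write_yaml(list(
    processes = as.list(spec@processes), trend = spec@trend,
    gamma = as.list(spec@gamma),
    B = lapply(seq_len(ncol(spec@B)),
               function(j) as.list(setNames(spec@B[, j], rownames(spec@B)))) |>
      setNames(colnames(spec@B)),
    Omega = apply(spec@Omega, 1, as.list, simplify = FALSE)), path)
  invisible(path)
}

#' @rdname writeDsemSpec
#' @export
readDsemSpec <- function(path) {
  x <- yaml::read_yaml(path)
  processes <- unlist(x$processes)
  nm <- dsemParamNames(processes, x$trend)
  gamma <- unlist(x$gamma)[nm]
  B <- sapply(COVARIATE_NAMES, function(v) unlist(x$B[[v]])[nm])
  Omega <- t(sapply(nm, function(r) unlist(x$Omega[[r]])[nm]))
  Omega <- (Omega + t(Omega)) / 2
  dsemSpec(processes, gamma, Omega = Omega, B = B, trend = x$trend)
}
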