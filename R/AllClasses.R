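#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   assayNames colData rowData
#' @importFrom S4Vectors DataFrame
#' @importFrom stats rnorm rbinom runif plogis qlogis quantile sd var median
#'   setNames complete.cases rchisq cov cov2cor coef lm glm binomial uniroot
#'   acf
#' @importFrom utils read.csv write.csv packageVersion
#' @useDynLib mooddsem, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

COVARIATE_NAMES <- c("bd2", "female", "age55", "rapid")
PROCESS_BOUNDS <- list(dep = c(0L, 27L), ins = c(0L, 9L), hypo = c(0L, 16L))

#' Canonical parameter names of a dynamic structural equation model
#'
#' Person-level parameters are stacked in a fixed order: individual means
#' `mu_<j>`, lag coefficients `phi_<j>_<k>` (effect of process `k` at week
#' t-1 on process `j` at week t, row-major), log innovation variances
#' `lnpi_<j>`, and, when a linear trend is modelled, slopes `slope_<j>`.
#'
#' @param processes character vector of process labels (length 1 or 2).
#' @param trend logical; include random linear slopes?
#' @return character vector of parameter names.
#' @export
dsemParamNames <- function(processes, trend = TRUE) {
  p <- length(processes)
  phi <- as.vector(t(outer(processes, processes,
                           function(j, k) paste0("phi_", j, "_", k))))
  nm <- c(paste0("mu_", processes), phi, paste0("lnpi_", processes))
  if (trend) nm <- c(nm, paste0("slope_", processes))
  nm
}

# index helpers into the canonical parameter vector
.paramIndex <- function(p, trend) {
  d <- 2L * p + p * p + if (trend) p else 0L
  list(d = d,
       mu = seq_len(p),
       phi = p + seq_len(p * p),
       lnpi = p + p * p + seq_len(p),
       slope = if (trend) 2L * p + p * p + seq_len(p) else integer(0))
}

#' Model parameterisation for a univariate or bivariate DSEM
#'
#' Describes the generative multilevel vector-autoregressive model of weekly
#' symptom scores: fixed effects `gamma` (population means of the person-level
#' parameters), covariate coefficients `B` (one column per baseline covariate),
#' and the between-person random-effect covariance `Omega`, all over the
#' canonical parameter vector of [dsemParamNames()].
#'
#' @slot processes character vector of process labels (1 or 2 of
#'   `"dep"`, `"ins"`, `"hypo"`).
#' @slot gamma named numeric vector of fixed effects.
#' @slot B numeric matrix of covariate coefficients (rows = parameters,
#'   columns = covariates `bd2`, `female`, `age55`, `rapid`).
#' @slot Omega symmetric positive semidefinite random-effect covariance.
#' @slot trend logical; random linear slopes included.
#' @export
setClass("DsemSpec",
         representation(processes = "character", gamma = "numeric",
                        B = "matrix", Omega = "matrix", trend = "logical"))

setValidity("DsemSpec", function(object) {
  msg <- character(0)
  p <- length(object@processes)
  if (!p %in% 1:2)
    msg <- c(msg, "'processes' must have length 1 or 2")
  if (anyDuplicated(object@processes))
    msg <- c(msg, "duplicate process labels")
  nm <- dsemParamNames(object@processes, object@trend)
  d <- length(nm)
  if (length(object@gamma) != d || !identical(names(object@gamma), nm))
    msg <- c(msg, sprintf("'gamma' must be named %s", paste(nm, collapse = ", ")))
  if (!identical(dim(object@B), c(d, 4L)))
    msg <- c(msg, "'B' must be a d x 4 matrix (bd2, female, age55, rapid)")
  if (!identical(dim(object@Omega), c(d, d)))
    msg <- c(msg, "'Omega' must be d x d")
  else {
    if (max(abs(object@Omega - t(object@Omega))) > 1e-8)
      msg <- c(msg, "'Omega' must be symmetric")
    else {
      ev <- eigen(object@Omega, symmetric = TRUE, only.values = TRUE)$values
      if (min(ev) < -1e-8 * max(abs(ev), 1))
        msg <- c(msg, sprintf("'Omega' has a negative eigenvalue (%.3g)", min(ev)))
    }
  }
  if (length(msg) == 0 && p >= 1) {
    idx <- .paramIndex(p, object@trend)
    Phi <- matrix(object@gamma[idx$phi], p, p, byrow = TRUE)
    if (max(Mod(eigen(Phi, only.values = TRUE)$values)) >= 1)
      msg <- c(msg, "mean lag matrix is non-stationary (spectral radius >= 1)")
  }
  if (length(msg)) msg else TRUE
})

#' Weekly symptom panel
#'
#' A [SummarizedExperiment::SummarizedExperiment] holding weekly symptom
#' scores on a common 1..T grid: rows are calendar weeks, columns are
#' participants, assays are the scored outcomes (`dep`, `ins`, `hypo`; any
#' non-empty subset), `colData` carries the four binary baseline covariates
#' and `rowData` the week index. Missing weeks are explicit `NA` cells.
#'
#' @export
setClass("MoodPanel", contains = "SummarizedExperiment")

setValidity("MoodPanel", function(object) {
  msg <- character(0)
  an <- SummarizedExperiment::assayNames(object)
  if (length(an) == 0 || !all(an %in% names(PROCESS_BOUNDS)))
    msg <- c(msg, "assays must be a non-empty subset of dep, ins, hypo")
  rd <- SummarizedExperiment::rowData(object)
  if (!"week" %in% colnames(rd))
    msg <- c(msg, "rowData must contain a 'week' column")
  else if (nrow(object) && !identical(as.integer(rd$week), seq_len(nrow(object))))
    msg <- c(msg, "week grid must be the consecutive integers 1..T")
  cd <- SummarizedExperiment::colData(object)
  miss <- setdiff(COVARIATE_NAMES, colnames(cd))
  if (length(miss))
    msg <- c(msg, paste("missing covariate columns:", paste(miss, collapse = ", ")))
  else {
    for (v in COVARIATE_NAMES)
      if (!all(cd[[v]] %in% c(0L, 1L)))
        msg <- c(msg, sprintf("covariate '%s' must be binary 0/1", v))
  }
  if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
    msg <- c(msg, "participant ids (colnames) must be unique and non-NULL")
  if (length(msg)) msg else TRUE
})

#' Configuration of the synthetic panel generator
#'
#' @slot spec a [DsemSpec-class] defining the generative model.
#' @slot n integer; number of participants (>= 2).
#' @slot nWeeks integer; grid length T (>= 3).
#' @slot prevalence named numeric; Bernoulli prevalences of the four binary
#'   baseline covariates.
#' @slot missingness one of `"none"`, `"mcar"`, `"mar"` (missingness
#'   probability a logistic function of the most recent observed score of the
#'   first process).
#' @slot rate target marginal missingness rate in `[0, 1)`.
#' @slot marSlope logistic slope per score point for the MAR mechanism.
#' @slot discretise logical; round and clip scores to their scale bounds.
#' @slot seed integer seed.
#' @export
setClass("GeneratorConfig",
         representation(spec = "DsemSpec", n = "integer", nWeeks = "integer",
                        prevalence = "numeric", missingness = "character",
                        rate = "numeric", marSlope = "numeric",
                        discretise = "logical", seed = "integer"))

setValidity("GeneratorConfig", function(object) {
  msg <- character(0)
  if (object@n < 2L) msg <- c(msg, "n must be >= 2")
  if (object@nWeeks < 3L) msg <- c(msg, "nWeeks must be >= 3")
  if (!identical(sort(names(object@prevalence)), sort(COVARIATE_NAMES)) ||
      any(object@prevalence < 0 | object@prevalence > 1))
    msg <- c(msg, "prevalence must name bd2, female, age55, rapid with values in [0,1]")
  if (!object@missingness %in% c("none", "mcar", "mar"))
    msg <- c(msg, "unknown missingness mechanism")
  if (object@rate < 0 || object@rate >= 1)
    msg <- c(msg, "rate must be in [0, 1)")
  if (length(msg)) msg else TRUE
})

#' Posterior sample from a fitted DSEM
#'
#' Holds per-chain posterior draws of the fixed effects, covariate
#' coefficients, random-effect covariance and every participant's person-level
#' parameters, together with sampler diagnostics and fit metadata.
#'
#' @slot spec the [DsemSpec-class] template that was fitted.
#' @slot draws list (one per chain) of iterations x parameter matrices for
#'   `gamma.*`, `beta.*` and `omega.*` parameters.
#' @slot personDraws list (one per chain) of d x n x iterations arrays of
#'   person-level parameter draws.
#' @slot participants character vector of participant ids (length n).
#' @slot covariateNames character; covariates entered in the model (may be
#'   empty).
#' @slot diagnostics list with per-parameter potential scale reduction,
#'   effective sample sizes and a convergence flag.
#' @slot accept list of sampler acceptance/rejection summaries.
#' @slot seed,chains,iterations,burnin sampler settings.
#' @export
setClass("DsemFit",
         representation(spec = "DsemSpec", draws = "list", personDraws = "list",
                        participants = "character", covariateNames = "character",
                        diagnostics = "list", accept = "list", seed = "integer",
                        chains = "integer", iterations = "integer",
                        burnin = "integer"))
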