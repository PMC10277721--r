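## Bayesian estimation of the univariate/bivariate DSEM.
##
## Sampler: Metropolis-within-Gibbs (compiled core). Conjugate normal
## updates for person means/slopes, lag coefficients (Metropolis-corrected
## for the stationary initial-condition prior, non-stationary proposals
## discarded), the fixed effects gamma and covariate coefficients B;
## adaptive random-walk Metropolis on each person's log innovation
## variances; inverse-Wishart for Omega; missing weeks and the pre-study
## deviation drawn from their full conditionals each sweep.

.panelCube <- function(panel, processes) {
  T <- nrow(panel); n <- ncol(panel)
  Y <- array(NA_real_, c(length(processes), T, n))
  for (j in seq_along(processes))
    Y[j, , ] <- scoreMatrix(panel, processes[j])
  Y
}

# crude per-person moment estimates: per-process OLS detrending, then a
# lagged regression of each process on all lagged processes (complete pairs
# only); used for chain starting values and for the empirical prior scale
.crudeEffects <- function(Y, trend) {
  p <- dim(Y)[1]; T <- dim(Y)[2]; n <- dim(Y)[3]
  idx <- .paramIndex(p, trend)
  eta <- matrix(0, idx$d, n)
  ct <- seq_len(T) - (T + 1) / 2
  for (i in seq_len(n)) {
    R <- matrix(NA_real_, p, T)
    for (j in seq_len(p)) {
      x <- Y[j, , i]
      obs <- !is.na(x)
      if (trend && sum(obs) > 4) {
        cf <- coef(lm(x[obs] ~ ct[obs]))
        eta[idx$mu[j], i] <- cf[1]
        eta[idx$slope[j], i] <- cf[2]
        R[j, obs] <- x[obs] - cf[1] - cf[2] * ct[obs]
      } else {
        eta[idx$mu[j], i] <- mean(x[obs])
        R[j, obs] <- x[obs] - mean(x[obs])
      }
    }
    pair <- which(colSums(is.na(R[, -1, drop = FALSE])) +
                    colSums(is.na(R[, -T, drop = FALSE])) == 0)
    for (j in seq_len(p)) {
      ok <- length(pair) > p + 2
      cf <- if (ok)
        tryCatch(coef(lm(R[j, pair + 1] ~ t(R[, pair, drop = FALSE]) - 1)),
                 error = function(e) NULL)
      else NULL
      if (is.null(cf) || anyNA(cf)) cf <- rep(0.1, p)
      eta[idx$phi[(j - 1) * p + seq_len(p)], i] <- cf
      res <- if (ok) R[j, pair + 1] - as.vector(cf %*% R[, pair, drop = FALSE])
             else R[j, !is.na(R[j, ])]
      eta[idx$lnpi[j], i] <- log(max(var(res), 0.02))
    }
    Phi <- matrix(eta[idx$phi, i], p, p, byrow = TRUE)
    rho <- max(Mod(eigen(Phi, only.values = TRUE)$values))
    if (rho >= 0.95) eta[idx$phi, i] <- eta[idx$phi, i] * 0.9 / rho
  }
  eta
}

# chain starting values: jittered crude estimates
.initChain <- function(crude, p, trend, jitter = 0.1) {
  idx <- .paramIndex(p, trend)
  eta <- crude + jitter * matrix(rnorm(length(crude)), nrow(crude)) *
    c(rep(1, p), rep(0.3, p * p), rep(0.3, p), rep(0.01, length(idx$slope)))
  for (i in seq_len(ncol(eta))) {
    Phi <- matrix(eta[idx$phi, i], p, p, byrow = TRUE)
    rho <- max(Mod(eigen(Phi, only.values = TRUE)$values))
    if (rho >= 0.95) eta[idx$phi, i] <- eta[idx$phi, i] * 0.9 / rho
  }
  gamma <- rowMeans(eta)
  Omega <- cov(t(eta)) + diag(0.02, idx$d)
  list(eta = eta, gamma = gamma, Omega = Omega)
}

#' Fit a dynamic structural equation model to a weekly panel
#'
#' Estimates the multilevel AR(1) model with person-specific means, lag
#' coefficients (inertias and, in the bivariate case, cross-lagged effects),
#' log innovation variances and optional linear slopes, by Markov chain Monte
#' Carlo. Missing weeks are imputed by data augmentation each sweep. When
#' `covariates = TRUE` the four baseline covariates enter jointly as
#' predictors of every random effect; `covariateSet` restricts to a subset
#' (e.g. one at a time).
#'
#' Priors: `gamma` entries Normal(0, 1e4) except log innovation-variance
#' means Normal(0, 10); `B` entries Normal(0, 1e4). For `Omega` the default
#' is a weakly informative inverse-Wishart IW(diag(v), d + 2) whose diagonal
#' scale `v` is the empirical variance of crude per-person moment estimates —
#' one pseudo-observation anchoring each variance at a data-driven magnitude.
#' The scale of this prior matters: a near-zero scale matrix favours singular
#' `Omega` and pushes weakly identified random-effect correlations towards
#' +-1, while a unit scale is orders of magnitude off for several components
#' and shrinks their correlations towards 0. `omegaPrior = "flat"` gives the
#' improper flat prior IW(0, -(d+1)) instead (proper posterior for
#' n > 2d + 2 participants).
#'
#' @param panel a [MoodPanel-class] (already filtered with
#'   [applyEligibility()]).
#' @param spec a [DsemSpec-class] template naming the processes and trend
#'   flag, or `NULL` to build one from `processes`.
#' @param processes outcome(s) to model when `spec` is `NULL`.
#' @param covariates logical; regress the random effects on the baseline
#'   covariates.
#' @param covariateSet covariate names entered when `covariates = TRUE`
#'   (default all four jointly).
#' @param chains,iterations,burnin MCMC settings (defaults 2 chains of 2000
#'   kept iterations after 2000 burn-in).
#' @param seed integer master seed; identical inputs and seed give
#'   bit-identical draws.
#' @param psrThreshold convergence threshold for the potential scale
#'   reduction (default 1.1).
#' @param storePerson keep person-level draws (needed for standardised
#'   effects).
#' @param omegaPrior `"empirical"` (default), `"flat"`, or a list with
#'   elements `scale` (diagonal of the inverse-Wishart scale matrix; scalar
#'   or length-d vector) and `df`.
#' @return a [DsemFit-class]. If any parameter's PSR exceeds the threshold
#'   the fit is returned with `convergence = FALSE` and a warning.
#' @export
fitDsem <- function(panel, spec = NULL, processes = c("dep", "ins"),
                    covariates = FALSE, covariateSet = COVARIATE_NAMES,
                    chains = 2L, iterations = 2000L, burnin = 2000L,
                    seed = 1L, psrThreshold = 1.1, storePerson = TRUE,
                    omegaPrior = "empirical") {
  if (is.null(spec)) spec <- defaultDsemSpec(processes)
  processes <- spec@processes
  trend <- spec@trend
  p <- length(processes)
  stopifnot(all(processes %in% processNames(panel)), chains >= 1)
  n <- ncol(panel)
  if (n < 2)
    stop("the hierarchical model needs at least 2 participants")
  Y <- .panelCube(panel, processes)
  nObs <- apply(!is.na(Y), 3, function(m) min(rowSums(m)))
  if (any(nObs < 3))
    stop(sprintf("%d participant(s) have fewer than 3 non-missing weeks on a modelled outcome; apply eligibility filtering first",
                 sum(nObs < 3)))
  covariateSet <- if (covariates) intersect(COVARIATE_NAMES, covariateSet)
                  else character(0)
  cd <- as.data.frame(SummarizedExperiment::colData(panel))
  X <- if (length(covariateSet))
    t(as.matrix(cd[, covariateSet, drop = FALSE]))
  else matrix(0, 0, n)
  idx <- .paramIndex(p, trend)
  nm <- dsemParamNames(processes, trend)
  crude <- .crudeEffects(Y, trend)
  if (identical(omegaPrior, "empirical")) {
    omegaS0 <- pmax(apply(crude, 1, var), 1e-8)
    omegaDf <- idx$d + 2
  } else if (identical(omegaPrior, "flat")) {
    omegaS0 <- rep(0, idx$d)
    omegaDf <- -(idx$d + 1)
  } else {
    omegaS0 <- rep_len(omegaPrior$scale, idx$d)
    omegaDf <- omegaPrior$df
  }
  # posterior df must exceed d + 1 for a proper posterior with finite mean
  if (omegaDf + n < idx$d + 2)
    stop(sprintf("the Omega posterior needs at least %d participants under this prior",
                 idx$d + 2 - omegaDf))

  set.seed(seed)
  chainSeeds <- sample.int(.Machine$integer.max - 1L, chains)
  draws <- vector("list", chains)
  personDraws <- vector("list", chains)
  accept <- list()
  for (ch in seq_len(chains)) {
    set.seed(chainSeeds[ch])
    init <- .initChain(crude, p, trend)
    res <- dsem_mcmc(Y, X, trend, as.integer(iterations), as.integer(burnin),
                     init$eta, init$gamma,
                     matrix(0, idx$d, nrow(X)), init$Omega,
                     1e4, 10, 1e4, omegaS0, omegaDf, storePerson)
    gnames <- paste0("gamma.", nm)
    onames <- as.vector(outer(nm, nm, function(a, b) paste0("omega.", a, ".", b)))
    dm <- cbind(res$gamma, res$Omega)
    colnames(dm) <- c(gnames, onames)
    if (nrow(X) > 0) {
      bnames <- as.vector(outer(nm, rownames(X),
                                function(a, b) paste0("beta.", a, ".", b)))
      bm <- res$B
      colnames(bm) <- bnames
      dm <- cbind(dm, bm)
    }
    draws[[ch]] <- dm
    if (storePerson) {
      dimnames(res$person) <- list(nm, participantIds(panel), NULL)
      personDraws[[ch]] <- res$person
    }
    accept[[ch]] <- list(lnpi = res$acceptLnpi,
                         phiNonstationaryRate = res$phiRejectRate,
                         phiAccept = res$phiAcceptRate,
                         nonstatPerSweep = mean(res$nonstat))
  }
  pars <- colnames(draws[[1]])
  psrv <- if (chains >= 2)
    vapply(pars, function(j)
      psr(lapply(draws, function(m) m[, j])), numeric(1))
  else setNames(rep(NA_real_, length(pars)), pars)
  essv <- vapply(pars, function(j)
    effectiveSize(unlist(lapply(draws, function(m) m[, j]))), numeric(1))
  conv <- if (chains >= 2) all(is.finite(psrv) & psrv < psrThreshold) else NA
  if (isFALSE(conv))
    warning(sprintf("convergence not reached: %d parameter(s) with PSR >= %.2f (max %.3f)",
                    sum(!(is.finite(psrv) & psrv < psrThreshold)),
                    psrThreshold, max(psrv, na.rm = TRUE)))
  methods::new("DsemFit", spec = spec, draws = draws,
               personDraws = personDraws,
               participants = participantIds(panel),
               covariateNames = covariateSet,
               diagnostics = list(psr = psrv, ess = essv,
                                  convergence = conv,
                                  threshold = psrThreshold),
               accept = accept, seed = as.integer(seed),
               chains = as.integer(chains),
               iterations = as.integer(iterations),
               burnin = as.integer(burnin))
}
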