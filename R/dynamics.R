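## Model mathematics: latent decomposition, within-person AR(1) dynamics,
## stationary covariance, per-person standardisation.
##
## Observation model for person i, process j, week t on a 1..T grid:
##   Y_ijt = mu_ij + s_ij * (t - tbar) + y_ijt,        tbar = (T + 1) / 2
##   y_ijt = sum_k phi_jk,i * y_ik,t-1 + e_ijt,        e_ijt ~ N(0, pi_ij)
## The trend is centred at the grid midpoint so the individual mean keeps its
## interpretation as the mid-study stable level.

.effectsParts <- function(effects, processes, trend = TRUE) {
  p <- length(processes)
  nm <- dsemParamNames(processes, trend)
  if (!is.null(names(effects))) effects <- effects[nm]
  if (length(effects) != length(nm) || anyNA(effects))
    stop("person effects must supply the parameters ",
         paste(nm, collapse = ", "))
  idx <- .paramIndex(p, trend)
  list(mu = unname(effects[idx$mu]),
       Phi = matrix(effects[idx$phi], p, p, byrow = TRUE),
       pi = exp(unname(effects[idx$lnpi])),
       slope = if (trend) unname(effects[idx$slope]) else numeric(p))
}

#' One step of the within-person dynamics
#'
#' Advances a participant's latent deviations one week and assembles the
#' observed scores: the new deviation is `Phi %*% prevDeviation + shock` and
#' the observation adds the individual mean and the centred linear trend.
#'
#' @param effects named person-level parameter vector (see
#'   [dsemParamNames()]).
#' @param processes process labels defining the parameter layout.
#' @param prevDeviation numeric vector of last week's deviations (length p).
#' @param shock numeric vector of this week's innovations (length p).
#' @param week integer week index t.
#' @param nWeeks grid length T (sets the trend centre `(T+1)/2`).
#' @param trend logical; include the linear trend term.
#' @return list with `deviation` (new latent deviation) and `observation`
#'   (scores Y at week t).
#' @export
advanceDynamics <- function(effects, processes, prevDeviation, shock,
                            week, nWeeks, trend = TRUE) {
  pe <- .effectsParts(effects, processes, trend)
  p <- length(processes)
  if (length(prevDeviation) != p || length(shock) != p)
    stop(sprintf("deviation and shock must have length %d (processes: %s)",
                 p, paste(processes, collapse = ", ")))
  dev <- as.vector(pe$Phi %*% prevDeviation) + shock
  obs <- pe$mu + pe$slope * (week - (nWeeks + 1) / 2) + dev
  list(deviation = setNames(dev, processes),
       observation = setNames(obs, processes))
}

#' Stationary within-person covariance of the AR(1) process
#'
#' Solves the discrete Lyapunov equation `Sigma = Phi Sigma Phi' + Psi` for
#' the stationary covariance of the latent deviations, via the vectorised
#' linear system `(I - Phi (x) Phi) vec(Sigma) = vec(Psi)`.
#'
#' @param Phi person lag matrix (p x p), spectral radius < 1.
#' @param Psi innovation covariance (diagonal positive, or a positive vector
#'   of innovation variances).
#' @return symmetric positive-definite p x p matrix.
#' @export
stationaryCovariance <- function(Phi, Psi) {
  Phi <- as.matrix(Phi)
  p <- nrow(Phi)
  if (is.vector(Psi) || length(Psi) == p) Psi <- diag(as.numeric(Psi), p)
  if (any(diag(Psi) <= 0)) stop("innovation variances must be positive")
  rho <- max(Mod(eigen(Phi, only.values = TRUE)$values))
  if (rho >= 1)
    stop(sprintf("non-stationary lag matrix: spectral radius %.4f >= 1", rho))
  S <- matrix(solve(diag(p * p) - kronecker(Phi, Phi), as.vector(Psi)), p, p)
  (S + t(S)) / 2
}

#' Person-level standardised lag matrix
#'
#' Standardises a participant's lag coefficients by that person's stationary
#' within-person standard deviations: `phi*_jk = phi_jk * sigma_k / sigma_j`,
#' with `sigma` from [stationaryCovariance()] of the person's own `(Phi, Psi)`
#' (deviations exclude the trend, so the trend never enters). The univariate
#' standardised inertia equals the raw inertia.
#'
#' @param effects named person-level parameter vector, or `NULL` when `Phi`
#'   and `psi` are given directly.
#' @param processes process labels.
#' @param Phi,psi alternative direct interface: lag matrix and innovation
#'   variances.
#' @param trend logical; layout of `effects`.
#' @return p x p matrix of standardised lag coefficients (dimnames = process
#'   labels; entry `[j, k]` is the standardised effect of `k` on `j`).
#' @export
standardisePerson <- function(effects = NULL, processes, Phi = NULL,
                              psi = NULL, trend = TRUE) {
  if (is.null(Phi)) {
    pe <- .effectsParts(effects, processes, trend)
    Phi <- pe$Phi; psi <- pe$pi
  }
  S <- stationaryCovariance(Phi, psi)
  sdv <- sqrt(diag(S))
  out <- Phi * outer(1 / sdv, sdv)
  dimnames(out) <- list(processes, processes)
  out
}
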