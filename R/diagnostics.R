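#' One-tailed MCMC p-value
#'
#' The smaller of the posterior probabilities that the quantity is above or
#' below zero, estimated from posterior draws — the tail probability
#' conventionally reported for MCMC fixed effects.
#'
#' @param draws numeric vector of posterior draws.
#' @return probability in `[0, 0.5]`.
#' @export
oneTailedP <- function(draws) {
  if (length(draws) == 0) stop("empty draw vector")
  min(mean(draws > 0), mean(draws < 0))
}

#' Potential scale reduction (Gelman-Rubin)
#'
#' Between/within-chain variance ratio form: with `m` chains of length `n`,
#' `W` the mean within-chain variance and `B/n` the variance of the chain
#' means, the statistic is `sqrt(((n-1)/n W + B/n) / W)`.
#'
#' @param chains list of equal-length numeric vectors, one per chain.
#' @return the PSR value (1 when all chains are degenerate and identical).
#' @export
psr <- function(chains) {
  if (!is.list(chains) || length(chains) < 2)
    stop("psr needs at least 2 chains")
  n <- unique(lengths(chains))
  if (length(n) != 1) stop("chains must have equal lengths")
  W <- mean(vapply(chains, var, numeric(1)))
  B <- n * var(vapply(chains, mean, numeric(1)))
  if (W == 0) return(if (B == 0) 1 else Inf)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Effective sample size
#'
#' Autocorrelation-based estimate `N / (1 + 2 sum rho_t)`, truncating the
#' autocorrelation sum at the first negative value (initial positive
#' sequence).
#'
#' @param draws numeric vector of (pooled) posterior draws.
#' @return estimated effective sample size.
#' @export
effectiveSize <- function(draws) {
  N <- length(draws)
  if (N < 10 || var(draws) == 0) return(N)
  rho <- acf(draws, lag.max = min(N - 1, 200), plot = FALSE)$acf[-1]
  neg <- which(rho < 0)
  if (length(neg)) rho <- rho[seq_len(neg[1] - 1)]
  max(1, min(N, N / (1 + 2 * sum(rho))))
}

#' Posterior summary of a draw vector
#'
#' @param draws numeric vector of posterior draws.
#' @param level credible level (default 0.95, equal-tailed).
#' @return named vector: `mean`, `median`, `lower`, `upper`.
#' @export
posteriorSummary <- function(draws, level = 0.95) {
  a <- (1 - level) / 2
  qs <- quantile(draws, c(a, 1 - a), names = FALSE)
  c(mean = mean(draws), median = median(draws), lower = qs[1], upper = qs[2])
}
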