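#' Configure the synthetic panel generator
#'
#' The generator emulates a weekly mood-monitoring cohort: multivariate-normal
#' person-level random effects (optionally shifted by binary baseline
#' covariates), within-person AR(1) deviations started from each person's
#' stationary distribution, a small random linear trend, and optional MCAR or
#' MAR missingness. Defaults: 649 participants, 91 weeks, covariate
#' prevalences bd2 0.384, female 0.68, age55 0.40, rapid 0.30.
#'
#' @param spec a [DsemSpec-class] (default [defaultDsemSpec()]).
#' @param n participants.
#' @param nWeeks grid length T.
#' @param prevalence named covariate prevalences.
#' @param missingness `"none"`, `"mcar"` or `"mar"`.
#' @param rate target marginal missingness rate.
#' @param marSlope logistic slope (per score point of the first process) of
#'   the MAR mechanism.
#' @param discretise round and clip scores to their scale bounds.
#' @param seed integer seed.
#' @return a [GeneratorConfig-class].
#' @export
generatorConfig <- function(spec = defaultDsemSpec(), n = 649L, nWeeks = 91L,
                            prevalence = c(bd2 = 0.384, female = 0.68,
                                           age55 = 0.40, rapid = 0.30),
                            missingness = "none", rate = 0, marSlope = 0.1,
                            discretise = FALSE, seed = 1L) {
  methods::new("GeneratorConfig", spec = spec, n = as.integer(n),
               nWeeks = as.integer(nWeeks),
               prevalence = prevalence[COVARIATE_NAMES],
               missingness = missingness, rate = rate, marSlope = marSlope,
               discretise = discretise, seed = as.integer(seed))
}

#' Draw baseline covariates
#'
#' Independent Bernoulli columns at the configured prevalences.
#'
#' @param n participants.
#' @param prevalence named numeric prevalences for `bd2`, `female`, `age55`,
#'   `rapid`.
#' @param seed integer seed.
#' @return data.frame of 0/1 columns.
#' @export
drawCovariates <- function(n, prevalence = c(bd2 = 0.384, female = 0.68,
                                             age55 = 0.40, rapid = 0.30),
                           seed = 1L) {
  set.seed(seed)
  out <- lapply(prevalence[COVARIATE_NAMES],
                function(pr) rbinom(n, 1L, pr))
  as.data.frame(out)
}

# spectral radius of per-person 2x2 (or 1x1) lag matrices, vectorised
.specRadius <- function(phi, p) {
  if (p == 1L) return(abs(phi[1, ]))
  a <- phi[1, ]; b <- phi[2, ]; c <- phi[3, ]; d <- phi[4, ]
  tr <- (a + d) / 2
  det <- a * d - b * c
  disc <- tr^2 - det
  r <- sqrt(pmax(disc, 0))
  # real eigenvalues when disc >= 0, else a complex pair of modulus sqrt(det)
  ifelse(disc >= 0, pmax(abs(tr + r), abs(tr - r)), sqrt(pmax(det, 0)))
}

#' Draw person-level random effects
#'
#' `eta_i = gamma + B x_i + u_i`, `u_i ~ N(0, Omega)`; draws whose lag matrix
#' is non-stationary (spectral radius >= 1) are rejected and redrawn, keeping
#' every generated participant inside the stationary region.
#'
#' @param spec a [DsemSpec-class].
#' @param covariates data.frame of binary covariates, one row per
#'   participant.
#' @param seed integer seed.
#' @param maxRejectRate error if more than this fraction of draws is rejected
#'   (default 0.5), a sign the spec needs revision.
#' @return list with `effects` (d x n matrix, rows named as
#'   [dsemParamNames()]) and `rejections` (redraw count).
#' @export
drawPersonEffects <- function(spec, covariates, seed = 1L,
                              maxRejectRate = 0.5) {
  validateSpec(spec)
  set.seed(seed)
  p <- length(spec@processes)
  idx <- .paramIndex(p, spec@trend)
  d <- idx$d
  n <- nrow(covariates)
  X <- t(as.matrix(covariates[, COVARIATE_NAMES, drop = FALSE]))
  m <- spec@gamma + spec@B %*% X  # d x n conditional means
  L <- t(chol(spec@Omega + diag(1e-12, d)))
  eff <- matrix(NA_real_, d, n, dimnames = list(names(spec@gamma), NULL))
  todo <- seq_len(n)
  rejections <- 0L
  total <- 0L
  while (length(todo)) {
    u <- L %*% matrix(rnorm(d * length(todo)), d)
    cand <- m[, todo, drop = FALSE] + u
    ok <- .specRadius(cand[idx$phi, , drop = FALSE], p) < 1
    eff[, todo[ok]] <- cand[, ok, drop = FALSE]
    total <- total + length(todo)
    rejections <- rejections + sum(!ok)
    todo <- todo[!ok]
    if (total > 1000 * n)
      stop("stationary rejection sampling failed to terminate; revise the spec")
  }
  if (rejections / total > maxRejectRate)
    stop(sprintf(paste("rejection rate %.0f%% exceeds %d%%: the random-effect",
                       "distribution puts too much mass outside the",
                       "stationary region; revise the spec"),
                 100 * rejections / total, round(100 * maxRejectRate)))
  list(effects = eff, rejections = rejections)
}

# stationary covariance entries for many 2x2 systems at once (Cramer's rule
# on the 3x3 vectorised Lyapunov system); psi are innovation variances
.statCov2 <- function(a, b, c, d, p1, p2) {
  m11 <- 1 - a * a; m12 <- -2 * a * b; m13 <- -b * b
  m21 <- -a * c;    m22 <- 1 - (a * d + b * c); m23 <- -b * d
  m31 <- -c * c;    m32 <- -2 * c * d; m33 <- 1 - d * d
  det <- m11 * (m22 * m33 - m23 * m32) - m12 * (m21 * m33 - m23 * m31) +
    m13 * (m21 * m32 - m22 * m31)
  # Cramer solves with rhs c(p1, 0, p2)
  s11 <- (p1 * (m22 * m33 - m23 * m32) - m12 * (0 * m33 - m23 * p2) +
            m13 * (0 * m32 - m22 * p2)) / det
  s12 <- (m11 * (0 * m33 - m23 * p2) - p1 * (m21 * m33 - m23 * m31) +
            m13 * (m21 * p2 - 0 * m31)) / det
  s22 <- (m11 * (m22 * p2 - 0 * m32) - m12 * (m21 * p2 - 0 * m31) +
            p1 * (m21 * m32 - m22 * m31)) / det
  list(s11 = s11, s12 = s12, s22 = s22)
}

#' Implied average individually standardised lag effects of a spec
#'
#' Monte-Carlo estimate, over the spec's random-effect distribution (and
#' covariate prevalences when `B` is non-zero), of the population average of
#' the person-level standardised lag matrix — the estimand reported by
#' [averageStandardisedEffects()] on a fitted model.
#'
#' @param spec a [DsemSpec-class].
#' @param prevalence covariate prevalences (used only when `B` has non-zero
#'   entries).
#' @param nsim Monte-Carlo persons.
#' @param seed integer seed.
#' @return p x p matrix of implied average standardised effects.
#' @export
impliedStandardisedEffects <- function(spec, prevalence = c(bd2 = 0.384,
                                                            female = 0.68,
                                                            age55 = 0.40,
                                                            rapid = 0.30),
                                       nsim = 20000L, seed = 1L) {
  p <- length(spec@processes)
  covs <- if (any(spec@B != 0))
    drawCovariates(nsim, prevalence, seed = seed + 1L)
  else
    as.data.frame(matrix(0L, nsim, 4, dimnames = list(NULL, COVARIATE_NAMES)))
  eff <- drawPersonEffects(spec, covs, seed = seed)$effects
  idx <- .paramIndex(p, spec@trend)
  phi <- eff[idx$phi, , drop = FALSE]
  psi <- exp(eff[idx$lnpi, , drop = FALSE])
  if (p == 1L) {
    out <- matrix(mean(phi[1, ]), 1, 1)
  } else {
    s <- .statCov2(phi[1, ], phi[2, ], phi[3, ], phi[4, ], psi[1, ], psi[2, ])
    sd1 <- sqrt(s$s11); sd2 <- sqrt(s$s22)
    out <- matrix(c(mean(phi[1, ]), mean(phi[2, ] * sd2 / sd1),
                    mean(phi[3, ] * sd1 / sd2), mean(phi[4, ])),
                  2, 2, byrow = TRUE)
  }
  dimnames(out) <- list(spec@processes, spec@processes)
  out
}

#' Calibrate a raw cross-lag fixed effect to a target standardised average
#'
#' Adjusts the fixed-effect mean of one cross-lag coefficient so that the
#' spec's implied average individually standardised effect (computed by
#' Monte-Carlo with common random numbers) hits `target`.
#'
#' @param spec a bivariate [DsemSpec-class].
#' @param target desired average standardised effect of `from` on `to`.
#' @param from,to process labels (effect of `from` at week t-1 on `to` at
#'   week t).
#' @param nsim Monte-Carlo persons per evaluation.
#' @param seed integer seed.
#' @return the spec with the calibrated `gamma` entry.
#' @export
calibrateCrossLag <- function(spec, target, from, to, nsim = 20000L,
                              seed = 1L) {
  stopifnot(length(spec@processes) == 2L,
            all(c(from, to) %in% spec@processes))
  par <- paste0("phi_", to, "_", from)
  f <- function(g) {
    s <- spec
    s@gamma[par] <- g
    impliedStandardisedEffects(s, nsim = nsim, seed = seed)[to, from] - target
  }
  sol <- uniroot(f, interval = c(-0.5, 0.5), tol = 1e-5)
  spec@gamma[par] <- sol$root
  validateSpec(spec)
  spec
}

#' Simulate a synthetic weekly panel
#'
#' Draws covariates and person effects, starts each participant's deviations
#' from that person's stationary distribution, recurses the within-person
#' dynamics over the 1..T grid, assembles observations (individual mean +
#' centred trend + deviation), optionally discretises to the scale bounds,
#' and injects missingness. The returned truth record stores everything the
#' generator used, so recovery can be checked against ground truth.
#'
#' @param config a [GeneratorConfig-class].
#' @return list with `panel` (a [MoodPanel-class]) and `truth` (list:
#'   `spec`, `effects` d x n matrix, `rejections`, `seed`).
#' @export
simulatePanel <- function(config) {
  methods::validObject(config)
  spec <- validateSpec(config@spec)
  n <- config@n; T <- config@nWeeks
  p <- length(spec@processes)
  idx <- .paramIndex(p, spec@trend)
  covs <- drawCovariates(n, config@prevalence, seed = config@seed)
  pe <- drawPersonEffects(spec, covs, seed = config@seed + 1L)
  eff <- pe$effects
  set.seed(config@seed + 2L)
  phi <- eff[idx$phi, , drop = FALSE]
  sdInn <- exp(eff[idx$lnpi, , drop = FALSE] / 2)
  mu <- eff[idx$mu, , drop = FALSE]
  slope <- if (spec@trend) eff[idx$slope, , drop = FALSE] else
    matrix(0, p, n)
  # initial deviation from each person's stationary distribution
  dev <- matrix(0, p, n)
  if (p == 1L) {
    dev[1, ] <- rnorm(n, 0, sqrt(sdInn[1, ]^2 / (1 - phi[1, ]^2)))
  } else {
    s <- .statCov2(phi[1, ], phi[2, ], phi[3, ], phi[4, ],
                   sdInn[1, ]^2, sdInn[2, ]^2)
    z1 <- rnorm(n); z2 <- rnorm(n)
    l11 <- sqrt(s$s11); l21 <- s$s12 / l11
    l22 <- sqrt(pmax(s$s22 - l21^2, 1e-12))
    dev[1, ] <- l11 * z1
    dev[2, ] <- l21 * z1 + l22 * z2
  }
  tbar <- (T + 1) / 2
  Y <- array(NA_real_, c(p, T, n))
  for (t in seq_len(T)) {
    shock <- sdInn * matrix(rnorm(p * n), p, n)
    if (p == 1L) {
      dev <- phi * dev + shock
    } else {
      d1 <- phi[1, ] * dev[1, ] + phi[2, ] * dev[2, ] + shock[1, ]
      d2 <- phi[3, ] * dev[1, ] + phi[4, ] * dev[2, ] + shock[2, ]
      dev <- rbind(d1, d2)
    }
    Y[, t, ] <- mu + slope * (t - tbar) + dev
  }
  scores <- lapply(setNames(seq_len(p), spec@processes), function(j) {
    m <- matrix(Y[j, , ], T, n)
    if (config@discretise) {
      b <- PROCESS_BOUNDS[[spec@processes[j]]]
      m <- pmin(pmax(round(m), b[1]), b[2])
    }
    colnames(m) <- sprintf("P%04d", seq_len(n))
    m
  })
  panel <- MoodPanel(scores, covs)
  if (config@missingness != "none")
    panel <- injectMissingness(panel, config@missingness, config@rate,
                               marSlope = config@marSlope,
                               seed = config@seed + 3L)
  list(panel = panel,
       truth = list(spec = spec, effects = eff, rejections = pe$rejections,
                    seed = config@seed))
}

#' Inject missingness into a panel
#'
#' Whole weeks are removed (all outcomes at once). `"mcar"` removes each
#' participant-week independently with probability `rate`. `"mar"` makes the
#' removal probability a logistic function of the most recent *observed*
#' score of `process` (so missingness depends only on observed data and the
#' mechanism is missing-at-random): the intercept is set so that a week at
#' the panel's grand mean is missing with probability `rate`, and the slope
#' is `marSlope` per score point.
#'
#' @param panel a [MoodPanel-class].
#' @param mechanism `"none"`, `"mcar"` or `"mar"`.
#' @param rate missingness rate in `[0, 1)`.
#' @param marSlope logistic slope for `"mar"`.
#' @param process score driving the MAR mechanism (default first assay).
#' @param seed integer seed.
#' @return the panel with `NA` cells injected.
#' @export
injectMissingness <- function(panel, mechanism = c("mcar", "mar", "none"),
                              rate, marSlope = 0.1,
                              process = processNames(panel)[1], seed = 1L) {
  mechanism <- match.arg(mechanism)
  if (mechanism == "none" || rate == 0) return(panel)
  stopifnot(rate >= 0, rate < 1)
  set.seed(seed)
  T <- nrow(panel); n <- ncol(panel)
  if (mechanism == "mcar") {
    drop <- matrix(runif(T * n) < rate, T, n)
  } else {
    ref <- scoreMatrix(panel, process)
    # calibrate the intercept so the marginal missingness rate over the
    # panel's observed score distribution equals the target rate
    obs <- ref[!is.na(ref)]
    a <- uniroot(function(a) mean(plogis(a + marSlope * obs)) - rate,
                 interval = c(-50, 50))$root
    drop <- matrix(FALSE, T, n)
    last <- ref[1, ]  # most recent observed score per participant
    drop[1, ] <- runif(n) < rate
    for (t in 2:T) {
      obs <- !drop[t - 1, ] & !is.na(ref[t - 1, ])
      last[obs] <- ref[t - 1, obs]
      pr <- ifelse(is.na(last), rate, plogis(a + marSlope * last))
      drop[t, ] <- runif(n) < pr
    }
  }
  assays <- lapply(setNames(processNames(panel), processNames(panel)),
                   function(v) {
                     m <- scoreMatrix(panel, v)
                     m[drop] <- NA_real_
                     m
                   })
  MoodPanel(assays, covariates(panel))
}

#' Write a generator truth record as structured text
#'
#' @param truth the `truth` element returned by [simulatePanel()].
#' @param path output YAML file.
#' @return `path`, invisibly.
#' @export
writeTruthRecord <- function(truth, path) {
  yaml::write_yaml(list(
    seed = truth$seed, rejections = truth$rejections,
    processes = as.list(truth$spec@processes),
    gamma = as.list(truth$spec@gamma),
    effects = apply(truth$effects, 2, as.list, simplify = FALSE)), path)
  invisible(path)
}
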