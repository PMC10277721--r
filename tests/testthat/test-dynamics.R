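# within-person dynamics, stationary covariance, per-person standardisation

test_that("model equations reduce correctly in degenerate cases", {
  eff <- c(mu_dep = 7, phi_dep_dep = 0, lnpi_dep = 1, slope_dep = 0)
  st <- advanceDynamics(eff, "dep", prevDeviation = 5, shock = 0,
                        week = 3, nWeeks = 9)
  expect_equal(unname(st$observation), 7)
  eff["phi_dep_dep"] <- 0.5
  st <- advanceDynamics(eff, "dep", prevDeviation = 2, shock = 0,
                        week = 5, nWeeks = 9)   # midpoint: no trend offset
  expect_equal(unname(st$deviation), 1)
  expect_equal(unname(st$observation), 8)
})

test_that("bivariate step is the hand-computed matrix-vector recursion", {
  eff <- setNames(c(7, 3, 0.4, 0.1, 0.2, 0.3, 1, 0.5, 0.1, -0.1),
                  dsemParamNames(c("dep", "ins")))
  prev <- c(2, -1); shock <- c(0.5, 0.25)
  st <- advanceDynamics(eff, c("dep", "ins"), prev, shock,
                        week = 7, nWeeks = 9)
  # Phi %*% prev = (0.4*2 + 0.1*(-1), 0.2*2 + 0.3*(-1)) = (0.7, 0.1)
  expect_equal(unname(st$deviation), c(1.2, 0.35))
  # observation adds mu + slope * (7 - 5)
  expect_equal(unname(st$observation), c(7 + 0.2 + 1.2, 3 - 0.2 + 0.35))
})

test_that("stationary covariance solves the Lyapunov equation", {
  expect_equal(stationaryCovariance(matrix(0, 2, 2), c(1, 2)),
               diag(c(1, 2)))
  expect_equal(stationaryCovariance(matrix(0.5), 3), matrix(4),
               tolerance = 1e-10)
  Phi <- matrix(c(0.4, 0.1, 0.2, 0.3), 2, 2, byrow = TRUE)
  S <- stationaryCovariance(Phi, c(1, 2))
  expect_equal(S, Phi %*% S %*% t(Phi) + diag(c(1, 2)), tolerance = 1e-12)
  expect_error(stationaryCovariance(matrix(1.01), 1), "non-stationary")
  expect_error(stationaryCovariance(matrix(0.5), 0), "positive")
})

test_that("stationary covariance matches a long-simulation estimate", {
  Phi <- matrix(c(0.4, 0.1, 0.2, 0.3), 2, 2, byrow = TRUE)
  psi <- c(1, 2)
  S <- stationaryCovariance(Phi, psi)
  set.seed(1)
  n <- 2e5
  y <- matrix(0, 2, n)
  e <- rbind(rnorm(n, 0, 1), rnorm(n, 0, sqrt(2)))
  for (t in 2:n) y[, t] <- Phi %*% y[, t - 1] + e[, t]
  emp <- tcrossprod(y[, -(1:100)]) / (n - 100)
  expect_equal(emp, S, tolerance = 0.03)
})

test_that("Lyapunov residual is at solver tolerance for random stationary systems", {
  set.seed(8)
  for (k in 1:25) {
    repeat {
      Phi <- matrix(rnorm(4, 0, 0.4), 2, 2)
      if (max(Mod(eigen(Phi, only.values = TRUE)$values)) < 0.98) break
    }
    psi <- exp(rnorm(2))
    S <- stationaryCovariance(Phi, psi)
    expect_lt(max(abs(S - Phi %*% S %*% t(Phi) - diag(psi))), 1e-10)
  }
})

test_that("univariate closed form pi/(1-phi^2) holds to 10 significant digits", {
  for (phi in c(-0.9, -0.3, 0, 0.47, 0.95)) {
    for (pi in c(0.1, 3, 40)) {
      expect_equal(stationaryCovariance(matrix(phi), pi)[1, 1],
                   pi / (1 - phi^2), tolerance = 1e-10)
    }
  }
})

test_that("standardisation: inertia invariant, scales cancel where equal", {
  # univariate: sigma cancels entirely
  eff <- c(mu_dep = 7, phi_dep_dep = 0.47, lnpi_dep = 1.8, slope_dep = 0)
  expect_equal(standardisePerson(eff, "dep")[1, 1], 0.47)
  # bivariate with identical marginal scales: cross-lags unchanged
  Phi <- matrix(c(0.3, 0.1, 0.1, 0.3), 2, 2)
  S <- stationaryCovariance(Phi, c(1, 1))
  expect_equal(S[1, 1], S[2, 2])
  std <- standardisePerson(processes = c("dep", "ins"), Phi = Phi,
                           psi = c(1, 1))
  expect_equal(std, Phi, ignore_attr = TRUE)
  # inertias are never rescaled, bivariate included
  eff2 <- randomEffects(c("dep", "ins"), seed = 12)
  std2 <- standardisePerson(eff2, c("dep", "ins"))
  expect_equal(std2["dep", "dep"], unname(eff2["phi_dep_dep"]))
  expect_equal(std2["ins", "ins"], unname(eff2["phi_ins_ins"]))
})

test_that("standardised cross-lag matches a regression on standardised series", {
  eff <- setNames(c(0, 0, 0.45, 0.12, 0.2, 0.3, log(2), log(1.3), 0, 0),
                  dsemParamNames(c("dep", "ins")))
  std <- standardisePerson(eff, c("dep", "ins"))
  set.seed(2)
  n <- 5e5
  Phi <- matrix(eff[3:6], 2, 2, byrow = TRUE)
  y <- matrix(0, 2, n)
  e <- rbind(rnorm(n, 0, sqrt(2)), rnorm(n, 0, sqrt(1.3)))
  for (t in 2:n) y[, t] <- Phi %*% y[, t - 1] + e[, t]
  z <- y / apply(y, 1, sd)   # per-series standardisation
  b <- coef(lm(z[1, -1] ~ z[1, -n] + z[2, -n] - 1))
  expect_equal(unname(b[2]), std["dep", "ins"], tolerance = 0.05)
})

test_that("standardisation ignores the trend term and time relabelling", {
  eff <- randomEffects(c("dep", "ins"), seed = 21)
  base <- standardisePerson(eff, c("dep", "ins"))
  shifted <- eff
  shifted[c("slope_dep", "slope_ins")] <- c(0.3, -0.2)
  expect_equal(standardisePerson(shifted, c("dep", "ins")), base)
  shifted[c("mu_dep", "mu_ins")] <- shifted[c("mu_dep", "mu_ins")] + 100
  expect_equal(standardisePerson(shifted, c("dep", "ins")), base)
})

test_that("non-stationary persons are reported as errors", {
  eff <- c(mu_dep = 0, phi_dep_dep = 1.05, lnpi_dep = 0, slope_dep = 0)
  expect_error(standardisePerson(eff, "dep"), "non-stationary")
})
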