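# synthetic panel generator: the ground-truth oracle for everything else

test_that("covariate draws honour prevalences and determinism", {
  z <- drawCovariates(50, c(bd2 = 0, female = 1, age55 = 0.5, rapid = 0.3),
                      seed = 1)
  expect_true(all(z$bd2 == 0))
  expect_true(all(z$female == 1))
  big <- drawCovariates(10000, seed = 2)
  expect_lt(abs(mean(big$bd2) - 0.384), 0.02)
  expect_lt(abs(mean(big$female) - 0.68), 0.02)
  expect_identical(drawCovariates(200, seed = 9), drawCovariates(200, seed = 9))
})

test_that("degenerate random effects collapse to the fixed effects", {
  spec <- defaultDsemSpec(c("dep", "ins"))
  spec@Omega <- matrix(0, 10, 10, dimnames = dimnames(spec@Omega))
  covs <- drawCovariates(8, seed = 3)
  eff <- drawPersonEffects(spec, covs, seed = 4)
  expect_equal(eff$effects, matrix(spec@gamma, 10, 8,
                                   dimnames = list(names(spec@gamma), NULL)),
               tolerance = 1e-3)
  expect_equal(eff$rejections, 0L)
})

test_that("drawn effects reproduce Omega and covariate shifts", {
  spec <- setSpecCorrelation(defaultDsemSpec(c("dep", "ins")),
                             "lnpi_dep", "lnpi_ins", 0.5)
  covs <- drawCovariates(5000, seed = 5)
  eff <- drawPersonEffects(spec, covs, seed = 6)$effects
  emp <- cov(t(eff))
  expect_equal(emp["mu_dep", "mu_dep"], 21.10, tolerance = 0.06 * 21.10)
  expect_equal(emp["lnpi_dep", "lnpi_ins"],
               spec@Omega["lnpi_dep", "lnpi_ins"], tolerance = 0.02)
  # a planted covariate effect shifts the group means by its coefficient
  spec2 <- defaultDsemSpec("dep")
  spec2@B["mu_dep", "bd2"] <- 2.5
  eff2 <- drawPersonEffects(spec2, covs, seed = 7)$effects
  gap <- mean(eff2["mu_dep", covs$bd2 == 1]) -
    mean(eff2["mu_dep", covs$bd2 == 0])
  expect_equal(gap, 2.5, tolerance = 0.35)
})

test_that("an over-dispersed lag distribution triggers the rejection guard", {
  spec <- defaultDsemSpec("dep")
  spec@gamma["phi_dep_dep"] <- 0.95
  spec@Omega["phi_dep_dep", "phi_dep_dep"] <- 4
  covs <- drawCovariates(100, seed = 8)
  expect_error(drawPersonEffects(spec, covs, seed = 9), "rejection rate")
})

test_that("noiseless configuration produces constant series at the mean", {
  spec <- defaultDsemSpec("dep")
  spec@gamma["phi_dep_dep"] <- 0
  spec@gamma["lnpi_dep"] <- -40
  spec@gamma["slope_dep"] <- 0
  spec@Omega <- matrix(0, 4, 4, dimnames = dimnames(spec@Omega))
  sim <- simulatePanel(generatorConfig(spec, n = 5, nWeeks = 10, seed = 10))
  expect_lt(max(abs(scoreMatrix(sim$panel, "dep") - 7.33)), 1e-4)
})

test_that("the generator is bit-reproducible under a fixed seed", {
  cfg <- generatorConfig(defaultDsemSpec(c("dep", "ins")), n = 12,
                         nWeeks = 15, missingness = "mcar", rate = 0.2,
                         seed = 11)
  s1 <- simulatePanel(cfg); s2 <- simulatePanel(cfg)
  expect_identical(scoreMatrix(s1$panel, "dep"), scoreMatrix(s2$panel, "dep"))
  expect_identical(s1$truth$effects, s2$truth$effects)
})

test_that("per-person lag covariance over a long series matches the Lyapunov solution", {
  spec <- defaultDsemSpec(c("dep", "ins"), trend = TRUE)
  spec@gamma[c("slope_dep", "slope_ins")] <- 0
  sl <- c("slope_dep", "slope_ins")
  spec@Omega[sl, ] <- 0; spec@Omega[, sl] <- 0
  sim <- simulatePanel(generatorConfig(spec, n = 3, nWeeks = 20000, seed = 12))
  eff <- sim$truth$effects
  for (i in 1:3) {
    Phi <- matrix(eff[3:6, i], 2, 2, byrow = TRUE)
    S <- stationaryCovariance(Phi, exp(eff[7:8, i]))
    dev <- rbind(scoreMatrix(sim$panel, "dep")[, i] - eff["mu_dep", i],
                 scoreMatrix(sim$panel, "ins")[, i] - eff["mu_ins", i])
    emp <- tcrossprod(dev) / ncol(dev)
    expect_equal(emp, S, tolerance = 0.08)
  }
})

test_that("the grand mean of simulated depression matches its fixed effect", {
  sim <- simulatePanel(generatorConfig(defaultDsemSpec("dep"), n = 1000,
                                       nWeeks = 91, seed = 13))
  expect_equal(mean(scoreMatrix(sim$panel, "dep")), 7.33, tolerance = 0.35)
})

test_that("missingness mechanisms hit their rates and stay whole-week", {
  cfg <- generatorConfig(defaultDsemSpec(c("dep", "ins")), n = 150,
                         nWeeks = 91, seed = 14)
  sim <- simulatePanel(cfg)
  expect_identical(injectMissingness(sim$panel, "mcar", rate = 0),
                   sim$panel)
  mcar <- injectMissingness(sim$panel, "mcar", rate = 0.2, seed = 15)
  expect_equal(missingnessSummary(mcar)$overall, 0.2, tolerance = 0.015)
  # both assays lose the same weeks
  expect_identical(is.na(scoreMatrix(mcar, "dep")),
                   is.na(scoreMatrix(mcar, "ins")))
  mar <- injectMissingness(sim$panel, "mar", rate = 0.2, marSlope = 0.15,
                           seed = 16)
  expect_lt(abs(missingnessSummary(mar)$overall - 0.2), 0.025)
  expect_error(injectMissingness(sim$panel, "jumpy", rate = 0.1),
               "arg")
})

test_that("MAR missingness follows the configured logistic in the lagged score", {
  cfg <- generatorConfig(defaultDsemSpec("dep"), n = 400, nWeeks = 91,
                         seed = 17)
  sim <- simulatePanel(cfg)
  mar <- injectMissingness(sim$panel, "mar", rate = 0.25, marSlope = 0.2,
                           seed = 18)
  Y <- scoreMatrix(sim$panel, "dep")
  M <- is.na(scoreMatrix(mar, "dep"))
  prevObs <- !M[-nrow(M), ]
  fitg <- glm(as.vector(M[-1, ])[prevObs] ~ as.vector(Y[-nrow(Y), ])[prevObs],
              family = binomial())
  expect_equal(unname(coef(fitg)[2]), 0.2, tolerance = 0.035)
})

test_that("discretisation respects scale bounds and creates no missingness", {
  cfg <- generatorConfig(defaultDsemSpec(c("dep", "ins")), n = 200,
                         nWeeks = 60, discretise = TRUE, seed = 19)
  sim <- simulatePanel(cfg)
  dep <- scoreMatrix(sim$panel, "dep"); ins <- scoreMatrix(sim$panel, "ins")
  expect_false(anyNA(dep))
  expect_true(all(dep == round(dep) & dep >= 0 & dep <= 27))
  expect_true(all(ins == round(ins) & ins >= 0 & ins <= 9))
})

test_that("cross-lag calibration hits the requested standardised average", {
  spec <- defaultDsemSpec(c("dep", "ins"))
  cal <- calibrateCrossLag(spec, target = 0.065, from = "dep", to = "ins",
                           nsim = 30000, seed = 20)
  imp <- impliedStandardisedEffects(cal, nsim = 60000, seed = 21)
  expect_lt(abs(imp["ins", "dep"] - 0.065), 0.004)
  # only the targeted fixed effect moved
  moved <- names(which(cal@gamma != spec@gamma))
  expect_equal(moved, "phi_ins_dep")
})

test_that("truth records round trip through the structured-text sidecar", {
  sim <- smallSim("dep", n = 4, T = 6, seed = 22)
  f <- tempfile(fileext = ".yaml")
  writeTruthRecord(sim$truth, f)
  x <- yaml::read_yaml(f)
  expect_equal(unlist(x$processes), "dep")
  expect_equal(length(x$effects), 4L)
  expect_equal(unlist(x$effects[[2]]),
               setNames(sim$truth$effects[, 2],
                        rownames(sim$truth$effects)),
               tolerance = 1e-8)
})
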