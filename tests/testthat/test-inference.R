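# MCMC machinery: p-values, diagnostics, estimation, determinism

test_that("one-tailed p is the smaller sign fraction", {
  expect_equal(oneTailedP(c(1, 2, 3)), 0)
  set.seed(1)
  expect_equal(oneTailedP(c(rnorm(5000), -rnorm(5000))), 0.5, tolerance = 0.02)
  expect_equal(oneTailedP(rnorm(2e5, 1.96, 1)), pnorm(-1.96), tolerance = 0.01)
  expect_error(oneTailedP(numeric(0)), "empty")
})

test_that("potential scale reduction follows the between/within formula", {
  x <- rnorm(100)
  expect_equal(psr(list(x, x)), sqrt(99 / 100))
  expect_gt(psr(list(rnorm(200), rnorm(200) + 50)), 10)
  # hand-computed two-chain fixture of 5 draws each
  a <- c(1, 2, 3, 4, 5); b <- c(2, 3, 4, 5, 9)
  W <- (var(a) + var(b)) / 2
  B <- 5 * var(c(mean(a), mean(b)))
  expect_equal(psr(list(a, b)), sqrt((4 / 5 * W + B / 5) / W))
  expect_error(psr(list(a)), "2 chains")
  expect_error(psr(list(a, b[1:3])), "equal lengths")
})

test_that("posterior summaries are exact on analytic draw sets", {
  expect_equal(posteriorSummary(rep(3, 200)),
               c(mean = 3, median = 3, lower = 3, upper = 3))
  expect_equal(posteriorSummary(1:100)[["median"]], 50.5)
  set.seed(4)
  s <- posteriorSummary(rnorm(2e5))
  expect_equal(unname(s[c("lower", "upper")]), c(-1.96, 1.96),
               tolerance = 0.02)
})

test_that("fitDsem enforces its preconditions", {
  sim <- smallSim("dep", n = 12, T = 20, seed = 31)
  expect_error(fitDsem(sim$panel[, 1], spec = defaultDsemSpec("dep")),
               "2 participants")
  short <- scoreMatrix(sim$panel, "dep")
  short[3:20, 2] <- NA
  p <- MoodPanel(list(dep = short), covariates(sim$panel))
  expect_error(fitDsem(p, spec = defaultDsemSpec("dep")), "3 non-missing")
})

test_that("identical seed and inputs give bit-identical draws", {
  sim <- smallSim("dep", n = 15, T = 25, seed = 32)
  f1 <- quietFit(sim$panel, spec = defaultDsemSpec("dep"), chains = 2,
                 iterations = 60, burnin = 60, seed = 5)
  f2 <- quietFit(sim$panel, spec = defaultDsemSpec("dep"), chains = 2,
                 iterations = 60, burnin = 60, seed = 5)
  expect_identical(posteriorDraws(f1), posteriorDraws(f2))
  expect_identical(personDraws(f1), personDraws(f2))
  f3 <- quietFit(sim$panel, spec = defaultDsemSpec("dep"), chains = 2,
                 iterations = 60, burnin = 60, seed = 6)
  expect_false(identical(posteriorDraws(f1), posteriorDraws(f3)))
})

test_that("a null autoregression is recovered near zero", {
  spec <- defaultDsemSpec("ins")
  spec@gamma["phi_ins_ins"] <- 0
  sim <- simulatePanel(generatorConfig(spec, n = 80, nWeeks = 60, seed = 33))
  fit <- quietFit(sim$panel, spec = defaultDsemSpec("ins"), chains = 2,
                  iterations = 500, burnin = 500, seed = 7)
  expect_lt(abs(mean(posteriorDraws(fit)[, "gamma.phi_ins_ins"])), 0.05)
})

test_that("with near-zero heterogeneity the fixed lag effect matches pooled OLS", {
  spec <- defaultDsemSpec("dep")
  spec@Omega <- diag(c(0.01, 1e-6, 1e-6, 1e-10))
  spec@gamma["slope_dep"] <- 0
  sim <- simulatePanel(generatorConfig(spec, n = 30, nWeeks = 200, seed = 34))
  Y <- scoreMatrix(sim$panel, "dep")
  ols <- vapply(seq_len(ncol(Y)), function(i) {
    x <- Y[, i] - mean(Y[, i])
    unname(coef(lm(x[-1] ~ x[-length(x)] - 1)))
  }, numeric(1))
  fit <- quietFit(sim$panel, spec = defaultDsemSpec("dep"), chains = 2,
                  iterations = 500, burnin = 500, seed = 8)
  expect_lt(abs(mean(posteriorDraws(fit)[, "gamma.phi_dep_dep"]) - mean(ols)),
            0.02)
})

test_that("random-effect correlation output is a valid correlation matrix", {
  sim <- smallSim(c("dep", "ins"), n = 30, T = 30, seed = 36)
  fit <- quietFit(sim$panel, spec = defaultDsemSpec(c("dep", "ins")),
                  chains = 2, iterations = 150, burnin = 150, seed = 9)
  co <- randomEffectCorrelations(fit)
  expect_equal(diag(co), setNames(rep(1, 10), rownames(co)))
  expect_equal(co, t(co))
  expect_true(all(abs(co) <= 1))
  uni <- quietFit(sim$panel, spec = defaultDsemSpec("dep"), chains = 2,
                  iterations = 60, burnin = 60, seed = 10)
  expect_error(randomEffectCorrelations(uni), "bivariate")
})

test_that("non-convergence is flagged and warned, never silent", {
  sim <- smallSim("dep", n = 15, T = 20, seed = 37)
  expect_warning(
    fit <- fitDsem(sim$panel, spec = defaultDsemSpec("dep"), chains = 2,
                   iterations = 15, burnin = 5, seed = 11),
    "convergence")
  expect_false(convergenceDiagnostics(fit)$convergence)
})

test_that("draws persist as CSV with a JSON sidecar", {
  sim <- smallSim("dep", n = 12, T = 20, seed = 38)
  fit <- quietFit(sim$panel, spec = defaultDsemSpec("dep"), chains = 2,
                  iterations = 50, burnin = 50, seed = 12)
  d <- file.path(tempdir(), "fitout")
  writeFit(fit, d)
  draws <- read.csv(file.path(d, "fit_draws.csv"))
  expect_equal(nrow(draws), 100L)
  meta <- jsonlite::read_json(file.path(d, "fit_draws.json"))
  expect_equal(unlist(meta$parameters), colnames(posteriorDraws(fit)))
  expect_true(file.exists(file.path(d, "fit_diagnostics.json")))
})
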