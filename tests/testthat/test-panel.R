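# panel container, CSV round trip, eligibility filters

writeFixtureCsv <- function(df) {
  f <- tempfile(fileext = ".csv")
  write.csv(df, f, row.names = FALSE, na = "")
  f
}

test_that("readPanel parses the scores dialect onto a complete grid", {
  df <- data.frame(id = rep(c("a", "b"), each = 3), week = rep(1:3, 2),
                   bd2 = rep(c(0, 1), each = 3), female = 1, age55 = 0,
                   rapid = 0, dep = c(4, 5, 6, 10, 11, 12),
                   ins = c(1, 2, 3, 7, 8, 9), hypo = c(0, 0, 1, 2, 2, 2))
  p <- readPanel(writeFixtureCsv(df))
  expect_s4_class(p, "MoodPanel")
  expect_equal(dim(p), c(3L, 2L))
  expect_equal(nrow(covariates(p)), 2L)
  expect_equal(scoreMatrix(p, "dep")[, "b"], c(10, 11, 12))
})

test_that("absent weeks become explicit missing cells, grid unchanged", {
  df <- data.frame(id = c("a", "a", "a", "b", "b"), week = c(1, 2, 3, 1, 3),
                   bd2 = 0, female = 0, age55 = 0, rapid = 0,
                   dep = 1:5, ins = 0, hypo = 0)
  p <- readPanel(writeFixtureCsv(df))
  expect_equal(dim(p), c(3L, 2L))
  expect_true(is.na(scoreMatrix(p, "dep")[2, "b"]))
  expect_equal(missingnessSummary(p)$overall, 1 / 6)
})

test_that("items dialect scores agree with the scoring operations", {
  set.seed(7)
  q <- matrix(sample(0:3, 4 * 16, replace = TRUE), 4)
  a <- matrix(sample(0:4, 4 * 5, replace = TRUE), 4)
  df <- data.frame(id = rep(c("a", "b"), each = 2), week = rep(1:2, 2),
                   bd2 = 0, female = 1, age55 = 0, rapid = 1)
  df[sprintf("qids_%02d", 1:16)] <- as.data.frame(q)
  df[sprintf("asrm_%02d", 1:5)] <- as.data.frame(a)
  p <- readPanel(writeFixtureCsv(df), dialect = "items")
  expect_equal(as.vector(scoreMatrix(p, "dep")),
               as.numeric(scoreQidsDepression(q)))
  expect_equal(as.vector(scoreMatrix(p, "ins")),
               as.numeric(scoreQidsInsomnia(q)))
  expect_equal(as.vector(scoreMatrix(p, "hypo")), as.numeric(scoreAsrm(a)))
})

test_that("readPanel rejects malformed files", {
  base <- data.frame(id = "a", week = 1, bd2 = 0, female = 0, age55 = 0,
                     rapid = 0, dep = 1, ins = 1, hypo = 1)
  dup <- rbind(base, base)
  expect_error(readPanel(writeFixtureCsv(dup)), "duplicate")
  frac <- base; frac$week <- 1.5
  expect_error(readPanel(writeFixtureCsv(frac)), "non-integer")
  cov2 <- base; cov2$bd2 <- 2
  expect_error(readPanel(writeFixtureCsv(cov2)), "bd2")
})

test_that("write/read round trip preserves values and the missingness mask", {
  sim <- smallSim(c("dep", "ins"), n = 6, T = 12, seed = 99,
                  missingness = "mcar", rate = 0.25)
  f <- tempfile(fileext = ".csv")
  writePanel(sim$panel, f)
  back <- readPanel(f, nWeeks = 12)
  for (v in c("dep", "ins"))
    expect_identical(scoreMatrix(back, v), scoreMatrix(sim$panel, v))
  expect_identical(covariates(back), covariates(sim$panel))
})

test_that("eligibility removes short, empty and flat series with reasons", {
  dep <- cbind(A = c(5, 7, 6, 8), B = rep(NA_real_, 4),
               C = c(4, 4, 4, 4), D = c(1, 2, NA, NA))
  p <- MoodPanel(list(dep = dep),
                 data.frame(bd2 = 0L, female = 0L, age55 = 0L,
                            rapid = 0L)[rep(1, 4), ])
  el <- applyEligibility(p, minWeeks = 3, requireVariation = TRUE)
  expect_equal(participantIds(el$panel), "A")
  expect_equal(nrow(el$exclusions), 3L)
  expect_match(el$exclusions$reason[el$exclusions$id == "C"], "no variation")
  expect_match(el$exclusions$reason[el$exclusions$id == "B"], "fewer than 3")
  # exclusion log rows = participants in minus participants out
  expect_equal(nrow(el$exclusions), 4L - ncol(el$panel))
  # idempotence
  el2 <- applyEligibility(el$panel, minWeeks = 3, requireVariation = TRUE)
  expect_identical(participantIds(el2$panel), participantIds(el$panel))
  expect_equal(nrow(el2$exclusions), 0L)
})

test_that("a constant (hypo)mania series is excluded when variation is required", {
  sim <- smallSim(c("dep", "hypo"), n = 5, T = 20, seed = 3)
  panel <- sim$panel
  m <- scoreMatrix(panel, "hypo"); m[, 2] <- 0
  flat <- MoodPanel(list(dep = scoreMatrix(panel, "dep"), hypo = m),
                    covariates(panel))
  el <- applyEligibility(flat, minWeeks = 5, requireVariation = TRUE)
  expect_equal(nrow(el$exclusions), 1L)
  expect_match(el$exclusions$reason, "no variation in hypo")
  # with the flag off the participant is retained
  el2 <- applyEligibility(flat, minWeeks = 5, requireVariation = FALSE)
  expect_equal(ncol(el2$panel), 5L)
})

test_that("eligibility below-threshold counting matches a hand count", {
  set.seed(11)
  sim <- smallSim("dep", n = 10, T = 30, seed = 17)
  dep <- scoreMatrix(sim$panel, "dep")
  dep[sample(30, 15), 2] <- NA   # 15 observed
  dep[1:25, 5] <- NA             # 5 observed
  dep[1:12, 8] <- NA             # 18 observed
  p <- MoodPanel(list(dep = dep), covariates(sim$panel))
  el <- applyEligibility(p, minWeeks = 20, requireVariation = FALSE)
  expect_equal(ncol(el$panel), 7L)
  expect_error(applyEligibility(p, minWeeks = 31), "review")
})

test_that("missingness summary fractions are exact", {
  sim <- smallSim("dep", n = 4, T = 3, seed = 5)
  dep <- scoreMatrix(sim$panel, "dep")
  dep[1, 1] <- NA; dep[2, 1] <- NA; dep[3, 4] <- NA
  p <- MoodPanel(list(dep = dep), covariates(sim$panel))
  ms <- missingnessSummary(p)
  expect_equal(ms$overall, 3 / 12)
  expect_equal(ms$byParticipant$missingFraction, c(2 / 3, 0, 0, 1 / 3))
  expect_equal(ms$byWeek$missingFraction, c(1 / 4, 1 / 4, 1 / 4))
  full <- smallSim("dep", n = 3, T = 4, seed = 6)$panel
  expect_equal(missingnessSummary(full)$overall, 0)
})
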