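# shared fixtures, all generated in code

# a tiny complete two-participant panel with fixed values
tinyPanel <- function() {
  dep <- matrix(c(5, 7, 6, 10, 12, 11), nrow = 3,
                dimnames = list(NULL, c("A", "B")))
  ins <- matrix(c(2, 3, 2, 6, 5, 7), nrow = 3,
                dimnames = list(NULL, c("A", "B")))
  hypo <- matrix(c(1, 0, 2, 0, 1, 0), nrow = 3,
                 dimnames = list(NULL, c("A", "B")))
  MoodPanel(list(dep = dep, ins = ins, hypo = hypo),
            data.frame(bd2 = c(0L, 1L), female = c(1L, 1L),
                       age55 = c(0L, 1L), rapid = c(0L, 0L)))
}

# a small simulated panel for fit-based tests
smallSim <- function(processes = "dep", n = 40, T = 40, seed = 301, ...) {
  simulatePanel(generatorConfig(defaultDsemSpec(processes), n = n,
                                nWeeks = T, seed = seed, ...))
}

quietFit <- function(...) suppressWarnings(fitDsem(...))

# random stationary person-effect vector for property loops
randomEffects <- function(processes, seed) {
  set.seed(seed)
  spec <- defaultDsemSpec(processes)
  covs <- data.frame(bd2 = 0L, female = 0L, age55 = 0L, rapid = 0L)
  drawPersonEffects(spec, covs, seed = seed)$effects[, 1]
}
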