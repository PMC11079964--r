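# Memoized full-size cohort analyses shared by the acceptance tests.
# Simulation and analysis run once per test session, on first use.

.cohortCache <- new.env(parent = emptyenv())

defaultCohortResults <- function() {
  if (!exists("e1", .cohortCache)) {
    .cohortCache$e1 <- analyzeCohort(
      simConfig(montage = "compact"),
      infCfg = list(clusterAlpha = 0.05, nPermutations = 2000, seed = 1))
  }
  .cohortCache$e1
}

loadContrastCohortResults <- function() {
  if (!exists("e2", .cohortCache)) {
    .cohortCache$e2 <- analyzeCohort(
      simConfigLoadContrast(),
      infCfg = list(clusterAlpha = 0.05, nPermutations = 2000, seed = 1))
  }
  .cohortCache$e2
}
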