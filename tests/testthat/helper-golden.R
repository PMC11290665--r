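# The small, fully seeded scenario behind the committed golden files in
# fixtures/. Regenerate with scripts/make_fixtures.R after intentional
# behaviour changes.

goldenSimConfig <- function() {
  simConfig(surveys = c(2014L, 2015L, 2017L, 2019L, 2021L),
            eventYears = c(2015L, 2019L),
            sites = c("North", "South"),
            taxa = list(
              taxonConfig("Encruster", 15, c(0.3, 0.3, 0.1, 0.3), survA = 1.2),
              taxonConfig("Brancher", 15, c(0.1, 0.2, 0.1, 0.6),
                          survA = 2.0, survB = -0.3)),
            seed = 42L)
}

goldenRunConfig <- function(outDir) {
  runConfig(surveys = c(2014L, 2015L, 2017L, 2019L, 2021L),
            eventYears = c(2015L, 2019L),
            nResamples = 2000, minSurvivors = 5,
            seed = 42L, outDir = outDir)
}

runGoldenPipeline <- function(outDir) {
  cfg <- goldenSimConfig()
  sim <- simulateCommunity(cfg)
  suppressWarnings(
    runPipeline(goldenRunConfig(outDir), simulationSurvey(sim, cfg)))
}
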