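# Regenerates the golden pipeline outputs committed under
# tests/testthat/fixtures/. Run from the package root after an intentional
# behaviour change:
#   Rscript scripts/make_fixtures.R
devtools::load_all(".", quiet = TRUE)
source("tests/testthat/helper-golden.R")

out <- tempfile("golden")
runGoldenPipeline(out)
dir.create("tests/testthat/fixtures", showWarnings = FALSE, recursive = TRUE)
for (f in c("genets.csv", "responses.csv", "acclim_results.csv",
            "letters.csv", "popstats.json")) {
  file.copy(file.path(out, f), file.path("tests/testthat/fixtures", f),
            overwrite = TRUE)
}
cat("golden fixtures written:\n")
print(file.info(list.files("tests/testthat/fixtures", full.names = TRUE))["size"])
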