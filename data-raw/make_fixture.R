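## Generates the packaged synthetic end-to-end fixture: a 4-ancestry,
## 3-locus study with known ground truth, plus the golden ranked
## comparison table produced by the first verified pipeline run.
## Rerun from the repository root after any generator change:
##   Rscript data-raw/make_fixture.R
library(parGWAS)

dest <- file.path("inst", "extdata")
dir.create(dest, recursive = TRUE, showWarnings = FALSE)

cfg <- simulationConfig(
    seed = 20240923,
    ancestries = list(
        list(label = "EUR", n_cases = 8000, n_controls = 8000),
        list(label = "AFR", n_cases = 6000, n_controls = 6000),
        list(label = "EAS", n_cases = 6000, n_controls = 6000),
        list(label = "AMR", n_cases = 4000, n_controls = 4000)),
    loci = list(
        list(label = "APOE", n_variants = 4, causal_index = 2, ld_rho = 0.6,
             true_or = c(EUR = 3.2, AFR = 2.1, EAS = 3.6, AMR = 1.9),
             true_raf = c(EUR = 0.15, AFR = 0.22, EAS = 0.10, AMR = 0.12)),
        list(label = "PICALM", n_variants = 1, causal_index = 1, ld_rho = 0,
             true_or = c(EUR = 0.85, AFR = 0.87, EAS = 0.84, AMR = 0.88),
             true_raf = c(EUR = 0.64, AFR = 0.55, EAS = 0.60, AMR = 0.58)),
        list(label = "BIN1", n_variants = 3, causal_index = 1, ld_rho = 0.5,
             true_or = c(EUR = 1.20, AFR = 1.15, EAS = 1.25, AMR = 1.18),
             true_raf = c(EUR = 0.40, AFR = 0.30, EAS = 0.45, AMR = 0.35))),
    protectiveFraction = 0.3)

st <- simulateStudy(cfg, dest)
for (lab in names(st$strata))
    file.rename(file.path(dest, sprintf("sumstats_%s.tsv", lab)),
                file.path(dest, sprintf("synthetic_sumstats_%s.tsv", lab)))
file.rename(file.path(dest, "truth.tsv"),
            file.path(dest, "synthetic_truth.tsv"))

out <- tempfile()
pc <- pipelineConfig(
    inputs = vapply(names(st$strata), function(l)
        file.path(dest, sprintf("synthetic_sumstats_%s.tsv", l)),
        character(1)),
    outputDir = out, alpha = 0.05, topK = 3)
runPipeline(pc, quiet = TRUE)
file.copy(file.path(out, "comparison.tsv"),
          file.path(dest, "golden_comparison.tsv"), overwrite = TRUE)
cat("fixture written to", dest, "\n")
print(readSumstatsTable(file.path(dest, "golden_comparison.tsv")))
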