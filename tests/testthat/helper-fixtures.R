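## Random but valid variant tables for property-style tests.
## Uses the session RNG; call set.seed() in the test first.
randomVariantFrame <- function(n, ancestry = "EUR") {
    if (n == 0L)
        return(data.frame(variant_id = character(), chrom = character(),
                          pos = integer(), effect_allele = character(),
                          other_allele = character(), beta = numeric(),
                          se = numeric(), p_value = numeric(),
                          eaf = numeric(), locus = character(),
                          ancestry = character(),
                          stringsAsFactors = FALSE))
    alleles <- c("A", "C", "G", "T")
    ea <- sample(alleles, n, replace = TRUE)
    oa <- vapply(ea, function(a) sample(setdiff(alleles, a), 1L),
                 character(1))
    data.frame(variant_id = sprintf("rs%06d", sample.int(999999L, n)),
               chrom = as.character(sample.int(22L, n, replace = TRUE)),
               pos = sample.int(2e8L, n),
               effect_allele = ea, other_allele = unname(oa),
               beta = stats::rnorm(n, 0, 0.3),
               se = stats::runif(n, 0.01, 0.2),
               p_value = stats::runif(n),
               eaf = stats::runif(n, 0.01, 0.99),
               locus = sprintf("LOC%d", sample.int(max(1L, n %/% 3L), n,
                                                   replace = TRUE)),
               ancestry = ancestry,
               stringsAsFactors = FALSE)
}

## Independent quadrature oracle for the Wakefield Bayes factor: the
## ratio of the marginal likelihood of the estimate under a Gaussian
## effect prior to its likelihood under the null, integrated numerically.
quadratureBF <- function(betaHat, se, priorSd) {
    num <- stats::integrate(function(b)
        stats::dnorm(betaHat, b, se) * stats::dnorm(b, 0, priorSd),
        -Inf, Inf, rel.tol = 1e-12)$value
    num / stats::dnorm(betaHat, 0, se)
}

fixturePath <- function(...) {
    system.file("extdata", ..., package = "parGWAS", mustWork = TRUE)
}

fixturePipelineConfig <- function(outputDir) {
    pipelineConfig(
        inputs = c(EUR = fixturePath("synthetic_sumstats_EUR.tsv"),
                   AFR = fixturePath("synthetic_sumstats_AFR.tsv"),
                   EAS = fixturePath("synthetic_sumstats_EAS.tsv"),
                   AMR = fixturePath("synthetic_sumstats_AMR.tsv")),
        outputDir = outputDir, alpha = 0.05, topK = 3)
}
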