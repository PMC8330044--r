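# Small in-code fixtures shared across test files.

# A single-sample SNP profile data.frame.
mkProfile <- function(depth, vaf, snp_id = sprintf("SNP%03d", seq_along(depth))) {
  data.frame(snp_id = snp_id, chrom = "1", pos = seq_along(depth),
             depth = depth, vaf = vaf, stringsAsFactors = FALSE)
}

# A raw fusion-call row in the harmonized schema.
mkCall <- function(sample_id = "S1", gene5 = "BCR", gene3 = "ABL1",
                   chrom5 = "22", pos5 = 1000L, strand5 = "+",
                   chrom3 = "9", pos3 = 2000L, strand3 = "+",
                   supporting_reads = 10L) {
  data.frame(sample_id = sample_id, gene5 = gene5, gene3 = gene3,
             chrom5 = chrom5, pos5 = pos5, strand5 = strand5,
             chrom3 = chrom3, pos3 = pos3, strand3 = strand3,
             supporting_reads = supporting_reads, stringsAsFactors = FALSE)
}

# A consensus-style row (as produced by consensusFusions) for filter tests.
mkConsensus <- function(sample_id = "S1", gene5 = "BCR", gene3 = "ABL1",
                        chrom5 = "22", pos5 = 1000L, chrom3 = "9",
                        pos3 = 2000L, n_callers = 2L) {
  data.frame(sample_id = sample_id, gene5 = gene5, gene3 = gene3,
             chrom5 = chrom5, pos5 = pos5, chrom3 = chrom3, pos3 = pos3,
             strand5 = "+", strand3 = "+", supporting_reads = 10L,
             callers = paste(paste0("caller", seq_len(n_callers)),
                             collapse = ","),
             n_callers = n_callers,
             intra_chromosomal = chrom5 == chrom3, stringsAsFactors = FALSE)
}

# Independent oracle for the allele concordance score: explicit diploid
# allele multisets and multiset intersection, no dosage arithmetic.
oracleConcordance <- function(a, b) {
  alleles <- function(d) c(rep(0L, 2 - d), rep(1L, d))
  use <- !is.na(a) & !is.na(b)
  ident <- vapply(which(use), function(i) {
    x <- alleles(a[i]); y <- alleles(b[i])
    n <- 0L
    for (v in x) {
      j <- match(v, y)
      if (!is.na(j)) { y <- y[-j]; n <- n + 1L }
    }
    n
  }, integer(1))
  sum(ident) / (2 * sum(use))
}

# Independent brute-force oracle for the ploidy rule engine, written straight
# from the clinical rules: > minChanges changes selects a candidate; >= 5
# losses or joint loss of the marker chromosomes calls hypodiploid (evaluated
# first); >= 2 typical gains calls hyperdiploid.
oraclePloidy <- function(states, hyperChroms, hypoMarkers,
                         minChanges = 3, hypoMinLosses = 5, hyperMin = 2) {
  gains <- names(states)[states == "gain"]
  losses <- names(states)[states == "loss"]
  if (length(gains) + length(losses) <= minChanges) return("none")
  if (length(losses) >= hypoMinLosses || all(hypoMarkers %in% losses))
    return("low-hypodiploid/near-triploid")
  if (sum(hyperChroms %in% gains) >= hyperMin) return("high-hyperdiploid")
  "none"
}

# Small cached synthetic universe for tests that only need a valid annotation.
testAnnotation <- local({
  ann <- NULL
  function() {
    if (is.null(ann)) ann <<- syntheticGeneAnnotation()
    ann
  }
})
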