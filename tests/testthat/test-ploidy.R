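# Expression-derived copy-number states and the ploidy rule engine.

test_that("gene ratios are zero against a matching reference, floored genes drop", {
  genes <- sprintf("g%02d", 1:20)
  ref <- setNames(rep(5, 20), genes)
  m <- matrix(5, nrow = 20, ncol = 3, dimnames = list(genes, c("A", "B", "C")))
  r <- inferGeneLog2(m, ref)
  expect_true(all(r == 0))
  # reference floor: uninformative genes never enter the ratio matrix
  low <- referenceProfile(matrix(c(rep(5, 3), rep(0.2, 3)), nrow = 2,
                                 byrow = TRUE,
                                 dimnames = list(c("hi", "lo"), LETTERS[1:3])))
  expect_identical(names(low), "hi")
  # winsorization caps extreme single-gene ratios
  m2 <- m; m2[1, 1] <- 50
  expect_equal(max(inferGeneLog2(m2, ref, center = FALSE)), 3)
})

test_that("chromosome aggregation applies weight and threshold rules", {
  ann <- data.frame(gene_id = sprintf("g%03d", 1:100),
                    chrom = "1", stringsAsFactors = FALSE)
  m <- matrix(0, 100, 1, dimnames = list(ann$gene_id, "S"))
  st <- aggregateChromosome(m, ann)
  s1 <- st[st$chrom == "1", ]
  expect_identical(s1$state, "neutral")
  expect_equal(s1$n_genes, 100L)
  # 12 supporting genes is at or under the weight cutoff: forced neutral
  m12 <- matrix(0.6, 12, 1, dimnames = list(ann$gene_id[1:12], "S"))
  s12 <- aggregateChromosome(m12, ann)
  expect_identical(s12$state[s12$chrom == "1"], "neutral")
  expect_true(s12$low_weight[s12$chrom == "1"])
  # 50 genes at 0.2 exceed the 0.15 threshold: gain
  m50 <- matrix(0.2, 50, 1, dimnames = list(ann$gene_id[1:50], "S"))
  s50 <- aggregateChromosome(m50, ann)
  expect_identical(s50$state[s50$chrom == "1"], "gain")
  # symmetric loss threshold
  s50n <- aggregateChromosome(-m50, ann)
  expect_identical(s50n$state[s50n$chrom == "1"], "loss")
})

test_that("ploidy rules follow the clinical definitions", {
  mkStates <- function(gain = character(), loss = character()) {
    st <- setNames(rep("neutral", 22), as.character(1:22))
    st[gain] <- "gain"; st[loss] <- "loss"
    st
  }
  # specific loss of 3, 7, 13, 17 (4 changes > 3) -> hypodiploid
  p <- classifyPloidy(mkStates(loss = c("3", "7", "13", "17")))
  expect_identical(p$ploidy_group, "low-hypodiploid/near-triploid")
  # gains across the typical set -> hyperdiploid
  p2 <- classifyPloidy(mkStates(gain = as.character(c(4, 6, 10, 14, 17, 18, 21))))
  expect_identical(p2$ploidy_group, "high-hyperdiploid")
  # exactly 3 changes: not a candidate (strict inequality)
  p3 <- classifyPloidy(mkStates(gain = c("4", "6"), loss = "9"))
  expect_identical(p3$ploidy_group, "none")
  # 2 typical gains plus 2 atypical -> hyperdiploid
  p4 <- classifyPloidy(mkStates(gain = c("4", "10", "2", "9")))
  expect_identical(p4$ploidy_group, "high-hyperdiploid")
  # candidate matching neither rule
  p5 <- classifyPloidy(mkStates(gain = c("1", "2", "3", "5")))
  expect_identical(p5$ploidy_group, "none")
  expect_identical(p5$note, "candidate-unresolved")
  # both rules firing resolves to hypodiploid with a conflict note
  p6 <- classifyPloidy(mkStates(gain = c("4", "6"),
                                loss = as.character(c(1, 2, 3, 5, 9))))
  expect_identical(p6$ploidy_group, "low-hypodiploid/near-triploid")
  expect_match(p6$note, "conflict")
})

test_that("rule engine agrees with the brute-force oracle on random patterns", {
  set.seed(11)
  cfg <- ploidyConfig()
  for (i in 1:300) {
    st <- setNames(sample(c("gain", "loss", "neutral"), 22, replace = TRUE,
                          prob = c(0.25, 0.25, 0.5)), as.character(1:22))
    expect_identical(classifyPloidy(st, cfg)$ploidy_group,
                     oraclePloidy(st, cfg$hyperChroms, cfg$hypoMarkerChroms))
  }
})

test_that("a planted trisomy shows the expected dosage shift in expression", {
  cfg <- simConfig(nSamples = c("bcp-other" = 6L), nControls = 24L,
                   dosageTransmission = 1, deletionRate = 0, seed = 5L)
  ann <- syntheticGeneAnnotation()
  truth <- simulateTruth(cfg, ann)
  truth$chromosomeCn["8", ] <- 4L   # doubled chromosome 8 in every patient
  se <- renderCounts(truth, ann, cfg)
  e <- normalizeExpression(se)
  expr <- SummarizedExperiment::assay(e, "logCPM")
  ctl <- colnames(se)[se$cohort == "control"]
  ref <- referenceProfile(expr, ctl)
  ratios <- inferGeneLog2(expr[, truth$samples$sample_id, drop = FALSE], ref)
  onChr8 <- rownames(ratios) %in% ann$gene_id[ann$chrom == "8"]
  obs <- mean(ratios[onChr8, ])
  se3 <- 3 * sd(ratios[onChr8, ]) / sqrt(sum(onChr8) * ncol(ratios))
  expect_lt(abs(obs - 1), se3 + 0.05)  # log2(4/2) = 1 at full transmission
})

test_that("zero dosage transmission yields no ploidy candidates", {
  cfg <- simConfig(nSamples = c("high-hyperdiploid" = 4L,
                                "low-hypodiploid" = 4L),
                   nControls = 24L, dosageTransmission = 1e-9,
                   deletionRate = 0, seed = 9L)
  ann <- syntheticGeneAnnotation()
  truth <- simulateTruth(cfg, ann)
  se <- renderCounts(truth, ann, cfg)
  e <- normalizeExpression(se)
  expr <- SummarizedExperiment::assay(e, "logCPM")
  ctl <- colnames(se)[se$cohort == "control"]
  ref <- referenceProfile(expr, ctl)
  st <- aggregateChromosome(
    inferGeneLog2(expr[, truth$samples$sample_id, drop = FALSE], ref),
    ann)
  p <- classifyPloidy(st)
  expect_true(all(p$ploidy_group == "none"))
})
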