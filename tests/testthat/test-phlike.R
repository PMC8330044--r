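# Signature gene selection, median references, minimal-distance classification.

test_that("signature genes are ranked by median group separation", {
  set.seed(21)
  genes <- sprintf("g%03d", 1:50)
  m <- matrix(rnorm(50 * 20, 5, 0.1), nrow = 50,
              dimnames = list(genes, sprintf("P%02d", 1:20)))
  pos <- sprintf("P%02d", 1:10); neg <- sprintf("P%02d", 11:20)
  m["g007", pos] <- m["g007", pos] + 5
  expect_identical(selectSignatureGenes(m, pos, neg, k = 1), "g007")
  # full ranking against a brute-force sort
  d <- abs(apply(m[, pos], 1, median) - apply(m[, neg], 1, median))
  expect_identical(selectSignatureGenes(m, pos, neg, k = 50),
                   genes[order(-d, genes)])
  # identical groups: deterministic tie order (gene id)
  flat <- matrix(5, nrow = 5, ncol = 4,
                 dimnames = list(c("b", "a", "d", "c", "e"),
                                 c("P1", "P2", "N1", "N2")))
  expect_identical(selectSignatureGenes(flat, c("P1", "P2"), c("N1", "N2"),
                                        k = 5), c("a", "b", "c", "d", "e"))
  expect_error(selectSignatureGenes(m, character(), neg, k = 2), "non-empty")
})

test_that("reference medians match brute-force recomputation", {
  m <- matrix(c(1, 2, 3, 9, 8, 7), nrow = 1,
              dimnames = list("g1", sprintf("P%d", 1:6)))
  ref <- buildReference(m, posIds = c("P1", "P2", "P3"),
                        negIds = c("P4", "P5", "P6"), geneList = "g1")
  expect_equal(unname(ref@medianPos), 2)
  expect_equal(unname(ref@medianNeg), 8)
  # single positive sample: the median is that sample
  ref1 <- buildReference(m, "P1", c("P4", "P5"), "g1")
  expect_equal(unname(ref1@medianPos), 1)
  set.seed(31)
  for (i in 1:20) {
    mm <- matrix(rnorm(200), nrow = 10,
                 dimnames = list(sprintf("g%02d", 1:10), sprintf("P%02d", 1:20)))
    pos <- sample(colnames(mm), 7); neg <- setdiff(colnames(mm), pos)
    rf <- buildReference(mm, pos, neg, rownames(mm))
    expect_equal(unname(rf@medianPos),
                 unname(apply(mm[, pos], 1, median)))
    expect_equal(unname(rf@medianNeg),
                 unname(apply(mm[, neg], 1, median)))
  }
  expect_error(buildReference(m, "P1", "P4", "missing"), "missing")
})

test_that("minimal distance labels phlike, ties and discordance conservatively", {
  genes <- sprintf("g%02d", 1:10)
  posMed <- setNames(rep(5, 10), genes)
  negMed <- setNames(rep(3, 10), genes)
  ref <- new("SignatureReference", geneList = genes, medianPos = posMed,
             medianNeg = negMed, nPos = 10L, nNeg = 10L)
  m <- cbind(atPos = posMed, mid = (posMed + negMed) / 2, atNeg = negMed)
  rownames(m) <- genes
  out <- classifyPhlike(m, ref)
  expect_identical(out$label_A, c("phlike", "non-phlike", "non-phlike"))
  expect_equal(out$d_pos_A[1], 0)
  expect_identical(out$note[2], "tie")           # equidistant -> non-phlike
  # gene-order invariance and non-panel genes ignored
  m2 <- rbind(m[sample(nrow(m)), ], EXTRA = rep(99, 3))
  out2 <- classifyPhlike(m2, ref)
  expect_identical(out2$label_A, out$label_A)
  # uniform scaling preserves labels
  out3 <- classifyPhlike(m * 2, new("SignatureReference", geneList = genes,
                                    medianPos = posMed * 2,
                                    medianNeg = negMed * 2,
                                    nPos = 10L, nNeg = 10L))
  expect_identical(out3$label_A, out$label_A)
  # two panels: final phlike only on agreement
  refB <- new("SignatureReference", geneList = genes[1:5],
              medianPos = negMed[1:5], medianNeg = posMed[1:5],
              nPos = 10L, nNeg = 10L)  # deliberately inverted panel
  outAB <- classifyPhlike(m[, "atPos", drop = FALSE], ref, refB)
  expect_identical(outAB$final, "discordant")
  expect_error(classifyPhlike(m[-1, ], ref), "g01")
})

test_that("a planted signature shift is recovered at high rate", {
  cfg <- simConfig(nSamples = c("BCR-ABL1" = 10L, "bcp-other" = 20L,
                                "phlike" = 10L),
                   nControls = 0L, deletionRate = 0, callerFpRate = 0,
                   seed = 17L)
  ann <- syntheticGeneAnnotation()
  truth <- simulateTruth(cfg, ann)
  se <- renderCounts(truth, ann, cfg)
  expr <- SummarizedExperiment::assay(normalizeExpression(se), "logCPM")
  s <- truth$samples
  pos <- s$sample_id[s$entity == "BCR-ABL1"]
  neg <- s$sample_id[s$subgroup == "bcp-other"][1:10]
  test <- setdiff(s$sample_id, c(pos, neg))
  panels <- defaultPanels(ann)
  refA <- buildReference(expr, pos, neg, panels$panel_a)
  refB <- buildReference(expr, pos, neg, panels$panel_b)
  out <- classifyPhlike(expr[, test, drop = FALSE], refA, refB)
  wants <- s$phlike[match(out$sample_id, s$sample_id)]
  got <- out$final == "phlike"
  expect_gte(mean(got == wants), 0.9)
})
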