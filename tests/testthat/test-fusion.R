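# Harmonization, consensus filters, categorization, entity assignment and
# the comparison tables.

test_that("harmonization maps dialects and normalizes breakend orientation", {
  empty <- mkCall()[0, ]
  expect_equal(nrow(harmonizeFusions(list(a = empty, b = empty))), 0)
  # a breakend-style record reported as B-A on the opposite strand
  flipped <- mkCall(gene5 = "ABL1", gene3 = "BCR", chrom5 = "9", pos5 = 2000L,
                    strand5 = "-", chrom3 = "22", pos3 = 1000L, strand3 = "-")
  h <- harmonizeFusions(list(manta = flipped))
  expect_identical(h$gene5, "BCR")
  expect_identical(h$gene3, "ABL1")
  expect_identical(c(h$pos5, h$pos3), c(1000L, 2000L))
  expect_identical(c(h$strand5, h$strand3), c("+", "+"))
  # caller dialect: schema column -> caller column
  dialect <- list(odd = c(sample_id = "id", gene5 = "gA", gene3 = "gB",
                          chrom5 = "cA", pos5 = "pA", strand5 = "sA",
                          chrom3 = "cB", pos3 = "pB", strand3 = "sB",
                          supporting_reads = "reads"))
  raw <- mkCall()
  names(raw) <- c("id", "gA", "gB", "cA", "pA", "sA", "cB", "pB", "sB", "reads")
  h2 <- harmonizeFusions(list(odd = raw), dialect)
  expect_identical(h2$gene5, "BCR")
  names(raw)[2] <- "wrong"
  expect_error(harmonizeFusions(list(odd = raw), dialect), "odd.*gA")
  expect_error(harmonizeFusions(list(a = mkCall(pos5 = -5L))), "negative")
})

test_that("consensus requires two callers and merges nearby breakpoints", {
  one <- mkCall(); one$caller <- "arriba"
  expect_equal(nrow(consensusFusions(one)), 0)        # single caller dropped
  two <- rbind(one, one)
  two$caller <- c("arriba", "manta")
  two$pos5[2] <- two$pos5[2] + 3L                      # within tolerance
  cc <- consensusFusions(two)
  expect_equal(nrow(cc), 1)
  expect_identical(cc$callers, "arriba,manta")
  expect_equal(cc$n_callers, 2L)
  # caller-order permutation invariance
  cc2 <- consensusFusions(two[2:1, ])
  expect_identical(cc, cc2)
  # breakpoints beyond tolerance stay distinct clusters (each single-caller)
  far <- two; far$pos5[2] <- far$pos5[2] + 500L
  expect_equal(nrow(consensusFusions(far)), 0)
  expect_equal(nrow(consensusFusions(far, minCallers = 1L)), 2)
})

test_that("WGS confirmation matches breakends within the window, either order", {
  cf <- mkConsensus()
  svNear <- data.frame(sample_id = "S1", chrom1 = "22", pos1 = 21000L,
                       chrom2 = "9", pos2 = 22000L, stringsAsFactors = FALSE)
  expect_true(confirmWithWGS(cf, svNear)$wgs_confirmed)     # 20 kb away
  svSwap <- data.frame(sample_id = "S1", chrom1 = "9", pos1 = 2000L,
                       chrom2 = "22", pos2 = 1000L, stringsAsFactors = FALSE)
  expect_true(confirmWithWGS(cf, svSwap)$wgs_confirmed)     # ends swapped
  svFar <- data.frame(sample_id = "S1", chrom1 = "22", pos1 = 200000L,
                      chrom2 = "9", pos2 = 2000L, stringsAsFactors = FALSE)
  expect_false(confirmWithWGS(cf, svFar)$wgs_confirmed)
  expect_false(confirmWithWGS(cf, svNear[0, ])$wgs_confirmed)
})

test_that("control filtering removes shared gene pairs and nothing else", {
  cf <- rbind(mkConsensus(), mkConsensus(gene5 = "GENE0001", gene3 = "GENE0002"))
  out <- filterControls(cf, "GENE0001|GENE0002")
  expect_identical(out$in_controls, c(FALSE, TRUE))
  expect_false(any(filterControls(cf, character())$in_controls))
  out$wgs_confirmed <- TRUE
  fin <- finalConsensus(out)
  expect_equal(nrow(fin$final), 1)
  expect_identical(fin$final$gene5, "BCR")
})

test_that("categorization separates read-throughs, canonical, known, novel", {
  ann <- testAnnotation()
  mk <- function(g5, g3) mkConsensus(gene5 = g5, gene3 = g3,
                                     chrom5 = ann[g5, "chrom"],
                                     chrom3 = ann[g3, "chrom"])
  cf <- rbind(mk("MTAP", "ANRIL"), mk("BCR", "ABL1"), mk("SET", "NUP214"),
              mk("GENE0001", "GENE0002"))
  out <- categorizeFusions(cf, ann)
  expect_identical(out$category,
                   c("read-through", "canonical", "known", "novel"))
  expect_identical(out$deletion_annotation[1], "CDKN2A/B")
  # a collinear pair outside the indicator list needs a spanning deletion
  cf2 <- mk("GENE0001", "GENE0002")
  g5 <- ann["GENE0001", ]; g3 <- ann["GENE0002", ]
  sameChrom <- g5$chrom == g3$chrom
  if (sameChrom) {
    cnv <- data.frame(sample_id = "S1", chrom = g5$chrom,
                      start = min(g5$end, g3$end),
                      end = max(g5$start, g3$start), stringsAsFactors = FALSE)
    out2 <- categorizeFusions(cf2, ann, cnv = cnv)
    expect_identical(out2$category,
                     if (g5$end < g3$start) "read-through" else "novel")
  }
  expect_error(categorizeFusions(mkConsensus(gene5 = "NOPE"), ann), "NOPE")
})

test_that("entity assignment honors wildcards, priority and passengers", {
  cf <- mkConsensus(gene5 = "KMT2A", gene3 = "MLLT10")
  expect_identical(assignEntity(cf)$entity, "KMT2A-r")
  novel <- mkConsensus(gene5 = "GENE0001", gene3 = "GENE0002")
  expect_true(is.na(assignEntity(novel)$entity))
  both <- rbind(mkConsensus(gene5 = "BCR", gene3 = "ABL1"),
                mkConsensus(gene5 = "GENE0001", gene3 = "GENE0002"))
  a <- assignEntity(both)
  expect_identical(a$entity, "BCR-ABL1")
  expect_false(a$conflict)
  # two distinct entities in one sample: priority wins, conflict recorded
  two <- rbind(mkConsensus(gene5 = "BCR", gene3 = "ABL1"),
               mkConsensus(gene5 = "KMT2A", gene3 = "AFF1"))
  a2 <- assignEntity(two)
  expect_identical(a2$entity, "BCR-ABL1")
  expect_true(a2$conflict)
})

test_that("detection-rate table rounds half up and reports false positives", {
  dr <- detectionRate(c(X = 3L), c(X = 1L))
  expect_equal(dr$rate_pct[dr$entity == "X"], 33)
  same <- detectionRate(c(A = 5L, B = 7L), c(A = 5L, B = 7L))
  expect_true(all(same$rate_pct == 100))
  fp <- detectionRate(c(A = 2L), c(A = 1L, B = 3L))
  expect_identical(fp$note[fp$entity == "B"], "not expected")
  expect_true(is.na(fp$rate_pct[fp$entity == "B"]))
  expect_equal(fp$rate_pct[fp$entity == "overall"], 50)
})

test_that("singleton geography splits intra- from inter-chromosomal pairs", {
  cf <- rbind(mkConsensus(gene5 = "A", gene3 = "B", chrom5 = "1", chrom3 = "1"),
              mkConsensus(gene5 = "C", gene3 = "D", chrom5 = "1", chrom3 = "2"),
              mkConsensus(gene5 = "E", gene3 = "F", chrom5 = "3", chrom3 = "3"),
              # recurrent pair: excluded from the singleton set
              mkConsensus("S1", gene5 = "R", gene3 = "R2"),
              mkConsensus("S2", gene5 = "R", gene3 = "R2"))
  g <- fusionGeography(cf)
  expect_equal(g$n_singleton, 3)
  expect_equal(g$n_intra, 2)
  expect_equal(g$intra_pct, 67)   # 66.7 rounds half up to 67
  expect_equal(g$inter_pct, 33)
  expect_equal(g$intra_pct_raw + g$inter_pct_raw, 100)
})
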