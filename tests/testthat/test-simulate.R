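# Synthetic cohort generator: determinism, marginal statistics, truth
# invariants and the rendered data products.

test_that("empty configuration yields an empty cohort deterministically", {
  cfg <- simConfig(nSamples = c("bcp-other" = 0L), nControls = 0L)
  truth <- simulateTruth(cfg)
  expect_equal(nrow(truth$samples), 0)
  expect_equal(nrow(truth$fusions), 0)
  expect_error(simConfig(nSamples = c("bcp-other" = -1L)), "non-negative")
})

test_that("a fixed seed reproduces every rendered product exactly", {
  cfg <- simConfig(nSamples = c("BCR-ABL1" = 2L, "bcp-other" = 3L,
                                "T-ALL" = 2L),
                   nControls = 4L, seed = 7L)
  a <- simulateCohort(cfg)
  b <- simulateCohort(cfg)
  expect_identical(a@truth, b@truth)
  expect_identical(a@snpWts, b@snpWts)
  expect_identical(a@snpWgs, b@snpWgs)
  expect_identical(SummarizedExperiment::assay(a@counts),
                   SummarizedExperiment::assay(b@counts))
  expect_identical(a@fusionCalls, b@fusionCalls)
  expect_identical(a@svCalls, b@svCalls)
})

test_that("genotypes follow Hardy-Weinberg at the panel allele frequency", {
  panel <- syntheticSnpPanel(100)
  panel$maf <- 0.5
  cfg <- simConfig(nSamples = c("bcp-other" = 100L), nControls = 0L,
                   snpPanelSize = 100L, seed = 13L)
  truth <- simulateTruth(cfg, panel = panel)
  het <- mean(truth$genotypes == 1L)
  se3 <- 3 * sqrt(0.5 * 0.5 / length(truth$genotypes))
  expect_lt(abs(het - 0.5), se3)  # 2p(1-p) = 0.5 at p = 0.5
})

test_that("SNP profile rendering matches the binomial read model", {
  cfg <- simConfig(nSamples = c("bcp-other" = 50L), nControls = 0L,
                   errorRate = 0, mixupRate = 0, seed = 19L)
  panel <- syntheticSnpPanel(50)
  truth <- simulateTruth(cfg, panel = panel)
  prof <- renderSnpProfiles(truth, cfg, panel)
  # identity provenance without mix-ups
  expect_identical(prof$provenance$sample_id, prof$provenance$wgs_source)
  # homozygous-alt sites with reads are VAF 1.0 exactly at zero error rate
  dos <- truth$genotypes[cbind(prof$wgs$snp_id,
                               prof$wgs$sample_id)]
  hom <- dos == 2L & prof$wgs$depth > 0
  expect_true(all(prof$wgs$vaf[hom] == 1))
  # heterozygous site VAFs average 0.5 within 3 SE (binomial mean)
  hetIdx <- dos == 1L & prof$wgs$depth > 0
  vafs <- prof$wgs$vaf[hetIdx]
  se3 <- 3 * sqrt(sum(0.25 / prof$wgs$depth[hetIdx])) / sum(hetIdx)
  expect_lt(abs(mean(vafs) - 0.5), se3)
  # the long-tailed WTS depth model leaves a usable fraction under 5 reads
  expect_gt(mean(prof$wts$depth < 5), 0.02)
})

test_that("count rendering reflects dosage, shifts and the noise-free limit", {
  ann <- syntheticGeneAnnotation()
  cfg <- simConfig(nSamples = c("bcp-other" = 2L), nControls = 2L,
                   nbDispersion = 0, dosageTransmission = 1,
                   deletionRate = 0, seed = 23L)
  truth <- simulateTruth(cfg, ann)
  truth$chromosomeCn["4", ] <- 4L
  se <- renderCounts(truth, ann, cfg)
  counts <- SummarizedExperiment::assay(se)
  pat <- truth$samples$sample_id
  # noise-free limit: per-column counts proportional to baseline (x dosage)
  neutralGenes <- ann$gene_id[ann$chrom == "5" &
                              startsWith(ann$gene_id, "GENE") &
                              ann$baseline >= 100]
  ratio <- counts[neutralGenes, pat[1]] / ann[neutralGenes, "baseline"]
  expect_lt(diff(range(ratio)), 0.02)  # identical library factor per column
  # a cn = 4 chromosome doubles the expected mean at full transmission
  chr4 <- ann$gene_id[ann$chrom == "4" & startsWith(ann$gene_id, "GENE") &
                      ann$baseline >= 100]
  r4 <- counts[chr4, pat[1]] / ann[chr4, "baseline"]
  expect_equal(median(r4) / median(ratio), 2, tolerance = 0.02)
  # controls stay at neutral copy number
  ctl <- colnames(se)[se$cohort == "control"]
  rc <- counts[chr4, ctl[1]] / ann[chr4, "baseline"]
  rn <- counts[neutralGenes, ctl[1]] / ann[neutralGenes, "baseline"]
  expect_equal(median(rc) / median(rn), 1, tolerance = 0.02)
})

test_that("fusion tables contain exactly the truth at perfect sensitivity", {
  cfg <- simConfig(nSamples = c("BCR-ABL1" = 3L, "KMT2A-r" = 2L),
                   nControls = 2L,
                   callerSensitivities = c(arriba = 1, starfusion = 1,
                                           manta = 1),
                   callerFpRate = 0, nArtifacts = 0L, deletionRate = 0,
                   seed = 29L)
  ann <- syntheticGeneAnnotation()
  truth <- simulateTruth(cfg, ann)
  fc <- renderFusionCalls(truth, cfg, ann)
  h <- harmonizeFusions(fc$patients)
  for (cl in c("arriba", "starfusion", "manta")) {
    sub <- h[h$caller == cl, ]
    expect_equal(nrow(sub), nrow(truth$fusions))
    expect_setequal(paste(sub$sample_id, sub$gene5, sub$gene3),
                    paste(truth$fusions$sample_id, truth$fusions$gene5,
                          truth$fusions$gene3))
  }
  # the breakend caller's raw table is flipped; harmonization restored it
  raw <- fc$patients$manta
  expect_true(all(raw$strand5 == "-"))
  # artifact pairs are shared between patient and control tables
  cfg2 <- simConfig(nSamples = c("bcp-other" = 2L), nControls = 2L,
                    callerFpRate = 0, nArtifacts = 2L, deletionRate = 0,
                    seed = 29L)
  truth2 <- simulateTruth(cfg2, ann)
  fc2 <- renderFusionCalls(truth2, cfg2, ann)
  patPairs <- unique(paste(fc2$patients$arriba$gene5,
                           fc2$patients$arriba$gene3))
  ctlPairs <- unique(paste(fc2$controls$arriba$gene5,
                           fc2$controls$arriba$gene3))
  expect_equal(length(intersect(patPairs, ctlPairs)), 2)
})

test_that("WGS rendering mirrors truth with bounded jitter", {
  cfg0 <- simConfig(nSamples = c("bcp-other" = 2L), nControls = 0L,
                    deletionRate = 0, seed = 31L)
  truth0 <- simulateTruth(cfg0)
  wgs0 <- renderWgsCalls(truth0, cfg0)
  expect_equal(nrow(wgs0$sv), 0)
  expect_equal(nrow(wgs0$cnv), 0)
  cfg <- simConfig(nSamples = c("BCR-ABL1" = 3L), nControls = 0L,
                   breakpointJitter = 0, deletionRate = 1, seed = 31L)
  truth <- simulateTruth(cfg)
  wgs <- renderWgsCalls(truth, cfg)
  bnd <- wgs$sv[wgs$sv$svtype == "BND", ]
  expect_identical(bnd$pos1, truth$fusions$pos5)  # jitter 0: exact breakends
  expect_identical(bnd$pos2, truth$fusions$pos3)
  expect_equal(nrow(wgs$cnv), nrow(truth$deletions))
  expect_identical(wgs$cnv$start, truth$deletions$start)
  expect_identical(wgs$cnv$end, truth$deletions$end)
})

test_that("truth invariants hold across random configurations", {
  set.seed(37)
  ann <- syntheticGeneAnnotation()
  panel <- syntheticSnpPanel(20)
  for (i in 1:60) {
    n <- setNames(as.integer(sample(0:2, 10, replace = TRUE)),
                  c("BCR-ABL1", "KMT2A-r", "ETV6-RUNX1", "TCF3-PBX1",
                    "other-fusion", "high-hyperdiploid", "low-hypodiploid",
                    "phlike", "bcp-other", "T-ALL"))
    cfg <- simConfig(nSamples = n, nControls = 0L, snpPanelSize = 20L,
                     seed = sample.int(1e6, 1))
    truth <- simulateTruth(cfg, ann, panel)
    s <- truth$samples
    expect_equal(nrow(s), sum(n))
    expect_true(all(!s$phlike | s$entity == "none"))
    expect_equal(nrow(truth$genotypes), nrow(panel))
    for (j in seq_len(nrow(s))) {
      cn <- truth$chromosomeCn[, j]
      if (s$ploidy_group[j] == "high-hyperdiploid")
        expect_gte(sum(cn[c(4, 6, 10, 14, 17, 18, 21)] > 2), 2)
      if (s$ploidy_group[j] == "low-hypodiploid/near-triploid")
        expect_true(sum(cn < 2) >= 5 || all(cn[c(3, 7, 13, 17)] < 2))
      if (s$ploidy_group[j] == "neutral")
        expect_true(all(cn == 2))
    }
    # entity samples carry their defining fusion inside the gene bodies
    ent <- s[s$entity %in% c("BCR-ABL1", "ETV6-RUNX1", "TCF3-PBX1",
                             "KMT2A-r"), ]
    for (sid in ent$sample_id) {
      f <- truth$fusions[truth$fusions$sample_id == sid, ]
      expect_equal(nrow(f), 1)
      g5 <- ann[f$gene5, ]
      expect_true(f$pos5 >= g5$start && f$pos5 <= g5$end)
    }
  }
})
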