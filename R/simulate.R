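# Synthetic cohort generator: planted truth plus the four rendered data
# products (SNP profiles, counts, fusion-caller tables, WGS call tables).

#' Create a simulation configuration
#'
#' All generative parameters of the synthetic ALL cohort. Defaults emulate the
#' study conditions the pipeline was designed for: a 90x WGS assay, a
#' long-tailed WTS depth distribution at SNP sites (so the >= 5-read filter is
#' exercised), 64 healthy control transcriptomes, a 50-SNP genotyping panel,
#' negative-binomial counts with dispersion 0.1, 90% of the log2 copy-number
#' change transmitted to expression, three fusion callers at sensitivity 0.9,
#' a 1.5 log2 kinase-signature shift in BCR-ABL1/Ph-like samples and a 5 log2
#' CRLF2 shift in Ph-like samples.
#'
#' @param nSamples named integer vector of patients per subgroup; valid names:
#'   BCR-ABL1, KMT2A-r, ETV6-RUNX1, TCF3-PBX1, other-fusion, high-hyperdiploid,
#'   low-hypodiploid, phlike, bcp-other, T-ALL
#' @param nControls healthy controls sequenced alongside the cohort
#' @param snpPanelSize genotyping panel size
#' @param nbDispersion NB dispersion (variance = mu + disp * mu^2)
#' @param dosageTransmission fraction of log2 CN change seen in expression
#' @param lineageShift,phlikeShift,crlf2Shift,iamp21Shift log2 expression shifts
#' @param nIamp21 iAMP21-flagged samples planted among bcp-other
#' @param callerSensitivities named per-caller sensitivity
#' @param callerFpRate expected false fusions per sample per caller
#' @param nArtifacts recurrent artifact gene pairs injected into patients and
#'   controls alike
#' @param deletionRate per-BCP-sample probability of one indicator deletion
#' @param mixupRate per-sample probability of initiating a WGS profile swap
#' @param breakpointJitter max DNA-vs-RNA breakpoint offset (bp)
#' @param wtsDepthMeanlog,wtsDepthSdlog,wgsDepthMean SNP-site depth models
#' @param errorRate per-read sequencing error rate
#' @param seed RNG seed; fixed seed gives byte-identical cohorts
#' @return a [SimConfig-class]
#' @export
simConfig <- function(nSamples = c("BCR-ABL1" = 8L, "KMT2A-r" = 5L,
                                   "ETV6-RUNX1" = 2L, "TCF3-PBX1" = 2L,
                                   "other-fusion" = 3L,
                                   "high-hyperdiploid" = 4L,
                                   "low-hypodiploid" = 4L, "phlike" = 6L,
                                   "bcp-other" = 16L, "T-ALL" = 10L),
                      nControls = 64L, snpPanelSize = 50L,
                      nbDispersion = 0.1, dosageTransmission = 0.9,
                      lineageShift = 3, phlikeShift = 1.5, crlf2Shift = 5,
                      iamp21Shift = 2.5, nIamp21 = 0L,
                      callerSensitivities = c(arriba = 0.9, starfusion = 0.9,
                                              manta = 0.9),
                      callerFpRate = 1, nArtifacts = 2L, deletionRate = 0.15,
                      mixupRate = 0, breakpointJitter = 2e4,
                      wtsDepthMeanlog = log(20), wtsDepthSdlog = 1.2,
                      wgsDepthMean = 90, errorRate = 0.002, seed = 1L) {
  groups <- c("BCR-ABL1", "KMT2A-r", "ETV6-RUNX1", "TCF3-PBX1", "other-fusion",
              "high-hyperdiploid", "low-hypodiploid", "phlike", "bcp-other",
              "T-ALL")
  full <- setNames(integer(length(groups)), groups)
  if (length(nSamples)) {
    bad <- setdiff(names(nSamples), groups)
    stopifnot_msg(length(bad) == 0, "unknown subgroup(s): %s",
                  paste(bad, collapse = ", "))
    full[names(nSamples)] <- as.integer(nSamples)
  }
  stopifnot_msg(all(full >= 0), "subgroup counts must be non-negative")
  new("SimConfig", nSamples = full, nControls = as.integer(nControls),
      snpPanelSize = as.integer(snpPanelSize), nbDispersion = nbDispersion,
      dosageTransmission = dosageTransmission, lineageShift = lineageShift,
      phlikeShift = phlikeShift, crlf2Shift = crlf2Shift,
      iamp21Shift = iamp21Shift, nIamp21 = as.integer(nIamp21),
      callerSensitivities = callerSensitivities, callerFpRate = callerFpRate,
      nArtifacts = as.integer(nArtifacts), deletionRate = deletionRate,
      mixupRate = mixupRate, breakpointJitter = breakpointJitter,
      wtsDepthMeanlog = wtsDepthMeanlog, wtsDepthSdlog = wtsDepthSdlog,
      wgsDepthMean = wgsDepthMean, errorRate = errorRate,
      seed = as.integer(seed))
}

# Stage-specific deterministic seed derived from the config seed, kept inside
# 32-bit integer range.
.stageSeed <- function(config, k) {
  as.integer((as.numeric(config@seed) + k * 7919) %% 2147483647)
}

.hyperSet <- c(4, 6, 10, 14, 17, 18, 21)
.hypoMarkers <- c(3, 7, 13, 17)

#' Simulate planted cohort truth
#'
#' Draws per-sample truth: subgroup labels (lineage, entity, ploidy group,
#' Ph-like flag), chromosome copy numbers consistent with the ploidy-group
#' rules, Hardy-Weinberg genotypes over the SNP panel, entity-defining fusions
#' with breakpoints inside the configured gene bodies, and indicator deletions
#' that will surface as read-through chimeras.
#'
#' @param config a [SimConfig-class]
#' @param annotation gene annotation from [syntheticGeneAnnotation()]
#' @param panel SNP panel from [syntheticSnpPanel()]
#' @return truth list: `samples`, `chromosomeCn`, `genotypes`, `fusions`,
#'   `deletions`
#' @export
simulateTruth <- function(config,
                          annotation = syntheticGeneAnnotation(),
                          panel = syntheticSnpPanel(config@snpPanelSize)) {
  validObject(config)
  set.seed(.stageSeed(config, 1))
  n <- sum(config@nSamples)
  subgroup <- rep(names(config@nSamples), config@nSamples)
  samples <- data.frame(
    sample_id = sprintf("PT%03d", seq_len(max(n, 0))),
    subgroup = subgroup,
    lineage = ifelse(subgroup == "T-ALL", "T", "BCP"),
    entity = ifelse(subgroup %in% c("BCR-ABL1", "KMT2A-r", "ETV6-RUNX1",
                                    "TCF3-PBX1"), subgroup,
                    ifelse(subgroup == "other-fusion", "other-fusion", "none")),
    ploidy_group = ifelse(subgroup == "high-hyperdiploid", "high-hyperdiploid",
                   ifelse(subgroup == "low-hypodiploid",
                          "low-hypodiploid/near-triploid", "neutral")),
    phlike = subgroup == "phlike",
    iamp21 = rep(FALSE, n),
    stringsAsFactors = FALSE)[seq_len(n), , drop = FALSE]
  if (config@nIamp21 > 0) {
    idx <- which(samples$subgroup == "bcp-other")
    samples$iamp21[head(idx, config@nIamp21)] <- TRUE
  }

  # chromosome copy numbers
  cn <- matrix(2L, nrow = 22, ncol = n,
               dimnames = list(as.character(1:22), samples$sample_id))
  for (i in seq_len(n)) {
    if (samples$ploidy_group[i] == "high-hyperdiploid") {
      gains <- sample(.hyperSet, sample(3:6, 1))
      extra <- sample(setdiff(1:22, .hyperSet), sample(0:2, 1))
      cn[c(gains, extra), i] <- 3L
      if (21 %in% gains && runif(1) < 0.5) cn[21, i] <- 4L
    } else if (samples$ploidy_group[i] == "low-hypodiploid/near-triploid") {
      losses <- unique(c(.hypoMarkers,
                         sample(setdiff(1:22, .hypoMarkers), sample(2:5, 1))))
      cn[losses, i] <- 1L
    }
  }

  # Hardy-Weinberg genotypes (dosage of the alternate allele)
  geno <- matrix(rbinom(nrow(panel) * n, 2, rep(panel$maf, n)),
                 nrow = nrow(panel),
                 dimnames = list(panel$snp_id, samples$sample_id))

  # entity and other true fusions
  fus <- list()
  kmt2aPartners <- c("AFF1", "MLLT10", "MLLT1", "USP2")
  otherPairs <- list(c("EP300", "ZNF384"), c("TCF3", "ZNF384"),
                     c("BRD9", "NUTM1"), c("EBF1", "PDGFRB"), c("TCF3", "HLF"))
  for (i in seq_len(n)) {
    pair <- switch(samples$entity[i],
      "BCR-ABL1" = c("BCR", "ABL1"),
      "KMT2A-r" = c("KMT2A", sample(kmt2aPartners, 1,
                                    prob = c(0.85, 0.05, 0.05, 0.05))),
      "ETV6-RUNX1" = c("ETV6", "RUNX1"),
      "TCF3-PBX1" = c("TCF3", "PBX1"),
      "other-fusion" = otherPairs[[sample(length(otherPairs), 1)]],
      NULL)
    if (is.null(pair) && samples$lineage[i] == "T" && runif(1) < 0.3)
      pair <- c("SET", "NUP214")   # nuclear-pore fusions recur in T-ALL
    if (!is.null(pair)) {
      g5 <- annotation[pair[1], ]; g3 <- annotation[pair[2], ]
      fus[[length(fus) + 1]] <- data.frame(
        sample_id = samples$sample_id[i], gene5 = pair[1], gene3 = pair[2],
        chrom5 = g5$chrom, pos5 = g5$end - 1000L, strand5 = "+",
        chrom3 = g3$chrom, pos3 = g3$start + 1000L, strand3 = "+",
        stringsAsFactors = FALSE)
    }
  }
  fusions <- if (length(fus)) do.call(rbind, fus) else
    data.frame(sample_id = character(), gene5 = character(),
               gene3 = character(), chrom5 = character(), pos5 = integer(),
               strand5 = character(), chrom3 = character(), pos3 = integer(),
               strand3 = character(), stringsAsFactors = FALSE)

  # indicator deletions -> read-through chimeras downstream
  dels <- list()
  ind <- readthroughIndicators()
  for (i in seq_len(n)) {
    if (samples$lineage[i] == "BCP" && runif(1) < config@deletionRate) {
      r <- ind[sample(nrow(ind), 1), ]
      g5 <- annotation[r$gene5, ]; g3 <- annotation[r$gene3, ]
      dels[[length(dels) + 1]] <- data.frame(
        sample_id = samples$sample_id[i], chrom = g5$chrom,
        start = g5$end + 100L, end = g3$start - 100L,
        gene5 = r$gene5, gene3 = r$gene3, deleted = r$deleted,
        stringsAsFactors = FALSE)
    }
  }
  deletions <- if (length(dels)) do.call(rbind, dels) else
    data.frame(sample_id = character(), chrom = character(), start = integer(),
               end = integer(), gene5 = character(), gene3 = character(),
               deleted = character(), stringsAsFactors = FALSE)

  rownames(samples) <- NULL
  list(samples = samples, chromosomeCn = cn, genotypes = geno,
       fusions = fusions, deletions = deletions)
}

#' Render SNP observation profiles for both assays
#'
#' WGS depth is Poisson around a high mean (default 90, a standard genome
#' coverage); WTS depth is log-normal and long-tailed so that a fraction of
#' sites falls under the 5-read genotyping filter. Observed alternate-read
#' counts are Binomial(depth, p) with p derived from the allele dosage and the
#' sequencing error rate. With probability `mixupRate` a sample initiates a
#' WGS profile swap with another sample; swaps are recorded in the returned
#' provenance table.
#'
#' @param truth output of [simulateTruth()]
#' @param config a [SimConfig-class]
#' @param panel SNP panel table
#' @return list: `wts`, `wgs` (long data.frames sample_id, snp_id, chrom, pos,
#'   depth, vaf) and `provenance` (sample_id, wgs_source)
#' @export
renderSnpProfiles <- function(truth, config,
                              panel = syntheticSnpPanel(config@snpPanelSize)) {
  set.seed(.stageSeed(config, 2))
  ids <- truth$samples$sample_id
  n <- length(ids)
  stopifnot_msg(n > 0, "truth is empty")
  geno <- truth$genotypes
  eps <- config@errorRate

  renderOne <- function(depths, dosages) {
    p <- eps + (dosages / 2) * (1 - 2 * eps)
    alt <- rbinom(length(depths), depths, p)
    ifelse(depths > 0, alt / depths, NA_real_)
  }

  nSnp <- nrow(panel)
  wtsDepth <- pmax(0L, as.integer(round(rlnorm(nSnp * n,
                    config@wtsDepthMeanlog, config@wtsDepthSdlog))))
  wts <- data.frame(
    sample_id = rep(ids, each = nSnp),
    snp_id = rep(panel$snp_id, n), chrom = rep(panel$chrom, n),
    pos = rep(panel$pos, n), depth = wtsDepth,
    vaf = renderOne(wtsDepth, as.vector(geno[, ids, drop = FALSE])),
    stringsAsFactors = FALSE)

  # WGS profile swaps (sample mix-ups)
  source <- setNames(ids, ids)
  if (config@mixupRate > 0 && n > 1) {
    free <- ids
    for (s in ids) {
      if (!(s %in% free) || length(free) < 2) next
      if (runif(1) < config@mixupRate) {
        partner <- sample(setdiff(free, s), 1)
        source[c(s, partner)] <- c(source[partner], source[s])
        free <- setdiff(free, c(s, partner))
      }
    }
  }
  wgsDepth <- rpois(nSnp * n, config@wgsDepthMean)
  wgs <- data.frame(
    sample_id = rep(ids, each = nSnp),
    snp_id = rep(panel$snp_id, n), chrom = rep(panel$chrom, n),
    pos = rep(panel$pos, n), depth = wgsDepth,
    vaf = renderOne(wgsDepth, as.vector(geno[, source[ids], drop = FALSE])),
    stringsAsFactors = FALSE)

  list(wts = wts, wgs = wgs,
       provenance = data.frame(sample_id = ids, wgs_source = unname(source[ids]),
                               stringsAsFactors = FALSE))
}

#' Plant a WTS/WGS sample swap in a rendered cohort
#'
#' Deterministically exchanges the WGS SNP profiles of two samples (the
#' laboratory accident the pairing QC is designed to catch) and updates the
#' provenance table.
#'
#' @param cohort an [ALLCohort-class]
#' @param a,b sample ids to swap
#' @return the modified cohort
#' @export
plantSwap <- function(cohort, a, b) {
  wgs <- cohort@snpWgs
  stopifnot_msg(all(c(a, b) %in% wgs$sample_id), "unknown sample id")
  ia <- wgs$sample_id == a; ib <- wgs$sample_id == b
  wgs$sample_id[ia] <- b; wgs$sample_id[ib] <- a
  wgs <- wgs[order(match(wgs$sample_id, unique(cohort@snpWgs$sample_id))), ]
  rownames(wgs) <- NULL
  cohort@snpWgs <- wgs
  prov <- cohort@provenance
  pa <- prov$sample_id == a; pb <- prov$sample_id == b
  tmp <- prov$wgs_source[pa]
  prov$wgs_source[pa] <- prov$wgs_source[pb]
  prov$wgs_source[pb] <- tmp
  cohort@provenance <- prov
  cohort
}

#' Render raw gene counts for patients and controls
#'
#' Counts are negative-binomial with mean
#' `baseline * libraryFactor * 2^(dosageTransmission * log2(cn/2)) * shifts`,
#' where shifts multiply in lineage markers, the kinase signature (BCR-ABL1
#' and Ph-like samples), CRLF2 (Ph-like) and DYRK1A/CHAF1B (iAMP21 plants).
#' Controls are rendered at neutral copy number with no shifts. A dispersion
#' of (numerically) zero gives the noise-free limit `round(mean)`.
#'
#' @param truth output of [simulateTruth()]
#' @param annotation gene annotation with a `baseline` column
#' @param config a [SimConfig-class]
#' @param signatureGenes character vector of kinase-signature genes receiving
#'   the Ph-like shift (default: union of [defaultPanels()] panels)
#' @return SummarizedExperiment of counts; `colData()$cohort` is "patient" or
#'   "control"
#' @export
renderCounts <- function(truth, annotation, config,
                         signatureGenes = NULL) {
  stopifnot_msg(!anyNA(annotation$chrom), "every gene needs a chromosome")
  set.seed(.stageSeed(config, 3))
  if (is.null(signatureGenes)) {
    p <- defaultPanels(annotation)
    signatureGenes <- union(p$panel_a, p$panel_b)
  }
  samples <- truth$samples
  ids <- samples$sample_id
  nPat <- length(ids); nCtl <- config@nControls
  ctlIds <- if (nCtl > 0) sprintf("CTRL%03d", seq_len(nCtl)) else character()
  genes <- annotation$gene_id
  nG <- length(genes)
  mc <- markerConfig()

  libFac <- rlnorm(nPat + nCtl, 0, 0.15)
  mu <- matrix(annotation$baseline, nrow = nG, ncol = nPat + nCtl,
               dimnames = list(genes, c(ids, ctlIds)))
  mu <- sweep(mu, 2, libFac, `*`)

  cnFac <- 2^(config@dosageTransmission *
              log2(truth$chromosomeCn[annotation$chrom, ids, drop = FALSE] / 2))
  mu[, ids] <- mu[, ids] * cnFac

  for (i in seq_len(nPat)) {
    mk <- if (samples$lineage[i] == "T") mc$t_markers else mc$b_markers
    mu[mk, ids[i]] <- mu[mk, ids[i]] * 2^config@lineageShift
    if (samples$phlike[i] || samples$entity[i] == "BCR-ABL1")
      mu[signatureGenes, ids[i]] <-
        mu[signatureGenes, ids[i]] * 2^config@phlikeShift
    if (samples$phlike[i])
      mu["CRLF2", ids[i]] <- mu["CRLF2", ids[i]] * 2^config@crlf2Shift
    if (samples$iamp21[i])
      mu[c("DYRK1A", "CHAF1B"), ids[i]] <-
        mu[c("DYRK1A", "CHAF1B"), ids[i]] * 2^config@iamp21Shift
  }

  counts <- if (config@nbDispersion < 1e-12) round(mu) else
    matrix(rnbinom(length(mu), mu = mu, size = 1 / config@nbDispersion),
           nrow = nG, dimnames = dimnames(mu))
  storage.mode(counts) <- "integer"
  SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    rowData = annotation,
    colData = S4Vectors::DataFrame(
      sample_id = c(ids, ctlIds),
      cohort = rep(c("patient", "control"), c(nPat, nCtl)),
      row.names = c(ids, ctlIds)))
}

#' Default Ph-like signature gene panels
#'
#' Two overlapping synthetic panels standing in for the published gene lists:
#' panel A has 26 genes, panel B 38, sharing 17 genes (about the two-thirds
#' overlap reported for the real lists).
#'
#' @param annotation gene annotation table
#' @param kA,kB panel sizes
#' @param overlap genes shared between the panels
#' @return list with `panel_a`, `panel_b`
#' @export
defaultPanels <- function(annotation, kA = 26L, kB = 38L, overlap = 17L) {
  free <- annotation$gene_id[startsWith(annotation$gene_id, "GENE")]
  stopifnot_msg(length(free) >= kA + kB - overlap, "gene universe too small")
  panelA <- free[seq_len(kA)]
  panelB <- c(panelA[seq_len(overlap)], free[(kA + 1):(kA + kB - overlap)])
  list(panel_a = panelA, panel_b = panelB)
}

#' Render per-caller fusion tables
#'
#' Each true fusion is emitted by each caller independently at that caller's
#' sensitivity, with small (<= 2 bp) RNA breakpoint jitter between callers.
#' The breakend-style caller ("manta") reports records in flipped orientation
#' (partners swapped, both strands "-"), exercising the harmonization step.
#' Read-through chimeras from planted deletions are emitted only by the two
#' RNA-centric callers. Per-sample false positives are Poisson at
#' `callerFpRate`, and `nArtifacts` recurrent artifact pairs are injected into
#' every patient and control table for the first two callers.
#'
#' @param truth output of [simulateTruth()]
#' @param config a [SimConfig-class]
#' @param annotation gene annotation table
#' @return list: `patients` and `controls`, each a named list of per-caller
#'   data.frames
#' @export
renderFusionCalls <- function(truth, config,
                              annotation = syntheticGeneAnnotation()) {
  set.seed(.stageSeed(config, 4))
  callers <- names(config@callerSensitivities)
  stopifnot_msg(length(callers) >= 1, "callerSensitivities must be named")
  free <- annotation$gene_id[startsWith(annotation$gene_id, "GENE")]
  artifacts <- if (config@nArtifacts > 0)
    data.frame(gene5 = free[seq(100, by = 2, length.out = config@nArtifacts)],
               gene3 = free[seq(101, by = 2, length.out = config@nArtifacts)],
               stringsAsFactors = FALSE) else NULL

  emptyTab <- function() data.frame(
    sample_id = character(), gene5 = character(), gene3 = character(),
    chrom5 = character(), pos5 = integer(), strand5 = character(),
    chrom3 = character(), pos3 = integer(), strand3 = character(),
    supporting_reads = integer(), stringsAsFactors = FALSE)

  mkRow <- function(sid, g5, g3, p5 = NULL, p3 = NULL) {
    a5 <- annotation[g5, ]; a3 <- annotation[g3, ]
    data.frame(sample_id = sid, gene5 = g5, gene3 = g3,
               chrom5 = a5$chrom, pos5 = as.integer(p5 %||% (a5$end - 1000L)),
               strand5 = "+", chrom3 = a3$chrom,
               pos3 = as.integer(p3 %||% (a3$start + 1000L)), strand3 = "+",
               supporting_reads = rpois(1, 20) + 2L, stringsAsFactors = FALSE)
  }
  flip <- function(tab) {
    if (!nrow(tab)) return(tab)
    data.frame(sample_id = tab$sample_id, gene5 = tab$gene3,
               gene3 = tab$gene5, chrom5 = tab$chrom3, pos5 = tab$pos3,
               strand5 = "-", chrom3 = tab$chrom5, pos3 = tab$pos5,
               strand3 = "-", supporting_reads = tab$supporting_reads,
               stringsAsFactors = FALSE)
  }

  renderTables <- function(ids, trueFus, deletions) {
    out <- setNames(vector("list", length(callers)), callers)
    for (ci in seq_along(callers)) {
      sens <- config@callerSensitivities[ci]
      rows <- list()
      if (nrow(trueFus)) for (j in seq_len(nrow(trueFus))) {
        if (runif(1) < sens) {
          r <- trueFus[j, ]
          jit <- sample(-2:2, 2, replace = TRUE)
          rows[[length(rows) + 1]] <- data.frame(
            sample_id = r$sample_id, gene5 = r$gene5, gene3 = r$gene3,
            chrom5 = r$chrom5, pos5 = r$pos5 + jit[1], strand5 = r$strand5,
            chrom3 = r$chrom3, pos3 = r$pos3 + jit[2], strand3 = r$strand3,
            supporting_reads = rpois(1, 20) + 2L, stringsAsFactors = FALSE)
        }
      }
      # read-throughs: RNA-centric callers only (first two)
      if (ci <= 2 && nrow(deletions)) for (j in seq_len(nrow(deletions))) {
        if (runif(1) < sens) {
          d <- deletions[j, ]
          rows[[length(rows) + 1]] <- mkRow(d$sample_id, d$gene5, d$gene3)
        }
      }
      # false positives: random gene pairs, never WGS-supported
      for (sid in ids) {
        nFp <- rpois(1, config@callerFpRate)
        for (k in seq_len(nFp)) {
          pair <- sample(free, 2)
          rows[[length(rows) + 1]] <- mkRow(sid, pair[1], pair[2])
        }
      }
      # recurrent artifacts in every sample (first two callers)
      if (ci <= 2 && !is.null(artifacts)) for (sid in ids)
        for (k in seq_len(nrow(artifacts)))
          rows[[length(rows) + 1]] <- mkRow(sid, artifacts$gene5[k],
                                            artifacts$gene3[k])
      tab <- if (length(rows)) do.call(rbind, rows) else emptyTab()
      if (callers[ci] == "manta") tab <- flip(tab)
      rownames(tab) <- NULL
      out[[ci]] <- tab
    }
    out
  }

  patIds <- truth$samples$sample_id
  ctlIds <- if (config@nControls > 0)
    sprintf("CTRL%03d", seq_len(config@nControls)) else character()
  noFus <- truth$fusions[0, ]; noDel <- truth$deletions[0, ]
  list(patients = renderTables(patIds, truth$fusions, truth$deletions),
       controls = renderTables(ctlIds, noFus, noDel))
}

#' Render WGS structural-variant and copy-number tables
#'
#' Every true fusion yields one SV record whose breakends sit within
#' `breakpointJitter` of the RNA breakpoints (the DNA break falls in an
#' intron, the RNA breakpoint at an exon boundary); every planted deletion
#' yields one deletion SV plus one CNV segment. False-positive fusion calls
#' have no genomic counterpart by construction.
#'
#' @param truth output of [simulateTruth()]
#' @param config a [SimConfig-class]
#' @return list: `sv` (sample_id, chrom1, pos1, chrom2, pos2, svtype) and
#'   `cnv` (sample_id, chrom, start, end, log2, weight)
#' @export
renderWgsCalls <- function(truth, config) {
  set.seed(.stageSeed(config, 5))
  jit <- function(n) as.integer(round(runif(n, -config@breakpointJitter,
                                            config@breakpointJitter)))
  fus <- truth$fusions
  sv <- if (nrow(fus)) data.frame(
    sample_id = fus$sample_id, chrom1 = fus$chrom5,
    pos1 = fus$pos5 + jit(nrow(fus)), chrom2 = fus$chrom3,
    pos2 = fus$pos3 + jit(nrow(fus)), svtype = "BND",
    stringsAsFactors = FALSE) else
    data.frame(sample_id = character(), chrom1 = character(),
               pos1 = integer(), chrom2 = character(), pos2 = integer(),
               svtype = character(), stringsAsFactors = FALSE)
  del <- truth$deletions
  if (nrow(del)) {
    sv <- rbind(sv, data.frame(
      sample_id = del$sample_id, chrom1 = del$chrom,
      pos1 = del$start + pmin(0L, jit(nrow(del))),
      chrom2 = del$chrom, pos2 = del$end + pmax(0L, jit(nrow(del))),
      svtype = "DEL", stringsAsFactors = FALSE))
  }
  cnv <- if (nrow(del)) data.frame(
    sample_id = del$sample_id, chrom = del$chrom, start = del$start,
    end = del$end, log2 = -1, weight = 20, stringsAsFactors = FALSE) else
    data.frame(sample_id = character(), chrom = character(),
               start = integer(), end = integer(), log2 = numeric(),
               weight = numeric(), stringsAsFactors = FALSE)
  rownames(sv) <- rownames(cnv) <- NULL
  list(sv = sv, cnv = cnv)
}

#' Simulate a full synthetic cohort
#'
#' Runs [simulateTruth()] and all four renderers under stage-specific seeds
#' derived from `config@seed`, returning an [ALLCohort-class] ready for
#' [runClassification()].
#'
#' @param config a [SimConfig-class]
#' @param annotation gene annotation (default [syntheticGeneAnnotation()])
#' @param panel SNP panel (default [syntheticSnpPanel()] at the configured size)
#' @return an [ALLCohort-class]
#' @export
simulateCohort <- function(config = simConfig(),
                           annotation = syntheticGeneAnnotation(),
                           panel = syntheticSnpPanel(config@snpPanelSize)) {
  truth <- simulateTruth(config, annotation, panel)
  snp <- renderSnpProfiles(truth, config, panel)
  counts <- renderCounts(truth, annotation, config)
  fus <- renderFusionCalls(truth, config, annotation)
  wgs <- renderWgsCalls(truth, config)
  new("ALLCohort", truth = truth, snpWts = snp$wts, snpWgs = snp$wgs,
      provenance = snp$provenance, counts = counts,
      fusionCalls = fus$patients, controlFusions = fus$controls,
      svCalls = wgs$sv, cnvSegments = wgs$cnv, annotation = annotation,
      snpPanel = panel, config = config)
}
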