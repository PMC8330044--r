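# Stepwise cohort classification: pairing QC -> lineage -> entity fusions ->
# ploidy groups -> Ph-like signature -> residual BCP-ALL 'other'.

#' Classifier configuration
#'
#' Bundles every tunable of the stepwise pipeline with its default.
#'
#' @param hetLow,hetHigh,minDepth genotype-calling bands and depth filter
#' @param flagThreshold pairing concordance flag threshold (default 0.8)
#' @param minTotal gene-filter threshold
#' @param prior log-CPM prior count
#' @param markers lineage marker configuration
#' @param minCallers,bpTolerance,confirmWindow consensus fusion settings
#' @param et entity table; `priority` its label precedence
#' @param kb fusion knowledge base
#' @param indicators read-through indicator table
#' @param ploidy a [ploidyConfig()]
#' @param panelA,panelB Ph-like signature gene lists; NULL derives panel A
#'   (k = 26) and panel B (k = 38) from the cohort's BCR-ABL1 split
#' @param zCut iAMP21 candidate z threshold
#' @param keepUnpaired keep QC-flagged samples in the run (default FALSE:
#'   flagged samples are excluded, as a diagnostic workflow would)
#' @param dialects fusion caller dialect maps
#' @return list of settings for [runClassification()]
#' @export
classifierConfig <- function(hetLow = 0.1, hetHigh = 0.9, minDepth = 5L,
                             flagThreshold = 0.8, minTotal = 2L, prior = 0.5,
                             markers = markerConfig(), minCallers = 2L,
                             bpTolerance = 10L, confirmWindow = 1e5,
                             et = entityTable(),
                             priority = c("BCR-ABL1", "KMT2A-r", "ETV6-RUNX1",
                                          "TCF3-PBX1"),
                             kb = fusionKnowledgeBase(),
                             indicators = readthroughIndicators(),
                             ploidy = ploidyConfig(), panelA = NULL,
                             panelB = NULL, zCut = 2, keepUnpaired = FALSE,
                             dialects = NULL) {
  as.list(environment())
}

#' Run the stepwise classification on a cohort
#'
#' Stage order is strict: (1) WTS/WGS pairing QC by allele concordance, with
#' flagged samples excluded (unless `keepUnpaired`); (2) lineage assignment
#' from marker expression; (3) consensus fusion calling and WHO entity
#' assignment for BCP samples (T-ALL samples keep their fusion evidence but
#' are not subtyped further); (4) expression-derived ploidy groups for BCP
#' samples without an entity; (5) Ph-like classification of the remaining BCP
#' 'other' samples against median reference profiles; (6) the residual is
#' labeled BCP-ALL-other. Advisory flags (iAMP21 candidate, CRLF2-high,
#' discordant panels, low-weight chromosomes) never change the subtype.
#'
#' @param cohort an [ALLCohort-class]
#' @param config a [classifierConfig()]
#' @return an [ALLClassification-class]
#' @export
runClassification <- function(cohort, config = classifierConfig()) {
  ids <- cohort@truth$samples$sample_id
  evidence <- setNames(lapply(ids, function(x)
    data.frame(stage = character(), detail = character(),
               stringsAsFactors = FALSE)), ids)
  note <- function(sid, stage, detail) {
    evidence[[sid]] <<- rbind(evidence[[sid]],
                              data.frame(stage = stage, detail = detail,
                                         stringsAsFactors = FALSE))
  }

  ## 1. pairing QC
  wtsG <- genotypeMatrix(cohort@snpWts, hetLow = config$hetLow,
                         hetHigh = config$hetHigh, minDepth = config$minDepth)
  wgsG <- genotypeMatrix(cohort@snpWgs, hetLow = config$hetLow,
                         hetHigh = config$hetHigh, minDepth = config$minDepth)
  pairing <- pairSamples(wtsG, wgsG, flagThreshold = config$flagThreshold)
  for (i in seq_len(nrow(pairing))) {
    p <- pairing[i, ]
    note(p$wts_sample, "pairing-qc",
         sprintf("best WGS match %s, score %.3f%s", p$best_wgs_sample,
                 p$score, if (p$flagged) " [FLAGGED]" else ""))
  }
  active <- if (config$keepUnpaired) ids else
    pairing$wts_sample[!pairing$flagged]
  for (sid in setdiff(ids, active))
    note(sid, "pairing-qc", "excluded: failed pairing QC")

  ## 2. expression normalization + lineage
  se <- normalizeExpression(cohort@counts, minTotal = config$minTotal,
                            prior = config$prior)
  expr <- .exprMatrix(se)
  patExpr <- expr[, intersect(colnames(expr), active), drop = FALSE]
  ctlIds <- colnames(se)[se$cohort == "control"]
  lin <- classifyLineage(patExpr, config$markers)
  for (i in seq_len(nrow(lin)))
    note(lin$sample_id[i], "lineage",
         sprintf("%s (margin %.2f)", lin$lineage[i], lin$margin[i]))
  lineageOf <- setNames(lin$lineage, lin$sample_id)

  ## 3. consensus fusion calling + entity assignment
  calls <- harmonizeFusions(cohort@fusionCalls, config$dialects)
  calls <- calls[calls$sample_id %in% active, , drop = FALSE]
  cons <- consensusFusions(calls, minCallers = config$minCallers,
                           bpTolerance = config$bpTolerance)
  cons <- confirmWithWGS(cons, cohort@svCalls, window = config$confirmWindow)
  ctrlPairs <- controlFusionPairs(cohort@controlFusions, config$dialects)
  cons <- filterControls(cons, ctrlPairs)
  fc <- finalConsensus(cons)
  final <- categorizeFusions(fc$final, cohort@annotation, config$kb,
                             config$indicators, cohort@cnvSegments)
  for (i in seq_len(nrow(final)))
    note(final$sample_id[i], "fusion",
         sprintf("%s-%s [%s]%s", final$gene5[i], final$gene3[i],
                 final$category[i],
                 ifelse(is.na(final$deletion_annotation[i]), "",
                        paste0(" del:", final$deletion_annotation[i]))))
  ent <- assignEntity(final, config$et, config$priority)
  entityOf <- setNames(ent$entity, ent$sample_id)

  subtype <- setNames(rep(NA_character_, length(ids)), ids)
  subtype[names(lineageOf)[lineageOf == "T"]] <- "T-ALL"
  bcp <- names(lineageOf)[lineageOf == "BCP"]
  for (sid in bcp) {
    e <- entityOf[sid]
    if (!is.na(e) && !is.na(match(sid, names(entityOf)))) {
      subtype[sid] <- e
      note(sid, "entity", sprintf("entity-defining fusion: %s", e))
    }
  }
  # known non-WHO defining fusions keep the sample out of later stages too
  otherFusion <- final$sample_id[final$category %in% c("known") &
                                 !(final$sample_id %in%
                                   names(subtype)[!is.na(subtype)])]
  for (sid in intersect(unique(otherFusion), bcp)) {
    subtype[sid] <- "other-defining-fusion"
    note(sid, "entity", "known defining fusion (non-WHO)")
  }

  ## 4. ploidy groups for entity-less BCP samples
  remaining <- bcp[is.na(subtype[bcp])]
  states <- NULL
  if (length(remaining) && length(ctlIds) >= 2) {
    ref <- referenceProfile(expr, ctlIds, floor = config$ploidy$referenceFloor)
    ratios <- inferGeneLog2(expr[, remaining, drop = FALSE], ref)
    states <- aggregateChromosome(ratios, cohort@annotation, config$ploidy)
    pl <- classifyPloidy(states, config$ploidy)
    for (i in seq_len(nrow(pl))) {
      sid <- pl$sample_id[i]
      note(sid, "ploidy",
           sprintf("%s (%d gains, %d losses)%s", pl$ploidy_group[i],
                   pl$n_gains[i], pl$n_losses[i],
                   ifelse(nzchar(pl$note[i]), paste0(" [", pl$note[i], "]"),
                          "")))
      if (pl$ploidy_group[i] != "none") subtype[sid] <- pl$ploidy_group[i]
    }
  }

  ## 5. Ph-like classification of the residual BCP 'other'
  remaining <- bcp[is.na(subtype[bcp])]
  phk <- NULL
  posIds <- bcp[!is.na(subtype[bcp]) & subtype[bcp] == "BCR-ABL1"]
  negIds <- bcp[!is.na(subtype[bcp]) & subtype[bcp] != "BCR-ABL1"]
  if (length(remaining) && length(posIds) >= 2 && length(negIds) >= 2) {
    panelA <- config$panelA %||%
      selectSignatureGenes(expr, posIds, negIds, k = 26L)
    panelB <- config$panelB %||%
      selectSignatureGenes(expr, posIds, negIds, k = 38L)
    refA <- buildReference(expr, posIds, negIds, panelA)
    refB <- buildReference(expr, posIds, negIds, panelB)
    phk <- classifyPhlike(expr[, remaining, drop = FALSE], refA, refB)
    for (i in seq_len(nrow(phk))) {
      sid <- phk$sample_id[i]
      note(sid, "phlike",
           sprintf("panel A %s / panel B %s -> %s", phk$label_A[i],
                   phk$label_B[i], phk$final[i]))
      if (phk$final[i] == "phlike") subtype[sid] <- "BCR-ABL1-like"
    }
  }

  ## 6. residual
  for (sid in bcp[is.na(subtype[bcp])]) {
    subtype[sid] <- "BCP-ALL-other"
    note(sid, "residual", "no defining abnormality: BCP-ALL-other")
  }

  ## advisory flags
  flags <- setNames(vector("list", length(ids)), ids)
  bcpOther <- names(subtype)[!is.na(subtype) &
                             subtype %in% c("BCP-ALL-other", "BCR-ABL1-like")]
  if (length(bcpOther) >= 4 && "CRLF2" %in% rownames(expr)) {
    bm <- flagBimodalHigh(expr[, bcpOther, drop = FALSE], "CRLF2")
    if (bm$bimodal) for (sid in names(bm$high)[bm$high])
      flags[[sid]] <- c(flags[[sid]], "CRLF2-high")
  }
  noEntity <- bcp[subtype[bcp] %in% c("BCP-ALL-other", "BCR-ABL1-like",
                                      "high-hyperdiploid",
                                      "low-hypodiploid/near-triploid")]
  if (length(noEntity) >= 2 &&
      all(c("DYRK1A", "CHAF1B") %in% rownames(expr))) {
    ia <- iamp21Candidate(expr[, noEntity, drop = FALSE], zCut = config$zCut)
    for (sid in names(ia)[ia]) flags[[sid]] <- c(flags[[sid]],
                                                 "iAMP21-candidate")
  }
  if (!is.null(states)) {
    lw <- unique(states$sample_id[states$low_weight])
    for (sid in lw) flags[[sid]] <- c(flags[[sid]], "low-weight-chromosomes")
  }
  if (!is.null(phk)) for (sid in phk$sample_id[phk$final == "discordant"])
    flags[[sid]] <- c(flags[[sid]], "discordant-panels")
  for (sid in ids) for (fl in flags[[sid]] %||% character())
    note(sid, "advisory", fl)

  results <- data.frame(
    sample_id = ids,
    qc_paired = ids %in% active,
    qc_score = pairing$score[match(ids, pairing$wts_sample)],
    qc_flagged = pairing$flagged[match(ids, pairing$wts_sample)],
    lineage = unname(lineageOf[ids]),
    lineage_margin = lin$margin[match(ids, lin$sample_id)],
    subtype = unname(subtype[ids]),
    advisory_flags = vapply(ids, function(s)
      paste(flags[[s]] %||% character(), collapse = ","), character(1)),
    stringsAsFactors = FALSE)
  rownames(results) <- NULL
  new("ALLClassification", results = results, evidence = evidence,
      pairing = pairing,
      details = list(consensus = cons, final_fusions = final,
                     entities = ent, states = states, phlike = phk))
}

#' Cohort-level report
#'
#' Subtype frequency table, optional detection-rate comparison against
#' cytogenetically expected entity counts, and the advisory-flag summary.
#'
#' @param cls an [ALLClassification-class]
#' @param expected optional named vector of expected entity counts; detected
#'   counts are taken from the classification results
#' @return list: `frequencies`, `comparison` (NULL without `expected`),
#'   `advisory`
#' @export
cohortReport <- function(cls, expected = NULL) {
  res <- cls@results
  stopifnot_msg(nrow(res) > 0, "no results")
  freq <- as.data.frame(table(subtype = res$subtype), stringsAsFactors = FALSE)
  names(freq) <- c("subtype", "n")
  comparison <- NULL
  if (!is.null(expected) && length(expected)) {
    det <- table(res$subtype[res$subtype %in% names(expected)])
    detected <- setNames(as.integer(det), names(det))
    comparison <- detectionRate(expected, detected)
  }
  adv <- unlist(strsplit(res$advisory_flags[nzchar(res$advisory_flags)], ","))
  advisory <- if (length(adv))
    as.data.frame(table(flag = adv), stringsAsFactors = FALSE) else
    data.frame(flag = character(), Freq = integer())
  list(frequencies = freq, comparison = comparison, advisory = advisory)
}
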