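# Expression-derived chromosome copy-number states and rule-based ploidy
# group calls (high hyperdiploid, low hypodiploid/near-triploid).

#' Ploidy-rule configuration
#'
#' All constants of the chromosome-level rule engine. Aberrant states use a
#' symmetric log2 threshold (gain above +threshold, loss below -threshold);
#' "more than" thresholds are strict inequalities.
#'
#' @param log2Threshold aberrant-state threshold on the per-chromosome log2
#'   ratio (default 0.15)
#' @param minWeight minimum supporting genes per chromosome; at or below this
#'   the chromosome is forced neutral with a low-weight flag (default 15)
#' @param minChanges candidate rule: total gains+losses must strictly exceed
#'   this (default 3)
#' @param hypoMinLosses losses needed for the hypodiploid call (default 5)
#' @param hypoMarkerChroms chromosome set whose joint loss also calls
#'   hypodiploid (default 3, 7, 13, 17; conjunction)
#' @param hyperChroms hyperdiploidy-typical chromosomes (default 4, 6, 10, 14,
#'   17, 18, 21)
#' @param hyperMinGained minimum gained chromosomes from `hyperChroms`
#'   (default 2)
#' @param referenceFloor minimum reference median log2 CPM for a gene to be
#'   copy-number informative (default 1)
#' @return list of class parameters used by the ploidy operations
#' @export
ploidyConfig <- function(log2Threshold = 0.15, minWeight = 15, minChanges = 3L,
                         hypoMinLosses = 5L, hypoMarkerChroms = c(3, 7, 13, 17),
                         hyperChroms = c(4, 6, 10, 14, 17, 18, 21),
                         hyperMinGained = 2L, referenceFloor = 1) {
  stopifnot_msg(log2Threshold > 0 && minWeight > 0, "thresholds must be positive")
  list(log2Threshold = log2Threshold, minWeight = minWeight,
       minChanges = as.integer(minChanges),
       hypoMinLosses = as.integer(hypoMinLosses),
       hypoMarkerChroms = as.character(hypoMarkerChroms),
       hyperChroms = as.character(hyperChroms),
       hyperMinGained = as.integer(hyperMinGained),
       referenceFloor = referenceFloor)
}

#' Diploid reference profile from a control cohort
#'
#' Per-gene median log2 CPM over control samples; genes whose reference
#' median falls below the floor are dropped as copy-number uninformative.
#'
#' @param e normalized SummarizedExperiment or log2 CPM matrix (controls only,
#'   or pass `controlIds` to subset)
#' @param controlIds optional sample ids to use
#' @param floor minimum reference median log2 CPM (default 1)
#' @return named numeric vector of reference medians
#' @export
referenceProfile <- function(e, controlIds = NULL, floor = 1) {
  m <- .exprMatrix(e)
  if (!is.null(controlIds)) m <- m[, controlIds, drop = FALSE]
  med <- apply(m, 1, median)
  med[med >= floor]
}

#' Per-gene log2 expression ratios to a diploid reference
#'
#' Sample log2 CPM minus the reference median, median-centered per sample and
#' winsorized at +/- 3. The per-sample centering (standard in CNV inference
#' from expression) anchors the majority-neutral chromosomes at zero:
#' CPM normalization makes values relative to the total transcriptome, so an
#' aneuploid genome would otherwise shift every chromosome, not just the
#' aberrant ones.
#'
#' @param e normalized SummarizedExperiment or log2 CPM matrix
#' @param reference named vector from [referenceProfile()]
#' @param winsor winsorization bound (log2 units)
#' @param center median-center each sample's ratios (default TRUE)
#' @return gene x sample ratio matrix over the informative genes
#' @export
inferGeneLog2 <- function(e, reference, winsor = 3, center = TRUE) {
  m <- .exprMatrix(e)
  genes <- intersect(names(reference), rownames(m))
  stopifnot_msg(length(genes) > 0, "no informative genes shared with reference")
  r <- m[genes, , drop = FALSE] - reference[genes]
  if (center) r <- sweep(r, 2, apply(r, 2, median))
  pmin(pmax(r, -winsor), winsor)
}

#' Aggregate gene ratios into chromosome copy-number states
#'
#' Per chromosome and sample, the 10%-trimmed mean of the gene ratios; weight
#' is the number of contributing genes. When at least five chromosomes carry
#' data, each sample's chromosome values are re-centered by their median:
#' per-gene noise skews the gene-level median in aneuploid samples, whereas
#' the median chromosome is neutral as long as fewer than half the autosomes
#' are aberrant. Chromosomes with weight at or below `minWeight` are forced
#' neutral and flagged low-weight. States follow the symmetric log2
#' threshold.
#'
#' @param ratios gene x sample matrix from [inferGeneLog2()]
#' @param annotation gene annotation mapping genes to autosomes
#' @param cfg a [ploidyConfig()]
#' @param center re-center chromosome values by their per-sample median
#'   (default TRUE; skipped below five informative chromosomes)
#' @return data.frame with sample_id, chrom, log2, state, n_genes, low_weight
#' @export
aggregateChromosome <- function(ratios, annotation, cfg = ploidyConfig(),
                                center = TRUE) {
  chromOf <- setNames(annotation$chrom, annotation$gene_id)
  chroms <- as.character(1:22)
  rows <- list()
  for (s in colnames(ratios)) {
    x <- ratios[, s]
    byChrom <- split(x, factor(chromOf[names(x)], levels = chroms))
    n <- vapply(byChrom, length, integer(1))
    log2v <- vapply(byChrom, function(v)
      if (length(v)) mean(v, trim = 0.1) else NA_real_, numeric(1))
    if (center && sum(!is.na(log2v)) >= 5)
      log2v <- log2v - median(log2v, na.rm = TRUE)
    low <- n <= cfg$minWeight
    state <- ifelse(low | is.na(log2v), "neutral",
             ifelse(log2v > cfg$log2Threshold, "gain",
             ifelse(log2v < -cfg$log2Threshold, "loss", "neutral")))
    rows[[length(rows) + 1]] <- data.frame(
      sample_id = s, chrom = chroms, log2 = unname(log2v),
      state = unname(state), n_genes = unname(n), low_weight = unname(low),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Rule-based ploidy group calls
#'
#' A sample is a candidate when its total chromosome changes (gains plus
#' losses) strictly exceed `minChanges`. Among candidates the hypodiploid rule
#' is evaluated first (at least `hypoMinLosses` losses, or loss of all marker
#' chromosomes), then the hyperdiploid rule (at least `hyperMinGained` of the
#' typical chromosomes gained). A candidate matching neither rule is "none"
#' with a candidate-unresolved note; both rules firing resolves to hypodiploid
#' with a conflict note.
#'
#' @param states per-chromosome state data.frame from [aggregateChromosome()],
#'   or a named character vector of states for a single sample
#' @param cfg a [ploidyConfig()]
#' @return data.frame with sample_id, ploidy_group, n_gains, n_losses, note
#' @export
classifyPloidy <- function(states, cfg = ploidyConfig()) {
  if (is.character(states) && !is.null(names(states))) {
    states <- data.frame(sample_id = "sample", chrom = names(states),
                         state = unname(states), stringsAsFactors = FALSE)
  }
  sid <- factor(states$sample_id, levels = unique(states$sample_id))
  isGain <- states$state == "gain"
  isLoss <- states$state == "loss"
  nG <- as.integer(tapply(isGain, sid, sum))
  nL <- as.integer(tapply(isLoss, sid, sum))
  hyperN <- as.integer(tapply(isGain & states$chrom %in% cfg$hyperChroms,
                              sid, sum))
  markerLost <- as.integer(tapply(isLoss &
                                  states$chrom %in% cfg$hypoMarkerChroms,
                                  sid, sum))
  candidate <- nG + nL > cfg$minChanges
  hypo <- candidate & (nL >= cfg$hypoMinLosses |
                       markerLost == length(cfg$hypoMarkerChroms))
  hyper <- candidate & hyperN >= cfg$hyperMinGained
  group <- rep("none", nlevels(sid))
  group[hyper] <- "high-hyperdiploid"
  group[hypo] <- "low-hypodiploid/near-triploid"
  note <- rep("", nlevels(sid))
  note[candidate & !hypo & !hyper] <- "candidate-unresolved"
  note[hypo & hyper] <- "conflict: both rules fired"
  out <- data.frame(sample_id = levels(sid), ploidy_group = group,
                    n_gains = nG, n_losses = nL, note = note,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(out$sample_id), , drop = FALSE]
}
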