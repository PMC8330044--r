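# Synthetic gene universe, SNP panel and the curated lookup tables used by the
# fusion and expression modules.

# Real marker and fusion-partner gene names reserved in the synthetic universe,
# with the chromosome each one sits on. Coordinates are synthetic; only the
# chromosome assignment (and adjacency for read-through pairs) matters.
.reservedGenes <- function() {
  data.frame(
    gene_id = c(
      # lineage / subtype markers
      "CD19", "CD79A", "CD79B", "MS4A1", "VPREB1",
      "CD3D", "CD3E", "CD3G", "CCR9", "LCK",
      "MME", "CD1A",
      # iAMP21 expression markers
      "DYRK1A", "CHAF1B",
      # entity fusion partners
      "BCR", "ABL1", "KMT2A", "AFF1", "MLLT10", "MLLT1", "USP2",
      "ETV6", "RUNX1", "TCF3", "PBX1",
      # other known partners
      "SET", "NUP214", "ZNF384", "EP300", "NUTM1", "BRD9", "HLF",
      "EBF1", "PDGFRB", "PAX5",
      # read-through pairs (adjacent, same strand) and their deletion targets
      "MTAP", "CDKN2A", "ANRIL",
      "RCBTB2", "RB1", "LPAR6",
      "DLEU2", "MIR15A", "SPRYD7",
      "P2RY8", "CRLF2"),
    chrom = c(
      "16", "19", "17", "11", "22",
      "11", "11", "11", "3", "1",
      "3", "1",
      "21", "21",
      "22", "9", "11", "4", "10", "19", "11",
      "12", "21", "19", "1",
      "9", "9", "12", "22", "15", "5", "17",
      "5", "5", "9",
      "9", "9", "9",
      "13", "13", "13",
      "13", "13", "13",
      "5", "5"),
    stringsAsFactors = FALSE)
}

#' Synthetic gene universe
#'
#' Builds a deterministic gene annotation for 22 autosomes: genes laid out on
#' a 1 Mb grid (50 kb bodies, all on the "+" strand so read-through
#' collinearity reduces to coordinate adjacency), with real marker and
#' fusion-partner gene names reserved at fixed slots and a per-gene baseline
#' expression level drawn from a log-normal. Read-through indicator pairs
#' (e.g. MTAP upstream of ANRIL with CDKN2A in between) occupy consecutive
#' slots so that an intervening deletion produces a collinear chimera.
#'
#' The baseline column is part of the generative model: control and patient
#' counts are both rendered from it, so control medians are a valid diploid
#' reference for copy-number inference.
#'
#' @param nGenes total number of genes (>= number of reserved names)
#' @param seed seed for the baseline draw (the layout is fully deterministic)
#' @return data.frame with gene_id, chrom, start, end, strand, baseline
#' @export
syntheticGeneAnnotation <- function(nGenes = 1100, seed = 1L) {
  reserved <- .reservedGenes()
  stopifnot_msg(nGenes >= nrow(reserved) + 22,
                "nGenes too small for the reserved gene set")
  perChrom <- ceiling(nGenes / 22)
  chrom <- rep(as.character(1:22), each = perChrom)[seq_len(nGenes)]
  ann <- data.frame(gene_id = NA_character_, chrom = chrom,
                    stringsAsFactors = FALSE)
  # slot index within each chromosome
  slot <- stats::ave(seq_len(nGenes), chrom, FUN = seq_along)
  ann$start <- (slot - 1L) * 1e6 + 50001
  ann$end <- ann$start + 49999
  ann$strand <- "+"
  # drop reserved names into the first free slots of their chromosome
  for (i in seq_len(nrow(reserved))) {
    idx <- which(ann$chrom == reserved$chrom[i] & is.na(ann$gene_id))[1]
    stopifnot_msg(!is.na(idx), "no free slot on chromosome %s", reserved$chrom[i])
    ann$gene_id[idx] <- reserved$gene_id[i]
  }
  free <- which(is.na(ann$gene_id))
  ann$gene_id[free] <- sprintf("GENE%04d", seq_along(free))
  old <- .Random.seed_save()
  set.seed(seed)
  ann$baseline <- round(rlnorm(nGenes, meanlog = log(150), sdlog = 1), 2)
  # markers get a solid moderate baseline so shifts are measurable
  ann$baseline[ann$gene_id %in% reserved$gene_id] <- 120
  # CRLF2 is low at baseline; Ph-like samples shift it up (bimodal pattern)
  ann$baseline[ann$gene_id == "CRLF2"] <- 8
  .Random.seed_restore(old)
  rownames(ann) <- ann$gene_id
  ann
}

#' Synthetic genotyping SNP panel
#'
#' Common SNPs (minor allele frequency 0.2-0.5) spread over the autosomes at
#' positions inside expressed gene bodies, so WTS read depth at the sites is
#' expression-driven.
#'
#' @param n panel size
#' @param seed seed for position/frequency draws
#' @return data.frame with snp_id, chrom, pos, maf
#' @export
syntheticSnpPanel <- function(n = 50L, seed = 1L) {
  old <- .Random.seed_save()
  set.seed(seed)
  panel <- data.frame(
    snp_id = sprintf("SNP%03d", seq_len(n)),
    chrom = as.character(sample(1:22, n, replace = TRUE)),
    pos = sample.int(4e7, n),
    maf = round(runif(n, 0.2, 0.5), 3),
    stringsAsFactors = FALSE)
  .Random.seed_restore(old)
  panel
}

# Save/restore the RNG state so deterministic default tables do not perturb a
# caller's random stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}

#' Default lineage marker configuration
#'
#' Twelve lineage markers (five B-cell, five T-cell, plus the CD10/CD1A
#' maturation markers reported as values only): BCP-ALL is characterized by
#' homogeneous CD19 expression while T-ALL expresses CD3D and CCR9.
#'
#' @return list with `b_markers`, `t_markers`, `subtype_markers`
#' @export
markerConfig <- function() {
  list(b_markers = c("CD19", "CD79A", "CD79B", "MS4A1", "VPREB1"),
       t_markers = c("CD3D", "CD3E", "CD3G", "CCR9", "LCK"),
       subtype_markers = c(CD10 = "MME", CD1A = "CD1A"))
}

#' WHO entity table for fusion-based subtyping
#'
#' Gene-pair patterns defining the four fusion entities, in clinical priority
#' order (BCR-ABL1 first). A `*` wildcard on the 3' side covers the KMT2A
#' fusion-partner spectrum (AFF1, MLLT10, MLLT1, USP2, ...).
#'
#' @return data.frame with gene5, gene3, entity
#' @export
entityTable <- function() {
  data.frame(
    gene5 = c("BCR", "KMT2A", "ETV6", "TCF3"),
    gene3 = c("ABL1", "*", "RUNX1", "PBX1"),
    entity = c("BCR-ABL1", "KMT2A-r", "ETV6-RUNX1", "TCF3-PBX1"),
    stringsAsFactors = FALSE)
}

#' Local fusion knowledge base
#'
#' A small curated table of recurrent, previously described fusions standing
#' in for the Mitelman/ChimerDB lookup; pairs in the entity table are
#' "canonical", the rest "known". Anything absent is categorized "novel".
#'
#' @return data.frame with gene5, gene3, status
#' @export
fusionKnowledgeBase <- function() {
  et <- entityTable()
  known <- data.frame(
    gene5 = c("SET", "EP300", "TCF3", "BRD9", "EBF1", "TCF3",
              "KMT2A", "KMT2A", "KMT2A", "KMT2A", "P2RY8"),
    gene3 = c("NUP214", "ZNF384", "ZNF384", "NUTM1", "PDGFRB", "HLF",
              "AFF1", "MLLT10", "MLLT1", "USP2", "CRLF2"),
    status = "known", stringsAsFactors = FALSE)
  rbind(data.frame(gene5 = et$gene5, gene3 = et$gene3, status = "canonical",
                   stringsAsFactors = FALSE), known)
}

#' Read-through deletion indicator table
#'
#' Recurrent read-through chimeras whose presence indicates deletion of an
#' intervening tumor-suppressor locus.
#'
#' @return data.frame with gene5, gene3, deleted
#' @export
readthroughIndicators <- function() {
  data.frame(
    gene5 = c("MTAP", "RCBTB2", "DLEU2", "P2RY8"),
    gene3 = c("ANRIL", "LPAR6", "SPRYD7", "CRLF2"),
    deleted = c("CDKN2A/B", "RB1", "MIR15A/16-1", "PAR1"),
    stringsAsFactors = FALSE)
}
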