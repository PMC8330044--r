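# Plain-text (TSV) interchange for every pipeline input and output.

.writeTsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a gene count matrix as TSV
#'
#' Genes in rows (first column `gene_id`), one column per sample.
#'
#' @param path file path
#' @return `readCountsTsv()` returns an integer matrix with gene rownames
#' @export
readCountsTsv <- function(path) {
  tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- tab[[1]]
  m
}

#' @rdname readCountsTsv
#' @param counts gene x sample matrix or SummarizedExperiment
#' @export
writeCountsTsv <- function(counts, path) {
  m <- if (methods::is(counts, "SummarizedExperiment"))
    SummarizedExperiment::assay(counts, "counts") else counts
  .writeTsv(data.frame(gene_id = rownames(m), m, check.names = FALSE), path)
}

#' Read a long SNP profile table
#'
#' Expects columns sample_id, snp_id, chrom, pos, depth, vaf.
#' @param path file path
#' @return data.frame
#' @export
readSnpProfilesTsv <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(chrom = "character"))
  need <- c("sample_id", "snp_id", "chrom", "pos", "depth", "vaf")
  missing <- setdiff(need, names(tab))
  stopifnot_msg(length(missing) == 0, "SNP profile table lacks column(s): %s",
                paste(missing, collapse = ", "))
  tab
}

#' Read per-caller fusion tables from a directory
#'
#' One `<caller>.tsv` per caller with the harmonized schema columns (or a
#' caller dialect resolvable via the `dialects` argument of
#' [harmonizeFusions()]).
#'
#' @param dir directory of TSV files
#' @return named list of data.frames
#' @export
readFusionTablesTsv <- function(dir) {
  files <- list.files(dir, pattern = "\\.tsv$", full.names = TRUE)
  stopifnot_msg(length(files) > 0, "no .tsv files in %s", dir)
  tabs <- lapply(files, function(f)
    read.delim(f, stringsAsFactors = FALSE,
               colClasses = c(chrom5 = "character", chrom3 = "character")))
  names(tabs) <- sub("\\.tsv$", "", basename(files))
  tabs
}

#' Write a synthetic cohort to a directory of TSV files
#'
#' Emits counts, gene annotation (BED-like, 0-based half-open), SNP profiles
#' for both assays, per-caller fusion tables for patients and controls, WGS
#' SV/CNV tables (1-based positions), truth labels and the mix-up provenance.
#'
#' @param cohort an [ALLCohort-class]
#' @param dir output directory (created if needed)
#' @return the directory, invisibly
#' @export
writeCohortTsv <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeCountsTsv(cohort@counts, file.path(dir, "counts.tsv"))
  ann <- cohort@annotation
  .writeTsv(data.frame(chrom = ann$chrom, start = ann$start - 1L,
                       end = ann$end, gene_id = ann$gene_id,
                       strand = ann$strand, baseline = ann$baseline),
            file.path(dir, "genes.bed.tsv"))
  .writeTsv(cohort@snpWts, file.path(dir, "snp_wts.tsv"))
  .writeTsv(cohort@snpWgs, file.path(dir, "snp_wgs.tsv"))
  .writeTsv(cohort@provenance, file.path(dir, "provenance.tsv"))
  .writeTsv(cohort@truth$samples, file.path(dir, "truth.tsv"))
  .writeTsv(cohort@svCalls, file.path(dir, "sv.tsv"))
  .writeTsv(cohort@cnvSegments, file.path(dir, "cnv.tsv"))
  fdir <- file.path(dir, "fusions"); cdir <- file.path(dir, "control_fusions")
  dir.create(fdir, showWarnings = FALSE); dir.create(cdir, showWarnings = FALSE)
  for (cl in names(cohort@fusionCalls))
    .writeTsv(cohort@fusionCalls[[cl]], file.path(fdir, paste0(cl, ".tsv")))
  for (cl in names(cohort@controlFusions))
    .writeTsv(cohort@controlFusions[[cl]], file.path(cdir, paste0(cl, ".tsv")))
  invisible(dir)
}

#' Write classification results as TSV
#'
#' @param cls an [ALLClassification-class]
#' @param path output file
#' @export
writeResultsTsv <- function(cls, path) {
  .writeTsv(cls@results, path)
}
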