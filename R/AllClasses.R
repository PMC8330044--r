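#' @import methods
#' @importFrom stats median quantile rbinom rnbinom rpois rlnorm runif rnorm setNames kmeans sd binom.test
#' @importFrom utils read.delim write.table head
NULL

#' Simulation configuration for synthetic ALL cohorts
#'
#' Holds every generative parameter of the synthetic cohort generator: how many
#' samples per subgroup, sequencing-noise settings for the SNP profiles, the
#' negative-binomial expression model, fusion-caller behaviour and the rate of
#' planted WTS/WGS sample mix-ups. Construct with [simConfig()].
#'
#' @slot nSamples named integer vector of samples per subgroup
#' @slot nControls number of healthy control transcriptomes
#' @slot snpPanelSize size of the genotyping SNP panel
#' @slot nbDispersion negative-binomial dispersion (variance = mu + disp*mu^2)
#' @slot dosageTransmission fraction of the log2 copy-number change transmitted
#'   to expression (blast-fraction analogue), in (0, 1]
#' @slot lineageShift log2 up-shift of lineage markers in the matching lineage
#' @slot phlikeShift log2 shift applied to the kinase-signature gene set in
#'   BCR-ABL1 and Ph-like samples
#' @slot crlf2Shift log2 CRLF2 up-shift in Ph-like samples (bimodal expression)
#' @slot iamp21Shift log2 up-shift of DYRK1A/CHAF1B in iAMP21-flagged samples
#' @slot nIamp21 number of iAMP21-flagged samples (advisory-flag plant)
#' @slot callerSensitivities named per-caller true-fusion emission probability
#' @slot callerFpRate expected false fusion calls per sample per caller
#' @slot nArtifacts number of recurrent artifact gene pairs injected into both
#'   patient and control tables
#' @slot deletionRate probability a BCP sample carries one of the read-through
#'   indicator deletions
#' @slot mixupRate probability a WGS profile is swapped with another sample's
#' @slot breakpointJitter max DNA-vs-RNA breakpoint offset in bp
#' @slot wtsDepthMeanlog,wtsDepthSdlog log-normal WTS depth model at SNP sites
#' @slot wgsDepthMean mean WGS depth at SNP sites
#' @slot errorRate per-read sequencing error rate at SNP sites
#' @slot seed integer seed; a fixed seed gives byte-identical output
#' @seealso [simConfig()], [simulateCohort()]
#' @export
setClass("SimConfig", representation(
  nSamples = "integer", nControls = "integer", snpPanelSize = "integer",
  nbDispersion = "numeric", dosageTransmission = "numeric",
  lineageShift = "numeric", phlikeShift = "numeric", crlf2Shift = "numeric",
  iamp21Shift = "numeric", nIamp21 = "integer",
  callerSensitivities = "numeric", callerFpRate = "numeric",
  nArtifacts = "integer", deletionRate = "numeric", mixupRate = "numeric",
  breakpointJitter = "numeric", wtsDepthMeanlog = "numeric",
  wtsDepthSdlog = "numeric", wgsDepthMean = "numeric", errorRate = "numeric",
  seed = "integer"))

setValidity("SimConfig", function(object) {
  msg <- character()
  if (any(object@nSamples < 0)) msg <- c(msg, "subgroup counts must be >= 0")
  if (object@nControls < 0) msg <- c(msg, "nControls must be >= 0")
  probs <- c(object@callerSensitivities, object@mixupRate,
             object@deletionRate, object@errorRate)
  if (any(probs < 0 | probs > 1)) msg <- c(msg, "probabilities must lie in [0, 1]")
  if (object@dosageTransmission <= 0 || object@dosageTransmission > 1)
    msg <- c(msg, "dosageTransmission must lie in (0, 1]")
  if (object@nbDispersion < 0) msg <- c(msg, "nbDispersion must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Synthetic ALL cohort with planted truth
#'
#' The full output of [simulateCohort()]: the planted truth (labels, chromosome
#' copy numbers, genotypes, fusions, deletions), and the four rendered data
#' products consumed by the pipeline: SNP profiles for both assays, a combined
#' patient+control count matrix as a [SummarizedExperiment::SummarizedExperiment],
#' per-caller fusion tables, and WGS structural-variant / copy-number tables.
#'
#' @slot truth list with elements `samples` (data.frame of per-sample labels),
#'   `chromosomeCn` (22 x n integer matrix), `genotypes` (SNP x n dosage
#'   matrix), `fusions` and `deletions` (data.frames)
#' @slot snpWts,snpWgs long data.frames (sample_id, snp_id, chrom, pos, depth, vaf)
#' @slot provenance data.frame recording which sample's genotypes each WGS
#'   profile was rendered from (identity unless a mix-up was planted)
#' @slot counts SummarizedExperiment of raw counts; `colData()$cohort` is
#'   "patient" or "control"
#' @slot fusionCalls,controlFusions named lists (one data.frame per caller)
#' @slot svCalls,cnvSegments data.frames of WGS structural-variant breakends
#'   and copy-number segments
#' @slot annotation gene annotation data.frame (gene_id, chrom, start, end,
#'   strand, baseline)
#' @slot snpPanel SNP panel data.frame (snp_id, chrom, pos, maf)
#' @slot config the [SimConfig-class] used
#' @export
setClass("ALLCohort", representation(
  truth = "list", snpWts = "data.frame", snpWgs = "data.frame",
  provenance = "data.frame", counts = "ANY",
  fusionCalls = "list", controlFusions = "list",
  svCalls = "data.frame", cnvSegments = "data.frame",
  annotation = "data.frame", snpPanel = "data.frame", config = "SimConfig"))

#' Median expression reference for Ph-like classification
#'
#' Per-gene median log2 CPM profiles of a BCR-ABL1-positive and a
#' BCR-ABL1-negative reference cohort over a fixed signature gene panel.
#' Construct with [buildReference()].
#'
#' @slot geneList ordered signature gene ids
#' @slot medianPos,medianNeg per-gene medians, aligned to `geneList`
#' @slot nPos,nNeg reference cohort sizes (metadata only; classification does
#'   not weight by n)
#' @export
setClass("SignatureReference", representation(
  geneList = "character", medianPos = "numeric", medianNeg = "numeric",
  nPos = "integer", nNeg = "integer"))

setValidity("SignatureReference", function(object) {
  n <- length(object@geneList)
  if (length(object@medianPos) != n || length(object@medianNeg) != n)
    return("median vectors must align with geneList")
  if (anyNA(c(object@medianPos, object@medianNeg)))
    return("reference medians must not contain NA")
  TRUE
})

#' Stepwise classification result for a cohort
#'
#' Output of [runClassification()]: one row per sample with the QC outcome,
#' lineage, final subtype and advisory flags, plus the per-sample evidence
#' chain (an ordered list of stage/detail records) and the pairing table.
#'
#' @slot results data.frame: sample_id, qc_paired, qc_score, qc_flagged,
#'   lineage, lineage_margin, subtype, advisory_flags
#' @slot evidence named list of per-sample data.frames (stage, detail)
#' @slot pairing the [pairSamples()] table
#' @slot details list of intermediate stage outputs (consensus fusions,
#'   chromosome states, Ph-like calls)
#' @export
setClass("ALLClassification", representation(
  results = "data.frame", evidence = "list", pairing = "data.frame",
  details = "list"))

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", sum(object@nSamples), "patients (",
      paste0(names(object@nSamples)[object@nSamples > 0], "=",
             object@nSamples[object@nSamples > 0], collapse = ", "),
      "), ", object@nControls, " controls, seed ", object@seed, "\n", sep = "")
})

setMethod("show", "ALLCohort", function(object) {
  cat("ALLCohort:", nrow(object@truth$samples), "patients,",
      object@config@nControls, "controls,",
      nrow(object@annotation), "genes,",
      nrow(object@snpPanel), "panel SNPs\n")
  cat("  subgroups:", paste(names(table(object@truth$samples$subgroup)),
      table(object@truth$samples$subgroup), collapse = ", "), "\n")
})

setMethod("show", "SignatureReference", function(object) {
  cat("SignatureReference:", length(object@geneList), "genes;",
      object@nPos, "positive /", object@nNeg, "negative reference samples\n")
})

setMethod("show", "ALLClassification", function(object) {
  cat("ALLClassification:", nrow(object@results), "samples\n")
  print(table(subtype = object@results$subtype, useNA = "ifany"))
})

#' Accessors for classification results
#'
#' @param x an [ALLClassification-class]
#' @return `classificationResults()` returns the per-sample results
#'   data.frame; `classificationEvidence()` the named list of evidence chains;
#'   `pairingTable()` the pairing QC table.
#' @export
classificationResults <- function(x) x@results

#' @rdname classificationResults
#' @export
classificationEvidence <- function(x) x@evidence

#' @rdname classificationResults
#' @export
pairingTable <- function(x) x@pairing

#' Accessors for synthetic cohorts
#'
#' @param x an [ALLCohort-class]
#' @return `cohortTruth()` returns the planted-truth list; `cohortCounts()` the
#'   count SummarizedExperiment; `geneAnnotation()` the gene table.
#' @export
cohortTruth <- function(x) x@truth

#' @rdname cohortTruth
#' @export
cohortCounts <- function(x) x@counts

#' @rdname cohortTruth
#' @export
geneAnnotation <- function(x) x@annotation
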