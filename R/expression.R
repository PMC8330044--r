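# Count filtering, TMM normalization, log2 CPM, lineage classification and
# expression marker flags (CRLF2 bimodality, iAMP21 candidates).

#' Filter non-expressed genes
#'
#' Drops genes that never reach `minTotal` counts in any sample (default 2),
#' preserving axis order.
#'
#' @param counts gene x sample count matrix or a SummarizedExperiment with a
#'   "counts" assay
#' @param minTotal minimum maximum-across-samples count for a gene to be kept
#' @return the filtered object, same class as the input
#' @export
filterGenes <- function(counts, minTotal = 2L) {
  stopifnot_msg(minTotal >= 0, "minTotal must be >= 0")
  m <- if (methods::is(counts, "SummarizedExperiment"))
    SummarizedExperiment::assay(counts, "counts") else counts
  keep <- apply(m, 1, max) >= minTotal
  if (!any(keep)) stop("no expressed genes after filtering", call. = FALSE)
  counts[keep, , drop = FALSE]
}

#' TMM normalization factors
#'
#' Trimmed-mean-of-M-values scaling factors via edgeR: the reference sample is
#' the one whose upper-quartile/library-size ratio is closest to the cohort
#' mean, per-sample log factors are doubly trimmed precision-weighted means of
#' the M values against the reference, and the factors are rescaled to
#' geometric mean 1.
#'
#' @param counts gene x sample count matrix (or SummarizedExperiment)
#' @param trimM,trimA M-value and A-value trim fractions
#' @return named numeric vector of normalization factors
#' @export
tmmFactors <- function(counts, trimM = 0.3, trimA = 0.05) {
  m <- if (methods::is(counts, "SummarizedExperiment"))
    SummarizedExperiment::assay(counts, "counts") else counts
  stopifnot_msg(ncol(m) >= 2, "TMM needs at least two samples")
  bad <- colSums(m) == 0
  if (any(bad))
    stop("sample(s) with no positive genes: ",
         paste(colnames(m)[bad], collapse = ", "), call. = FALSE)
  f <- edgeR::calcNormFactors(m, method = "TMM", logratioTrim = trimM,
                              sumTrim = trimA)
  if (any(!is.finite(f)))
    stop("TMM factor undefined for sample(s): ",
         paste(colnames(m)[!is.finite(f)], collapse = ", "), call. = FALSE)
  setNames(as.numeric(f), colnames(m))
}

#' Log2 counts per million
#'
#' `log2((count + prior) / (libSize * factor + 2 * prior) * 1e6)`, with a
#' fixed per-sample prior count (default 0.5) so zero counts stay finite.
#'
#' @param counts gene x sample count matrix (or SummarizedExperiment)
#' @param factors per-sample normalization factors (default: [tmmFactors()])
#' @param prior prior count added to the numerator (and doubled in the
#'   denominator)
#' @return for a matrix input, the log2 CPM matrix with attributes
#'   `norm.factors` and `lib.sizes`; for a SummarizedExperiment, the object
#'   with a "logCPM" assay and colData columns `norm_factor`, `lib_size`
#' @export
logCPM <- function(counts, factors = NULL, prior = 0.5) {
  stopifnot_msg(prior > 0, "prior must be > 0")
  se <- if (methods::is(counts, "SummarizedExperiment")) counts else NULL
  m <- if (is.null(se)) counts else SummarizedExperiment::assay(se, "counts")
  lib <- colSums(m)
  if (any(lib <= 0)) stop("zero library size", call. = FALSE)
  if (is.null(factors)) factors <- tmmFactors(m)
  stopifnot_msg(all(factors > 0), "factors must be positive")
  eff <- lib * factors[colnames(m)]
  vals <- log2(sweep(m + prior, 2, eff + 2 * prior, `/`) * 1e6)
  if (is.null(se)) {
    attr(vals, "norm.factors") <- factors
    attr(vals, "lib.sizes") <- lib
    return(vals)
  }
  SummarizedExperiment::assay(se, "logCPM") <- vals
  se$norm_factor <- unname(factors[colnames(m)])
  se$lib_size <- unname(lib)
  se
}

#' Filter and normalize a count SummarizedExperiment
#'
#' Convenience wrapper: [filterGenes()] then [logCPM()] with TMM factors.
#'
#' @param se SummarizedExperiment with a "counts" assay
#' @param minTotal gene filter threshold
#' @param prior log-CPM prior count
#' @return the filtered SummarizedExperiment with a "logCPM" assay
#' @export
normalizeExpression <- function(se, minTotal = 2L, prior = 0.5) {
  logCPM(filterGenes(se, minTotal), prior = prior)
}

# Extract the logCPM matrix from either representation.
.exprMatrix <- function(e) {
  if (methods::is(e, "SummarizedExperiment"))
    SummarizedExperiment::assay(e, "logCPM") else e
}

#' Classify lineage from marker expression
#'
#' Nearest-marker-centroid rule on cohort z-scores: per sample, the mean
#' z-scored expression of the B-lineage markers is compared with that of the
#' T-lineage markers; the larger mean wins and the difference is reported as
#' the margin. Exact ties (margin below 1e-9) default to BCP with a warning
#' record so ambiguous samples stay visible.
#'
#' @param e log2 CPM matrix or normalized SummarizedExperiment
#' @param markers a [markerConfig()]-style list
#' @return data.frame with sample_id, lineage, margin, tied
#' @export
classifyLineage <- function(e, markers = markerConfig()) {
  m <- .exprMatrix(e)
  b <- intersect(markers$b_markers, rownames(m))
  t <- intersect(markers$t_markers, rownames(m))
  stopifnot_msg(length(b) >= 3 && length(t) >= 3,
                "need at least 3 markers per lineage in the matrix")
  z <- t(apply(m[c(b, t), , drop = FALSE], 1, rowZ))
  colnames(z) <- colnames(m)
  bScore <- colMeans(z[b, , drop = FALSE])
  tScore <- colMeans(z[t, , drop = FALSE])
  margin <- bScore - tScore
  tied <- abs(margin) < 1e-9
  if (any(tied))
    warning(sprintf("%d sample(s) with tied lineage scores labeled BCP",
                    sum(tied)))
  data.frame(sample_id = colnames(m),
             lineage = ifelse(margin >= 0 | tied, "BCP", "T"),
             margin = unname(margin), tied = unname(tied),
             stringsAsFactors = FALSE)
}

#' Flag samples in the high mode of a bimodally expressed gene
#'
#' A 2-means split (centers initialized at the observed extremes, so the
#' result is deterministic) of one gene's expression across samples; samples
#' above the midpoint of the two cluster centers are flagged high. When the
#' centers are less than `minGap` log2 units apart the gene is declared not
#' bimodal and nothing is flagged.
#'
#' @param e log2 CPM matrix or normalized SummarizedExperiment
#' @param gene gene id
#' @param minGap minimum center separation to accept bimodality (log2 units)
#' @return list: `high` (named logical), `cut` (midpoint or NA), `bimodal`,
#'   `note`
#' @export
flagBimodalHigh <- function(e, gene, minGap = 1) {
  m <- .exprMatrix(e)
  stopifnot_msg(gene %in% rownames(m), "gene %s not in matrix", gene)
  x <- m[gene, ]
  stopifnot_msg(length(x) >= 4, "need at least 4 samples")
  if (diff(range(x)) < .Machine$double.eps^0.5) {
    return(list(high = setNames(rep(FALSE, length(x)), names(x)),
                cut = NA_real_, bimodal = FALSE, note = "not bimodal"))
  }
  km <- kmeans(x, centers = matrix(range(x), ncol = 1))
  centers <- sort(as.numeric(km$centers))
  if (diff(centers) < minGap) {
    return(list(high = setNames(rep(FALSE, length(x)), names(x)),
                cut = NA_real_, bimodal = FALSE, note = "not bimodal"))
  }
  cut <- mean(centers)
  list(high = x > cut, cut = cut, bimodal = TRUE, note = "")
}

#' Flag iAMP21 expression candidates
#'
#' Advisory flag only (never a final subtype): a sample is a candidate when
#' the cohort z-scores of both marker genes exceed `zCut`.
#'
#' @param e log2 CPM matrix or normalized SummarizedExperiment
#' @param markers the two marker genes (default DYRK1A and CHAF1B)
#' @param zCut z-score threshold (default 2)
#' @return named logical vector over samples
#' @export
iamp21Candidate <- function(e, markers = c("DYRK1A", "CHAF1B"), zCut = 2) {
  m <- .exprMatrix(e)
  miss <- setdiff(markers, rownames(m))
  stopifnot_msg(length(miss) == 0, "marker(s) absent from matrix: %s",
                paste(miss, collapse = ", "))
  z <- t(apply(m[markers, , drop = FALSE], 1, rowZ))
  setNames(apply(z > zCut, 2, all), colnames(m))
}
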