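# Genotype calling from VAF tables, allele concordance scoring, WTS/WGS
# best-match pairing, and WTS/WGS variant intersection.

#' Call diploid genotypes from a VAF profile
#'
#' Sites below `minDepth` reads are missing; otherwise the VAF is banded into
#' homozygous-reference, heterozygous and homozygous-alternate calls. The
#' default het band (0.1-0.9) is deliberately wide to tolerate allelic
#' expression imbalance on the RNA side.
#'
#' @param profile data.frame with columns snp_id, depth, vaf (one sample)
#' @param hetLow,hetHigh VAF band for heterozygous calls
#' @param minDepth minimum read depth (default 5; sites below are missing)
#' @return named integer vector of alternate-allele dosages (0, 1, 2; NA for
#'   missing), one entry per panel SNP
#' @export
callGenotypes <- function(profile, hetLow = 0.1, hetHigh = 0.9, minDepth = 5L) {
  stopifnot_msg(hetLow > 0 && hetHigh < 1 && hetLow < hetHigh,
                "need 0 < hetLow < hetHigh < 1")
  stopifnot_msg(minDepth >= 0, "minDepth must be >= 0")
  vaf <- profile$vaf
  ok <- !is.na(vaf)
  if (any(vaf[ok] < 0 | vaf[ok] > 1))
    stop("VAF outside [0, 1]", call. = FALSE)
  g <- ifelse(vaf < hetLow, 0L, ifelse(vaf <= hetHigh, 1L, 2L))
  g[profile$depth < minDepth | is.na(vaf)] <- NA_integer_
  setNames(as.integer(g), profile$snp_id)
}

#' Genotype all samples of a long SNP profile table
#'
#' @param profiles long data.frame (sample_id, snp_id, depth, vaf)
#' @param ... passed to [callGenotypes()]
#' @return SNP x sample integer dosage matrix (NA = missing)
#' @export
genotypeMatrix <- function(profiles, ...) {
  ids <- unique(profiles$sample_id)
  cols <- lapply(ids, function(s)
    callGenotypes(profiles[profiles$sample_id == s, , drop = FALSE], ...))
  snps <- names(cols[[1]])
  mat <- vapply(cols, function(g) g[snps], integer(length(snps)))
  dimnames(mat) <- list(snps, ids)
  mat
}

#' Allele concordance score between two genotype vectors
#'
#' The score is the ratio between the number of identical alleles and the
#' total number of alleles over the SNPs callable in both profiles. Each SNP
#' contributes two alleles; the identical-allele count per SNP is the size of
#' the multiset intersection of the two diploid allele multisets, which for
#' dosages a and b equals `2 - |a - b|`.
#'
#' @param a,b named integer dosage vectors over the same SNP panel
#' @return list with `score` in \[0, 1\] and `n_used`, the number of SNPs
#'   compared
#' @export
concordanceScore <- function(a, b) {
  common <- intersect(names(a), names(b))
  stopifnot_msg(length(common) > 0, "disjoint SNP panels")
  a <- a[common]; b <- b[common]
  use <- !is.na(a) & !is.na(b)
  if (!any(use)) stop("no informative SNPs", call. = FALSE)
  ident <- 2L - abs(a[use] - b[use])
  list(score = sum(ident) / (2 * sum(use)), n_used = sum(use))
}

#' Pair WTS profiles to their best-matching WGS profiles
#'
#' Scores every WTS genotype vector against every WGS vector and reports the
#' argmax. Ties are broken toward the lexicographically smallest WGS id and
#' flagged. A pairing is also flagged when the best score falls below
#' `flagThreshold`, or when a WGS profile with the same sample id exists but
#' scores below the threshold (the mix-up signature: the nominal partner
#' diverges even though some other profile matches well).
#'
#' @param wts,wgs SNP x sample dosage matrices (see [genotypeMatrix()])
#' @param flagThreshold minimum acceptable concordance (default 0.8)
#' @return data.frame with wts_sample, best_wgs_sample, score, n_snps_used,
#'   nominal_score, flagged; all pairwise scores in `attr(, "all_scores")`
#' @export
pairSamples <- function(wts, wgs, flagThreshold = 0.8) {
  stopifnot_msg(ncol(wts) >= 1 && ncol(wgs) >= 1,
                "need at least one profile per assay")
  scores <- matrix(NA_real_, ncol(wts), ncol(wgs),
                   dimnames = list(colnames(wts), colnames(wgs)))
  nUsed <- scores
  for (i in seq_len(ncol(wts))) for (j in seq_len(ncol(wgs))) {
    cs <- tryCatch(concordanceScore(wts[, i], wgs[, j]),
                   error = function(e) list(score = NA_real_, n_used = 0L))
    scores[i, j] <- cs$score; nUsed[i, j] <- cs$n_used
  }
  res <- lapply(seq_len(ncol(wts)), function(i) {
    s <- scores[i, ]
    if (all(is.na(s)))
      return(data.frame(wts_sample = colnames(wts)[i],
                        best_wgs_sample = NA_character_, score = NA_real_,
                        n_snps_used = 0L, nominal_score = NA_real_,
                        flagged = TRUE, stringsAsFactors = FALSE))
    best <- max(s, na.rm = TRUE)
    cand <- sort(names(s)[!is.na(s) & s == best])
    tie <- length(cand) > 1
    nominal <- if (colnames(wts)[i] %in% names(s)) s[[colnames(wts)[i]]]
               else NA_real_
    data.frame(wts_sample = colnames(wts)[i], best_wgs_sample = cand[1],
               score = best, n_snps_used = nUsed[i, cand[1]],
               nominal_score = nominal,
               flagged = tie || best < flagThreshold ||
                 (!is.na(nominal) && nominal < flagThreshold),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  attr(out, "all_scores") <- scores
  out
}

#' Intersect WTS variants with WGS confirmation
#'
#' Keeps WTS variants that passed their caller's filters and whose
#' (chrom, pos, ref, alt) key has a matching WGS call.
#'
#' @param wtsVariants data.frame with chrom, pos, ref, alt, filter
#' @param wgsVariants data.frame with chrom, pos, ref, alt
#' @return the confirmed subset of `wtsVariants`
#' @export
intersectVariants <- function(wtsVariants, wgsVariants) {
  need <- c("chrom", "pos", "ref", "alt")
  stopifnot_msg(all(need %in% names(wtsVariants)) &&
                all(need %in% names(wgsVariants)),
                "variant tables need chrom, pos, ref, alt columns")
  stopifnot_msg("filter" %in% names(wtsVariants),
                "WTS variant table needs a filter column")
  key <- function(tab) paste(tab$chrom, tab$pos, tab$ref, tab$alt, sep = ":")
  keep <- wtsVariants$filter == "PASS" & key(wtsVariants) %in% key(wgsVariants)
  out <- wtsVariants[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
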