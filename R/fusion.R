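# Fusion-call harmonization, consensus building (two-caller support, WGS
# confirmation, control filtering), categorization and entity assignment.

.fusionSchema <- c("sample_id", "gene5", "gene3", "chrom5", "pos5", "strand5",
                   "chrom3", "pos3", "strand3", "supporting_reads")

#' Harmonize per-caller fusion tables
#'
#' Maps each caller's column dialect onto the common schema and canonicalizes
#' orientation: breakend-style callers report a junction read on the opposite
#' strand (both partner strands "-", partners swapped); such records are
#' flipped back to the annotated 5'-to-3' transcript orientation.
#'
#' @param tables named list (caller -> data.frame) of raw calls
#' @param dialects optional named list (caller -> named character vector
#'   mapping schema column -> caller column); callers absent from the list are
#'   assumed to use the schema columns directly
#' @return one data.frame of normalized calls with a `caller` column
#' @export
harmonizeFusions <- function(tables, dialects = NULL) {
  stopifnot_msg(!is.null(names(tables)), "tables must be a named list")
  out <- lapply(names(tables), function(caller) {
    tab <- tables[[caller]]
    map <- dialects[[caller]]
    if (!is.null(map)) {
      missing <- setdiff(unname(map), names(tab))
      stopifnot_msg(length(missing) == 0,
                    "caller %s: unmappable column(s) %s", caller,
                    paste(missing, collapse = ", "))
      tab <- tab[, unname(map), drop = FALSE]
      names(tab) <- names(map)
    }
    missing <- setdiff(.fusionSchema, names(tab))
    stopifnot_msg(length(missing) == 0, "caller %s: missing column(s) %s",
                  caller, paste(missing, collapse = ", "))
    tab <- tab[, .fusionSchema, drop = FALSE]
    if (nrow(tab)) {
      if (any(tab$pos5 < 0 | tab$pos3 < 0))
        stop("negative breakpoint position", call. = FALSE)
      if (!all(c(tab$strand5, tab$strand3) %in% c("+", "-")))
        stop("strands must be '+' or '-'", call. = FALSE)
      flip <- tab$strand5 == "-" & tab$strand3 == "-"
      if (any(flip)) {
        f <- tab[flip, ]
        tab[flip, c("gene5", "gene3")] <- f[, c("gene3", "gene5")]
        tab[flip, c("chrom5", "chrom3")] <- f[, c("chrom3", "chrom5")]
        tab[flip, c("pos5", "pos3")] <- f[, c("pos3", "pos5")]
        tab[flip, c("strand5", "strand3")] <- "+"
      }
      tab$caller <- caller
    } else tab$caller <- character(0)
    tab
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Build consensus fusions across callers
#'
#' Groups harmonized calls per sample by gene pair, merging breakpoint
#' clusters within `bpTolerance` at the RNA level, and keeps groups supported
#' by at least `minCallers` distinct callers. Supporting reads are the max
#' over callers; representative breakpoints are the medians.
#'
#' @param calls harmonized call data.frame (see [harmonizeFusions()])
#' @param minCallers minimum distinct callers (default 2)
#' @param bpTolerance RNA breakpoint merge tolerance in bp (default 10)
#' @return data.frame of consensus records with `callers` (comma-joined),
#'   `n_callers` and `intra_chromosomal`
#' @export
consensusFusions <- function(calls, minCallers = 2L, bpTolerance = 10L) {
  stopifnot_msg(minCallers >= 1, "minCallers must be >= 1")
  empty <- data.frame(sample_id = character(), gene5 = character(),
                      gene3 = character(), chrom5 = character(),
                      pos5 = integer(), chrom3 = character(),
                      pos3 = integer(), strand5 = character(),
                      strand3 = character(), supporting_reads = integer(),
                      callers = character(), n_callers = integer(),
                      intra_chromosomal = logical(), stringsAsFactors = FALSE)
  if (!nrow(calls)) return(empty)
  keyList <- split(calls, paste(calls$sample_id, calls$gene5, calls$gene3,
                                sep = "\r"))
  rows <- lapply(keyList, function(g) {
    g <- g[order(g$pos5, g$pos3), ]
    # single-linkage clustering of 5' breakpoints within tolerance
    cl <- cumsum(c(1L, diff(g$pos5) > bpTolerance))
    do.call(rbind, lapply(split(g, cl), function(h) {
      data.frame(sample_id = h$sample_id[1], gene5 = h$gene5[1],
                 gene3 = h$gene3[1], chrom5 = h$chrom5[1],
                 pos5 = as.integer(median(h$pos5)), chrom3 = h$chrom3[1],
                 pos3 = as.integer(median(h$pos3)), strand5 = h$strand5[1],
                 strand3 = h$strand3[1],
                 supporting_reads = max(h$supporting_reads),
                 callers = paste(sort(unique(h$caller)), collapse = ","),
                 n_callers = length(unique(h$caller)),
                 intra_chromosomal = h$chrom5[1] == h$chrom3[1],
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  out <- out[out$n_callers >= minCallers, , drop = FALSE]
  out <- out[order(out$sample_id, out$gene5, out$gene3), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Confirm consensus fusions against WGS structural variants
#'
#' A consensus fusion is confirmed when an SV record exists (in the same
#' sample) with both breakends on the matching chromosomes within `window` bp
#' of the respective RNA breakpoints, in either end order.
#'
#' @param cf consensus fusion data.frame
#' @param sv SV table (sample_id, chrom1, pos1, chrom2, pos2)
#' @param window matching window in bp (default 1e5, comfortably above
#'   intron-scale DNA/RNA breakpoint offsets)
#' @return `cf` with a logical `wgs_confirmed` column
#' @export
confirmWithWGS <- function(cf, sv, window = 1e5) {
  if (!nrow(cf)) { cf$wgs_confirmed <- logical(0); return(cf) }
  cf$wgs_confirmed <- vapply(seq_len(nrow(cf)), function(i) {
    r <- cf[i, ]
    s <- sv[sv$sample_id == r$sample_id, , drop = FALSE]
    if (!nrow(s)) return(FALSE)
    fwd <- s$chrom1 == r$chrom5 & abs(s$pos1 - r$pos5) <= window &
           s$chrom2 == r$chrom3 & abs(s$pos2 - r$pos3) <= window
    rev <- s$chrom2 == r$chrom5 & abs(s$pos2 - r$pos5) <= window &
           s$chrom1 == r$chrom3 & abs(s$pos1 - r$pos3) <= window
    any(fwd | rev)
  }, logical(1))
  cf
}

#' Build the control fusion pair set
#'
#' Harmonizes and consensus-groups control-cohort tables at `minCallers = 1`
#' (any-caller: the stricter reading of "not detected in controls") and
#' returns the distinct gene pairs seen.
#'
#' @param controlTables named list of per-caller control call tables
#' @param dialects optional dialect maps (see [harmonizeFusions()])
#' @return character vector of "gene5|gene3" pairs
#' @export
controlFusionPairs <- function(controlTables, dialects = NULL) {
  cf <- consensusFusions(harmonizeFusions(controlTables, dialects),
                         minCallers = 1L)
  unique(paste(cf$gene5, cf$gene3, sep = "|"))
}

#' Mark consensus fusions seen in control samples
#'
#' Matching is by gene pair, not breakpoint: recurrent artifacts wander in
#' exact coordinates.
#'
#' @param cf consensus fusion data.frame
#' @param controlPairs pair set from [controlFusionPairs()]
#' @return `cf` with a logical `in_controls` column
#' @export
filterControls <- function(cf, controlPairs) {
  cf$in_controls <- paste(cf$gene5, cf$gene3, sep = "|") %in% controlPairs
  cf
}

#' Apply all three consensus filters
#'
#' The final consensus set: called by at least `minCallers` callers, confirmed
#' by WGS, and not detected in control samples. Records failing a filter are
#' retained in the annotated table but excluded from the final set.
#'
#' @param cf output of [filterControls()] after [confirmWithWGS()]
#' @return list: `final` (surviving records) and `annotated` (all records)
#' @export
finalConsensus <- function(cf) {
  keep <- cf$wgs_confirmed & !cf$in_controls
  final <- cf[keep, , drop = FALSE]
  rownames(final) <- NULL
  list(final = final, annotated = cf)
}

#' Categorize consensus fusions
#'
#' A fusion is a read-through when the partners lie on the same chromosome and
#' strand, collinear in transcriptional order, and either the intervening gap
#' is spanned by a WGS deletion segment or the pair is in the curated
#' deletion-indicator table. Otherwise it is canonical if it matches the
#' entity table, known if present in the local knowledge base, novel
#' otherwise. The `deletion_annotation` column carries the indicator target
#' (e.g. CDKN2A/B) or the named genes overlapped by the supporting deletion.
#'
#' @param cf consensus fusion data.frame
#' @param annotation gene annotation table (gene_id, chrom, start, end, strand)
#' @param kb knowledge base from [fusionKnowledgeBase()]
#' @param indicators indicator table from [readthroughIndicators()]
#' @param cnv optional WGS deletion segment table (sample_id, chrom, start,
#'   end)
#' @return `cf` with `category` and `deletion_annotation` columns
#' @export
categorizeFusions <- function(cf, annotation, kb = fusionKnowledgeBase(),
                              indicators = readthroughIndicators(),
                              cnv = NULL) {
  if (!nrow(cf)) {
    cf$category <- character(0); cf$deletion_annotation <- character(0)
    return(cf)
  }
  missing <- setdiff(unique(c(cf$gene5, cf$gene3)), annotation$gene_id)
  stopifnot_msg(length(missing) == 0, "gene(s) missing from annotation: %s",
                paste(missing, collapse = ", "))
  et <- entityTable()
  kbKey <- paste(kb$gene5, kb$gene3, sep = "|")
  indKey <- paste(indicators$gene5, indicators$gene3, sep = "|")
  canonical <- kbKey[kb$status == "canonical"]

  cf$category <- NA_character_
  cf$deletion_annotation <- NA_character_
  for (i in seq_len(nrow(cf))) {
    g5 <- annotation[cf$gene5[i], ]; g3 <- annotation[cf$gene3[i], ]
    key <- paste(cf$gene5[i], cf$gene3[i], sep = "|")
    rt <- FALSE
    if (g5$chrom == g3$chrom && g5$strand == g3$strand) {
      collinear <- if (g5$strand == "+") g5$end < g3$start else
        g5$start > g3$end
      if (collinear) {
        gap <- if (g5$strand == "+") c(g5$end, g3$start) else
          c(g3$end, g5$start)
        spanned <- FALSE
        if (!is.null(cnv) && nrow(cnv)) {
          seg <- cnv[cnv$sample_id == cf$sample_id[i] &
                     cnv$chrom == g5$chrom, , drop = FALSE]
          spanned <- any(seg$start <= gap[1] + 1 & seg$end >= gap[2] - 1)
          if (spanned) {
            hit <- seg[seg$start <= gap[1] + 1 & seg$end >= gap[2] - 1, ][1, ]
            inside <- annotation$chrom == g5$chrom &
              annotation$start >= hit$start & annotation$end <= hit$end
            cf$deletion_annotation[i] <-
              paste(annotation$gene_id[inside], collapse = ",")
          }
        }
        if (key %in% indKey) {
          rt <- TRUE
          cf$deletion_annotation[i] <- indicators$deleted[match(key, indKey)]
        } else if (spanned) rt <- TRUE
      }
    }
    cf$category[i] <- if (rt) "read-through"
      else if (any(.entityMatch(cf$gene5[i], cf$gene3[i], et))) "canonical"
      else if (key %in% kbKey) "known"
      else "novel"
  }
  cf
}

# Wildcard-aware entity pattern match; returns a logical over entity rows.
.entityMatch <- function(g5, g3, et) {
  (et$gene5 == g5 | et$gene5 == "*") & (et$gene3 == g3 | et$gene3 == "*")
}

#' Assign WHO entities from the final consensus set
#'
#' Per sample, matches fusions against the entity table (wildcards honored)
#' and labels the highest-priority match; multiple distinct matching entities
#' in one sample produce a conflict record.
#'
#' @param cf final consensus fusion data.frame
#' @param et entity table (default [entityTable()], rows in priority order)
#' @param priority entity labels in decreasing clinical priority
#' @return data.frame with sample_id, entity (NA if none), defining_fusion,
#'   conflict
#' @export
assignEntity <- function(cf, et = entityTable(),
                         priority = c("BCR-ABL1", "KMT2A-r", "ETV6-RUNX1",
                                      "TCF3-PBX1")) {
  ids <- unique(cf$sample_id)
  rows <- lapply(ids, function(sid) {
    s <- cf[cf$sample_id == sid, , drop = FALSE]
    hits <- unique(unlist(lapply(seq_len(nrow(s)), function(i) {
      et$entity[.entityMatch(s$gene5[i], s$gene3[i], et)]
    })))
    if (!length(hits))
      return(data.frame(sample_id = sid, entity = NA_character_,
                        defining_fusion = NA_character_, conflict = FALSE,
                        stringsAsFactors = FALSE))
    ord <- hits[order(match(hits, priority))]
    win <- ord[1]
    i <- which(vapply(seq_len(nrow(s)), function(i)
      win %in% et$entity[.entityMatch(s$gene5[i], s$gene3[i], et)],
      logical(1)))[1]
    data.frame(sample_id = sid, entity = win,
               defining_fusion = paste(s$gene5[i], s$gene3[i], sep = "-"),
               conflict = length(hits) > 1, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows) %||%
    data.frame(sample_id = character(), entity = character(),
               defining_fusion = character(), conflict = logical(),
               stringsAsFactors = FALSE)
  if (is.null(out)) return(out)
  rownames(out) <- NULL
  out
}

#' Detection-rate comparison table
#'
#' Per-entity percentage of cytogenetically expected fusions recovered,
#' rounded half up to integer percent, plus an overall row over the entity
#' totals. An entity with detections but zero expectation is reported as a
#' "not expected" row (false positives), not as a rate.
#'
#' @param expected named integer vector: expected fusions per entity
#' @param detected named integer vector: detected fusions per entity
#' @return data.frame with entity, expected, detected, rate_pct, note
#' @export
detectionRate <- function(expected, detected) {
  entities <- union(names(expected), names(detected))
  exp <- setNames(rep(0L, length(entities)), entities)
  det <- exp
  exp[names(expected)] <- as.integer(expected)
  det[names(detected)] <- as.integer(detected)
  rows <- lapply(entities, function(e) {
    if (exp[e] == 0 && det[e] > 0)
      return(data.frame(entity = e, expected = 0L, detected = det[[e]],
                        rate_pct = NA_real_, note = "not expected",
                        stringsAsFactors = FALSE))
    note <- if (det[e] > exp[e]) "false positives" else ""
    data.frame(entity = e, expected = exp[[e]], detected = det[[e]],
               rate_pct = if (exp[e] > 0)
                 halfUp(100 * min(det[[e]], exp[[e]]) / exp[[e]]) else
                 NA_real_,
               note = note, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  ok <- out$note != "not expected"
  overall <- data.frame(
    entity = "overall", expected = sum(out$expected[ok]),
    detected = sum(pmin(out$detected[ok], out$expected[ok])),
    rate_pct = halfUp(100 * sum(pmin(out$detected[ok], out$expected[ok])) /
                      sum(out$expected[ok])),
    note = "", stringsAsFactors = FALSE)
  out <- rbind(out, overall)
  rownames(out) <- NULL
  out
}

#' Singleton-fusion geography
#'
#' Among gene pairs seen in exactly one sample, the percentage of
#' intra-chromosomal versus inter-chromosomal fusions (rounded half up;
#' unrounded values are also returned).
#'
#' @param cf consensus fusion data.frame with `sample_id`, `gene5`, `gene3`
#'   and `intra_chromosomal`
#' @return list: n_singleton, n_intra, n_inter, intra_pct, inter_pct,
#'   intra_pct_raw, inter_pct_raw
#' @export
fusionGeography <- function(cf) {
  pair <- paste(cf$gene5, cf$gene3, sep = "|")
  counts <- table(pair)
  singleton <- names(counts)[counts == 1]
  s <- cf[pair %in% singleton, , drop = FALSE]
  n <- nrow(s)
  stopifnot_msg(n > 0, "no singleton fusions")
  nIntra <- sum(s$intra_chromosomal)
  list(n_singleton = n, n_intra = nIntra, n_inter = n - nIntra,
       intra_pct = halfUp(100 * nIntra / n),
       inter_pct = halfUp(100 * (n - nIntra) / n),
       intra_pct_raw = 100 * nIntra / n,
       inter_pct_raw = 100 * (n - nIntra) / n)
}
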