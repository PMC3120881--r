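# Exon-intron structure comparison between mapped transcripts and the local
# annotation: comparability (>= 50 bp exonic overlap, shared intron),
# compatibility along the common subinterval within a boundary margin V,
# the seven-level best-match priority code, and the Table-style rollup.

#' Exon structure object
#'
#' A light-weight view of an exon-intron structure on a genome: the exon
#' intervals of either an annotated transcript or an alignment projection.
#'
#' @param chrom chromosome id.
#' @param exons data frame with ascending `start`/`end` columns.
#' @param strand optional strand (structures are compared strand-agnostic).
#' @param id,gene_name,evidence carried metadata.
#' @return object of class `ExonStructure`.
#' @export
exon_structure <- function(chrom, exons, strand = "+", id = NULL,
                           gene_name = NULL, evidence = NULL) {
  exons <- data.frame(start = as.integer(exons$start),
                      end = as.integer(exons$end))
  exons <- exons[order(exons$start), , drop = FALSE]
  rownames(exons) <- NULL
  stopifnot(nrow(exons) >= 1L, all(exons$end >= exons$start))
  structure(list(chrom = as.character(chrom), strand = strand,
                 exons = exons, id = id, gene_name = gene_name,
                 evidence = evidence), class = "ExonStructure")
}

#' @rdname exon_structure
#' @param tx a `Transcript`.
#' @export
structure_of_transcript <- function(tx) {
  exon_structure(tx$chrom, tx$exons, tx$strand, id = tx$id,
                 gene_name = tx$gene_name, evidence = tx$evidence)
}

#' Alignment-projected exon structure
#'
#' The comparator consumes the projection of the foreign transcript onto
#' the local genome (its alignment blocks), not its native coordinates.
#'
#' @param aln a `SplicedAlignment`.
#' @param tx optional source `Transcript` supplying gene name and evidence.
#' @export
projected_structure <- function(aln, tx = NULL) {
  exon_structure(aln$chrom,
                 data.frame(start = aln$blocks$gstart,
                            end = aln$blocks$gend),
                 aln$strand, id = aln$query_id,
                 gene_name = if (!is.null(tx)) tx$gene_name,
                 evidence = if (!is.null(tx)) tx$evidence)
}

.struct_span <- function(s) c(min(s$exons$start), max(s$exons$end))

.introns_of <- function(s) {
  n <- nrow(s$exons)
  if (n < 2L) return(data.frame(start = integer(0), end = integer(0)))
  data.frame(start = s$exons$end[-n] + 1L, end = s$exons$start[-1L] - 1L)
}

#' Total exonic overlap between two structures in bp
#' @param a,b `ExonStructure` objects.
#' @export
exonic_overlap <- function(a, b) {
  if (a$chrom != b$chrom) return(0L)
  ia <- IRanges::IRanges(a$exons$start, a$exons$end)
  ib <- IRanges::IRanges(b$exons$start, b$exons$end)
  sum(IRanges::width(IRanges::intersect(ia, ib)))
}

#' Are two structures comparable?
#'
#' Structures are compared only if their exons overlap by at least
#' `min_overlap` bp and, when both have multiple exons, they share at least
#' one intron (both boundaries within the margin).
#'
#' @param a,b `ExonStructure` objects.
#' @param min_overlap minimum exonic overlap in bp.
#' @param margin boundary tolerance V in bp for the shared-intron test.
#' @export
is_comparable <- function(a, b, min_overlap = 50, margin = 20) {
  if (a$chrom != b$chrom) return(FALSE)
  if (exonic_overlap(a, b) < min_overlap) return(FALSE)
  if (nrow(a$exons) > 1L && nrow(b$exons) > 1L) {
    ia <- .introns_of(a); ib <- .introns_of(b)
    shared <- outer(ia$start, ib$start, function(x, y) abs(x - y) <= margin) &
      outer(ia$end, ib$end, function(x, y) abs(x - y) <= margin)
    return(any(shared))
  }
  TRUE
}

# clip a structure to [lo, hi]; drops exons that fall outside
.clip_structure <- function(s, lo, hi) {
  e <- s$exons
  e$start <- pmax(e$start, lo)
  e$end <- pmin(e$end, hi)
  e[e$start <= e$end, , drop = FALSE]
}

#' Are two structures compatible?
#'
#' Compatible means identical exon-intron structure along the genomic
#' interval covered by both, allowing `margin` bp of error at every exon
#' and intron boundary. Symmetric in its arguments.
#'
#' @param a,b `ExonStructure` objects (should be comparable).
#' @param margin boundary tolerance V in bp.
#' @export
is_compatible <- function(a, b, margin = 20) {
  if (a$chrom != b$chrom) return(FALSE)
  lo <- max(min(a$exons$start), min(b$exons$start))
  hi <- min(max(a$exons$end), max(b$exons$end))
  if (lo > hi) return(FALSE)
  ca <- .clip_structure(a, lo, hi)
  cb <- .clip_structure(b, lo, hi)
  if (nrow(ca) == 0L || nrow(cb) == 0L) return(FALSE)
  if (nrow(ca) != nrow(cb)) return(FALSE)
  all(abs(ca$start - cb$start) <= margin) &&
    all(abs(ca$end - cb$end) <= margin)
}

#' Number of common exons between two structures
#'
#' An exon is common when some exon of the other structure matches both of
#' its boundaries within the margin; used as the tie-break when several
#' candidates share a priority code.
#'
#' @param a,b `ExonStructure` objects.
#' @param margin boundary tolerance V in bp.
#' @export
common_exons <- function(a, b, margin = 20) {
  if (a$chrom != b$chrom) return(0L)
  m <- outer(a$exons$start, b$exons$start,
             function(x, y) abs(x - y) <= margin) &
    outer(a$exons$end, b$exons$end, function(x, y) abs(x - y) <= margin)
  sum(apply(m, 1L, any))
}

.match_levels <- c("name_and_evidence", "identical_structure",
                   "single_extension", "double_extension",
                   "single_truncation", "truncation_or_mixed", "complex")

#' Classify a comparable structure pair
#'
#' Assigns the priority code P1..P7: P1 identical gene name and evidence
#' accession (and compatible structures); P2 identical structures (ends
#' within the margin both sides); P3/P4 the candidate extends beyond the
#' mapped structure at one/both ends; P5 the candidate stops short at one
#' end; P6 short at both ends or short at one and long at the other; P7
#' complex (not compatible).
#'
#' @param a the mapped (projected) structure being tracked.
#' @param b the candidate structure from the local annotation.
#' @param margin boundary tolerance V in bp.
#' @return list with integer `level` (1..7) and `label`.
#' @export
classify_pair <- function(a, b, margin = 20) {
  if (!is_comparable(a, b, margin = margin))
    stop("classify_pair: structures are not comparable")
  compatible <- is_compatible(a, b, margin)
  if (!compatible) return(list(level = 7L, label = .match_levels[7L]))
  if (!is.null(a$gene_name) && !is.null(b$gene_name) &&
      !is.null(a$evidence) && !is.null(b$evidence) &&
      identical(a$gene_name, b$gene_name) &&
      identical(a$evidence, b$evidence))
    return(list(level = 1L, label = .match_levels[1L]))
  sa <- .struct_span(a); sb <- .struct_span(b)
  left <- if (sb[1L] < sa[1L] - margin) "ext"
    else if (sb[1L] > sa[1L] + margin) "short" else "same"
  right <- if (sb[2L] > sa[2L] + margin) "ext"
    else if (sb[2L] < sa[2L] - margin) "short" else "same"
  n_ext <- sum(c(left, right) == "ext")
  n_short <- sum(c(left, right) == "short")
  lev <- if (n_short == 0L && n_ext == 0L) 2L
    else if (n_short == 0L && n_ext == 1L) 3L
    else if (n_short == 0L && n_ext == 2L) 4L
    else if (n_short == 1L && n_ext == 0L) 5L
    else 6L
  list(level = lev, label = .match_levels[lev])
}

#' Best match for a mapped structure among candidates
#'
#' The candidate with the lowest priority level wins; ties are broken by
#' the largest number of common exons, then deterministically by lowest
#' genomic start.
#'
#' @param a mapped `ExonStructure`.
#' @param candidates list of candidate `ExonStructure` (already
#'   comparable).
#' @param margin boundary tolerance V in bp.
#' @return list(candidate, class) or `NULL` when `candidates` is empty.
#' @export
assign_best_match <- function(a, candidates, margin = 20) {
  if (length(candidates) == 0L) return(NULL)
  cls <- lapply(candidates, function(b) classify_pair(a, b, margin))
  lev <- vapply(cls, `[[`, integer(1), "level")
  best <- which(lev == min(lev))
  if (length(best) > 1L) {
    ce <- vapply(candidates[best], function(b) common_exons(a, b, margin),
                 integer(1))
    best <- best[ce == max(ce)]
  }
  if (length(best) > 1L) {
    st <- vapply(candidates[best], function(b) min(b$exons$start),
                 integer(1))
    best <- best[which.min(st)]
  }
  best <- best[1L]
  list(candidate = candidates[[best]], class = cls[[best]])
}

#' Compare projected structures against a local annotation
#'
#' For each query, candidate transcripts of the local annotation on the
#' same chromosome are screened with [is_comparable()] and the best match
#' is chosen per the priority code. When a query has several primary
#' alignments, the best match over all of them is reported.
#'
#' @param alns list of `SplicedAlignment` (primaries flagged).
#' @param annotation local `AnnotationSet`.
#' @param source_annotation optional `AnnotationSet` the queries came from
#'   (supplies gene names and evidence accessions for the P1 test).
#' @param margin boundary tolerance V in bp.
#' @param min_overlap minimum exonic overlap in bp.
#' @param use one of `"primary"` (default) or `"all"` alignments.
#' @return data frame: query, candidate, level, label, common_exons
#'   (`NA` candidate when nothing is comparable).
#' @export
compare_annotations <- function(alns, annotation, source_annotation = NULL,
                                margin = 20, min_overlap = 50,
                                use = c("primary", "all")) {
  use <- match.arg(use)
  if (use == "primary") alns <- Filter(function(a) a$is_primary, alns)
  spans <- annotation_spans(annotation)
  structs <- lapply(annotation$transcripts, structure_of_transcript)
  qids <- unique(vapply(alns, `[[`, character(1), "query_id"))
  rows <- lapply(qids, function(qid) {
    qalns <- Filter(function(a) a$query_id == qid, alns)
    tx <- if (!is.null(source_annotation))
      source_annotation$transcripts[[qid]] else NULL
    best <- NULL
    for (al in qalns) {
      pr <- projected_structure(al, tx)
      sp <- .struct_span(pr)
      hit <- spans[spans$chrom == pr$chrom & spans$start <= sp[2L] &
                     spans$end >= sp[1L], ]
      cand <- Filter(function(b) is_comparable(pr, b, min_overlap, margin),
                     structs[hit$id])
      bm <- assign_best_match(pr, cand, margin)
      if (is.null(bm)) next
      if (is.null(best) || bm$class$level < best$class$level ||
          (bm$class$level == best$class$level &&
             common_exons(pr, bm$candidate, margin) > best$ce)) {
        best <- list(pr = pr, candidate = bm$candidate, class = bm$class,
                     ce = common_exons(pr, bm$candidate, margin))
      }
    }
    if (is.null(best))
      return(data.frame(query = qid, candidate = NA_character_,
                        level = NA_integer_, label = NA_character_,
                        common_exons = NA_integer_,
                        stringsAsFactors = FALSE))
    data.frame(query = qid, candidate = best$candidate$id,
               level = best$class$level, label = best$class$label,
               common_exons = best$ce, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Roll up best-match classes into the summary table
#'
#' P1-P2 count as identical, P3-P4 as extensions, P5 as truncations, P6 as
#' both extensions & truncations, P7 as complex structural differences.
#' Percentages are computed against the total of matched transcripts and
#' rounded half-up to one decimal.
#'
#' @param matches data frame from [compare_annotations()].
#' @return data frame (classification, n, pct) in fixed row order, with a
#'   `total` attribute.
#' @export
summarize_classes <- function(matches) {
  lev <- matches$level[!is.na(matches$level)]
  n <- c(identical = sum(lev <= 2L),
         extensions = sum(lev %in% c(3L, 4L)),
         truncations = sum(lev == 5L),
         both = sum(lev == 6L),
         complex = sum(lev == 7L))
  total <- length(lev)
  out <- data.frame(
    classification = c("Identical", "Extensions", "Truncations",
                       "Both extensions & truncations",
                       "Complex structural differences"),
    n = as.integer(n), pct = pct_of(as.integer(n), total),
    stringsAsFactors = FALSE)
  attr(out, "total") <- total
  out
}

#' Agreement curve between mapped genes and the local annotation
#'
#' For each query, the fraction of its (aligned) length whose genomic
#' projection is covered by exons of the local annotation; the curve counts
#' queries with fraction at least x. `all` uses every retained alignment,
#' `best` only primaries.
#'
#' @param alns list of `SplicedAlignment`.
#' @param annotation local `AnnotationSet`.
#' @param query_lengths named integer vector.
#' @param mode `"all"` or `"best"`.
#' @param xs threshold grid.
#' @return data frame (x, count).
#' @export
agreement_curve <- function(alns, annotation, query_lengths,
                            mode = c("all", "best"),
                            xs = seq(0, 1, by = 0.05)) {
  mode <- match.arg(mode)
  use <- if (mode == "best") Filter(function(a) a$is_primary, alns) else alns
  # exonic union of the annotation per chromosome
  ex <- lapply(split(
    do.call(rbind, lapply(annotation$transcripts, function(tx)
      data.frame(chrom = tx$chrom, start = tx$exons$start,
                 end = tx$exons$end, stringsAsFactors = FALSE))),
    ~chrom), function(d)
      IRanges::reduce(IRanges::IRanges(d$start, d$end)))
  qid <- vapply(use, `[[`, character(1), "query_id")
  frac <- vapply(split(use, qid), function(as) {
    L <- query_lengths[[as[[1L]]$query_id]]
    segs <- list()
    for (a in as) {
      ann_ir <- ex[[a$chrom]]
      if (is.null(ann_ir)) next
      for (i in seq_len(nrow(a$blocks))) {
        b <- a$blocks[i, ]
        ov <- IRanges::intersect(IRanges::IRanges(b$gstart, b$gend), ann_ir)
        if (length(ov) == 0L) next
        # map covered genomic sub-ranges back to query offsets
        if (a$strand == "+") {
          qs <- b$qstart + (IRanges::start(ov) - b$gstart)
          qe <- b$qstart + (IRanges::end(ov) - b$gstart)
        } else {
          qe <- b$qend - (IRanges::start(ov) - b$gstart)
          qs <- b$qend - (IRanges::end(ov) - b$gstart)
        }
        segs[[length(segs) + 1L]] <- cbind(qs, qe)
      }
    }
    if (length(segs) == 0L) return(0)
    m <- do.call(rbind, segs)
    covered <- IRanges::reduce(IRanges::IRanges(pmax(1L, m[, 1L]),
                                                pmin(L, m[, 2L])))
    sum(IRanges::width(covered)) / L
  }, numeric(1))
  data.frame(x = xs, count = vapply(xs, function(x) sum(frac >= x),
                                    integer(1)))
}

#' Reciprocal one-to-one correspondences
#'
#' Pairs (a, b) where a's best match is b, b's best match is a, and neither
#' is the best match of any other transcript (an interpretation of clear
#' one-to-one correspondence; gene fragmentation and paralogy break it).
#'
#' @param best_ab data frame from [compare_annotations()] mapping set A
#'   queries to set B candidates.
#' @param best_ba the reverse direction.
#' @return data frame (a, b) of one-to-one pairs.
#' @export
reciprocal_one_to_one <- function(best_ab, best_ba) {
  ab <- best_ab[!is.na(best_ab$candidate), c("query", "candidate")]
  ba <- best_ba[!is.na(best_ba$candidate), c("query", "candidate")]
  if (nrow(ab) == 0L || nrow(ba) == 0L)
    return(data.frame(a = character(0), b = character(0)))
  rows <- list()
  for (i in seq_len(nrow(ab))) {
    a <- ab$query[i]; b <- ab$candidate[i]
    back <- ba$candidate[ba$query == b]
    if (length(back) != 1L || back != a) next
    if (sum(ab$candidate == b) != 1L) next
    if (sum(ba$candidate == a) != 1L) next
    rows[[length(rows) + 1L]] <- data.frame(a = a, b = b,
                                            stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L)
    return(data.frame(a = character(0), b = character(0)))
  do.call(rbind, rows)
}

#' Sequence-level validation of unmatched transcripts
#'
#' Transcripts with no comparable candidate are searched, at the sequence
#' level, against the other annotation's spliced mRNA sequences; local
#' alignments at or above the identity threshold are reported with a
#' completeness flag (full-length versus partial).
#'
#' @param unique_seqs named character vector of spliced sequences of the
#'   unmatched transcripts.
#' @param other_seqs named character vector of the other annotation's
#'   spliced sequences.
#' @param min_identity minimum aligned identity.
#' @param min_len minimum aligned length in bp (screens out the short
#'   perfect matches any two sequences share).
#' @param complete_frac aligned query fraction at or above which a hit is
#'   flagged complete.
#' @return data frame (query, subject, identity, query_coverage, complete).
#' @export
validate_unique <- function(unique_seqs, other_seqs, min_identity = 0.95,
                            min_len = 50, complete_frac = 0.95) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2)
  rows <- list()
  for (q in names(unique_seqs)) {
    for (s in names(other_seqs)) {
      pa <- Biostrings::pairwiseAlignment(
        Biostrings::DNAString(unique_seqs[[q]]),
        Biostrings::DNAString(other_seqs[[s]]),
        type = "local", substitutionMatrix = mat,
        gapOpening = 5, gapExtension = 2)
      alen <- nchar(as.character(Biostrings::alignedPattern(pa)))
      if (alen < min_len) next
      idn <- Biostrings::nmatch(pa) / alen
      if (idn < min_identity) next
      qcov <- (Biostrings::width(Biostrings::pattern(pa))) /
        nchar(unique_seqs[[q]])
      rows[[length(rows) + 1L]] <- data.frame(
        query = q, subject = s, identity = idn, query_coverage = qcov,
        complete = qcov >= complete_frac, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(query = character(0), subject = character(0),
                      identity = numeric(0), query_coverage = numeric(0),
                      complete = logical(0)))
  do.call(rbind, rows)
}
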