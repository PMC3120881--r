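# Lift-over of annotation through the event coordinate map produced by
# apply_events(). The lifted annotation plays the role of the derived
# assembly's own (naively re-derived) annotation: exons falling in gaps or
# excised sequence are dropped, genes split by breakpoints keep their
# largest collinear part, and the CDS is re-derived from surviving coding
# bases (frame-aligned at the start, floored to a codon multiple at the
# end) -- the behaviour expected of an evidence-based annotator run on the
# rearranged sequence.

# map one source interval; returns data.frame of target segments
.lift_segments <- function(map, chrom, start, end) {
  rows <- map[map$kind %in% c("copy", "gap") & !is.na(map$src_chrom) &
                map$src_chrom == chrom & map$src_start <= end &
                map$src_end >= start & map$dup == 0L, , drop = FALSE]
  if (nrow(rows) == 0L)
    return(data.frame(b_chrom = character(0), b_start = integer(0),
                      b_end = integer(0), strand = character(0),
                      kind = character(0), src_start = integer(0),
                      src_end = integer(0)))
  out <- lapply(seq_len(nrow(rows)), function(i) {
    r <- rows[i, ]
    s <- max(start, r$src_start); e <- min(end, r$src_end)
    if (r$strand == "+") {
      bs <- r$b_start + (s - r$src_start)
      be <- r$b_start + (e - r$src_start)
    } else {
      be <- r$b_end - (s - r$src_start)
      bs <- r$b_end - (e - r$src_start)
    }
    data.frame(b_chrom = r$b_chrom, b_start = bs, b_end = be,
               strand = r$strand, kind = r$kind, src_start = s, src_end = e,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# lift a single source position to its primary target position (NULL if lost)
.lift_pos <- function(map, chrom, pos) {
  seg <- .lift_segments(map, chrom, pos, pos)
  seg <- seg[seg$kind == "copy", , drop = FALSE]
  if (nrow(seg) == 0L) return(NULL)
  list(b_chrom = seg$b_chrom[1L], pos = seg$b_start[1L],
       strand = seg$strand[1L])
}

# lift one exon: drop gap-covered parts, merge segments that are adjacent
# in the target (small indels), then keep the largest merged segment
.lift_exon <- function(map, chrom, start, end, merge_gap = 10L) {
  seg <- .lift_segments(map, chrom, start, end)
  seg <- seg[seg$kind == "copy", , drop = FALSE]
  if (nrow(seg) == 0L) return(NULL)
  merged <- list()
  for (bc in unique(seg$b_chrom)) for (st in c("+", "-")) {
    s2 <- seg[seg$b_chrom == bc & seg$strand == st, , drop = FALSE]
    if (nrow(s2) == 0L) next
    s2 <- s2[order(s2$b_start), , drop = FALSE]
    cur <- s2[1L, ]
    for (i in seq_len(nrow(s2))[-1L]) {
      if (s2$b_start[i] - cur$b_end - 1L <= merge_gap) {
        cur$b_end <- max(cur$b_end, s2$b_end[i])
        cur$src_start <- min(cur$src_start, s2$src_start[i])
        cur$src_end <- max(cur$src_end, s2$src_end[i])
      } else {
        merged[[length(merged) + 1L]] <- cur
        cur <- s2[i, ]
      }
    }
    merged[[length(merged) + 1L]] <- cur
  }
  m <- do.call(rbind, merged)
  m[which.max(m$b_end - m$b_start), , drop = FALSE]
}

# lift one transcript; returns a Transcript on the target assembly or NULL
.lift_transcript <- function(tx, map, id = tx$id) {
  n <- nrow(tx$exons)
  lifted <- vector("list", n)
  for (i in seq_len(n)) {
    lifted[[i]] <- .lift_exon(map, tx$chrom, tx$exons$start[i],
                              tx$exons$end[i])
  }
  alive <- which(!vapply(lifted, is.null, logical(1)))
  if (length(alive) == 0L) return(NULL)

  # largest collinear run of surviving exons (in source genomic order)
  link_ok <- function(a, b) {
    a$b_chrom == b$b_chrom && a$strand == b$strand &&
      (if (a$strand == "+") b$b_start > a$b_end else b$b_end < a$b_start)
  }
  runs <- list(); cur <- alive[1L]
  for (i in seq_along(alive)[-1L]) {
    prev <- lifted[[cur[length(cur)]]]
    this <- lifted[[alive[i]]]
    if (link_ok(prev, this)) cur <- c(cur, alive[i])
    else { runs[[length(runs) + 1L]] <- cur; cur <- alive[i] }
  }
  runs[[length(runs) + 1L]] <- cur
  bp <- vapply(runs, function(r) sum(vapply(lifted[r], function(x)
    x$b_end - x$b_start + 1L, numeric(1))), numeric(1))
  run <- runs[[which.max(bp)]]

  seg <- do.call(rbind, lifted[run])
  flip <- seg$strand[1L] == "-"
  b_strand <- if (!flip) tx$strand else if (tx$strand == "+") "-" else "+"
  exons <- data.frame(start = seg$b_start, end = seg$b_end)
  exons <- exons[order(exons$start), , drop = FALSE]

  txb <- transcript(id, seg$b_chrom[1L], b_strand, exons,
                    gene_name = tx$gene_name, evidence = tx$evidence)

  if (is.null(tx$cds)) return(txb)

  # surviving CDS bases, in source transcript coordinates
  surv_t <- list()
  for (i in run) {
    tt <- sort(genome_to_tx(tx, c(lifted[[i]]$src_start,
                                  lifted[[i]]$src_end)))
    lo <- max(tt[1L], tx$cds[1L]); hi <- min(tt[2L], tx$cds[2L])
    if (lo <= hi) surv_t[[length(surv_t) + 1L]] <- c(lo, hi)
  }
  if (length(surv_t) == 0L) return(txb)
  st <- do.call(rbind, surv_t)
  st <- st[order(st[, 1L]), , drop = FALSE]
  a_lo <- st[1L, 1L]; a_hi <- st[nrow(st), 2L]
  # align start to the original reading frame
  a_lo <- a_lo + (3L - (a_lo - tx$cds[1L]) %% 3L) %% 3L
  if (a_lo > a_hi) return(txb)

  g1 <- tx_to_genome(tx, a_lo, a_lo)
  g2 <- tx_to_genome(tx, a_hi, a_hi)
  p1 <- .lift_pos(map, tx$chrom, g1$start[1L])
  p2 <- .lift_pos(map, tx$chrom, g2$start[1L])
  if (is.null(p1) || is.null(p2)) return(txb)
  t1 <- genome_to_tx(txb, p1$pos)
  t2 <- genome_to_tx(txb, p2$pos)
  if (is.na(t1) || is.na(t2)) return(txb)
  lo <- min(t1, t2); hi <- max(t1, t2)
  hi <- hi - (hi - lo + 1L) %% 3L
  if (hi - lo + 1L < 6L) return(txb)
  transcript(id, txb$chrom, txb$strand, txb$exons, cds = c(lo, hi),
             gene_name = tx$gene_name, evidence = tx$evidence)
}

#' Lift an annotation set through an event map
#'
#' Produces the derived assembly's annotation from the source annotation and
#' the coordinate map returned by [apply_events()]. Genes wholly inside a
#' duplicated segment are annotated at both loci (the copy gets a
#' `_dupN`-suffixed transcript id but keeps the gene name and evidence
#' accession). Genes whose sequence is entirely lost are absent from the
#' result.
#'
#' @param annotation source `AnnotationSet`.
#' @param map coordinate map from [apply_events()].
#' @param genome_b optional target `GenomeAssembly` for validation.
#' @param assembly_name label for the returned set.
#' @return an `AnnotationSet` on the target assembly.
#' @export
lift_annotation <- function(annotation, map, genome_b = NULL,
                            assembly_name = "assembly_B") {
  out <- list()
  dup_ids <- setdiff(unique(map$dup), 0L)
  for (tx in annotation$transcripts) {
    txb <- .lift_transcript(tx, map)
    if (!is.null(txb)) out[[length(out) + 1L]] <- txb
    sp <- tx_span(tx)
    for (d in dup_ids) {
      dup_rows <- map[map$dup == d, , drop = FALSE]
      if (any(dup_rows$src_chrom == tx$chrom &
                dup_rows$src_start <= sp[1L] & dup_rows$src_end >= sp[1L]) &&
          any(dup_rows$src_chrom == tx$chrom &
                dup_rows$src_start <= sp[2L] & dup_rows$src_end >= sp[2L])) {
        txd <- .lift_dup_transcript(tx, map, d)
        if (!is.null(txd)) out[[length(out) + 1L]] <- txd
      }
    }
  }
  annotation_set(out, assembly_name = assembly_name, genome = genome_b)
}

# lift a transcript through one duplicate copy of a segment
.lift_dup_transcript <- function(tx, map, dup_instance) {
  dmap <- map[map$dup == dup_instance, , drop = FALSE]
  dmap$dup <- 0L
  .lift_transcript(tx, dmap, id = paste0(tx$id, "_dup", dup_instance))
}
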