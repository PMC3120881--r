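#' Genome assembly container
#'
#' Holds named chromosome sequences plus an optional pool of unplaced
#' contigs. All downstream stages (alignment, simulation, SNP mapping) act on
#' this container. By default only placed chromosomes are searched; the
#' unplaced pool is kept separate because unplaced sequence behaves very
#' differently for annotation and SNP recovery.
#'
#' @param placed named character vector of chromosome sequences (A/C/G/T/N).
#' @param unplaced named character vector of unplaced contig sequences.
#' @param name a label for the assembly.
#' @return an object of class `GenomeAssembly`.
#' @export
genome_assembly <- function(placed, unplaced = character(0), name = "genome") {
  placed <- toupper(unlist(placed))
  unplaced <- toupper(unlist(unplaced))
  if (length(placed) == 0L) stop("assembly needs at least one placed sequence")
  ids <- c(names(placed), names(unplaced))
  if (is.null(names(placed)) || any(!nzchar(ids)))
    stop("all sequences must be named")
  if (anyDuplicated(ids))
    stop("duplicate sequence id: ", ids[duplicated(ids)][1L])
  seqs <- c(placed, unplaced)
  if (any(nchar(seqs) == 0L))
    stop("empty sequence: ", ids[nchar(seqs) == 0L][1L])
  bad <- !is_dna_string(seqs)
  if (any(bad))
    stop("sequence with characters outside {A,C,G,T,N}: ", ids[bad][1L])
  structure(list(name = name, placed = placed, unplaced = unplaced),
            class = "GenomeAssembly")
}

#' @export
print.GenomeAssembly <- function(x, ...) {
  cat(sprintf("GenomeAssembly '%s': %d placed (%s bp), %d unplaced (%s bp)\n",
              x$name, length(x$placed),
              format(sum(nchar(x$placed)), big.mark = ","),
              length(x$unplaced),
              format(sum(nchar(x$unplaced)), big.mark = ",")))
  invisible(x)
}

#' Look up one sequence of an assembly by id (placed or unplaced)
#' @param genome a `GenomeAssembly`.
#' @param id sequence id.
#' @return the sequence as a character scalar.
#' @export
genome_seq <- function(genome, id) {
  if (id %in% names(genome$placed)) return(genome$placed[[id]])
  if (id %in% names(genome$unplaced)) return(genome$unplaced[[id]])
  stop("sequence id not in assembly: ", id)
}

#' @keywords internal
genome_seqlen <- function(genome, id) nchar(genome_seq(genome, id))

#' Genomic interval(s)
#'
#' 1-based, inclusive coordinates on a named sequence, the coordinate style
#' in which annotation and assembly positions are conventionally printed.
#' Vectorised: returns a data frame with one row per interval.
#'
#' @param chrom sequence id(s).
#' @param start,end 1-based inclusive bounds, `start <= end`.
#' @param strand `"+"` or `"-"`.
#' @export
gintv <- function(chrom, start, end, strand = "+") {
  start <- as.integer(round(start)); end <- as.integer(round(end))
  if (any(is.na(start) | is.na(end)) || any(start < 1L) || any(end < start))
    stop("invalid interval: need 1 <= start <= end")
  if (!all(strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  data.frame(chrom = as.character(chrom), start = start, end = end,
             strand = strand, stringsAsFactors = FALSE)
}

#' Length of genomic interval(s) in bp
#'
#' @param iv a data frame with `start` and `end` columns (see [gintv()]).
#' @return integer vector of `end - start + 1`.
#' @export
interval_length <- function(iv) as.integer(iv$end - iv$start + 1L)

#' Overlap length between two genomic intervals in bp
#'
#' Zero when the intervals are disjoint or on different sequences.
#'
#' @param a,b interval data frames (recycled row-wise).
#' @return integer vector of overlap lengths.
#' @export
overlap_length <- function(a, b) {
  ov <- pmin(a$end, b$end) - pmax(a$start, b$start) + 1L
  as.integer(ifelse(a$chrom == b$chrom, pmax(0L, ov), 0L))
}

#' Transcript model
#'
#' An exon-intron structure on one chromosome and strand, with an optional
#' coding region given in 1-based transcript (spliced) coordinates. Exons are
#' stored in ascending genomic order regardless of strand; transcript order
#' is derived from the strand. Consecutive exons must be separated by at
#' least 1 bp of intron.
#'
#' @param id transcript id (unique within an annotation set).
#' @param chrom chromosome id.
#' @param strand `"+"` or `"-"`.
#' @param exons data frame with `start`/`end` columns, ascending and
#'   non-overlapping.
#' @param cds optional `c(start, end)` in transcript coordinates; length must
#'   be a multiple of 3.
#' @param gene_name,evidence optional gene symbol and evidence accession used
#'   by the best-match priority code.
#' @return an object of class `Transcript`.
#' @export
transcript <- function(id, chrom, strand, exons, cds = NULL,
                       gene_name = NULL, evidence = NULL) {
  stopifnot(is.character(id), length(id) == 1L, strand %in% c("+", "-"))
  exons <- data.frame(start = as.integer(exons$start),
                      end = as.integer(exons$end))
  exons <- exons[order(exons$start), , drop = FALSE]
  rownames(exons) <- NULL
  if (nrow(exons) == 0L) stop("transcript ", id, ": no exons")
  if (any(exons$end < exons$start))
    stop("transcript ", id, ": exon with end < start")
  if (nrow(exons) > 1L) {
    gaps <- exons$start[-1L] - exons$end[-nrow(exons)] - 1L
    if (any(gaps < 1L))
      stop("transcript ", id, ": exons overlap or touch (intron < 1 bp)")
  }
  slen <- sum(exons$end - exons$start + 1L)
  if (!is.null(cds)) {
    cds <- as.integer(cds)
    if (length(cds) != 2L || cds[1L] < 1L || cds[2L] < cds[1L] || cds[2L] > slen)
      stop("transcript ", id, ": CDS outside spliced length")
    if ((cds[2L] - cds[1L] + 1L) %% 3L != 0L)
      stop("transcript ", id, ": CDS length not a multiple of 3")
  }
  structure(list(id = id, chrom = as.character(chrom), strand = strand,
                 exons = exons, cds = cds,
                 gene_name = gene_name, evidence = evidence),
            class = "Transcript")
}

#' @export
print.Transcript <- function(x, ...) {
  cat(sprintf("Transcript %s [%s] %s:%d-%d (%s), %d exon(s), %d bp spliced%s\n",
              x$id, x$gene_name %||% "-", x$chrom,
              min(x$exons$start), max(x$exons$end), x$strand,
              nrow(x$exons), spliced_length(x),
              if (is.null(x$cds)) "" else
                sprintf(", CDS %d-%d", x$cds[1L], x$cds[2L])))
  invisible(x)
}

#' Spliced (mRNA) length of a transcript
#' @param tx a `Transcript`.
#' @export
spliced_length <- function(tx) sum(interval_length(tx$exons))

#' @keywords internal
tx_span <- function(tx) c(min(tx$exons$start), max(tx$exons$end))

#' Convert transcript coordinates to genomic intervals
#'
#' Maps a closed interval `[tstart, tend]` in spliced transcript coordinates
#' to its (possibly multi-exon) genomic footprint.
#'
#' @param tx a `Transcript`.
#' @param tstart,tend 1-based transcript coordinates.
#' @return data frame of genomic `start`/`end` intervals in ascending order.
#' @export
tx_to_genome <- function(tx, tstart, tend) {
  slen <- spliced_length(tx)
  stopifnot(tstart >= 1L, tend >= tstart, tend <= slen)
  lens <- interval_length(tx$exons)
  n <- nrow(tx$exons)
  # offsets of each exon in transcript order
  ord <- if (tx$strand == "+") seq_len(n) else rev(seq_len(n))
  off <- cumsum(c(0L, lens[ord]))[seq_len(n)] # transcript offset before exon ord[i]
  out <- list()
  for (i in seq_len(n)) {
    e <- ord[i]
    lo <- max(tstart, off[i] + 1L)
    hi <- min(tend, off[i] + lens[e])
    if (lo > hi) next
    if (tx$strand == "+") {
      gs <- tx$exons$start[e] + (lo - off[i] - 1L)
      ge <- tx$exons$start[e] + (hi - off[i] - 1L)
    } else {
      ge <- tx$exons$end[e] - (lo - off[i] - 1L)
      gs <- tx$exons$end[e] - (hi - off[i] - 1L)
    }
    out[[length(out) + 1L]] <- c(gs, ge)
  }
  m <- do.call(rbind, out)
  m <- m[order(m[, 1L]), , drop = FALSE]
  data.frame(start = as.integer(m[, 1L]), end = as.integer(m[, 2L]))
}

#' Convert a genomic position to transcript coordinates
#'
#' @param tx a `Transcript`.
#' @param gpos genomic position(s); must fall inside an exon.
#' @return integer transcript coordinate(s); `NA` for intronic/outside
#'   positions.
#' @export
genome_to_tx <- function(tx, gpos) {
  lens <- interval_length(tx$exons)
  n <- nrow(tx$exons)
  ord <- if (tx$strand == "+") seq_len(n) else rev(seq_len(n))
  off <- integer(n)
  off[ord] <- cumsum(c(0L, lens[ord]))[seq_len(n)]
  res <- rep(NA_integer_, length(gpos))
  for (e in seq_len(n)) {
    inside <- gpos >= tx$exons$start[e] & gpos <= tx$exons$end[e]
    if (!any(inside)) next
    res[inside] <- if (tx$strand == "+") {
      off[e] + (gpos[inside] - tx$exons$start[e]) + 1L
    } else {
      off[e] + (tx$exons$end[e] - gpos[inside]) + 1L
    }
  }
  as.integer(res)
}

#' Annotation set
#'
#' A collection of transcripts on one assembly, with unique ids. When a
#' genome is supplied, every exon is checked against chromosome bounds.
#'
#' @param transcripts list of `Transcript` objects.
#' @param assembly_name label of the assembly the coordinates refer to.
#' @param genome optional `GenomeAssembly` for bounds checking.
#' @return an object of class `AnnotationSet`.
#' @export
annotation_set <- function(transcripts, assembly_name = "assembly",
                           genome = NULL) {
  ids <- vapply(transcripts, function(t) t$id, character(1))
  if (anyDuplicated(ids))
    stop("duplicate transcript id: ", ids[duplicated(ids)][1L])
  names(transcripts) <- ids
  if (!is.null(genome)) {
    for (tx in transcripts) {
      if (!(tx$chrom %in% c(names(genome$placed), names(genome$unplaced))))
        stop("transcript ", tx$id, ": chromosome '", tx$chrom,
             "' absent from genome")
      if (max(tx$exons$end) > genome_seqlen(genome, tx$chrom))
        stop("transcript ", tx$id, ": exon beyond end of ", tx$chrom)
    }
  }
  structure(list(assembly_name = assembly_name, transcripts = transcripts),
            class = "AnnotationSet")
}

#' @export
print.AnnotationSet <- function(x, ...) {
  cat(sprintf("AnnotationSet on '%s': %d transcript(s)\n",
              x$assembly_name, length(x$transcripts)))
  invisible(x)
}

#' Per-transcript span table of an annotation set
#'
#' @param ann an `AnnotationSet`.
#' @return a `data.table` with id, chrom, strand, span and exon count,
#'   keyed by chromosome (the per-chromosome interval index used to find
#'   candidate matches).
#' @export
annotation_spans <- function(ann) {
  dt <- data.table::rbindlist(lapply(ann$transcripts, function(tx) {
    sp <- tx_span(tx)
    data.table::data.table(id = tx$id, chrom = tx$chrom, strand = tx$strand,
                           start = sp[1L], end = sp[2L],
                           n_exons = nrow(tx$exons),
                           exonic_bp = spliced_length(tx))
  }))
  data.table::setkeyv(dt, c("chrom", "start"))
  dt[]
}

#' Extract the spliced (mRNA) sequence of a transcript
#'
#' Concatenates the exon substrings in genomic order and reverse-complements
#' the result for minus-strand transcripts.
#'
#' @param tx a `Transcript`.
#' @param genome a `GenomeAssembly` containing `tx$chrom`.
#' @return the spliced sequence as a character scalar.
#' @export
splice_transcript <- function(tx, genome) {
  s <- genome_seq(genome, tx$chrom)
  if (max(tx$exons$end) > nchar(s))
    stop("transcript ", tx$id, ": exon beyond end of ", tx$chrom)
  mrna <- paste(substring(s, tx$exons$start, tx$exons$end), collapse = "")
  if (tx$strand == "-") mrna <- revcomp(mrna)
  mrna
}

#' Protein record
#'
#' Amino-acid sequence over the 20 standard residues plus `*` (stop codon
#' read through, as in uncurated conceptual translations) and `X` (codon with
#' an ambiguous base).
#'
#' @param id record id.
#' @param sequence amino-acid string.
#' @export
protein_record <- function(id, sequence) {
  stopifnot(is.character(id), length(id) == 1L)
  sequence <- toupper(sequence)
  if (!nzchar(sequence)) stop("protein ", id, ": empty sequence")
  if (grepl("[^ACDEFGHIKLMNPQRSTVWY*X]", sequence))
    stop("protein ", id, ": illegal residue character")
  structure(list(id = id, sequence = sequence), class = "ProteinRecord")
}

#' Translate a CDS nucleotide string
#'
#' Standard genetic code; internal stops are emitted as `*` (no correction),
#' codons containing `N` translate to `X`, and a trailing stop codon is
#' dropped.
#'
#' @param dna CDS string, length a multiple of 3.
#' @return amino-acid string.
#' @export
translate_cds <- function(dna) {
  n <- nchar(dna)
  if (n %% 3L != 0L) stop("CDS length not a multiple of 3")
  if (n == 0L) return("")
  starts <- seq.int(1L, n, by = 3L)
  codons <- substring(dna, starts, starts + 2L)
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  aa[is.na(aa)] <- "X"
  if (aa[length(aa)] == "*") aa <- aa[-length(aa)]
  paste(aa, collapse = "")
}

#' Conceptual translation of a transcript
#'
#' Direct translation of the annotated CDS from the genomic sequence, with
#' no frameshift correction or curation: internal stop codons stay in the
#' protein as `*`. This mirrors how uncurated annotation-pipeline
#' translations expose assembly errors in the underlying sequence.
#'
#' @param tx a `Transcript` with a CDS.
#' @param genome the `GenomeAssembly` the coordinates refer to.
#' @return a `ProteinRecord`.
#' @export
conceptual_translation <- function(tx, genome) {
  if (is.null(tx$cds))
    stop("transcript ", tx$id, " has no CDS")
  mrna <- splice_transcript(tx, genome)
  cds <- substr(mrna, tx$cds[1L], tx$cds[2L])
  protein_record(tx$id, translate_cds(cds))
}

#' Conceptual translations for every coding transcript of an annotation
#'
#' @param ann an `AnnotationSet`.
#' @param genome the matching `GenomeAssembly`.
#' @return named character vector of protein sequences.
#' @export
translate_annotation <- function(ann, genome) {
  coding <- Filter(function(tx) !is.null(tx$cds), ann$transcripts)
  vapply(coding, function(tx) conceptual_translation(tx, genome)$sequence,
         character(1))
}
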