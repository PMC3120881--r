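#' Read a FASTA file into a named character vector
#'
#' Ids are the first whitespace-delimited token of each header; sequences are
#' uppercased on read. Malformed records are rejected rather than repaired.
#'
#' @param path file path.
#' @param alphabet `"dna"` restricts to A/C/G/T/N; `"protein"` to amino
#'   acids plus `*`/`X`; `"any"` skips the check.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path, alphabet = c("dna", "protein", "any")) {
  alphabet <- match.arg(alphabet)
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (any(!nzchar(ids))) stop("FASTA record with empty id in ", path)
  if (anyDuplicated(ids))
    stop("duplicate FASTA id '", ids[duplicated(ids)][1L], "' in ", path)
  seqs <- toupper(as.character(set))
  names(seqs) <- ids
  if (any(nchar(seqs) == 0L))
    stop("empty FASTA record '", ids[nchar(seqs) == 0L][1L], "' in ", path)
  pat <- switch(alphabet, dna = "[^ACGTN]", protein = "[^ACDEFGHIKLMNPQRSTVWY*X]",
                any = NULL)
  if (!is.null(pat)) {
    bad <- grepl(pat, seqs)
    if (any(bad))
      stop("illegal characters in FASTA record '", ids[bad][1L], "' in ", path)
  }
  seqs
}

#' Write sequences to a FASTA file
#'
#' @param seqs named character vector.
#' @param path output path.
#' @param line_width wrap width (default 60).
#' @export
write_fasta <- function(seqs, path, line_width = 60) {
  stopifnot(!is.null(names(seqs)), all(nzchar(names(seqs))))
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path,
                              width = line_width)
  invisible(path)
}

# -- GFF3 ---------------------------------------------------------------

#' Read a GFF3 annotation
#'
#' Expects `gene`/`mRNA`/`exon`/`CDS` rows linked by `ID`/`Parent`
#' attributes; the optional attributes `gene_name` and `evidence` (this
#' package's convention) are picked up from the mRNA row or its parent gene.
#' CDS rows are converted to transcript coordinates. Structural problems
#' (exon without a parent mRNA, CDS outside exons, coordinates beyond the
#' chromosome) are errors, not warnings.
#'
#' @param path GFF3 file; the `##gff-version 3` pragma is required.
#' @param genome optional `GenomeAssembly` used to validate chromosome ids
#'   and coordinate bounds.
#' @param assembly_name label for the returned set.
#' @return an `AnnotationSet`.
#' @export
read_gff3 <- function(path, genome = NULL, assembly_name = "assembly") {
  first <- readLines(path, n = 1L)
  if (length(first) == 0L || !grepl("^##gff-version[ \t]+3", first))
    stop("not a GFF3 file (missing ##gff-version 3 pragma): ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  df$seqnames <- as.character(df$seqnames)
  df$strand <- as.character(df$strand)
  df$type <- as.character(df$type)
  df$Parent <- vapply(df$Parent, function(p)
    if (length(p)) as.character(p)[1L] else NA_character_, character(1))
  genes <- df[df$type == "gene", , drop = FALSE]
  mrnas <- df[df$type == "mRNA", , drop = FALSE]
  get_attr <- function(row, what)
    if (!is.null(mrnas[[what]]) && !is.na(mrnas[[what]][row]))
      mrnas[[what]][row] else NULL
  if (nrow(mrnas) == 0L) stop("no mRNA features in ", path)
  if (any(is.na(mrnas$ID))) stop("mRNA row without ID in ", path)

  txs <- vector("list", nrow(mrnas))
  for (i in seq_len(nrow(mrnas))) {
    mid <- mrnas$ID[i]
    ex <- df[df$type == "exon" & !is.na(df$Parent) & df$Parent == mid, ,
             drop = FALSE]
    if (nrow(ex) == 0L) stop("mRNA '", mid, "' has no exon rows in ", path)
    if (any(ex$seqnames != mrnas$seqnames[i]))
      stop("exon of '", mid, "' on a different chromosome in ", path)
    strand <- mrnas$strand[i]
    if (!strand %in% c("+", "-"))
      stop("mRNA '", mid, "' without strand in ", path)

    gene_name <- get_attr(i, "gene_name")
    evidence <- get_attr(i, "evidence")
    if (is.null(gene_name) && !is.na(mrnas$Parent[i]) && nrow(genes)) {
      g <- which(genes$ID == mrnas$Parent[i])
      if (length(g) && !is.null(genes$gene_name) && !is.na(genes$gene_name[g[1L]]))
        gene_name <- genes$gene_name[g[1L]]
    }

    tx <- transcript(mid, mrnas$seqnames[i], strand,
                     data.frame(start = ex$start, end = ex$end),
                     gene_name = gene_name, evidence = evidence)

    cds_rows <- df[df$type == "CDS" & !is.na(df$Parent) & df$Parent == mid, ,
                   drop = FALSE]
    if (nrow(cds_rows)) {
      tpos <- genome_to_tx(tx, c(cds_rows$start, cds_rows$end))
      if (anyNA(tpos))
        stop("CDS of '", mid, "' outside its exons in ", path)
      tx <- transcript(mid, tx$chrom, tx$strand, tx$exons,
                       cds = range(tpos), gene_name = gene_name,
                       evidence = evidence)
    }
    txs[[i]] <- tx
  }
  orphans <- df$type == "exon" & (is.na(df$Parent) | !(df$Parent %in% mrnas$ID))
  if (any(orphans))
    stop("exon row without a parent mRNA (line ~", which(orphans)[1L],
         " of feature table) in ", path)
  annotation_set(txs, assembly_name = assembly_name, genome = genome)
}

#' Write an annotation set as GFF3
#'
#' Emits one `gene` row per transcript plus `mRNA`, `exon` and `CDS` rows;
#' `gene_name` and `evidence` are written as attributes of the mRNA row.
#'
#' @param ann an `AnnotationSet`.
#' @param path output path.
#' @export
write_gff3 <- function(ann, path) {
  rows <- list()
  for (tx in ann$transcripts) {
    gid <- paste0("gene:", tx$id)
    sp <- tx_span(tx)
    rows[[length(rows) + 1L]] <- data.frame(
      seqnames = tx$chrom, start = sp[1L], end = sp[2L], strand = tx$strand,
      type = "gene", ID = gid, Parent = NA_character_,
      gene_name = tx$gene_name %||% NA_character_,
      evidence = NA_character_, stringsAsFactors = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(
      seqnames = tx$chrom, start = sp[1L], end = sp[2L], strand = tx$strand,
      type = "mRNA", ID = tx$id, Parent = gid,
      gene_name = tx$gene_name %||% NA_character_,
      evidence = tx$evidence %||% NA_character_, stringsAsFactors = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(
      seqnames = tx$chrom, start = tx$exons$start, end = tx$exons$end,
      strand = tx$strand, type = "exon", ID = NA_character_, Parent = tx$id,
      gene_name = NA_character_, evidence = NA_character_,
      stringsAsFactors = FALSE)
    if (!is.null(tx$cds)) {
      giv <- tx_to_genome(tx, tx$cds[1L], tx$cds[2L])
      ord <- if (tx$strand == "+") seq_len(nrow(giv)) else rev(seq_len(nrow(giv)))
      lens <- (giv$end - giv$start + 1L)[ord]
      phase <- integer(nrow(giv))
      phase[ord] <- (3L - cumsum(c(0L, lens[-length(lens)])) %% 3L) %% 3L
      rows[[length(rows) + 1L]] <- data.frame(
        seqnames = tx$chrom, start = giv$start, end = giv$end,
        strand = tx$strand, type = "CDS", ID = NA_character_, Parent = tx$id,
        gene_name = NA_character_, evidence = NA_character_,
        phase = phase, stringsAsFactors = FALSE)
    }
  }
  for (i in seq_along(rows))
    if (is.null(rows[[i]]$phase)) rows[[i]]$phase <- NA_integer_
  df <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(
    seqnames = df$seqnames,
    ranges = IRanges::IRanges(df$start, df$end),
    strand = df$strand)
  gr$type <- df$type
  gr$phase <- df$phase
  gr$ID <- df$ID
  gr$Parent <- df$Parent
  gr$gene_name <- df$gene_name
  gr$evidence <- df$evidence
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

# -- SNP tables ---------------------------------------------------------

#' Construct a SNP flanking-context record
#'
#' @param rsid SNP identifier.
#' @param flank5,flank3 flanking genomic sequence on each side (one may be
#'   empty, not both).
#' @param alleles character vector of 1-bp alleles (at least two distinct),
#'   or a single `"A/G"`-style string.
#' @return one-row data frame with columns rsid, flank5, alleles, flank3.
#' @export
snp_context <- function(rsid, flank5, alleles, flank3) {
  if (length(alleles) == 1L && grepl("/", alleles))
    alleles <- strsplit(alleles, "/", fixed = TRUE)[[1L]]
  alleles <- toupper(alleles)
  flank5 <- toupper(flank5); flank3 <- toupper(flank3)
  if (!nzchar(flank5) && !nzchar(flank3))
    stop("SNP ", rsid, ": both flanks empty")
  if (!all(alleles %in% c("A", "C", "G", "T")) ||
      length(unique(alleles)) < 2L)
    stop("SNP ", rsid, ": need >= 2 distinct alleles from {A,C,G,T}")
  if (!all(is_dna_string(c(flank5, flank3))))
    stop("SNP ", rsid, ": flank with illegal characters")
  data.frame(rsid = rsid, flank5 = flank5,
             alleles = paste(alleles, collapse = "/"),
             flank3 = flank3, stringsAsFactors = FALSE)
}

#' Read a SNP context table
#'
#' Accepts either a 4-column TSV (`rsid`, `flank5`, `alleles`, `flank3`,
#' alleles as `A/G`) or the 2-column dbSNP-style bracket form
#' (`rsid<TAB>ACGT...[A/G]...ACGT`). Lines starting with `#` are skipped.
#'
#' @param path file path.
#' @return data frame with columns rsid, flank5, alleles, flank3.
#' @export
read_snp_table <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) stop("no SNP records in ", path)
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) == 2L) {
      m <- regmatches(f[2L], regexec("^([ACGTNacgtn]*)\\[([ACGTacgt/]+)\\]([ACGTNacgtn]*)$", f[2L]))[[1L]]
      if (length(m) != 4L)
        stop("malformed bracket context on line ", i, " of ", path)
      out[[i]] <- snp_context(f[1L], m[2L], m[3L], m[4L])
    } else if (length(f) == 4L) {
      out[[i]] <- snp_context(f[1L], f[2L], f[3L], f[4L])
    } else {
      stop("SNP line ", i, " of ", path, ": expected 2 or 4 columns")
    }
  }
  snps <- do.call(rbind, out)
  if (anyDuplicated(snps$rsid))
    stop("duplicate rsid in ", path, ": ",
         snps$rsid[duplicated(snps$rsid)][1L])
  snps
}

#' Write a SNP context table (4-column TSV)
#'
#' @param snps data frame with rsid, flank5, alleles, flank3.
#' @param path output path.
#' @export
write_snp_table <- function(snps, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#rsid\tflank5\talleles\tflank3", con)
  writeLines(paste(snps$rsid, snps$flank5, snps$alleles, snps$flank3,
                   sep = "\t"), con)
  invisible(path)
}
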