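#' Build a k-mer index of an assembly
#'
#' Indexes every forward-strand k-mer position of the selected sequences;
#' the opposite strand is searched by reverse-complementing queries. k-mers
#' containing N are skipped. Candidate regions for spliced alignment and SNP
#' context mapping are found by joining query k-mers against this index.
#'
#' @param genome a `GenomeAssembly`.
#' @param k k-mer size (8..25; default 20, long enough that random hits are
#'   rare in a mammalian-sized target).
#' @param sequences which pool to index: placed chromosomes (default),
#'   unplaced contigs, or both.
#' @return an object of class `KmerIndex`.
#' @export
kmer_index <- function(genome, k = 20,
                       sequences = c("placed", "unplaced", "all")) {
  sequences <- match.arg(sequences)
  stopifnot(k >= 8, k <= 25)
  seqs <- switch(sequences,
                 placed = genome$placed,
                 unplaced = genome$unplaced,
                 all = c(genome$placed, genome$unplaced))
  if (length(seqs) == 0L) stop("no sequences to index (", sequences, ")")
  parts <- lapply(names(seqs), function(id) {
    codes <- kmer_codes_cpp(seqs[[id]], k)
    keep <- which(!is.na(codes))
    if (length(keep) == 0L) return(NULL)
    data.table::data.table(code = codes[keep], seqid = id, pos = keep)
  })
  dt <- data.table::rbindlist(parts)
  data.table::setkey(dt, code)
  structure(list(k = k, dt = dt,
                 seq_lens = vapply(seqs, nchar, integer(1))),
            class = "KmerIndex")
}

#' @export
print.KmerIndex <- function(x, ...) {
  cat(sprintf("KmerIndex: k=%d, %s positions over %d sequence(s)\n",
              x$k, format(nrow(x$dt), big.mark = ","),
              length(x$seq_lens)))
  invisible(x)
}

#' Positions of one k-mer in the index
#' @param index a `KmerIndex`.
#' @param kmer a k-character DNA string.
#' @return data frame of (seqid, pos); zero rows when absent.
#' @export
lookup_kmer <- function(index, kmer) {
  stopifnot(nchar(kmer) == index$k)
  qcode <- kmer_codes_cpp(toupper(kmer), index$k)[1L]
  if (is.na(qcode))
    return(data.frame(seqid = character(0), pos = integer(0)))
  hit <- index$dt[list(code = qcode), on = "code", nomatch = NULL]
  data.frame(seqid = hit$seqid, pos = hit$pos, stringsAsFactors = FALSE)
}

#' Find candidate genomic windows sharing seeds with a query
#'
#' Both strands are searched (the query is reverse-complemented for the
#' minus strand); seed hits on one sequence are clustered wherever
#' consecutive hits are closer than `cluster_gap`, and each cluster with at
#' least `min_shared_kmers` distinct query seeds becomes a padded window for
#' the chaining aligner.
#'
#' @param query query sequence (transcript or SNP context).
#' @param index a `KmerIndex` of the target assembly.
#' @param min_shared_kmers minimum distinct query k-mers shared.
#' @param pad_bp padding added to each side of the seed cluster.
#' @param cluster_gap maximum genomic distance between seeds of one cluster
#'   (bounds the largest intron that can be spanned).
#' @return data frame (seqid, strand, start, end, n_seeds), possibly empty.
#' @export
find_candidates <- function(query, index, min_shared_kmers = 2,
                            pad_bp = 2000, cluster_gap = 5e4) {
  qlen <- nchar(query)
  if (qlen < index$k) stop("query shorter than k")
  out <- list()
  for (strand in c("+", "-")) {
    qs <- if (strand == "+") query else revcomp(query)
    codes <- kmer_codes_cpp(qs, index$k)
    qpos <- which(!is.na(codes))
    if (length(qpos) == 0L) next
    qdt <- data.table::data.table(code = codes[qpos], qpos = qpos)
    hits <- index$dt[qdt, on = "code", nomatch = NULL,
                     allow.cartesian = TRUE]
    if (nrow(hits) == 0L) next
    data.table::setorder(hits, seqid, pos)
    for (sid in unique(hits$seqid)) {
      h <- hits[hits$seqid == sid, ]
      grp <- cumsum(c(1L, diff(h$pos) > cluster_gap))
      for (g in split(seq_len(nrow(h)), grp)) {
        hh <- h[g, ]
        if (length(unique(hh$qpos)) < min_shared_kmers) next
        ws <- max(1L, min(hh$pos - hh$qpos + 1L) - as.integer(pad_bp))
        we <- min(index$seq_lens[[sid]],
                  max(hh$pos + (qlen - hh$qpos)) + as.integer(pad_bp))
        out[[length(out) + 1L]] <- data.frame(
          seqid = sid, strand = strand, start = ws, end = we,
          n_seeds = nrow(hh), stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0L)
    return(data.frame(seqid = character(0), strand = character(0),
                      start = integer(0), end = integer(0),
                      n_seeds = integer(0)))
  do.call(rbind, out)
}
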