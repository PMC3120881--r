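# Spliced alignment of a cDNA-like query to a genomic window: exact-seed
# anchors are chained collinearly; small inter-anchor gaps are closed by a
# unit-cost DP; genomic gaps at least `min_intron` larger than the query gap
# become introns with zero column cost, with the exon boundary placed by a
# match-count split and shifted (within 10 bp, match-preserving) onto
# canonical splice signals where attainable; query segments that match
# nothing (deleted exons) stay unaligned and reduce coverage.

# maximal exact match anchors between query and window (same-diagonal runs
# of shared k-mers)
.find_anchors <- function(qs, wseq, k, max_anchors = 400L) {
  wc <- kmer_codes_cpp(wseq, k)
  qc <- kmer_codes_cpp(qs, k)
  wkeep <- which(!is.na(wc)); qkeep <- which(!is.na(qc))
  if (length(wkeep) == 0L || length(qkeep) == 0L) return(NULL)
  wdt <- data.table::data.table(code = wc[wkeep], wpos = wkeep)
  qdt <- data.table::data.table(code = qc[qkeep], qpos = qkeep)
  data.table::setkey(wdt, code)
  hits <- wdt[qdt, on = "code", nomatch = NULL, allow.cartesian = TRUE]
  if (nrow(hits) == 0L) return(NULL)
  hits[, diag := wpos - qpos]
  data.table::setorder(hits, diag, qpos)
  run <- cumsum(c(1L, diff(hits$qpos) != 1L | diff(hits$diag) != 0L))
  data.table::set(hits, j = "run", value = run)
  a <- hits[, list(qs = min(qpos), qe = max(qpos) + k - 1L,
                   ws = min(wpos), we = max(wpos) + k - 1L), by = run]
  a[, len := qe - qs + 1L]
  a <- as.data.frame(a[order(-len)])
  if (nrow(a) > max_anchors) a <- a[seq_len(max_anchors), , drop = FALSE]
  a <- a[order(a$qs, a$ws), , drop = FALSE]
  rownames(a) <- NULL
  a
}

# collinear chain maximizing anchored bases (small penalties keep chains
# tight; long genomic gaps are near-free so introns can be spanned)
.chain_anchors <- function(a) {
  n <- nrow(a)
  score <- as.numeric(a$len)
  prev <- integer(n)
  if (n > 1L) {
    for (j in 2:n) {
      for (i in 1:(j - 1L)) {
        if (a$qs[j] <= a$qs[i] || a$qe[j] <= a$qe[i] ||
            a$ws[j] <= a$ws[i] || a$we[j] <= a$we[i]) next
        gapq <- a$qs[j] - a$qe[i] - 1L
        gapg <- a$ws[j] - a$we[i] - 1L
        if (gapg - gapq < -100L) next      # genome cannot lag far behind
        pen <- max(0L, -gapq) + max(0L, -gapg) +
          0.01 * max(gapq, 0L) + 1e-5 * max(gapg, 0L)
        s <- score[i] + a$len[j] - pen
        if (s > score[j]) { score[j] <- s; prev[j] <- i }
      }
    }
  }
  j <- which.max(score)
  chain <- j
  while (prev[j] > 0L) { j <- prev[j]; chain <- c(j, chain) }
  chain
}

# score of extending into `gq` against `gg` (equal-length char vectors):
# best prefix length under +1 match / -2 mismatch, X-drop style
.best_ext <- function(eq) {
  n <- length(eq)
  if (n == 0L) return(list(len = 0L, matches = 0L))
  m_full <- sum(eq)
  # under modest noise, extend all the way rather than clipping a noisy
  # tail; random sequence (~25% matches) still falls back to the best
  # scoring prefix
  if (m_full >= 0.7 * n) return(list(len = n, matches = m_full))
  sc <- cumsum(ifelse(eq, 1, -2))
  best <- which.max(sc)
  if (sc[best] <= 0) return(list(len = 0L, matches = 0L))
  list(len = best, matches = sum(eq[seq_len(best)]))
}

.flush_block <- function(blocks, cur) { blocks[[length(blocks) + 1L]] <- cur; blocks }

# assemble chained anchors into alignment blocks
.build_blocks <- function(qs_seq, wseq, a, min_intron, strand,
                          max_nw = 2000L, shift_bp = 10L) {
  want_d <- if (strand == "+") "GT" else "CT"
  want_a <- if (strand == "+") "AG" else "AC"
  wlen <- nchar(wseq)
  blocks <- list()
  cur <- list(qs = a$qs[1L], qe = a$qe[1L], ws = a$ws[1L], we = a$we[1L],
              m = a$len[1L], mm = 0L, ind = 0L)
  nr <- nrow(a)
  for (idx in seq_len(nr)[-1L]) {
    aq <- a$qs[idx]; ae <- a$qe[idx]; aw <- a$ws[idx]; av <- a$we[idx]
    alen <- a$len[idx]
    if (is.null(cur)) {
      cur <- list(qs = aq, qe = ae, ws = aw, we = av, m = alen, mm = 0L,
                  ind = 0L)
      next
    }
    # trim overlaps with the closed part of the chain
    oq <- cur$qe - aq + 1L
    if (oq > 0L) { aq <- aq + oq; aw <- aw + oq; alen <- alen - oq }
    og <- cur$we - aw + 1L
    if (og > 0L) { aq <- aq + og; aw <- aw + og; alen <- alen - og }
    if (alen <= 0L || aq > ae || aw > av) next
    gapq <- aq - cur$qe - 1L
    gapg <- aw - cur$we - 1L

    if (gapg - gapq >= min_intron) {
      # splice or unaligned break: split the query gap between the two
      # exon ends by match count
      m <- gapq
      if (m > 0L) {
        qg <- chars(substring(qs_seq, cur$qe + 1L, aq - 1L))
        gl <- chars(substring(wseq, cur$we + 1L, cur$we + m))
        gr <- chars(substring(wseq, aw - m, aw - 1L))
        SLm <- c(0L, cumsum(qg == gl))          # matches, left ext of len j
        SRm <- c(0L, cumsum(rev(qg == gr)))     # matches, right ext of len j
        SL <- SLm - 2 * (seq_len(m + 1L) - 1L - SLm)
        SR <- SRm - 2 * (seq_len(m + 1L) - 1L - SRm)
      } else {
        SLm <- SRm <- 0L; SL <- SR <- 0
      }
      # clean splice: all query bases assigned (j left, m - j right)
      diag_sc <- SL[seq_len(m + 1L)] + rev(SR)[seq_len(m + 1L)]
      don <- substring(wseq, cur$we + seq_len(m + 1L),
                       cur$we + seq_len(m + 1L) + 1L)
      acc <- substring(wseq, aw - (m + 1L) + seq_len(m + 1L) - 2L,
                       aw - (m + 1L) + seq_len(m + 1L) - 1L)
      diag_sc <- diag_sc + 0.5 * (don == want_d) + 0.5 * (acc == want_a)
      # split choice: best clean splice vs best partial extensions
      bestSR_to <- cummax(SR)
      split_sc <- max(vapply(seq_len(m + 1L), function(jl)
        SL[jl] + bestSR_to[m + 1L - jl + 1L], numeric(1)))
      if (max(diag_sc) + 1e-9 >= split_sc) {
        j <- which.max(diag_sc) - 1L
        lq <- cur$qe + j; lg <- cur$we + j; rg <- aw - (m - j)
        # match-preserving shift onto canonical splice signals
        sig_ok <- function(lg2, rg2)
          substring(wseq, lg2 + 1L, lg2 + 2L) == want_d &&
          substring(wseq, rg2 - 2L, rg2 - 1L) == want_a
        if (!sig_ok(lg, rg)) {
          for (s in c(seq(-1L, -shift_bp), seq_len(shift_bp))) {
            lq2 <- lq + s; lg2 <- lg + s; rg2 <- rg + s
            if (lq2 < cur$qs || lq2 > ae || lg2 < 1L || rg2 > wlen) next
            if (rg2 - lg2 - 1L < min_intron) next
            ok <- if (s > 0L)
              substring(wseq, lg + 1L, lg + s) ==
                substring(qs_seq, lq + 1L, lq + s)
            else
              substring(wseq, rg + s, rg - 1L) ==
                substring(qs_seq, lq + s + 1L, lq)
            if (ok && sig_ok(lg2, rg2)) { lq <- lq2; lg <- lg2; rg <- rg2; break }
          }
        }
        # close left block at (lq, lg); recount the boundary region
        if (lq >= cur$qe) {
          eq <- lq - cur$qe
          if (eq > 0L) {
            ml <- sum(chars(substring(qs_seq, cur$qe + 1L, lq)) ==
                        chars(substring(wseq, cur$we + 1L, lg)))
            cur$m <- cur$m + ml; cur$mm <- cur$mm + eq - ml
          }
        } else {
          cur$m <- cur$m - (cur$qe - lq)   # unwound anchor bases were matches
        }
        cur$qe <- lq; cur$we <- lg
        blocks <- .flush_block(blocks, cur)
        # open right block at (lq + 1, rg)
        nqs <- lq + 1L; nws <- rg
        m2 <- 0L; mm2 <- 0L
        if (nqs < aq) {
          ext <- sum(chars(substring(qs_seq, nqs, aq - 1L)) ==
                       chars(substring(wseq, nws, aw - 1L)))
          m2 <- ext; mm2 <- (aq - nqs) - ext
        } else if (nqs > aq) {
          drop <- nqs - aq
          alen <- alen - drop; aw <- aw + drop; aq <- nqs
          if (alen <= 0L) { cur <- NULL; next }
        }
        cur <- list(qs = nqs, qe = ae, ws = nws, we = av,
                    m = m2 + alen, mm = mm2, ind = 0L)
      } else {
        # unaligned query segment: partial extensions on both sides
        el <- .best_ext(if (m > 0L) (qg == gl) else logical(0))
        er <- .best_ext(if (m > 0L) rev(qg == gr) else logical(0))
        if (el$len + er$len > m) {  # extensions cannot overlap
          er$len <- m - el$len
          er$matches <- if (er$len > 0L)
            sum(rev(qg == gr)[seq_len(er$len)]) else 0L
        }
        cur$qe <- cur$qe + el$len; cur$we <- cur$we + el$len
        cur$m <- cur$m + el$matches
        cur$mm <- cur$mm + el$len - el$matches
        blocks <- .flush_block(blocks, cur)
        cur <- list(qs = aq - er$len, qe = ae, ws = aw - er$len, we = av,
                    m = alen + er$matches, mm = er$len - er$matches,
                    ind = 0L)
      }
    } else if (gapq == 0L && gapg == 0L) {
      cur$qe <- ae; cur$we <- av; cur$m <- cur$m + alen
    } else if (gapq > max_nw || gapg > max_nw) {
      blocks <- .flush_block(blocks, cur)
      cur <- list(qs = aq, qe = ae, ws = aw, we = av, m = alen, mm = 0L,
                  ind = 0L)
    } else {
      nw <- nw_counts_cpp(substring(qs_seq, cur$qe + 1L, aq - 1L),
                          substring(wseq, cur$we + 1L, aw - 1L))
      # merge small balanced gaps (indels / local noise clusters)
      # unconditionally; larger or unbalanced gaps only when the fill is
      # a credible alignment -- random sequence chained by spurious seeds
      # fails this and the block is broken instead (the gap stays
      # unaligned)
      if ((abs(gapg - gapq) <= 10L && max(gapq, gapg) <= 60L) ||
          nw[1L] >= 0.6 * (nw[1L] + nw[2L] + nw[3L] + nw[4L])) {
        cur$m <- cur$m + nw[1L] + alen
        cur$mm <- cur$mm + nw[2L]
        cur$ind <- cur$ind + nw[3L] + nw[4L]
        cur$qe <- ae; cur$we <- av
      } else {
        blocks <- .flush_block(blocks, cur)
        cur <- list(qs = aq, qe = ae, ws = aw, we = av, m = alen, mm = 0L,
                    ind = 0L)
      }
    }
  }
  if (!is.null(cur)) blocks <- .flush_block(blocks, cur)
  blocks
}

# extend the outermost blocks toward the query ends: the whole unaligned
# tail is closed by DP when that yields a credible alignment (noisy but
# genuine sequence), otherwise a conservative matching prefix is kept
# (garbage or gap tails stay unaligned)
.extend_ends <- function(blocks, qs_seq, wseq) {
  qlen <- nchar(qs_seq); wlen <- nchar(wseq)
  b1 <- blocks[[1L]]
  t <- min(b1$qs - 1L, b1$ws - 1L, 2000L)
  if (t > 0L) {
    qtail <- substring(qs_seq, b1$qs - t, b1$qs - 1L)
    gseg <- substring(wseq, b1$ws - t, b1$ws - 1L)
    nw <- nw_counts_cpp(qtail, gseg)
    if (nw[1L] >= 0.6 * sum(nw)) {
      b1$qs <- b1$qs - t; b1$ws <- b1$ws - t
      b1$m <- b1$m + nw[1L]; b1$mm <- b1$mm + nw[2L]
      b1$ind <- b1$ind + nw[3L] + nw[4L]
    } else {
      eq <- rev(chars(qtail)) == rev(chars(gseg))
      e <- .best_ext(eq)
      if (e$len > 0L) {
        b1$qs <- b1$qs - e$len; b1$ws <- b1$ws - e$len
        b1$m <- b1$m + e$matches; b1$mm <- b1$mm + e$len - e$matches
      }
    }
    blocks[[1L]] <- b1
  }
  bn <- blocks[[length(blocks)]]
  t <- min(qlen - bn$qe, wlen - bn$we, 2000L)
  if (t > 0L) {
    qtail <- substring(qs_seq, bn$qe + 1L, bn$qe + t)
    gseg <- substring(wseq, bn$we + 1L, bn$we + t)
    nw <- nw_counts_cpp(qtail, gseg)
    if (nw[1L] >= 0.6 * sum(nw)) {
      bn$qe <- bn$qe + t; bn$we <- bn$we + t
      bn$m <- bn$m + nw[1L]; bn$mm <- bn$mm + nw[2L]
      bn$ind <- bn$ind + nw[3L] + nw[4L]
    } else {
      eq <- chars(qtail) == chars(gseg)
      e <- .best_ext(eq)
      if (e$len > 0L) {
        bn$qe <- bn$qe + e$len; bn$we <- bn$we + e$len
        bn$m <- bn$m + e$matches; bn$mm <- bn$mm + e$len - e$matches
      }
    }
    blocks[[length(blocks)]] <- bn
  }
  blocks
}

#' Spliced alignment of a query against one candidate window
#'
#' @param query query sequence (original orientation).
#' @param genome target `GenomeAssembly`.
#' @param window one-row data frame from [find_candidates()] (seqid,
#'   strand, start, end).
#' @param query_id id recorded in the result.
#' @param min_intron smallest genomic gap treated as an intron rather than
#'   an indel (bp).
#' @param anchor_k seed size used inside the window.
#' @param max_nw largest gap closed by dynamic programming.
#' @return a `SplicedAlignment`, or `NULL` when no anchor chain is found.
#'   Block coordinates: `qstart`/`qend` are 1-based positions in the
#'   original query orientation; `gstart`/`gend` are forward-genome
#'   coordinates; `strand` records which strand the query matched.
#'   `identity` counts matching aligned columns over aligned (non-gap)
#'   columns; `coverage` is the fraction of query bases inside blocks.
#' @export
align_spliced <- function(query, genome, window, query_id = "query",
                          min_intron = 30, anchor_k = 12, max_nw = 2000) {
  qlen <- nchar(query)
  strand <- window$strand
  qs_seq <- if (strand == "+") query else revcomp(query)
  wseq <- substr(genome_seq(genome, window$seqid), window$start, window$end)
  anchors <- .find_anchors(qs_seq, wseq, anchor_k)
  if (is.null(anchors)) return(NULL)
  chain <- .chain_anchors(anchors)
  blocks <- .build_blocks(qs_seq, wseq, anchors[chain, , drop = FALSE],
                          as.integer(min_intron), strand,
                          as.integer(max_nw))
  if (length(blocks) == 0L) return(NULL)
  blocks <- .extend_ends(blocks, qs_seq, wseq)
  bdf <- do.call(rbind, lapply(blocks, as.data.frame))
  bdf$gstart <- bdf$ws + window$start - 1L
  bdf$gend <- bdf$we + window$start - 1L
  if (strand == "-") {
    qstart <- qlen - bdf$qe + 1L
    qend <- qlen - bdf$qs + 1L
  } else {
    qstart <- bdf$qs; qend <- bdf$qe
  }
  out <- data.frame(qstart = as.integer(qstart), qend = as.integer(qend),
                    gstart = as.integer(bdf$gstart),
                    gend = as.integer(bdf$gend),
                    matches = as.integer(bdf$m),
                    mismatches = as.integer(bdf$mm),
                    indels = as.integer(bdf$ind))
  out <- out[order(out$gstart), , drop = FALSE]
  rownames(out) <- NULL
  M <- sum(out$matches); MM <- sum(out$mismatches); IND <- sum(out$indels)
  if (M + MM == 0L) return(NULL)
  structure(list(query_id = query_id, chrom = window$seqid, strand = strand,
                 blocks = out,
                 identity = M / (M + MM),
                 identity_with_gaps = M / (M + MM + IND),
                 coverage = sum(out$qend - out$qstart + 1L) / qlen,
                 aligned_bp = sum(out$qend - out$qstart + 1L),
                 qlen = qlen, is_primary = FALSE),
            class = "SplicedAlignment")
}

#' @export
print.SplicedAlignment <- function(x, ...) {
  cat(sprintf(
    "SplicedAlignment %s -> %s(%s): %d block(s), id %.4f, cov %.4f%s\n",
    x$query_id, x$chrom, x$strand, nrow(x$blocks), x$identity, x$coverage,
    if (x$is_primary) " [primary]" else ""))
  invisible(x)
}

#' Map one query against an indexed assembly
#'
#' Finds candidate windows and aligns the query in each; overlapping window
#' results for the same locus are deduplicated, keeping the higher-scoring
#' alignment.
#'
#' @param query query sequence.
#' @param genome target `GenomeAssembly`.
#' @param index a `KmerIndex` of the target.
#' @param query_id id recorded in results.
#' @param min_shared_kmers,pad_bp,cluster_gap see [find_candidates()].
#' @param min_intron,anchor_k,max_nw see [align_spliced()].
#' @return list of `SplicedAlignment` (possibly empty).
#' @export
map_query <- function(query, genome, index, query_id = "query",
                      min_shared_kmers = 2, pad_bp = 2000,
                      cluster_gap = 5e4, min_intron = 30, anchor_k = 12,
                      max_nw = 2000) {
  wins <- find_candidates(query, index, min_shared_kmers, pad_bp,
                          cluster_gap)
  alns <- list()
  if (nrow(wins) == 0L) return(alns)
  for (i in seq_len(nrow(wins))) {
    al <- align_spliced(query, genome, wins[i, , drop = FALSE], query_id,
                        min_intron = min_intron, anchor_k = anchor_k,
                        max_nw = max_nw)
    if (!is.null(al)) alns[[length(alns) + 1L]] <- al
  }
  if (length(alns) <= 1L) return(alns)
  # deduplicate same-locus results from overlapping windows
  key <- vapply(alns, function(a)
    paste(a$chrom, a$strand, a$blocks$gstart[1L] %/% 50L), character(1))
  score <- vapply(alns, function(a) a$aligned_bp * a$identity, numeric(1))
  keep <- vapply(split(seq_along(alns), key), function(ii)
    ii[which.max(score[ii])], integer(1))
  alns[sort(keep)]
}

#' Retain alignments passing the length and identity filter
#'
#' @param alns list of `SplicedAlignment`.
#' @param min_len minimum aligned query span in bp.
#' @param min_identity minimum fraction of matching aligned columns.
#' @return the retained subset (possibly empty list).
#' @export
filter_alignments <- function(alns, min_len = 100, min_identity = 0.95) {
  Filter(function(a) a$aligned_bp >= min_len && a$identity >= min_identity,
         alns)
}

#' Flag primary alignments
#'
#' The primary alignment of a query maximizes (coverage, then identity,
#' then aligned bp); all exact ties at the maximum are flagged primary, so
#' a transcript inside a perfect segmental duplication keeps both copies as
#' primary.
#'
#' @param alns list of `SplicedAlignment` (any mix of queries).
#' @return the same list with `is_primary` set.
#' @export
select_primary <- function(alns) {
  if (length(alns) == 0L) return(alns)
  qid <- vapply(alns, `[[`, character(1), "query_id")
  for (ids in split(seq_along(alns), qid)) {
    cov <- vapply(alns[ids], `[[`, numeric(1), "coverage")
    idn <- vapply(alns[ids], `[[`, numeric(1), "identity")
    ab <- vapply(alns[ids], `[[`, numeric(1), "aligned_bp")
    best <- cov == max(cov)
    best[best] <- idn[best] == max(idn[best])
    best[best] <- ab[best] == max(ab[best])
    for (i in seq_along(ids)) alns[[ids[i]]]$is_primary <- best[i]
  }
  alns
}

#' Map, filter and rank a set of transcript sequences
#'
#' Convenience wrapper running [map_query()] for every query, applying the
#' retention filter and flagging primary alignments.
#'
#' @param queries named character vector of query sequences.
#' @param genome target `GenomeAssembly`.
#' @param index optional prebuilt `KmerIndex` (built with `k` otherwise).
#' @param k seed size for the genome index.
#' @param min_len,min_identity retention filter (see
#'   [filter_alignments()]).
#' @param ... passed on to [map_query()].
#' @return list of retained `SplicedAlignment` with primaries flagged.
#' @export
align_transcripts <- function(queries, genome, index = NULL, k = 20,
                              min_len = 100, min_identity = 0.95, ...) {
  if (is.null(index)) index <- kmer_index(genome, k)
  alns <- list()
  for (id in names(queries)) {
    alns <- c(alns, map_query(queries[[id]], genome, index, query_id = id,
                              ...))
  }
  select_primary(filter_alignments(alns, min_len, min_identity))
}

#' Tabular summary of alignments
#'
#' @param alns list of `SplicedAlignment`.
#' @return data frame with one row per alignment; blocks are encoded as
#'   comma-separated `qstart-qend:gstart-gend` spans.
#' @export
alignment_table <- function(alns) {
  if (length(alns) == 0L)
    return(data.frame(query = character(0), chrom = character(0),
                      strand = character(0), blocks = character(0),
                      identity = numeric(0), coverage = numeric(0),
                      primary = logical(0)))
  do.call(rbind, lapply(alns, function(a) data.frame(
    query = a$query_id, chrom = a$chrom, strand = a$strand,
    blocks = paste(sprintf("%d-%d:%d-%d", a$blocks$qstart, a$blocks$qend,
                           a$blocks$gstart, a$blocks$gend), collapse = ","),
    identity = a$identity, coverage = a$coverage, primary = a$is_primary,
    stringsAsFactors = FALSE)))
}

#' Coverage curve over a set of queries
#'
#' For each threshold x on a fixed grid, counts the queries whose aligned
#' coverage is at least x. In `all` mode the coverage of a query is the
#' union of aligned query positions over all of its retained alignments; in
#' `best` mode only primary alignments contribute. Queries with no retained
#' alignment are not counted at any x.
#'
#' @param alns list of `SplicedAlignment` (primaries flagged).
#' @param query_lengths named integer vector of query lengths.
#' @param mode `"all"` or `"best"`.
#' @param xs threshold grid.
#' @return data frame (x, count), non-increasing in x.
#' @export
coverage_curve <- function(alns, query_lengths, mode = c("all", "best"),
                           xs = seq(0, 1, by = 0.05)) {
  mode <- match.arg(mode)
  use <- if (mode == "best") Filter(function(a) a$is_primary, alns) else alns
  qid <- vapply(use, `[[`, character(1), "query_id")
  cov <- vapply(split(use, qid), function(as) {
    L <- query_lengths[[as[[1L]]$query_id]]
    ir <- IRanges::IRanges(
      start = unlist(lapply(as, function(a) a$blocks$qstart)),
      end = unlist(lapply(as, function(a) a$blocks$qend)))
    sum(IRanges::width(IRanges::reduce(ir))) / L
  }, numeric(1))
  data.frame(x = xs, count = vapply(xs, function(x) sum(cov >= x),
                                    integer(1)))
}
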