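# Two-stage remapping of SNP flanking-context sequences and the
# found/mapped two-tier filter: stage 1 searches with long (k=20) seeds;
# stage 2, applied only when stage 1 finds nothing, retries with short
# (k=11) seeds to retrieve lower-similarity placements. 'found' requires
# >= 90% identity over >= 90% of the context anywhere; 'mapped'
# additionally requires a unique placement at > 95% identity.

.snp_ref <- function(snp) strsplit(snp$alleles, "/", fixed = TRUE)[[1L]][1L]

#' Context query sequence of a SNP (flank5 + reference allele + flank3)
#' @param snp one-row SNP data frame (rsid, flank5, alleles, flank3).
#' @export
snp_query <- function(snp) paste0(snp$flank5, .snp_ref(snp), snp$flank3)

# turn one spliced alignment of a context into a hit record, scoring the
# variant column as a free match
.aln_to_hit <- function(al, snp) {
  qvar <- nchar(snp$flank5) + 1L
  b <- al$blocks
  i <- which(b$qstart <= qvar & b$qend >= qvar)
  snp_pos <- NA_integer_
  m <- sum(b$matches); mm <- sum(b$mismatches)
  if (length(i) == 1L) {
    # project the variant column (exact when the block has no indels)
    snp_pos <- if (al$strand == "+")
      b$gstart[i] + (qvar - b$qstart[i]) else b$gend[i] - (qvar - b$qstart[i])
  }
  data.frame(chrom = al$chrom, start = min(b$gstart), end = max(b$gend),
             strand = al$strand, identity = al$identity,
             coverage = al$coverage, snp_pos = snp_pos,
             matches = m, mismatches = mm, stringsAsFactors = FALSE)
}

#' Map one SNP context onto a genome
#'
#' @param snp one-row SNP data frame.
#' @param genome target `GenomeAssembly`.
#' @param index stage-1 `KmerIndex` (k = 20 by convention).
#' @param index2 optional stage-2 `KmerIndex` with shorter seeds (k = 11),
#'   consulted only when stage 1 yields nothing.
#' @param min_context minimum context length.
#' @return data frame of hits (chrom, start, end, strand, identity,
#'   coverage, snp_pos), possibly empty.
#' @export
map_context <- function(snp, genome, index, index2 = NULL,
                        min_context = 40) {
  query <- snp_query(snp)
  if (nchar(query) < min_context)
    stop("SNP ", snp$rsid, ": context shorter than ", min_context, " bp")
  stage <- function(idx, min_seeds) {
    wins <- find_candidates(query, idx, min_shared_kmers = min_seeds,
                            pad_bp = 200, cluster_gap = 2000)
    hits <- list()
    if (nrow(wins) == 0L) return(hits)
    for (i in seq_len(nrow(wins))) {
      al <- align_spliced(query, genome, wins[i, , drop = FALSE],
                          query_id = snp$rsid, min_intron = 10^9,
                          anchor_k = min(idx$k, 12L))
      if (is.null(al)) next
      hits[[length(hits) + 1L]] <- .aln_to_hit(al, snp)
    }
    hits
  }
  hits <- stage(index, 2L)
  if (length(hits) == 0L && !is.null(index2)) hits <- stage(index2, 3L)
  if (length(hits) == 0L)
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      identity = numeric(0), coverage = numeric(0),
                      snp_pos = integer(0)))
  h <- do.call(rbind, hits)
  # variant column scores as a free match: if the genome base at the
  # projected position differs from the reference allele, promote that
  # mismatch to a match
  for (i in seq_len(nrow(h))) {
    if (is.na(h$snp_pos[i])) next
    gb <- substr(genome_seq(genome, h$chrom[i]), h$snp_pos[i], h$snp_pos[i])
    qb <- .snp_ref(snp)
    qb_eff <- if (h$strand[i] == "-") revcomp(qb) else qb
    if (gb != qb_eff && h$mismatches[i] > 0L) {
      h$identity[i] <- (h$matches[i] + 1) /
        (h$matches[i] + h$mismatches[i])
    }
  }
  h[, c("chrom", "start", "end", "strand", "identity", "coverage",
        "snp_pos")]
}

#' Classify the hits of one SNP into the unmapped/found/mapped tier
#'
#' Hits whose genomic intervals overlap by at least half the shorter one
#' are first merged (best identity kept), guarding against split reports
#' of one locus. `found`: at least one merged hit with identity >=
#' `found_id` and coverage >= `found_cov`. `mapped`: exactly one merged
#' hit with identity > `mapped_id` and coverage >= `found_cov`.
#'
#' @param hits data frame from [map_context()].
#' @param found_id,found_cov,mapped_id tier thresholds.
#' @return list(status, hits) with status one of `"unmapped"`, `"found"`,
#'   `"mapped"`.
#' @export
classify_snp <- function(hits, found_id = 0.90, found_cov = 0.90,
                         mapped_id = 0.95) {
  if (nrow(hits) > 1L) {
    hits <- hits[order(hits$chrom, hits$start), , drop = FALSE]
    keep <- rep(TRUE, nrow(hits))
    grp <- integer(nrow(hits)); grp[1L] <- 1L
    for (i in seq_len(nrow(hits))[-1L]) {
      prev <- max(which(grp[seq_len(i - 1L)] > 0L))
      ov <- min(hits$end[i], hits$end[prev]) -
        max(hits$start[i], hits$start[prev]) + 1L
      shorter <- min(hits$end[i] - hits$start[i],
                     hits$end[prev] - hits$start[prev]) + 1L
      same <- hits$chrom[i] == hits$chrom[prev] && ov >= 0.5 * shorter
      grp[i] <- if (same) grp[prev] else max(grp) + 1L
    }
    hits <- do.call(rbind, lapply(split(hits, grp), function(h)
      h[which.max(h$identity), , drop = FALSE]))
  }
  found <- hits$identity >= found_id & hits$coverage >= found_cov
  mapped <- hits$identity > mapped_id & hits$coverage >= found_cov
  status <- if (sum(mapped) == 1L) "mapped"
    else if (any(found)) "found" else "unmapped"
  list(status = status, hits = hits)
}

#' Map a SNP table onto a genome
#'
#' Runs the two-stage context search for every SNP and classifies each
#' into the unmapped/found/mapped tier.
#'
#' @param snps SNP data frame (rsid, flank5, alleles, flank3).
#' @param genome target `GenomeAssembly`.
#' @param sequences which pool to search (`"placed"` by default, matching
#'   the convention that only chromosomes are searched).
#' @param index optional prebuilt stage-1 index of that pool.
#' @param stage2 build and consult the short-seed stage-2 index for SNPs
#'   that stage 1 misses.
#' @param found_id,found_cov,mapped_id tier thresholds.
#' @return data frame (rsid, status, n_hits, best_identity, best_coverage,
#'   chrom, pos).
#' @export
map_snps <- function(snps, genome, sequences = "placed", index = NULL,
                     stage2 = TRUE, found_id = 0.90, found_cov = 0.90,
                     mapped_id = 0.95) {
  if (is.null(index)) index <- kmer_index(genome, 20, sequences)
  index2 <- NULL
  rows <- vector("list", nrow(snps))
  for (i in seq_len(nrow(snps))) {
    snp <- snps[i, , drop = FALSE]
    hits <- map_context(snp, genome, index, index2)
    if (nrow(hits) == 0L && stage2 && is.null(index2)) {
      index2 <- kmer_index(genome, 11, sequences)
      hits <- map_context(snp, genome, index, index2)
    }
    cl <- classify_snp(hits, found_id, found_cov, mapped_id)
    best <- if (nrow(cl$hits)) which.max(cl$hits$identity) else NA_integer_
    rows[[i]] <- data.frame(
      rsid = snp$rsid, status = cl$status, n_hits = nrow(cl$hits),
      best_identity = if (!is.na(best)) cl$hits$identity[best] else NA_real_,
      best_coverage = if (!is.na(best)) cl$hits$coverage[best] else NA_real_,
      chrom = if (cl$status == "mapped") cl$hits$chrom[best] else NA_character_,
      pos = if (cl$status == "mapped") cl$hits$snp_pos[best] else NA_integer_,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Compare SNP recoverability between two assemblies
#'
#' Maps every SNP onto the placed chromosomes of both assemblies, reports
#' per-assembly found/mapped counts and assembly-specific (found in one,
#' not the other) sets, and optionally rescues one-assembly SNPs by
#' re-searching the other assembly's unplaced contig pool.
#'
#' @param snps SNP data frame.
#' @param genome_a,genome_b the two assemblies.
#' @param rescue_unplaced re-search assembly-specific SNPs against the
#'   other assembly's unplaced contigs.
#' @param ... thresholds passed to [map_snps()].
#' @return list with `status_a`, `status_b` (per-SNP tables), `summary`
#'   (data frame) and, when rescue is on, `rescued_in_a`/`rescued_in_b`
#'   rsid vectors.
#' @export
compare_assemblies <- function(snps, genome_a, genome_b,
                               rescue_unplaced = FALSE, ...) {
  sa <- map_snps(snps, genome_a, ...)
  sb <- map_snps(snps, genome_b, ...)
  found_a <- sa$rsid[sa$status != "unmapped"]
  found_b <- sb$rsid[sb$status != "unmapped"]
  unique_a <- setdiff(found_a, found_b)
  unique_b <- setdiff(found_b, found_a)
  rescued_a <- rescued_b <- character(0)
  if (rescue_unplaced) {
    # SNPs found only in B may sit on the other assembly's unplaced contigs
    if (length(unique_b) && length(genome_a$unplaced)) {
      ra <- map_snps(snps[snps$rsid %in% unique_b, , drop = FALSE],
                     genome_a, sequences = "unplaced", ...)
      rescued_a <- ra$rsid[ra$status != "unmapped"]
    }
    if (length(unique_a) && length(genome_b$unplaced)) {
      rb <- map_snps(snps[snps$rsid %in% unique_a, , drop = FALSE],
                     genome_b, sequences = "unplaced", ...)
      rescued_b <- rb$rsid[rb$status != "unmapped"]
    }
  }
  summary <- data.frame(
    assembly = c(genome_a$name, genome_b$name),
    found = c(length(found_a), length(found_b)),
    mapped = c(sum(sa$status == "mapped"), sum(sb$status == "mapped")),
    unique_found = c(length(unique_a), length(unique_b)),
    rescued_on_other_unplaced = c(length(rescued_b), length(rescued_a)),
    stringsAsFactors = FALSE)
  list(status_a = sa, status_b = sb, summary = summary,
       unique_a = unique_a, unique_b = unique_b,
       rescued_in_a = rescued_a, rescued_in_b = rescued_b)
}
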