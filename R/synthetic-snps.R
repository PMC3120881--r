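#' Plant SNPs with flanking-context sequences into a genome
#'
#' Positions are sampled uniformly over the placed chromosomes (optionally
#' restricted to, or kept away from, given regions); the context sequence is
#' copied verbatim from the source genome with the reference base at the
#' variant position, so in unique sequence `flank5 + ref + flank3` occurs
#' exactly once in the genome.
#'
#' @param genome a `GenomeAssembly`.
#' @param n_snps number of SNPs.
#' @param flank_bp flanking length on each side (>= 1; dbSNP contexts are
#'   typically ~250 bp).
#' @param within optional data frame (`chrom`,`start`,`end`); contexts are
#'   placed entirely inside these regions.
#' @param avoid optional data frame of regions the context must not touch.
#' @param min_spacing minimum distance between planted variant positions.
#' @param rsid_prefix id prefix (`rs` by default).
#' @param seed RNG seed.
#' @return list with `snps` (rsid/flank5/alleles/flank3 data frame, ref
#'   allele listed first) and `positions` (rsid/chrom/pos/ref/alt).
#' @export
plant_snps <- function(genome, n_snps, flank_bp = 250, within = NULL,
                       avoid = NULL, min_spacing = 1, rsid_prefix = "rs",
                       seed = 1) {
  flank_bp <- as.integer(flank_bp)
  if (flank_bp < 1L)
    stop("flank_bp must be >= 1 (a context needs flanking sequence)")
  with_seed(seed, {
    lens <- nchar(genome$placed)
    # sampling domains: (chrom, lo, hi) for the variant position
    if (is.null(within)) {
      dom <- data.frame(chrom = names(lens), lo = flank_bp + 1L,
                        hi = as.integer(lens) - flank_bp,
                        stringsAsFactors = FALSE)
    } else {
      dom <- data.frame(chrom = as.character(within$chrom),
                        lo = as.integer(within$start) + flank_bp,
                        hi = as.integer(within$end) - flank_bp,
                        stringsAsFactors = FALSE)
    }
    dom <- dom[dom$hi >= dom$lo, , drop = FALSE]
    if (nrow(dom) == 0L) stop("plant_snps: no room for contexts")
    w <- dom$hi - dom$lo + 1L

    bad_pos <- function(chrom, pos) {
      if (is.null(avoid)) return(FALSE)
      any(avoid$chrom == chrom &
            pos + flank_bp >= avoid$start & pos - flank_bp <= avoid$end)
    }

    chosen <- data.frame(chrom = character(0), pos = integer(0))
    tries <- 0L
    while (nrow(chosen) < n_snps) {
      tries <- tries + 1L
      if (tries > 200L * n_snps)
        stop("plant_snps: could not place ", n_snps, " SNPs")
      d <- dom[sample.int(nrow(dom), 1L, prob = w), ]
      pos <- rint(d$lo, d$hi)
      if (bad_pos(d$chrom, pos)) next
      if (any(chosen$chrom == d$chrom & abs(chosen$pos - pos) < min_spacing))
        next
      ref <- substr(genome$placed[[d$chrom]], pos, pos)
      if (ref == "N") next
      chosen <- rbind(chosen, data.frame(chrom = d$chrom, pos = pos,
                                         stringsAsFactors = FALSE))
    }
    chosen <- chosen[order(chosen$chrom, chosen$pos), , drop = FALSE]

    rsid <- sprintf("%s%06d", rsid_prefix, seq_len(n_snps))
    ref <- substring(genome$placed[chosen$chrom], chosen$pos, chosen$pos)
    alt <- vapply(ref, function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1),
      USE.NAMES = FALSE)
    flank5 <- substring(genome$placed[chosen$chrom],
                        chosen$pos - flank_bp, chosen$pos - 1L)
    flank3 <- substring(genome$placed[chosen$chrom],
                        chosen$pos + 1L, chosen$pos + flank_bp)
    snps <- data.frame(rsid = rsid, flank5 = flank5,
                       alleles = paste(ref, alt, sep = "/"),
                       flank3 = flank3, stringsAsFactors = FALSE)
    positions <- data.frame(rsid = rsid, chrom = chosen$chrom,
                            pos = chosen$pos, ref = ref, alt = alt,
                            stringsAsFactors = FALSE)
    list(snps = snps, positions = positions)
  })
}

#' Expected mapping outcome for planted SNPs under an event list
#'
#' A SNP whose context lies wholly inside a duplicated segment is expected
#' `found_not_mapped` (two perfect placements); wholly inside an unplaced
#' segment, `unmapped` against the placed chromosomes (and recoverable when
#' the unplaced pool is searched); overlapping deleted sequence, `unmapped`;
#' inside a segment that is merely moved or inverted, and everywhere else,
#' `mapped`.
#'
#' @param positions `positions` data frame from [plant_snps()].
#' @param events list of `EventSpec`.
#' @param flank_bp context flank length used when planting.
#' @return data frame with subject_id, subject_type, event_kinds,
#'   expected_outcome.
#' @export
snp_truth <- function(positions, events, flank_bp = 250) {
  if (inherits(events, "EventSpec")) events <- list(events)
  rows <- lapply(seq_len(nrow(positions)), function(i) {
    chrom <- positions$chrom[i]; pos <- positions$pos[i]
    lo <- pos - flank_bp; hi <- pos + flank_bp
    kinds <- character(0); outcome <- "mapped"
    for (e in events) {
      if (!e$kind %in% c("inversion", "translocation", "deletion",
                         "duplication", "unplace")) next
      if (e$chrom != chrom || e$start > hi || e$end < lo) next
      kinds <- c(kinds, e$kind)
      contains <- e$start <= lo && e$end >= hi
      outcome <- if (e$kind == "duplication" && contains) "found_not_mapped"
        else if (e$kind == "unplace" && contains) "unmapped"
        else if (e$kind == "deletion") "unmapped"
        else if (contains) "mapped"
        else "uncertain"
    }
    data.frame(subject_id = positions$rsid[i], subject_type = "snp",
               event_kinds = paste(unique(kinds), collapse = ","),
               expected_outcome = outcome, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
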