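#' Generate a random source genome
#'
#' Chromosome sequences are i.i.d. draws at a target GC fraction; output is a
#' pure function of the arguments including `seed`. This is the substrate
#' into which genes and SNPs are planted and from which a second, rearranged
#' assembly is derived.
#'
#' @param n_chrom number of placed chromosomes (>= 1).
#' @param chrom_length length of each chromosome in bp (recycled; >= 10 kb).
#' @param gc_fraction target GC content.
#' @param n_unplaced,unplaced_length optional pre-existing unplaced contigs.
#' @param seed RNG seed.
#' @return a `GenomeAssembly` with chromosomes `chr1..chrN`.
#' @export
generate_genome <- function(n_chrom = 2, chrom_length = 5e5,
                            gc_fraction = 0.42, n_unplaced = 0,
                            unplaced_length = 1e4, seed = 1) {
  stopifnot(n_chrom >= 1, all(chrom_length >= 1e4))
  lens <- rep_len(as.integer(chrom_length), n_chrom)
  with_seed(seed, {
    placed <- vapply(lens, random_dna, character(1), gc = gc_fraction)
    names(placed) <- paste0("chr", seq_len(n_chrom))
    unplaced <- character(0)
    if (n_unplaced > 0) {
      unplaced <- vapply(rep_len(as.integer(unplaced_length), n_unplaced),
                         random_dna, character(1), gc = gc_fraction)
      names(unplaced) <- paste0("un", seq_len(n_unplaced))
    }
    genome_assembly(placed, unplaced, name = "synthetic")
  })
}

# sense-strand codon tables for CDS construction
.sense_codons <- function() {
  gc <- Biostrings::GENETIC_CODE
  names(gc)[gc != "*"]
}
.stop_codons <- c("TAA", "TAG", "TGA")

# Build the sense-strand parts of one gene: utr5 | CDS | utr3 distributed
# over exons, introns forced to GT...AG. Returns list(mrna, protein, region,
# exon_offsets) where region is the genomic sense-strand gene region.
.build_gene <- function(exon_lens, intron_lens, utr5, utr3) {
  L <- sum(exon_lens)
  cds_len <- L - utr5 - utr3
  stopifnot(cds_len >= 9, cds_len %% 3 == 0)
  n_codon <- cds_len / 3
  body <- paste(sample(.sense_codons(), n_codon - 2L, replace = TRUE),
                collapse = "")
  cds <- paste0("ATG", body, sample(.stop_codons, 1L))
  mrna <- paste0(random_dna(utr5), cds, random_dna(utr3))
  introns <- vapply(intron_lens, function(n)
    paste0("GT", random_dna(n - 4L), "AG"), character(1))
  # interleave exons and introns on the sense strand
  ends <- cumsum(exon_lens)
  starts <- ends - exon_lens + 1L
  pieces <- character(0)
  for (i in seq_along(exon_lens)) {
    pieces <- c(pieces, substr(mrna, starts[i], ends[i]))
    if (i < length(exon_lens)) pieces <- c(pieces, introns[i])
  }
  region <- paste(pieces, collapse = "")
  # sense-strand offsets of each exon within the region
  off <- cumsum(c(0L, exon_lens[-length(exon_lens)] +
                    intron_lens))
  list(mrna = mrna, cds = c(utr5 + 1L, utr5 + cds_len), region = region,
       exon_off = off, exon_lens = exon_lens,
       protein = translate_cds(cds))
}

#' Plant multi-exon genes into a genome
#'
#' Writes non-overlapping gene regions into the chromosome sequences. Every
#' planted gene has canonical GT..AG introns, a CDS that starts with ATG,
#' ends with a stop codon and contains no internal stop, short UTRs, a gene
#' name (`GENE0001` ...) and an evidence accession (`EV000001` ...). Genes
#' land on both strands with equal probability. The stored model mRNA equals
#' the spliced transcript sequence and the model protein equals its
#' conceptual translation, by construction (and both are verified by tests).
#'
#' @param genome a `GenomeAssembly` (placed chromosomes are modified).
#' @param n_genes number of genes to plant.
#' @param exon_count_range,exon_len_range,intron_len_range inclusive ranges
#'   sampled uniformly per gene/exon/intron.
#' @param utr_len_range range of 5'/3' UTR lengths.
#' @param intergenic_min minimum gap between planted gene regions.
#' @param frame_preserving force every exon and UTR length to a multiple of
#'   3, so that skipping an exon keeps the downstream reading frame (used by
#'   exon-exclusion protein scenarios).
#' @param seed RNG seed.
#' @return list with elements `genome` (modified assembly), `annotation`
#'   (an `AnnotationSet`), `mrnas` and `proteins` (named character vectors).
#' @export
plant_genes <- function(genome, n_genes, exon_count_range = c(2, 8),
                        exon_len_range = c(100, 300),
                        intron_len_range = c(60, 2000),
                        utr_len_range = c(9, 30),
                        intergenic_min = 300, frame_preserving = FALSE,
                        seed = 1) {
  stopifnot(n_genes >= 1, intron_len_range[1] >= 10)
  with_seed(seed, {
    chrom_ids <- names(genome$placed)
    seqs <- genome$placed
    cursors <- vapply(chrom_ids, function(i) rint(50L, 200L), integer(1))
    txs <- vector("list", n_genes)
    mrnas <- character(n_genes)
    prots <- character(n_genes)
    r3 <- function(x) if (frame_preserving) pmax(3L, as.integer(round(x / 3) * 3)) else as.integer(x)
    ci <- 1L
    for (g in seq_len(n_genes)) {
      n_ex <- rint(exon_count_range[1], exon_count_range[2])
      exon_lens <- r3(rint(exon_len_range[1], exon_len_range[2], n_ex))
      intron_lens <- if (n_ex > 1)
        rint(intron_len_range[1], intron_len_range[2], n_ex - 1L) else integer(0)
      utr5 <- r3(rint(utr_len_range[1], utr_len_range[2]))
      utr3 <- r3(rint(utr_len_range[1], utr_len_range[2]))
      # keep CDS length a codon multiple
      rem <- (sum(exon_lens) - utr5 - utr3) %% 3L
      utr3 <- utr3 + rem
      span <- sum(exon_lens) + sum(intron_lens)

      placed_ok <- FALSE
      gap <- intergenic_min + rint(0L, intergenic_min)
      for (try in seq_along(chrom_ids)) {
        id <- chrom_ids[ci]
        start <- cursors[ci] + gap
        if (start + span - 1L <= nchar(seqs[[id]]) - 100L) {
          placed_ok <- TRUE
          break
        }
        ci <- ci %% length(chrom_ids) + 1L
      }
      if (!placed_ok)
        stop("plant_genes: insufficient space for gene ", g, " of ", n_genes)

      gene <- .build_gene(exon_lens, intron_lens, utr5, utr3)
      strand <- sample(c("+", "-"), 1L)
      region <- if (strand == "+") gene$region else revcomp(gene$region)
      Lr <- nchar(region)
      id <- chrom_ids[ci]
      substr(seqs[[id]], start, start + Lr - 1L) <- region
      cursors[ci] <- start + Lr - 1L
      ci <- ci %% length(chrom_ids) + 1L

      # genomic exon intervals (ascending order)
      if (strand == "+") {
        es <- start + gene$exon_off
        ee <- es + gene$exon_lens - 1L
      } else {
        # sense offset o (0-based) maps to genomic start + Lr - 1 - o
        ee <- start + Lr - 1L - gene$exon_off
        es <- ee - gene$exon_lens + 1L
        o <- order(es); es <- es[o]; ee <- ee[o]
      }
      tid <- sprintf("t%04d", g)
      txs[[g]] <- transcript(tid, id, strand,
                             data.frame(start = es, end = ee),
                             cds = gene$cds,
                             gene_name = sprintf("GENE%04d", g),
                             evidence = sprintf("EV%06d", g))
      mrnas[g] <- gene$mrna
      prots[g] <- gene$protein
    }
    names(mrnas) <- names(prots) <- vapply(txs, `[[`, character(1), "id")
    genome2 <- genome_assembly(seqs, genome$unplaced, name = genome$name)
    list(genome = genome2,
         annotation = annotation_set(txs, genome$name, genome2),
         mrnas = mrnas, proteins = prots)
  })
}
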