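# High-level simulation drivers: one call produces a source assembly with
# planted genes and SNPs, a derived assembly carrying labelled events, the
# derived assembly's (naively re-annotated) gene set, and ground truth for
# every planted gene and SNP.

#' Intergenic loci of an annotation
#'
#' Midpoints of gaps between annotated gene spans (and the chromosome
#' ends), used as safe destinations for translocations and duplications.
#'
#' @param annotation an `AnnotationSet`.
#' @param genome the matching `GenomeAssembly`.
#' @param min_gap smallest usable gap.
#' @return data frame (chrom, pos), ordered by decreasing gap size.
#' @export
intergenic_loci <- function(annotation, genome, min_gap = 500) {
  spans <- annotation_spans(annotation)
  rows <- list()
  for (chrom in names(genome$placed)) {
    sp <- spans[spans$chrom == chrom, ]
    bounds <- c(1L, sort(sp$end) + 1L)
    ends <- c(sort(sp$start) - 1L, genome_seqlen(genome, chrom))
    for (i in seq_along(bounds)) {
      w <- ends[i] - bounds[i] + 1L
      if (w >= min_gap)
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = chrom, pos = as.integer((bounds[i] + ends[i]) %/% 2L),
          gap = w, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(chrom = character(0), pos = integer(0)))
  out <- do.call(rbind, rows)
  out[order(-out$gap), c("chrom", "pos")]
}

# transcript-terminal exon (3' end) in genomic coordinates
.terminal_exon <- function(tx) {
  i <- if (tx$strand == "+") nrow(tx$exons) else 1L
  tx$exons[i, , drop = FALSE]
}

#' Build an event plan over planted genes
#'
#' Assigns disjoint genes to event categories and constructs the concrete
#' event list: `terminal_deletion` gaps out the 3'-terminal exon;
#' `internal_deletion` gaps out a middle exon; `inversion_breakpoint`
#' inverts a segment from mid-intron 1 to the last intron's midpoint
#' (breakpoints inside the gene); `translocation` and `duplication` move or
#' copy the whole gene span to an intergenic locus; `unplace` moves the
#' gene span to the unplaced pool; `frameshift` plants a 1-2 bp CDS indel.
#' Genes not assigned to any category stay event-free.
#'
#' @param planted result of [plant_genes()].
#' @param per_category genes per category.
#' @param categories subset of the categories above.
#' @param seed RNG seed for the assignment.
#' @return list(events, assignment) where assignment maps gene id to
#'   category (`"none"` for event-free genes).
#' @export
benchmark_event_plan <- function(planted,
                                 per_category = 20,
                                 categories = c("terminal_deletion",
                                                "internal_deletion",
                                                "inversion_breakpoint",
                                                "translocation",
                                                "frameshift"),
                                 seed = 1) {
  ann <- planted$annotation
  with_seed(seed, {
    ids <- sample(names(ann$transcripts))
    n_ex <- vapply(ann$transcripts[ids], function(tx) nrow(tx$exons),
                   integer(1))
    needs_multi <- c("internal_deletion", "inversion_breakpoint")
    assign <- stats::setNames(rep("none", length(ids)), ids)
    for (cat in categories) {
      pool <- names(assign)[assign == "none"]
      if (cat %in% needs_multi) pool <- pool[n_ex[pool] >= 3L]
      if (length(pool) < per_category)
        stop("not enough eligible genes for category ", cat)
      assign[pool[seq_len(per_category)]] <- cat
    }
    dests <- intergenic_loci(ann, planted$genome, min_gap = 300)
    di <- 0L
    next_dest <- function() {
      di <<- di + 1L
      if (di > nrow(dests)) stop("no intergenic destination left")
      dests[di, ]
    }
    events <- list()
    for (id in names(assign)[assign != "none"]) {
      tx <- ann$transcripts[[id]]
      sp <- tx_span(tx)
      cat <- assign[[id]]
      ev <- switch(
        cat,
        terminal_deletion = {
          e <- .terminal_exon(tx)
          event_spec("deletion", tx$chrom, e$start, e$end)
        },
        internal_deletion = {
          i <- (nrow(tx$exons) + 1L) %/% 2L
          i <- max(2L, min(i, nrow(tx$exons) - 1L))
          event_spec("deletion", tx$chrom, tx$exons$start[i],
                     tx$exons$end[i])
        },
        inversion_breakpoint = {
          n <- nrow(tx$exons)
          s <- (tx$exons$end[1L] + tx$exons$start[2L]) %/% 2L
          e <- (tx$exons$end[n - 1L] + tx$exons$start[n]) %/% 2L
          event_spec("inversion", tx$chrom, s, e)
        },
        translocation = {
          d <- next_dest()
          event_spec("translocation", tx$chrom, max(1L, sp[1L] - 50L),
                     sp[2L] + 50L, dest_chrom = d$chrom, dest_pos = d$pos)
        },
        duplication = {
          d <- next_dest()
          event_spec("duplication", tx$chrom, max(1L, sp[1L] - 50L),
                     sp[2L] + 50L, dest_chrom = d$chrom, dest_pos = d$pos)
        },
        unplace = event_spec("unplace", tx$chrom, max(1L, sp[1L] - 50L),
                             sp[2L] + 50L),
        frameshift = event_spec("frameshift_indel", gene = id,
                                indel = sample(c(-2L, -1L, 1L, 2L), 1L)),
        stop("unknown category ", cat))
      events[[length(events) + 1L]] <- ev
    }
    list(events = events,
         assignment = data.frame(gene = names(assign),
                                 category = unname(assign),
                                 stringsAsFactors = FALSE))
  })
}

#' Simulate a dual-assembly annotation benchmark
#'
#' One call builds the whole study system: a source genome with planted
#' genes and SNPs, a derived assembly carrying the requested events, the
#' derived assembly's lifted annotation, and truth records for every gene
#' and SNP. Deterministic for a given seed.
#'
#' @param n_chrom,chrom_length,gc_fraction source genome shape.
#' @param n_genes genes planted (see [plant_genes()]; `gene_opts` passes
#'   extra arguments through).
#' @param events list of `EventSpec`, or a function of the
#'   [plant_genes()] result returning one (so targets can reference
#'   genes), or `NULL` for none.
#' @param n_snps SNPs planted outside event targets ("unique" SNPs).
#' @param snp_in_events named integer vector: extra SNPs planted wholly
#'   inside targets of the named event kinds, e.g.
#'   `c(duplication = 100, unplace = 100)`.
#' @param flank_bp SNP context flank length.
#' @param gene_opts list of extra arguments for [plant_genes()].
#' @param seed master seed; stage seeds are derived from it.
#' @return list with genome_a, annotation_a, mrnas, proteins, genome_b,
#'   annotation_b, map, events, snps, snp_positions, truth (genes and SNPs
#'   combined), flank_bp, seed.
#' @export
simulate_benchmark <- function(n_chrom = 2, chrom_length = 5e5,
                               gc_fraction = 0.42, n_genes = 100,
                               events = NULL, n_snps = 0,
                               snp_in_events = NULL, flank_bp = 250,
                               gene_opts = list(), seed = 1) {
  seed <- as.integer(seed)
  g0 <- generate_genome(n_chrom, chrom_length, gc_fraction,
                        seed = seed)
  pg <- do.call(plant_genes, c(list(genome = g0, n_genes = n_genes,
                                    seed = seed + 1L), gene_opts))
  if (is.function(events)) events <- events(pg)
  if (is.null(events)) events <- list()

  targets <- do.call(rbind, lapply(events, function(e)
    if (!is.null(e$chrom)) data.frame(chrom = e$chrom, start = e$start,
                                      end = e$end, kind = e$kind,
                                      stringsAsFactors = FALSE)))
  # insertion junctions (translocation/duplication destinations) also
  # interrupt contexts that straddle them
  dests <- do.call(rbind, lapply(events, function(e)
    if (!is.null(e$dest_chrom)) data.frame(chrom = e$dest_chrom,
                                           start = e$dest_pos,
                                           end = e$dest_pos,
                                           kind = "destination",
                                           stringsAsFactors = FALSE)))

  snps <- positions <- NULL
  if (n_snps > 0) {
    ps <- plant_snps(pg$genome, n_snps, flank_bp = flank_bp,
                     avoid = rbind(targets, dests), seed = seed + 2L)
    snps <- ps$snps; positions <- ps$positions
  }
  if (!is.null(snp_in_events)) {
    for (k in names(snp_in_events)) {
      within <- targets[targets$kind == k, , drop = FALSE]
      if (nrow(within) == 0L)
        stop("snp_in_events: no ", k, " event present")
      ps <- plant_snps(pg$genome, snp_in_events[[k]], flank_bp = flank_bp,
                       within = within, seed = seed + 2L + match(
                         k, names(snp_in_events)),
                       rsid_prefix = paste0("rs", substr(k, 1L, 3L), "_"))
      snps <- rbind(snps, ps$snps)
      positions <- rbind(positions, ps$positions)
    }
  }

  ev <- apply_events(pg$genome, pg$annotation, events, seed = seed + 9L)
  ann_b <- lift_annotation(pg$annotation, ev$map, ev$genome,
                           assembly_name = ev$genome$name)
  truth <- ev$truth
  if (!is.null(positions))
    truth <- rbind(truth, snp_truth(positions, events, flank_bp))

  list(genome_a = pg$genome, annotation_a = pg$annotation,
       mrnas = pg$mrnas, proteins = pg$proteins,
       genome_b = ev$genome, annotation_b = ann_b, map = ev$map,
       events = events, snps = snps, snp_positions = positions,
       truth = truth, flank_bp = flank_bp, seed = seed)
}

#' Named scenario catalogue of classic mis-assembly failure modes
#'
#' Small, fully worked single-gene scenarios, each reproducing one failure
#' mode on a dedicated gene of one simulated system: `assembly_gap` (a
#' 200 bp gap in the core of an exon), `translocated_exon` (one internal
#' exon's segment moved away, recoverable only through a secondary
#' alignment), `inversion_split` (an intra-genic inversion splitting the
#' gene's alignments across strands), `tandem_duplication` (a whole-gene
#' segmental duplication giving multiple equally good placements),
#' `unplaced_segment` (a gene segment relocated to the unplaced pool) and
#' `inverted_contig_frameshift` (a small CDS indel scrambling the
#' downstream protein).
#'
#' @param seed RNG seed.
#' @return list with the simulation (`sim`) and `scenarios`, a data frame
#'   mapping scenario name to gene id and event kind.
#' @export
scenario_catalog <- function(seed = 1) {
  g0 <- generate_genome(2, 1.2e5, seed = seed)
  pg <- plant_genes(g0, 8, exon_count_range = c(4, 6),
                    intron_len_range = c(60, 500), seed = seed + 1L)
  ann <- pg$annotation
  ids <- names(ann$transcripts)
  dests <- intergenic_loci(ann, pg$genome)
  tx <- function(i) ann$transcripts[[ids[i]]]
  mid_exon <- function(t) {
    i <- (nrow(t$exons) + 1L) %/% 2L
    t$exons[max(2L, min(i, nrow(t$exons) - 1L)), , drop = FALSE]
  }
  e1 <- local({ # gap in the core of an exon
    ex <- mid_exon(tx(1)); mid <- (ex$start + ex$end) %/% 2L
    event_spec("deletion", tx(1)$chrom, mid - 100L, mid + 99L)
  })
  e2 <- local({ # internal exon segment translocated elsewhere
    ex <- mid_exon(tx(2))
    event_spec("translocation", tx(2)$chrom, ex$start, ex$end,
               dest_chrom = dests$chrom[1L], dest_pos = dests$pos[1L])
  })
  e3 <- local({ # intra-genic inversion
    t <- tx(3); n <- nrow(t$exons)
    event_spec("inversion", t$chrom,
               (t$exons$end[1L] + t$exons$start[2L]) %/% 2L,
               (t$exons$end[n - 1L] + t$exons$start[n]) %/% 2L)
  })
  e4 <- local({ # whole-gene duplication
    sp <- tx_span(tx(4))
    event_spec("duplication", tx(4)$chrom, sp[1L] - 50L, sp[2L] + 50L,
               dest_chrom = dests$chrom[2L], dest_pos = dests$pos[2L])
  })
  e5 <- local({ # gene segment moved to the unplaced pool
    sp <- tx_span(tx(5))
    event_spec("unplace", tx(5)$chrom, sp[1L] - 50L, sp[2L] + 50L)
  })
  e6 <- event_spec("frameshift_indel", gene = ids[6], indel = -1L)
  sim <- simulate_with_genome(pg, list(e1, e2, e3, e4, e5, e6),
                              seed = seed)
  list(sim = sim,
       scenarios = data.frame(
         scenario = c("assembly_gap", "translocated_exon",
                      "inversion_split", "tandem_duplication",
                      "unplaced_segment", "inverted_contig_frameshift"),
         gene = ids[1:6],
         kind = c("deletion", "translocation", "inversion", "duplication",
                  "unplace", "frameshift_indel"),
         stringsAsFactors = FALSE))
}

#' Finish a simulation from an existing planted genome and event list
#'
#' @param planted result of [plant_genes()].
#' @param events list of `EventSpec`.
#' @param seed RNG seed.
#' @return same shape as [simulate_benchmark()] (without SNPs).
#' @export
simulate_with_genome <- function(planted, events, seed = 1) {
  ev <- apply_events(planted$genome, planted$annotation, events,
                     seed = seed + 9L)
  ann_b <- lift_annotation(planted$annotation, ev$map, ev$genome,
                           assembly_name = ev$genome$name)
  list(genome_a = planted$genome, annotation_a = planted$annotation,
       mrnas = planted$mrnas, proteins = planted$proteins,
       genome_b = ev$genome, annotation_b = ann_b, map = ev$map,
       events = events, snps = NULL, snp_positions = NULL,
       truth = ev$truth, flank_bp = NA_integer_, seed = seed)
}
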