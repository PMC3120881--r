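test_that("genome generation is deterministic and respects GC content", {
  g1 <- generate_genome(2, 1e4 * 5, seed = 5)
  g2 <- generate_genome(2, 1e4 * 5, seed = 5)
  expect_identical(g1, g2)
  g3 <- generate_genome(2, 1e4 * 5, seed = 6)
  expect_false(identical(g1$placed, g3$placed))
  expect_equal(length(g1$placed), 2L)
  expect_equal(length(g1$unplaced), 0L)
  g <- generate_genome(1, 5e5, gc_fraction = 0.5, seed = 7)
  bases <- table(strsplit(g$placed[[1]], "")[[1]])
  gc <- sum(bases[c("C", "G")]) / sum(bases)
  expect_gte(gc, 0.48); expect_lte(gc, 0.52)
})

test_that("planted genes have canonical splice sites and clean CDS", {
  pg <- fx_small()
  for (tx in pg$annotation$transcripts) {
    s <- genome_seq(pg$genome, tx$chrom)
    n <- nrow(tx$exons)
    if (n < 2) next
    introns <- substring(s, tx$exons$end[-n] + 1, tx$exons$start[-1] - 1)
    # GT..AG on the gene's sense strand
    if (tx$strand == "-") introns <- rev(vapply(introns, revcomp, ""))
    expect_true(all(substr(introns, 1, 2) == "GT"))
    expect_true(all(substring(introns, nchar(introns) - 1) == "AG"))
    cds <- substr(pg$mrnas[[tx$id]], tx$cds[1], tx$cds[2])
    expect_equal(substr(cds, 1, 3), "ATG")
    expect_true(substring(cds, nchar(cds) - 2) %in% c("TAA", "TAG", "TGA"))
  }
  expect_false(any(grepl("*", pg$proteins, fixed = TRUE)))
})

test_that("planted transcripts do not overlap", {
  pg <- fx_small()
  sp <- annotation_spans(pg$annotation)
  for (ch in unique(sp$chrom)) {
    d <- sp[sp$chrom == ch][order(start)]
    if (nrow(d) > 1)
      expect_true(all(d$start[-1] > d$end[-nrow(d)]))
  }
})

test_that("an empty event list reproduces the source assembly exactly", {
  pg <- fx_small()
  ev <- apply_events(pg$genome, pg$annotation, list(), seed = 1)
  expect_identical(ev$genome$placed, pg$genome$placed)
  expect_true(all(ev$truth$expected_outcome == "identical"))
  annB <- lift_annotation(pg$annotation, ev$map, ev$genome)
  expect_identical(lapply(annB$transcripts, `[[`, "exons"),
                   lapply(pg$annotation$transcripts, `[[`, "exons"))
})

test_that("an inversion containing a gene preserves its spliced sequence", {
  pg <- fx_small()
  tx <- pg$annotation$transcripts[[2]]
  sp <- tx_span(tx)
  ev <- apply_events(pg$genome, pg$annotation,
                     list(event_spec("inversion", tx$chrom, sp[1] - 30,
                                     sp[2] + 30)), seed = 1)
  annB <- lift_annotation(pg$annotation, ev$map, ev$genome)
  txb <- annB$transcripts[[tx$id]]
  expect_false(txb$strand == tx$strand)
  expect_identical(splice_transcript(txb, ev$genome), pg$mrnas[[tx$id]])
  tr <- ev$truth[ev$truth$subject_id == tx$id, ]
  expect_equal(tr$expected_outcome, "identical")
})

test_that("deleting an internal exon removes exactly that sequence from B", {
  pg <- fx_small()
  multi <- Filter(function(t) nrow(t$exons) >= 3, pg$annotation$transcripts)
  tx <- multi[[1]]
  i <- 2L
  exon_seq <- substr(genome_seq(pg$genome, tx$chrom), tx$exons$start[i],
                     tx$exons$end[i])
  ev <- apply_events(pg$genome, pg$annotation,
                     list(event_spec("deletion", tx$chrom,
                                     tx$exons$start[i], tx$exons$end[i])),
                     seed = 1)
  bseq <- genome_seq(ev$genome, tx$chrom)
  expect_false(grepl(exon_seq, bseq, fixed = TRUE))          # exon gone
  expect_equal(nchar(bseq), genome_seqlen(pg$genome, tx$chrom))  # N gap
  tr <- ev$truth[ev$truth$subject_id == tx$id, ]
  expect_equal(tr$expected_outcome, "complex")
  # terminal-exon deletion of the same gene is a truncation instead
  term <- if (tx$strand == "+") nrow(tx$exons) else 1L
  ev2 <- apply_events(pg$genome, pg$annotation,
                      list(event_spec("deletion", tx$chrom,
                                      tx$exons$start[term],
                                      tx$exons$end[term])), seed = 1)
  expect_equal(ev2$truth$expected_outcome[ev2$truth$subject_id == tx$id],
               "truncation")
})

test_that("sequence totals are conserved up to the planted events", {
  pg <- fx_small()
  tot_a <- sum(nchar(pg$genome$placed))
  tx <- pg$annotation$transcripts[[3]]
  sp <- tx_span(tx)
  dests <- intergenic_loci(pg$annotation, pg$genome)
  ev <- apply_events(pg$genome, pg$annotation, list(
    event_spec("duplication", tx$chrom, sp[1], sp[2],
               dest_chrom = dests$chrom[1], dest_pos = dests$pos[1]),
    event_spec("deletion", dests$chrom[2], dests$pos[2] - 149,
               dests$pos[2] + 150, gap = FALSE)), seed = 1)
  dup_len <- sp[2] - sp[1] + 1
  expect_equal(sum(nchar(ev$genome$placed)), tot_a + dup_len - 300)
})

test_that("unplaced segments become unplaced contigs", {
  pg <- fx_small()
  tx <- pg$annotation$transcripts[[5]]
  sp <- tx_span(tx)
  ev <- apply_events(pg$genome, pg$annotation,
                     list(event_spec("unplace", tx$chrom, sp[1] - 20,
                                     sp[2] + 20)), seed = 1)
  expect_equal(length(ev$genome$unplaced), 1L)
  expect_equal(nchar(ev$genome$unplaced[[1]]), sp[2] - sp[1] + 41)
  annB <- lift_annotation(pg$annotation, ev$map, ev$genome)
  expect_equal(annB$transcripts[[tx$id]]$chrom, names(ev$genome$unplaced)[1])
  expect_equal(ev$truth$expected_outcome[ev$truth$subject_id == tx$id],
               "unplaced")
})

test_that("overlapping structural events are rejected", {
  pg <- fx_small()
  expect_error(apply_events(pg$genome, pg$annotation, list(
    event_spec("deletion", "chr1", 1000, 2000),
    event_spec("inversion", "chr1", 1500, 2500)), seed = 1),
    "overlapping")
})

test_that("substitution noise hits close to the requested rate", {
  pg <- fx_small()
  ev <- apply_events(pg$genome, pg$annotation,
                     list(event_spec("substitution_noise", rate = 0.01)),
                     seed = 3)
  a <- strsplit(pg$genome$placed[["chr1"]], "")[[1]]
  b <- strsplit(ev$genome$placed[["chr1"]], "")[[1]]
  rate <- mean(a != b)
  expect_gt(rate, 0.007); expect_lt(rate, 0.013)
  expect_true(all(ev$truth$expected_outcome == "near_identical"))
})

test_that("planted SNP contexts occur exactly once in the source genome", {
  pg <- fx_small()
  ps <- plant_snps(pg$genome, 10, flank_bp = 60, seed = 11)
  for (i in seq_len(10)) {
    ctx <- snp_query(ps$snps[i, ])
    hits <- sum(vapply(pg$genome$placed, function(s)
      length(gregexpr(ctx, s, fixed = TRUE)[[1]]) *
        (gregexpr(ctx, s, fixed = TRUE)[[1]][1] != -1), numeric(1)))
    expect_equal(hits, 1)
    # reference allele matches the genome at the planted position
    p <- ps$positions[i, ]
    expect_equal(substr(genome_seq(pg$genome, p$chrom), p$pos, p$pos),
                 p$ref)
  }
  expect_error(plant_snps(pg$genome, 5, flank_bp = 0), "flank")
  ps2 <- plant_snps(pg$genome, 10, flank_bp = 60, seed = 11)
  expect_identical(ps, ps2)
})

test_that("gene truth assigns frameshift and duplication outcomes", {
  sim <- fx_events()
  tg <- sim$truth[sim$truth$subject_type == "gene", ]
  expect_true(all(c("frameshift", "truncation", "complex", "identical")
                  %in% tg$expected_outcome))
  # every planted gene has exactly one truth record
  expect_setequal(tg$subject_id, names(sim$annotation_a$transcripts))
  expect_equal(anyDuplicated(tg$subject_id), 0L)
})
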