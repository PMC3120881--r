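test_that("k-mer index counts and lookups match direct enumeration", {
  g <- genome_assembly(c(chr = paste(rep("ACGTC", 6), collapse = "")))  # 30 bp
  idx <- kmer_index(g, k = 10)
  expect_equal(nrow(idx$dt), 21L)               # 30 - 10 + 1
  gN <- genome_assembly(c(chr = paste0(strrep("ACGTC", 3), "N",
                                       strrep("ACGTC", 3))))
  idxN <- kmer_index(gN, k = 10)
  expect_equal(nrow(idxN$dt), 22L - 10L)   # windows covering the N drop out
  hit <- lookup_kmer(idx, substr(g$placed[[1]], 3, 12))
  expect_true(3 %in% hit$pos)   # periodic sequence: every 5 bp
  none <- lookup_kmer(idx, "TTTTTTTTTT")
  expect_equal(nrow(none), 0L)
})

test_that("a duplicated segment doubles its k-mer positions", {
  set.seed(20)
  seg <- paste(sample(c("A", "C", "G", "T"), 1000, TRUE), collapse = "")
  g <- genome_assembly(c(chr = paste0(seg, strrep("T", 50), seg)))
  idx <- kmer_index(g, k = 20)
  for (off in c(1, 500, 981)) {
    hit <- lookup_kmer(idx, substr(seg, off, off + 19))
    expect_equal(nrow(hit), 2L)
  }
})

test_that("candidate windows contain the true locus and respect strand", {
  pg <- fx_small()
  idx <- fx_small_index()
  tx <- pg$annotation$transcripts[[1]]
  wins <- find_candidates(pg$mrnas[[tx$id]], idx)
  sp <- tx_span(tx)
  hitw <- wins[wins$seqid == tx$chrom & wins$strand == tx$strand, ]
  expect_gte(nrow(hitw), 1L)
  expect_true(any(hitw$start <= sp[1] & hitw$end >= sp[2]))
  set.seed(31)
  rnd <- paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
  expect_equal(nrow(find_candidates(rnd, idx)), 0L)
})

test_that("clean planted genes align back boundary- and strand-exact", {
  pg <- fx_small()
  alns <- fx_small_alns()
  expect_equal(length(alns), length(pg$mrnas))
  for (a in alns) {
    tx <- pg$annotation$transcripts[[a$query_id]]
    expect_identical(a$blocks$gstart, tx$exons$start)
    expect_identical(a$blocks$gend, tx$exons$end)
    expect_equal(a$strand, tx$strand)
    expect_equal(a$identity, 1)
    expect_equal(a$coverage, 1)
    expect_true(a$is_primary)
  }
})

test_that("a genome-deleted middle exon leaves that query segment unaligned", {
  pg <- fx_small()
  multi <- Filter(function(t) nrow(t$exons) >= 3,
                  pg$annotation$transcripts)
  tx <- multi[[1]]
  i <- 2L
  ev <- apply_events(pg$genome, pg$annotation,
                     list(event_spec("deletion", tx$chrom,
                                     tx$exons$start[i], tx$exons$end[i])),
                     seed = 2)
  idx <- kmer_index(ev$genome, 20)
  alns <- map_query(pg$mrnas[[tx$id]], ev$genome, idx, tx$id)
  expect_equal(length(alns), 1L)
  exon_len <- tx$exons$end[i] - tx$exons$start[i] + 1
  expect_equal(alns[[1]]$coverage,
               1 - exon_len / nchar(pg$mrnas[[tx$id]]), tolerance = 5e-3)
  expect_equal(alns[[1]]$identity, 1, tolerance = 1e-3)
})

test_that("the retention filter applies both thresholds at the boundary", {
  mk <- function(len, idn) structure(
    list(query_id = "q", aligned_bp = len, identity = idn,
         coverage = 1, is_primary = FALSE), class = "SplicedAlignment")
  kept <- filter_alignments(list(mk(99, 1), mk(1000, 0.951),
                                 mk(1000, 0.949), mk(100, 0.95)))
  expect_equal(vapply(kept, `[[`, numeric(1), "aligned_bp"), c(1000, 100))
  expect_true(all(vapply(kept, `[[`, numeric(1), "identity") >= 0.95))
})

test_that("primary selection prefers coverage, then identity, and keeps ties", {
  mk <- function(id, cov, idn, bp) structure(
    list(query_id = id, aligned_bp = bp, identity = idn, coverage = cov,
         is_primary = FALSE), class = "SplicedAlignment")
  out <- select_primary(list(mk("q", 0.9, 1.0, 900),
                             mk("q", 1.0, 0.96, 1000)))
  expect_equal(vapply(out, `[[`, logical(1), "is_primary"), c(FALSE, TRUE))
  ties <- select_primary(list(mk("q", 1, 1, 500), mk("q", 1, 1, 500)))
  expect_true(all(vapply(ties, `[[`, logical(1), "is_primary")))
  single <- select_primary(list(mk("q", 0.4, 0.9, 100)))
  expect_true(single[[1]]$is_primary)
})

test_that("a duplicated gene keeps both perfect copies as primary", {
  pg <- fx_small()
  tx <- pg$annotation$transcripts[[4]]
  sp <- tx_span(tx)
  dests <- intergenic_loci(pg$annotation, pg$genome)
  d <- dests[dests$chrom != tx$chrom, ][1, ]
  ev <- apply_events(pg$genome, pg$annotation,
                     list(event_spec("duplication", tx$chrom, sp[1] - 50,
                                     sp[2] + 50, dest_chrom = d$chrom,
                                     dest_pos = d$pos)), seed = 2)
  idx <- kmer_index(ev$genome, 20)
  alns <- select_primary(map_query(pg$mrnas[[tx$id]], ev$genome, idx,
                                   tx$id))
  expect_equal(length(alns), 2L)
  expect_true(all(vapply(alns, `[[`, logical(1), "is_primary")))
  # query overlapping a duplicated segment yields two candidate windows
  wins <- find_candidates(pg$mrnas[[tx$id]], idx)
  expect_gte(nrow(wins), 2L)
})

test_that("aligner identity agrees with the DP edit-distance oracle", {
  pg <- fx_small()
  set.seed(55)
  devs <- replicate(30, {
    L <- sample(120:500, 1)
    start <- sample(1e4, 1)
    target <- substr(pg$genome$placed[["chr1"]], start, start + L - 1)
    query <- mutate_dna(target, sub_rate = runif(1, 0, 0.08))
    g1 <- genome_assembly(c(win = paste0(strrep("T", 40), target,
                                         strrep("T", 40))))
    idx <- kmer_index(g1, 12)
    alns <- map_query(query, g1, idx, "q", min_intron = 1e9)
    if (length(alns) == 0) return(NA_real_)
    best <- alns[[which.max(vapply(alns, `[[`, numeric(1), "aligned_bp"))]]
    L <- max(nchar(query), nchar(target))
    cost <- sum(best$blocks$mismatches) + sum(best$blocks$indels) +
      (nchar(query) - best$aligned_bp)
    abs((1 - cost / L) - dp_identity_oracle(query, target))
  })
  expect_true(all(is.finite(devs)))
  expect_lte(max(devs), 0.01)
})

test_that("coverage curves are monotone and all >= best pointwise", {
  pg <- fx_small()
  alns <- fx_small_alns()
  qlen <- stats::setNames(nchar(pg$mrnas), names(pg$mrnas))
  all_c <- coverage_curve(alns, qlen, "all")
  best_c <- coverage_curve(alns, qlen, "best")
  expect_true(all(diff(all_c$count) <= 0))
  expect_true(all(diff(best_c$count) <= 0))
  expect_true(all(all_c$count >= best_c$count))
  # perfectly aligned queries: count = N at every x
  expect_true(all(all_c$count == length(pg$mrnas)))
})
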