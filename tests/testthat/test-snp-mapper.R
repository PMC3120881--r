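test_that("a planted SNP in unique sequence maps once, exactly", {
  pg <- fx_small()
  ps <- plant_snps(pg$genome, 6, flank_bp = 100, seed = 31)
  idx <- kmer_index(pg$genome, 20)
  for (i in seq_len(6)) {
    hits <- map_context(ps$snps[i, ], pg$genome, idx)
    expect_equal(nrow(hits), 1L)
    expect_equal(hits$identity, 1)
    expect_equal(hits$coverage, 1)
    expect_equal(hits$snp_pos, ps$positions$pos[i])
    expect_equal(hits$chrom, ps$positions$chrom[i])
  }
})

test_that("the variant column scores as a free match", {
  pg <- fx_small()
  ps <- plant_snps(pg$genome, 1, flank_bp = 100, seed = 32)
  p <- ps$positions[1, ]
  # mutate the genome at the variant site to the alternate allele
  seqs <- pg$genome$placed
  substr(seqs[[p$chrom]], p$pos, p$pos) <- p$alt
  g2 <- genome_assembly(seqs, name = "alt")
  hits <- map_context(ps$snps[1, ], g2, kmer_index(g2, 20))
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$identity, 1)   # would be 200/201 without the free match
  st <- classify_snp(hits)
  expect_equal(st$status, "mapped")
})

test_that("duplication doubles the placement; deletion removes it", {
  sim <- fx_memo("snp_events", function() {
    ev_fun <- function(pg) list(
      event_spec("duplication", "chr1", 150000, 190000,
                 dest_chrom = "chr2", dest_pos = 200000),
      event_spec("deletion", "chr2", 150000, 160000))
    simulate_benchmark(n_chrom = 2, chrom_length = 2.5e5, n_genes = 6,
                       events = ev_fun, n_snps = 10,
                       snp_in_events = c(duplication = 4, deletion = 3),
                       flank_bp = 150, seed = 33)
  })
  st <- map_snps(sim$snps, sim$genome_b)
  truth <- merge(st, sim$truth, by.x = "rsid", by.y = "subject_id")
  expect_true(all(truth$status[truth$expected_outcome == "mapped"] ==
                    "mapped"))
  expect_true(all(truth$status[truth$expected_outcome ==
                                 "found_not_mapped"] == "found"))
  expect_true(all(truth$status[truth$expected_outcome == "unmapped"] ==
                    "unmapped"))
  dup <- truth$rsid[truth$expected_outcome == "found_not_mapped"][1]
  hits <- map_context(sim$snps[sim$snps$rsid == dup, ], sim$genome_b,
                      kmer_index(sim$genome_b, 20))
  expect_equal(nrow(hits), 2L)
})

test_that("tier thresholds follow the 90/90 found and unique >95 mapped rule", {
  mk <- function(chrom, start, idn, cov) data.frame(
    chrom = chrom, start = start, end = start + 500L, strand = "+",
    identity = idn, coverage = cov, snp_pos = start + 250L,
    stringsAsFactors = FALSE)
  expect_equal(classify_snp(mk("c1", 1, 1, 1))$status, "mapped")
  two <- rbind(mk("c1", 1, 1, 1), mk("c2", 1, 1, 1))
  expect_equal(classify_snp(two)$status, "found")
  expect_equal(classify_snp(mk("c1", 1, 0.93, 0.95))$status, "found")
  expect_equal(classify_snp(mk("c1", 1, 0.95, 0.95))$status, "found")
  expect_equal(classify_snp(mk("c1", 1, 0.951, 0.95))$status, "mapped")
  expect_equal(classify_snp(mk("c1", 1, 0.89, 0.95))$status, "unmapped")
  expect_equal(classify_snp(mk("c1", 1, 1, 0.85))$status, "unmapped")
  # overlapping reports of one locus are merged before the uniqueness test
  split2 <- rbind(mk("c1", 1, 1, 1), mk("c1", 100, 0.97, 0.95))
  expect_equal(classify_snp(split2)$status, "mapped")
})

test_that("mapped implies found across random hit tables", {
  set.seed(44)
  for (i in 1:20) {
    n <- sample(0:4, 1)
    hits <- if (n == 0) {
      data.frame(chrom = character(0), start = integer(0),
                 end = integer(0), strand = character(0),
                 identity = numeric(0), coverage = numeric(0),
                 snp_pos = integer(0))
    } else {
      data.frame(chrom = sample(c("c1", "c2"), n, TRUE),
                 start = sample.int(1e5, n),
                 end = sample.int(1e5, n) + 1e5,
                 strand = "+",
                 identity = runif(n, 0.7, 1),
                 coverage = runif(n, 0.7, 1),
                 snp_pos = NA_integer_)
    }
    st <- classify_snp(hits)$status
    if (st == "mapped") {
      # a mapped SNP always satisfies the found filter too
      expect_true(any(hits$identity >= 0.90 & hits$coverage >= 0.90))
    }
    expect_true(st %in% c("unmapped", "found", "mapped"))
  }
})

test_that("reverse-complementing a chromosome preserves SNP status", {
  pg <- fx_small()
  ps <- plant_snps(pg$genome, 4, flank_bp = 120, seed = 35)
  st1 <- map_snps(ps$snps, pg$genome)
  flipped <- pg$genome$placed
  flipped[["chr1"]] <- revcomp(flipped[["chr1"]])
  g2 <- genome_assembly(flipped, name = "flipped")
  st2 <- map_snps(ps$snps, g2)
  expect_equal(st1$status, st2$status)
})

test_that("assembly comparison finds one-sided SNPs and rescues them", {
  sim <- fx_memo("snp_unplace", function() {
    ev_fun <- function(pg) list(event_spec("unplace", "chr1", 120000,
                                           170000))
    simulate_benchmark(n_chrom = 2, chrom_length = 2e5, n_genes = 4,
                       events = ev_fun, n_snps = 8,
                       snp_in_events = c(unplace = 5), flank_bp = 150,
                       seed = 36)
  })
  cmp <- compare_assemblies(sim$snps, sim$genome_a, sim$genome_b,
                            rescue_unplaced = TRUE)
  expect_equal(length(cmp$unique_a), 5L)   # the unplaced-segment SNPs
  expect_equal(length(cmp$unique_b), 0L)
  expect_setequal(cmp$rescued_in_b, cmp$unique_a)
  # identical assemblies: nothing is assembly-specific
  cmp2 <- compare_assemblies(sim$snps[1:3, ], sim$genome_a, sim$genome_a)
  expect_equal(length(cmp2$unique_a), 0L)
  expect_equal(length(cmp2$unique_b), 0L)
})
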