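test_that("interval arithmetic follows the 1-based inclusive convention", {
  expect_equal(interval_length(gintv("chr7", 49071505, 49071619)), 115L)
  expect_equal(interval_length(gintv("chr5", 45880245, 45886101)), 5857L)
  expect_equal(interval_length(gintv("chr1", 5, 5)), 1L)
  expect_error(gintv("chr1", 10, 5), "start")
})

test_that("overlap_length is symmetric, bounded and zero off-chromosome", {
  a <- gintv("chr1", 1, 100); b <- gintv("chr1", 51, 150)
  expect_equal(overlap_length(a, b), 50L)
  expect_equal(overlap_length(a, a), interval_length(a))
  expect_equal(overlap_length(a, gintv("chr1", 200, 300)), 0L)
  expect_equal(overlap_length(a, gintv("chr2", 1, 100)), 0L)
  set.seed(42)
  for (i in 1:25) {
    s1 <- sample(1000, 4)
    a <- gintv("c", min(s1[1:2]), max(s1[1:2]))
    b <- gintv("c", min(s1[3:4]), max(s1[3:4]))
    expect_equal(overlap_length(a, b), overlap_length(b, a))
    expect_lte(overlap_length(a, b),
               min(interval_length(a), interval_length(b)))
  }
})

test_that("splice extracts exon concatenation, reverse-complemented on minus", {
  g <- genome_assembly(c(chr = "ACGTACGTACGTACGTACGT"))
  tx_p <- transcript("p", "chr", "+",
                     data.frame(start = 3, end = 7))
  expect_equal(splice_transcript(tx_p, g), "GTACG")
  tx_m <- transcript("m", "chr", "-",
                     data.frame(start = c(3, 11), end = c(7, 15)))
  # exons GTACG + GTACG -> revcomp("GTACGGTACG") built by hand
  expect_equal(splice_transcript(tx_m, g), "CGTACCGTAC")
  expect_equal(spliced_length(tx_m), 10L)
  bad <- transcript("b", "chr", "+", data.frame(start = 15, end = 25))
  expect_error(splice_transcript(bad, g), "beyond")
  # reverse-complementing the assembly and flipping strand/coordinates
  # leaves the spliced sequence unchanged
  L <- nchar(g$placed[["chr"]])
  g_rc <- genome_assembly(c(chr = revcomp(g$placed[["chr"]])))
  tx_rc <- transcript("m2", "chr", "+",
                      data.frame(start = L - c(15, 7) + 1,
                                 end = L - c(11, 3) + 1))
  expect_equal(splice_transcript(tx_rc, g_rc), splice_transcript(tx_m, g))
})

test_that("planted genes splice back to their stored model mRNAs", {
  pg <- fx_small()
  for (id in names(pg$mrnas)) {
    expect_identical(splice_transcript(pg$annotation$transcripts[[id]],
                                       pg$genome), pg$mrnas[[id]])
  }
})

test_that("conceptual translation applies the standard code without correction", {
  g <- genome_assembly(c(chr = "AAATGAAATAACCC"))
  tx <- transcript("t", "chr", "+", data.frame(start = 1, end = 14),
                   cds = c(3, 11))
  expect_equal(conceptual_translation(tx, g)$sequence, "MK")
  # frameshifted CDS translated by hand: ATG AAC CCG GGT TTT GAC -> MNPGFD
  expect_equal(translate_cds("ATGAACCCGGGTTTTGAC"), "MNPGFD")
  # internal stop read through as '*': ATG TAA AAA TAA -> M*K
  expect_equal(translate_cds("ATGTAAAAATAA"), "M*K")
  # codon containing N -> X
  expect_equal(translate_cds("ATGANAAAA"), "MXK")
  no_cds <- transcript("n", "chr", "+", data.frame(start = 1, end = 14))
  expect_error(conceptual_translation(no_cds, g), "no CDS")
})

test_that("translation length equals CDS codons minus the trailing stop", {
  pg <- fx_small()
  for (id in names(pg$proteins)) {
    tx <- pg$annotation$transcripts[[id]]
    n_codon <- (tx$cds[2] - tx$cds[1] + 1) / 3
    expect_equal(nchar(pg$proteins[[id]]), n_codon - 1)  # stop dropped
    expect_false(grepl("*", pg$proteins[[id]], fixed = TRUE))
  }
})

test_that("transcript/genome coordinate conversion round-trips on both strands", {
  pg <- fx_small()
  for (id in head(names(pg$mrnas), 4)) {
    tx <- pg$annotation$transcripts[[id]]
    L <- spliced_length(tx)
    t_probe <- c(1L, 7L, L %/% 2L, L)
    for (tp in t_probe) {
      giv <- tx_to_genome(tx, tp, tp)
      expect_equal(genome_to_tx(tx, giv$start[1]), tp)
    }
    # whole CDS maps to intervals totalling the CDS length
    giv <- tx_to_genome(tx, tx$cds[1], tx$cds[2])
    expect_equal(sum(giv$end - giv$start + 1), tx$cds[2] - tx$cds[1] + 1)
  }
})

test_that("transcript invariants are enforced", {
  expect_error(transcript("t", "c", "+",
                          data.frame(start = c(1, 10), end = c(10, 20))),
               "intron")
  expect_error(transcript("t", "c", "+", data.frame(start = 1, end = 30),
                          cds = c(1, 10)), "multiple of 3")
  expect_error(transcript("t", "c", "+", data.frame(start = 1, end = 30),
                          cds = c(10, 45)), "outside")
  expect_error(annotation_set(list(
    transcript("a", "c", "+", data.frame(start = 1, end = 10)),
    transcript("a", "c", "+", data.frame(start = 20, end = 30)))),
    "duplicate")
})

test_that("protein records reject illegal residues", {
  expect_error(protein_record("p", "MKZ"), "illegal")
  expect_error(protein_record("p", ""), "empty")
  expect_equal(protein_record("p", "MK*X")$sequence, "MK*X")
})
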