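test_that("self-alignment is gapless, overhang-free and fully identical", {
  set.seed(4)
  p <- random_protein(120)
  a <- align_proteins(p, p)
  expect_equal(a$aligned_cols, 120L)
  expect_equal(a$identical_cols, 120L)
  expect_equal(a$gap_cols, 0L)
  expect_equal(unname(c(a$overhang_p, a$overhang_q)), rep(0L, 4))
  expect_equal(a$identity, 1)
})

test_that("a 15-aa tail on the model appears as a one-sided overhang", {
  set.seed(5)
  p <- random_protein(150)
  q <- paste0(p, random_protein(15))
  a <- align_proteins(p, q)
  expect_equal(max(a$overhang_p), 0L)
  expect_equal(max(a$overhang_q), 15L)
  expect_equal(a$identical_cols, 150L)
})

test_that("alignment score equals the local affine DP oracle on toys", {
  mat <- annotrack:::.blosum62()
  set.seed(6)
  for (i in 1:20) {
    n <- sample(8:50, 1); m <- sample(8:50, 1)
    p <- random_protein(n); q <- random_protein(m)
    a <- align_proteins(p, q)
    expect_equal(a$score, affine_local_score_oracle(p, q, mat),
                 tolerance = 1e-8)
  }
})

test_that("modified identity excludes gap columns from the denominator", {
  aln <- structure(list(aligned_cols = 100L, identical_cols = 85L,
                        gap_cols = 10L, gap_openings = 2L,
                        longest_gap = 6L, overhang_p = c(0L, 0L),
                        overhang_q = c(0L, 0L), identity = 0.85,
                        score = 0), class = "ProteinAlignment")
  expect_equal(modified_identity(aln), 85 / 90)
  all_gaps <- aln; all_gaps$gap_cols <- 100L
  expect_error(modified_identity(all_gaps), "gap")
})

test_that("the difference taxonomy assigns the documented classes", {
  set.seed(7)
  p <- random_protein(300)
  expect_equal(classify_protein_pair(p, p), "identical")
  # light substitution noise, no indels: near-identical
  pc <- strsplit(p, "")[[1]]
  at <- sample(300, 6)
  pc[at] <- vapply(pc[at], function(r)
    sample(setdiff(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], r), 1), "")
  noisy <- paste(pc, collapse = "")
  expect_equal(classify_protein_pair(noisy, p), "near_identical")
  # 30-aa internal deletion, rest exact: gapped
  del30 <- paste0(substr(p, 1, 100), substr(p, 131, 300))
  expect_equal(classify_protein_pair(del30, p), "gapped")
  # long extra tail on the prediction only: extension
  expect_equal(classify_protein_pair(paste0(p, random_protein(40)), p),
               "extension")
  # prediction stops 40 aa short: truncation
  expect_equal(classify_protein_pair(substr(p, 1, 260), p), "truncation")
  # prediction with an unalignable head, model with an unalignable tail:
  # the ends of both sequences fail to align
  div <- paste0(random_protein(40), substr(p, 41, 240))
  expect_equal(classify_protein_pair(div, p), "divergent_ends")
  # wholly unrelated sequences also clip both ends (documented precedence
  # of divergent_ends over different)
  expect_equal(classify_protein_pair(random_protein(200),
                                     random_protein(200)),
               "divergent_ends")
  # anchored ends with a garbage core: low identity, different
  garb <- paste0(substr(p, 1, 20), random_protein(160),
                 substr(p, 281, 300))
  expect_equal(classify_protein_pair(garb, p), "different")
})

test_that("every pair gets exactly one class and self-pairs are identical", {
  set.seed(9)
  classes <- annotrack:::.protein_classes
  for (i in 1:25) {
    p <- random_protein(sample(30:150, 1))
    q <- if (runif(1) < 0.3) p else {
      # random edits of p
      pc <- strsplit(p, "")[[1]]
      k <- sample(0:20, 1)
      if (k > 0) pc[sample(length(pc), min(k, length(pc)))] <-
          sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], min(k, length(pc)),
                 replace = TRUE)
      paste(pc, collapse = "")
    }
    cl <- classify_protein_pair(p, q)
    expect_true(cl %in% classes)
    expect_equal(classify_protein_pair(q, q), "identical")
  }
})

test_that("frameshifted conceptual translations leave the near-identical tier", {
  sim <- fx_events()
  shifted <- unlist(lapply(sim$events, function(e)
    if (e$kind == "frameshift_indel") e$gene))
  predicted <- translate_annotation(sim$annotation_b, sim$genome_b)
  for (id in shifted) {
    cl <- classify_protein_pair(predicted[[id]], sim$proteins[[id]])
    expect_false(cl %in% c("identical", "near_identical"))
    # the scrambled tail carries premature stops
    expect_true(grepl("*", predicted[[id]], fixed = TRUE))
  }
})

test_that("in-frame exon exclusion produces a gapped pair", {
  g0 <- generate_genome(1, 5e4, seed = 21)
  pg <- plant_genes(g0, 3, exon_count_range = c(4, 5),
                    exon_len_range = c(99, 201),
                    intron_len_range = c(60, 300),
                    frame_preserving = TRUE, seed = 22)
  tx <- pg$annotation$transcripts[[1]]
  ev <- apply_events(pg$genome, pg$annotation,
                     list(event_spec("deletion", tx$chrom,
                                     tx$exons$start[3], tx$exons$end[3])),
                     seed = 23)
  annB <- lift_annotation(pg$annotation, ev$map, ev$genome)
  pred <- conceptual_translation(annB$transcripts[[tx$id]], ev$genome)
  expect_equal(classify_protein_pair(pred, pg$proteins[[tx$id]]), "gapped")
})

test_that("the protein summary keeps the fixed row order and totals", {
  cls <- c(rep("identical", 5), rep("near_identical", 2), "gapped",
           "different", "other")
  s <- summarize_protein_classes(cls)
  expect_equal(s$classification[1:2], c("Identical", "Near-identical"))
  expect_equal(sum(s$n), attr(s, "total"))
  expect_equal(s$n[1], 5L)
  expect_equal(s$pct[1], 50)
})
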