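mk_struct <- function(starts, ends, chrom = "chr1", ...) {
  exon_structure(chrom, data.frame(start = starts, end = ends), ...)
}

test_that("comparability needs 50 bp of exonic overlap and a shared intron", {
  a <- mk_struct(c(100, 300, 600), c(200, 400, 700))
  expect_true(is_comparable(a, a))
  # 49 bp exonic overlap is below the threshold
  expect_false(is_comparable(a, mk_struct(152, 200)))
  b50 <- mk_struct(151, 200)
  expect_true(is_comparable(a, b50))   # single-exon partner: no intron rule
  # multi-exon pair with all intron boundaries shifted by 40 bp
  b_shift <- mk_struct(c(100, 340, 640), c(240, 440, 700))
  expect_false(is_comparable(a, b_shift))
  expect_false(is_comparable(a, mk_struct(100, 700, chrom = "chr2")))
})

test_that("compatibility tolerates the margin and is symmetric", {
  a <- mk_struct(c(100, 300, 600), c(200, 400, 700))
  expect_true(is_compatible(a, a))
  b19 <- mk_struct(c(100, 319, 600), c(200, 400, 700))
  expect_true(is_compatible(a, b19))
  b21 <- mk_struct(c(100, 321, 600), c(200, 400, 700))
  expect_false(is_compatible(a, b21))
  b_missing <- mk_struct(c(100, 600), c(200, 700))
  expect_false(is_compatible(a, b_missing))
  set.seed(12)
  for (i in 1:20) {
    sa <- sort(sample(1000, 6)); sb <- sort(sample(1000, 4))
    x <- mk_struct(sa[c(1, 3, 5)], sa[c(2, 4, 6)])
    y <- mk_struct(sb[c(1, 3)], sb[c(2, 4)])
    expect_equal(is_compatible(x, y), is_compatible(y, x))
  }
})

test_that("the priority code follows the documented order", {
  a <- mk_struct(c(100, 300, 600), c(200, 400, 700),
                 gene_name = "G1", evidence = "E1")
  same <- mk_struct(c(100, 300, 600), c(200, 400, 700),
                    gene_name = "G1", evidence = "E1")
  expect_equal(classify_pair(a, same)$level, 1L)
  anon <- mk_struct(c(100, 300, 600), c(200, 400, 700))
  expect_equal(classify_pair(a, anon)$level, 2L)
  # candidate with one extra upstream exon, internal structure identical
  ext1 <- mk_struct(c(10, 100, 300, 600), c(50, 200, 400, 700))
  expect_equal(classify_pair(a, ext1)$level, 3L)
  ext2 <- mk_struct(c(10, 100, 300, 600, 800), c(50, 200, 400, 700, 900))
  expect_equal(classify_pair(a, ext2)$level, 4L)
  tr1 <- mk_struct(c(141, 300, 600), c(200, 400, 700))
  expect_equal(classify_pair(a, tr1)$level, 5L)
  tr2 <- mk_struct(c(141, 300), c(200, 400))
  expect_equal(classify_pair(a, tr2)$level, 6L)
  # candidate merges a's first two exons (internal structure differs but
  # the second intron is still shared): complex
  cx <- mk_struct(c(100, 600), c(400, 700))
  expect_equal(classify_pair(a, cx)$level, 7L)
  expect_error(classify_pair(a, mk_struct(5000, 6000)), "comparable")
})

test_that("classification is exhaustive and self-pairs are identical", {
  pg <- fx_small()
  for (tx in pg$annotation$transcripts) {
    s <- structure_of_transcript(tx)
    cls <- classify_pair(s, s)
    expect_equal(cls$level, 1L)  # planted genes carry name and evidence
    anon <- s; anon$gene_name <- NULL; anon$evidence <- NULL
    expect_equal(classify_pair(anon, anon)$level, 2L)
  }
  set.seed(99)
  for (i in 1:40) {
    sa <- sort(sample(2000, 8)); sb <- sort(sample(2000, 6))
    x <- mk_struct(sa[c(1, 3, 5, 7)], sa[c(2, 4, 6, 8)])
    y <- mk_struct(sb[c(1, 3, 5)], sb[c(2, 4, 6)])
    if (!is_comparable(x, y)) next
    lev <- classify_pair(x, y)$level
    expect_true(lev %in% 1:7)  # exactly one class, always
  }
})

test_that("best-match assignment uses priority then common exons", {
  a <- mk_struct(c(100, 300, 600), c(200, 400, 700))
  p2 <- mk_struct(c(100, 300, 600), c(200, 400, 700), id = "p2")
  p3 <- mk_struct(c(10, 100, 300, 600), c(50, 200, 400, 700), id = "p3")
  bm <- assign_best_match(a, list(p3, p2))
  expect_equal(bm$candidate$id, "p2")
  expect_null(assign_best_match(a, list()))
  one <- assign_best_match(a, list(p3))
  expect_equal(one$candidate$id, "p3")
  # two complex candidates: more common exons wins
  c3 <- mk_struct(c(100, 300, 600, 900), c(200, 400, 700, 950), id = "c3")
  c1 <- mk_struct(c(100, 300, 900), c(200, 400, 950), id = "c1")
  a2 <- mk_struct(c(100, 300, 600, 820), c(200, 400, 700, 870))
  bm2 <- assign_best_match(a2, Filter(function(b)
    is_comparable(a2, b), list(c1, c3)))
  expect_equal(bm2$candidate$id, "c3")
})

test_that("the class rollup sums to the total and maps levels correctly", {
  m <- data.frame(query = paste0("q", 1:20),
                  level = c(rep(1, 4), rep(2, 6), rep(3, 2), rep(4, 1),
                            rep(5, 3), rep(6, 1), rep(7, 3)))
  s <- summarize_classes(m)
  expect_equal(s$n, c(10L, 3L, 3L, 1L, 3L))
  expect_equal(sum(s$n), attr(s, "total"))
  expect_equal(s$pct, c(50, 15, 15, 5, 15))
  empty <- summarize_classes(data.frame(query = character(0),
                                        level = integer(0)))
  expect_equal(attr(empty, "total"), 0L)
  expect_true(all(empty$pct == 0))
})

test_that("agreement curves: self-comparison is complete, all >= best", {
  pg <- fx_small()
  alns <- fx_small_alns()
  qlen <- stats::setNames(nchar(pg$mrnas), names(pg$mrnas))
  ac <- agreement_curve(alns, pg$annotation, qlen, "all")
  bc <- agreement_curve(alns, pg$annotation, qlen, "best")
  expect_true(all(diff(ac$count) <= 0))
  expect_true(all(ac$count >= bc$count))
  # annotation compared against itself: every gene overlaps fully
  expect_equal(ac$count[ac$x == 1], length(pg$mrnas))
})

test_that("one-to-one pairs survive a clean run and break under duplication", {
  pg <- fx_small()
  rep0 <- run_pipeline(simulate_with_genome(pg, list(), seed = 4))
  best_ab <- rep0$matches
  # self-inverse direction: map B (== A) transcripts back
  best_ba <- data.frame(query = best_ab$candidate,
                        candidate = best_ab$query,
                        stringsAsFactors = FALSE)
  oo <- reciprocal_one_to_one(best_ab, best_ba)
  expect_equal(nrow(oo), length(pg$mrnas))
  # duplicate one gene in B: its pair must drop out
  dup_q <- best_ab$query[1]
  best_ba2 <- rbind(best_ba,
                    data.frame(query = "t_extra", candidate = dup_q))
  oo2 <- reciprocal_one_to_one(best_ab, best_ba2)
  expect_false(dup_q %in% oo2$a)
  expect_equal(nrow(reciprocal_one_to_one(
    best_ab[0, ], best_ba[0, ])), 0L)
})

test_that("sequence validation finds full-length and rejects absent queries", {
  pg <- fx_small()
  seqs <- pg$mrnas
  hits <- validate_unique(seqs[1], seqs[1:3])
  expect_true(any(hits$subject == names(seqs)[1] & hits$complete))
  set.seed(8)
  rnd <- paste(sample(c("A", "C", "G", "T"), 400, TRUE), collapse = "")
  none <- validate_unique(c(x = rnd), seqs[1:3])
  expect_equal(nrow(none), 0L)
  # a 96 bp transcript fully contained in another mRNA: complete hit
  frag <- substr(seqs[[2]], 101, 196)
  cont <- validate_unique(c(frag96 = frag), seqs[2])
  expect_true(nrow(cont) == 1 && cont$complete)
})
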