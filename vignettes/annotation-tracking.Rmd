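---
title: "Tracking gene, protein and SNP annotation across assemblies of one genome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking gene, protein and SNP annotation across assemblies of one genome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

When a draft genome is re-assembled, its annotation changes with it. Some
changes reflect genuinely better sequence; others are artifacts of the
assembly itself — contig inversions and translocations that split genes
across strands, scaffold gaps that swallow exons, segmental duplications
that produce several equally good placements, sequence relocated to the
unplaced pool, and single-base errors or frameshifting indels that scramble
a predicted protein downstream of the error. A scientist tracking a gene
between two releases of the *same* genome needs to know whether the gene
moved, shrank, split, or disappeared — and whether an apparent change in
the protein is biology or a mis-assembly.

`annotrack` implements a complete, testable framework for that comparison:

* a **spliced aligner** that maps transcript sequences from one assembly
  onto the other,
* an **exon–intron structure comparator** that classifies each mapped
  transcript against the local annotation with a seven-level priority
  code,
* a **protein comparator** that classifies conceptual translations
  against their reference models,
* a **two-tier SNP remapper** for flanking-context sequences, and
* a **dual-assembly simulator** that plants genes and SNPs in a source
  genome, derives a second assembly carrying labelled mis-assembly events,
  and records the outcome every event is expected to produce — so every
  stage of the pipeline is validated against ground truth rather than
  against itself.

```{r, eval = FALSE}
library(annotrack)
sim <- simulate_benchmark(n_chrom = 2, chrom_length = 5e5, n_genes = 100,
                          n_snps = 500, seed = 1)
rep <- run_pipeline(sim)
rep
```

# The spliced aligner

Transcript-to-genome alignment runs in two stages. Candidate regions are
found by joining the query's 20-mers against a forward-strand k-mer index
of the target (`kmer_index()`, `find_candidates()`); the minus strand is
searched by reverse-complementing the query. Within each padded candidate
window, maximal exact matches of an inner seed size (12 by default) are
chained collinearly, and the chain is resolved into alignment blocks
(`align_spliced()`):

* small, balanced inter-anchor gaps are closed by a unit-cost
  Needleman–Wunsch fill (compiled);
* a genomic gap at least `min_intron` (30 bp) larger than the query gap
  becomes an **intron** with zero column cost; the exon boundary is placed
  by a match-count split of the ambiguous query bases and then shifted, by
  up to 10 bp and only when no matches are lost, onto canonical splice
  signals (GT..AG on the gene's sense strand);
* query segments that match nothing — a deleted exon, sequence swallowed
  by a gap — stay **unaligned** and reduce coverage rather than being
  forced into the alignment. Larger gap fills are accepted only when at
  least 60% of their columns match; this is what prevents chains of chance
  seed hits in random sequence from being laundered into high-identity
  alignments.

`identity` counts matching aligned columns over aligned (non-gap) columns
(a gap-inclusive variant is also reported); `coverage` is the fraction of
query bases inside blocks. Alignments are retained when the aligned span
is at least 100 bp at 95% identity or better, and the best alignment per
query — maximal coverage, then identity, then aligned length — is flagged
*primary*, with all exact ties kept (a transcript inside a perfect
segmental duplication legitimately has two primaries).

On clean simulated data the aligner recovers every planted gene's exon set
boundary-exactly, on the correct strand, at identity and coverage 1 — this
is a test invariant, not an aspiration. On noisy single-exon instances its
alignment cost (mismatches + indels + unaligned bases) stays within 1% of
the optimal edit-distance alignment computed by an independent dynamic
program.

# Structure comparison

The comparator never consumes the foreign transcript's native coordinates:
it compares the **alignment projection** (the blocks of the spliced
alignment) against the local annotation, which is what an annotation
browser effectively shows a user.

Two structures are *comparable* when their exons overlap by at least 50 bp
and, if both have several exons, they share at least one intron (both
boundaries within the margin). They are *compatible* when the structures
are identical along the genomic interval covered by both, with a margin of
error `V = 20` bp at every exon and intron boundary. Each comparable pair
gets one of seven priority levels: identical gene name and evidence
accession; identical structure; single- or double-end extension;
single-end truncation; double-end truncation or truncation coupled with
extension; complex. Best matches take the lowest level, with ties broken
by the largest number of common exons and finally by genomic coordinate so
that runs are exactly reproducible. The rollup maps P1–P2 to *identical*,
P3–P4 to *extensions*, P5 to *truncations*, P6 to *both*, P7 to *complex*.

Interpretations the method leaves open, fixed here: the shared-intron test
uses the same margin `V` as compatibility (configurable to exact); the
agreement curves measure exonic base pairs, not transcript spans; a
one-to-one correspondence means mutual best match with no third transcript
sharing either endpoint; and the common-exon tie-break uses margin `V`.

# Protein comparison

Conceptual translations are produced directly from the annotated CDS with
no curation: internal stop codons stay in the protein as `*` (read-through
rather than truncation — the convention under which frameshifts visibly
scramble the downstream sequence), and codons containing `N` translate to
`X`. Pairs are aligned with a local Smith–Waterman alignment (BLOSUM62,
affine gaps, via Biostrings) — the similarity-search style of alignment
classically used for this comparison; sequence ends that cannot be aligned
are reported as overhangs. A dovetail/ends-free mode was rejected because
it cannot leave both sequences' starts unaligned at once, which corrupts
overhang detection exactly in the divergent-ends cases it matters for.

The classifier applies, in order: **identical** (exact equality);
**near-identical** (end-to-end, identity ≥ 0.90, fewer than 10 gap
columns); **extension**/**truncation** (a near-identical region plus an
overhang > 10 aa on the predicted/model side only); **divergent ends**
(overhangs > 10 aa on both sequences); **gapped** (modified identity —
identity over non-gap columns — ≥ 0.90 with substantial gaps: ≥ 10
openings, one gap ≥ 30 aa, or ≥ 10 gap columns); **different** (aligned
identity < 0.50); **other**. Two quantifications are deliberate choices:
"few gaps" for near-identical is counted in gap *columns* rather than
openings, because a single clean 30-aa exon-skip gap must classify as
gapped, not near-identical; and `*` counts identical only against itself,
mismatching every residue. The divergent-ends test precedes the
low-identity test, so a pair failing at both ends is divergent rather than
different.

# SNP remapping

A SNP travels as its context sequence: the flanking genomic sequence
(250 bp each side in the simulator) with the variant base between. Mapping
is two-stage: long seeds (k = 20) first; only when that finds nothing, a
short-seed (k = 11) pass retrieves lower-similarity placements. The variant
column scores as a free match, so a genuine allele difference in the
target does not count against the placement. Hits whose intervals overlap
by at least half the shorter hit are merged before counting. A SNP is
**found** when some hit reaches 90% identity over 90% of the context, and
**mapped** when exactly one hit exceeds 95% identity at that coverage. By
default only placed chromosomes are searched; SNPs found in only one
assembly can be re-searched against the other assembly's unplaced contig
pool (`rescue_unplaced`), which recovers SNPs whose sequence was not lost
but merely unplaced. Coverage is computed against the full context length,
including the variant base.

# The simulator and its decision table

`generate_genome()` draws i.i.d. sequence at a target GC fraction (0.42 by
default, a mammalian-like value). `plant_genes()` writes non-overlapping
multi-exon genes with canonical GT..AG introns, an ATG..stop CDS free of
internal stops, short UTRs, and gene names/evidence accessions; genes land
on both strands with equal probability. Defaults — 2–8 exons of
100–300 bp, introns of 60–2000 bp, UTRs of 9–30 bp — produce compact but
realistically structured genes at the scale the package's validation runs
use (hundreds of kilobases per chromosome, around one gene per 4–8 kb).
The stored model mRNA equals the spliced transcript and the model protein
equals its conceptual translation by construction, and tests verify both.

`apply_events()` derives assembly B through a piece table: every output
sequence is an ordered list of copied (possibly reverse-complemented)
source intervals, N-gap pieces, and small insertions. Deletions default to
an equal-length run of N — a scaffold gap — with true excision as an
option; unplaced segments become unplaced contigs; substitution noise is
applied genome-wide; frameshift indels (±1–2 bp) land at the midpoint of a
gene's CDS so the scrambled tail is a substantial fraction of the protein.
The same piece table drives `lift_annotation()`, a deliberately *naive*
re-annotation of B: exons falling in gaps or excised sequence are dropped,
a gene split by a breakpoint keeps its largest collinear run of exons, the
CDS is re-derived from the surviving coding bases (frame-aligned at the
start, floored to a codon multiple), and genes wholly inside a duplicated
segment are annotated at both loci. This mirrors what an evidence-based
annotator produces on the rearranged sequence.

Every planted gene and SNP carries a truth record. The expected outcomes:
untouched genes are `identical` (`near_identical` under genome-wide
noise); deleting transcript-terminal exons is a `truncation`; an internal
exon deletion or an intra-genic inversion/translocation breakpoint is
`complex`; whole-gene inversions, translocations and duplications only
move the locus and stay `identical`; a frameshift changes the protein but
not the structure; whole-gene deletions are `lost` and unplaced genes
`unplaced`. SNPs inside duplicated segments are expected
`found_not_mapped`, inside unplaced segments `unmapped` (recoverable by
rescue), inside deletions `unmapped`, everywhere else `mapped`.

A subtlety worth stating: a deletion in B truncates *both* the projection
of A's transcript and B's re-derived annotation equally, so the pairwise
structure class of that gene is still "identical" — the information that
the gene shrank lives in the alignment geometry, not in the pair. The
pipeline therefore scores each gene with a composite observed outcome:
genes fragmented across loci or strands (union coverage of all retained
alignments exceeding primary coverage by more than `frag_tol` = 0.05) are
`complex`; an uncovered internal run longer than `gap_tol` = 20 bp is
`complex` and an uncovered terminal run a `truncation`; otherwise the
structure class decides, and for structurally identical genes the protein
class separates `identical`, `near_identical` and `protein_changed`. This
composite is what `evaluate_against_truth()` compares with the decision
table.

What the simulator does **not** emulate: repeat families and low-
complexity sequence (the i.i.d. background makes seeds more specific than
in a real mammalian genome), alternative splicing, non-canonical introns,
read-level artifacts, and annotation-evidence churn between releases
(which in real comparisons explains many extensions/truncations). Passing
recovery tests here therefore demonstrates the machinery's correctness on
unambiguous ground truth, not its robustness to repetitive genomes.

# Numerical and degenerate-input choices

Coordinates are 1-based inclusive everywhere; half-open external formats
are converted at the boundary. Exons are stored in ascending genomic order
regardless of strand. Percentages in report tables round half-up to one
decimal (`round_half_up()`), matching the convention of published summary
tables; empty inputs produce zero totals without division by zero. All
generator functions are pure functions of their arguments including the
seed, and the RNG state of the caller is restored afterwards. The final
best-match tie-break is genomic coordinate, so repeated runs are
byte-identical. Alignment windows, anchor chaining and gap fills are
bounded (window padding 2 kb, chain candidates capped, DP fills capped at
2 kb) so a pathological query degrades to a partial alignment rather than
a pathological runtime.

# Validation scales

The test suite and the acceptance script exercise the pipeline at sizes
chosen to give unambiguous statistics while staying comfortable on a
single CPU: null-case and SNP-tier runs on 2 × 400–500 kb genomes with
80–100 genes and 300–1000 SNPs, event-recovery runs with 15–20 genes per
event category among 150 planted genes, 100–200 random instances for the
aligner-versus-DP comparison, and 20-seed fuzz loops for the order and
containment invariants (curves non-increasing, all ≥ best pointwise,
mapped ⊆ found, classification exhaustive and exclusive).

# Limitations

The aligner is a purpose-built seeded heuristic, not a general-purpose
spliced aligner: it assumes seeds survive in most exons (exons shorter
than the inner seed size can only be recovered through the boundary-shift
step) and does not model polyA tails or processed pseudogenes. The
structure comparator is strand-agnostic by design — an inverted but intact
gene should still match its counterpart. The protein taxonomy thresholds
(90% identity, 10 gap columns, 10 aa overhangs, 50% for "different") are
the conventional values and are configurable; boundary cases between
`gapped`, `divergent_ends` and `other` are decided by the documented
precedence, not by optimization. Real-data comparisons should treat the
absolute percentages as convention-dependent and lean on the per-gene
tables the pipeline emits.
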