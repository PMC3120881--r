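# Comparison of conceptual protein translations against their reference
# models: local affine pairwise alignment (BLOSUM62) and the eight-class
# difference taxonomy (identical / near-identical / extension / truncation /
# divergent ends / gapped / different / other).

.blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

.aa_seq <- function(x) {
  if (inherits(x, "ProteinRecord")) x$sequence else as.character(x)
}

# gap-run statistics of an alignment string pair
.gap_stats <- function(p, s) {
  gp <- gregexpr("-+", p)[[1L]]
  gs <- gregexpr("-+", s)[[1L]]
  runs <- c(if (gp[1L] != -1L) attr(gp, "match.length"),
            if (gs[1L] != -1L) attr(gs, "match.length"))
  list(openings = length(runs), columns = sum(runs),
       longest = if (length(runs)) max(runs) else 0L)
}

#' Pairwise protein alignment
#'
#' Local (Smith-Waterman) alignment with BLOSUM62 scoring and affine gap
#' penalties, the classic similarity-search alignment for protein
#' comparison: unalignable sequence ends are left outside the aligned
#' region and reported as overhangs on each side of each sequence. Identity is
#' the fraction of alignment columns with identical residues; `*` (stop)
#' aligns like any other character and counts identical only against
#' itself.
#'
#' @param p predicted protein (conceptual translation); string or
#'   `ProteinRecord`.
#' @param q model (reference) protein.
#' @param gap_opening,gap_extension affine gap penalties.
#' @return an object of class `ProteinAlignment`: aligned_cols,
#'   identical_cols, gap_openings, gap_cols, longest_gap, overhang_p,
#'   overhang_q (2-vectors: start, end), identity, score.
#' @export
align_proteins <- function(p, q, gap_opening = 10, gap_extension = 0.5) {
  p <- .aa_seq(p); q <- .aa_seq(q)
  stopifnot(nzchar(p), nzchar(q))
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(p), Biostrings::AAString(q), type = "local",
    substitutionMatrix = .blosum62(), gapOpening = gap_opening,
    gapExtension = gap_extension)
  ap <- as.character(Biostrings::alignedPattern(pa))
  as_ <- as.character(Biostrings::alignedSubject(pa))
  cp <- chars(ap); cs <- chars(as_)
  aligned <- length(cp)
  identical_cols <- sum(cp == cs & cp != "-")
  gs <- .gap_stats(ap, as_)
  op <- c(Biostrings::start(Biostrings::pattern(pa)) - 1L,
          nchar(p) - Biostrings::end(Biostrings::pattern(pa)))
  oq <- c(Biostrings::start(Biostrings::subject(pa)) - 1L,
          nchar(q) - Biostrings::end(Biostrings::subject(pa)))
  structure(list(aligned_cols = aligned, identical_cols = identical_cols,
                 gap_openings = gs$openings, gap_cols = gs$columns,
                 longest_gap = gs$longest,
                 overhang_p = op, overhang_q = oq,
                 identity = if (aligned > 0) identical_cols / aligned else 0,
                 score = Biostrings::score(pa)),
            class = "ProteinAlignment")
}

#' @export
print.ProteinAlignment <- function(x, ...) {
  cat(sprintf(
    "ProteinAlignment: %d cols, %d identical (%.3f), %d gap cols in %d run(s), overhangs p=%d/%d q=%d/%d\n",
    x$aligned_cols, x$identical_cols, x$identity, x$gap_cols,
    x$gap_openings, x$overhang_p[1L], x$overhang_p[2L], x$overhang_q[1L],
    x$overhang_q[2L]))
  invisible(x)
}

#' Modified sequence identity of a protein alignment
#'
#' Average identity over the aligned residues only, excluding gap columns;
#' the statistic that lets an exon-exclusion alignment with long gaps still
#' show its residue-level agreement.
#'
#' @param aln a `ProteinAlignment`.
#' @return fraction in `[0, 1]`.
#' @export
modified_identity <- function(aln) {
  nongap <- aln$aligned_cols - aln$gap_cols
  if (nongap <= 0L) stop("modified_identity undefined: all columns are gaps")
  aln$identical_cols / nongap
}

.protein_classes <- c("identical", "near_identical", "extension",
                      "truncation", "divergent_ends", "gapped",
                      "different", "other")

#' Classify a predicted/model protein pair
#'
#' Decision order (first match wins): `identical` -- exact string equality;
#' `near_identical` -- end-to-end alignment (all overhangs <= `overhang_aa`)
#' with identity >= `min_identity` and fewer than `max_gap_cols` gap
#' columns; `extension` / `truncation` -- a near-identical aligned region
#' with an overhang longer than `overhang_aa` on the predicted / the model
#' side only; `divergent_ends` -- overhangs longer than `overhang_aa` on
#' both sequences; `gapped` -- modified identity >= `min_identity` with
#' substantial gaps (>= 10 gap openings, or a single gap >= 30 aa, or >= 10
#' gap columns) and short overhangs; `different` -- aligned identity below
#' `low_identity`; `other` -- everything else.
#'
#' @param p predicted protein; string or `ProteinRecord`.
#' @param q model protein.
#' @param min_identity identity threshold for near-identical and gapped.
#' @param max_gap_cols gap columns tolerated in a near-identical pair.
#' @param overhang_aa overhang length (aa) separating end differences from
#'   noise.
#' @param gapped_openings,gapped_long_gap gap-openings / single-gap-length
#'   alternatives qualifying a pair as gapped.
#' @param low_identity identity below which a pair is `different`.
#' @return the class label (character scalar).
#' @export
classify_protein_pair <- function(p, q, min_identity = 0.90,
                                  max_gap_cols = 10, overhang_aa = 10,
                                  gapped_openings = 10,
                                  gapped_long_gap = 30,
                                  low_identity = 0.50) {
  p <- .aa_seq(p); q <- .aa_seq(q)
  if (identical(p, q)) return("identical")
  a <- align_proteins(p, q)
  ohp <- max(a$overhang_p); ohq <- max(a$overhang_q)
  near_core <- a$identity >= min_identity && a$gap_cols < max_gap_cols
  if (ohp <= overhang_aa && ohq <= overhang_aa && near_core)
    return("near_identical")
  if (ohp > overhang_aa && ohq <= overhang_aa && near_core)
    return("extension")
  if (ohq > overhang_aa && ohp <= overhang_aa && near_core)
    return("truncation")
  if (ohp > overhang_aa && ohq > overhang_aa)
    return("divergent_ends")
  if (ohp <= overhang_aa && ohq <= overhang_aa &&
      a$aligned_cols > a$gap_cols &&
      modified_identity(a) >= min_identity &&
      (a$gap_openings >= gapped_openings ||
         a$longest_gap >= gapped_long_gap || a$gap_cols >= max_gap_cols))
    return("gapped")
  if (a$identity < low_identity) return("different")
  "other"
}

#' Compare a set of predicted proteins against their models
#'
#' @param predicted named character vector of conceptual translations.
#' @param models named character vector of model proteins.
#' @param pairs optional data frame (`predicted`, `model`); by default
#'   names shared by both vectors are paired (a `_dupN` suffix on a
#'   predicted id is ignored when matching).
#' @param ... thresholds passed to [classify_protein_pair()].
#' @return data frame (predicted, model, class).
#' @export
compare_proteomes <- function(predicted, models, pairs = NULL, ...) {
  if (is.null(pairs)) {
    base <- sub("_dup[0-9]+$", "", names(predicted))
    keep <- base %in% names(models)
    pairs <- data.frame(predicted = names(predicted)[keep],
                        model = base[keep], stringsAsFactors = FALSE)
  }
  cls <- vapply(seq_len(nrow(pairs)), function(i)
    classify_protein_pair(predicted[[pairs$predicted[i]]],
                          models[[pairs$model[i]]], ...), character(1))
  data.frame(predicted = pairs$predicted, model = pairs$model, class = cls,
             stringsAsFactors = FALSE)
}

#' Roll up protein classes into the summary table
#'
#' Fixed row order: Identical, Near-identical, Extensions, Truncations,
#' Divergent ends, Gapped, Different, Other; percentages against the total,
#' rounded half-up to one decimal.
#'
#' @param classes data frame from [compare_proteomes()] (or a character
#'   vector of class labels).
#' @return data frame (classification, n, pct) with a `total` attribute.
#' @export
summarize_protein_classes <- function(classes) {
  if (is.data.frame(classes)) classes <- classes$class
  n <- vapply(.protein_classes, function(k) sum(classes == k), integer(1))
  total <- length(classes)
  out <- data.frame(
    classification = c("Identical", "Near-identical", "Extensions",
                       "Truncations", "Divergent ends", "Gapped",
                       "Different", "Other"),
    n = as.integer(n), pct = pct_of(as.integer(n), total),
    stringsAsFactors = FALSE)
  attr(out, "total") <- total
  out
}
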