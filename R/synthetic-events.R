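#' Describe one assembly event
#'
#' The event vocabulary mirrors the mis-assembly failure modes that drive
#' annotation differences between assembly versions: contig inversions and
#' translocations, gaps (modelled as runs of N by default), segmental
#' duplications, relocation of a segment to the unplaced pool, genome-wide
#' substitution noise, and small frameshifting indels inside a gene's CDS.
#'
#' @param kind one of `"inversion"`, `"translocation"`, `"deletion"`,
#'   `"duplication"`, `"unplace"`, `"substitution_noise"`,
#'   `"frameshift_indel"`.
#' @param chrom,start,end target interval in source-genome coordinates
#'   (structural kinds).
#' @param dest_chrom,dest_pos destination locus (translocation/duplication),
#'   also in source coordinates; must not fall inside any event target.
#' @param rate per-base substitution probability (`substitution_noise`).
#' @param gene transcript id whose CDS receives a `frameshift_indel`.
#' @param indel signed indel length for `frameshift_indel`: -2, -1, +1 or +2.
#' @param gap for `deletion`: `TRUE` replaces the segment with N of equal
#'   length (a scaffold gap, the default); `FALSE` excises it.
#' @return an object of class `EventSpec`.
#' @export
event_spec <- function(kind, chrom = NULL, start = NULL, end = NULL,
                       dest_chrom = NULL, dest_pos = NULL, rate = NULL,
                       gene = NULL, indel = NULL, gap = TRUE) {
  kinds <- c("inversion", "translocation", "deletion", "duplication",
             "unplace", "substitution_noise", "frameshift_indel")
  if (!kind %in% kinds) stop("unknown event kind: ", kind)
  if (kind %in% c("inversion", "translocation", "deletion", "duplication",
                  "unplace")) {
    stopifnot(!is.null(chrom), !is.null(start), !is.null(end),
              start >= 1, end >= start)
  }
  if (kind %in% c("translocation", "duplication"))
    stopifnot(!is.null(dest_chrom), !is.null(dest_pos), dest_pos >= 1)
  if (kind == "substitution_noise")
    stopifnot(!is.null(rate), rate >= 0, rate <= 0.2)
  if (kind == "frameshift_indel")
    stopifnot(!is.null(gene), !is.null(indel), indel %in% c(-2L, -1L, 1L, 2L))
  structure(list(kind = kind, chrom = chrom,
                 start = if (!is.null(start)) as.integer(start),
                 end = if (!is.null(end)) as.integer(end),
                 dest_chrom = dest_chrom,
                 dest_pos = if (!is.null(dest_pos)) as.integer(dest_pos),
                 rate = rate, gene = gene,
                 indel = if (!is.null(indel)) as.integer(indel), gap = gap),
            class = "EventSpec")
}

# -- piece table --------------------------------------------------------
# Assembly B is an ordered list of "pieces" per output sequence. Each piece
# is either a copy of a source interval (possibly reverse-complemented), a
# gap of Ns with preserved source coordinates, or a short literal insertion.
# Events rearrange the piece lists; rendering concatenates them and records
# the source->target coordinate map used for annotation lift-over.

.mk_piece <- function(src_chrom, s, e, strand = "+", kind = "copy",
                      dup = 0L, ins_seq = NA_character_) {
  data.frame(src_chrom = src_chrom, src_start = as.integer(s),
             src_end = as.integer(e), strand = strand, kind = kind,
             dup = as.integer(dup), ins_seq = ins_seq,
             stringsAsFactors = FALSE)
}

# ensure a primary (+, dup 0) piece boundary exists at source position p
.split_src <- function(pieces, chrom, p) {
  for (bc in names(pieces)) {
    df <- pieces[[bc]]
    hit <- which(df$kind %in% c("copy", "gap") & df$dup == 0L &
                   df$strand == "+" & df$src_chrom == chrom &
                   df$src_start < p & df$src_end >= p)
    if (length(hit)) {
      i <- hit[1L]
      top <- df[seq_len(i - 1L), , drop = FALSE]
      bot <- df[-seq_len(i), , drop = FALSE]
      a <- df[i, , drop = FALSE]; b <- a
      a$src_end <- p - 1L; b$src_start <- p
      pieces[[bc]] <- rbind(top, a, b, bot)
      return(pieces)
    }
  }
  pieces
}

# locate the contiguous run of primary pieces exactly covering a target
.find_run <- function(pieces, chrom, s, e) {
  pieces <- .split_src(pieces, chrom, s)
  pieces <- .split_src(pieces, chrom, e + 1L)
  for (bc in names(pieces)) {
    df <- pieces[[bc]]
    idx <- which(df$kind %in% c("copy", "gap") & df$dup == 0L &
                   df$strand == "+" & df$src_chrom == chrom &
                   df$src_start >= s & df$src_end <= e)
    if (length(idx)) {
      if (any(diff(idx) != 1L))
        stop("event target ", chrom, ":", s, "-", e,
             " is no longer contiguous (overlapping events?)")
      covered <- sum(df$src_end[idx] - df$src_start[idx] + 1L)
      if (covered != e - s + 1L)
        stop("event target ", chrom, ":", s, "-", e,
             " not fully available (overlapping events?)")
      return(list(pieces = pieces, bc = bc, idx = idx))
    }
  }
  stop("event target ", chrom, ":", s, "-", e, " not found in assembly")
}

.drop_rows <- function(df, idx) df[-idx, , drop = FALSE]

.insert_rows <- function(df, rows, before) {
  if (before <= 1L) rbind(rows, df)
  else if (before > nrow(df)) rbind(df, rows)
  else rbind(df[seq_len(before - 1L), , drop = FALSE], rows,
             df[seq(before, nrow(df)), , drop = FALSE])
}

# insert rows at a source-coordinate destination
.insert_at_dest <- function(pieces, rows, dest_chrom, dest_pos) {
  pieces <- .split_src(pieces, dest_chrom, dest_pos)
  for (bc in names(pieces)) {
    df <- pieces[[bc]]
    at <- which(df$kind %in% c("copy", "gap") & df$dup == 0L &
                  df$strand == "+" & df$src_chrom == dest_chrom &
                  df$src_start == dest_pos)
    if (length(at)) {
      pieces[[bc]] <- .insert_rows(df, rows, at[1L])
      return(pieces)
    }
  }
  stop("destination ", dest_chrom, ":", dest_pos, " not available")
}

#' Derive a rearranged assembly from a source genome
#'
#' Applies a list of [event_spec()] events to the source assembly, producing
#' assembly B, a source-to-target coordinate map (used by
#' [lift_annotation()]), and ground-truth records assigning every annotated
#' gene the outcome category its events are expected to produce downstream.
#'
#' Structural event targets must be pairwise non-overlapping
#' (`substitution_noise` is genome-wide and exempt). Deletions default to an
#' equal-length run of N, modelling a scaffold gap; `gap = FALSE` excises
#' the segment instead. Segments moved by `unplace` become unplaced contigs
#' named `unplaced_1`, `unplaced_2`, ...
#'
#' @param genome source `GenomeAssembly`.
#' @param annotation optional `AnnotationSet` on the source genome (needed
#'   for `frameshift_indel` events and for gene truth records).
#' @param events list of `EventSpec` objects.
#' @param seed RNG seed (substitution noise, inserted bases).
#' @return list with `genome` (assembly B), `map` (piece table,
#'   a data frame), `truth` (gene truth records) and `events`.
#' @export
apply_events <- function(genome, annotation = NULL, events = list(),
                         seed = 1) {
  if (inherits(events, "EventSpec")) events <- list(events)
  structural <- Filter(function(e) e$kind %in%
                         c("inversion", "translocation", "deletion",
                           "duplication", "unplace"), events)
  noise <- Filter(function(e) e$kind == "substitution_noise", events)
  shifts <- Filter(function(e) e$kind == "frameshift_indel", events)

  # validate targets: in bounds, pairwise disjoint
  tgt <- data.frame(chrom = character(0), start = integer(0),
                    end = integer(0))
  for (e in structural) {
    if (!(e$chrom %in% names(genome$placed)))
      stop("event target on unknown chromosome ", e$chrom)
    if (e$end > genome_seqlen(genome, e$chrom))
      stop("event target beyond end of ", e$chrom)
    tgt <- rbind(tgt, data.frame(chrom = e$chrom, start = e$start,
                                 end = e$end))
  }
  if (nrow(tgt) > 1L) {
    for (i in seq_len(nrow(tgt) - 1L)) for (j in seq(i + 1L, nrow(tgt))) {
      if (tgt$chrom[i] == tgt$chrom[j] &&
          tgt$start[i] <= tgt$end[j] && tgt$end[i] >= tgt$start[j])
        stop("overlapping structural event targets")
    }
  }
  in_target <- function(chrom, pos)
    any(tgt$chrom == chrom & tgt$start <= pos & tgt$end >= pos)
  for (e in structural) {
    if (e$kind %in% c("translocation", "duplication") &&
        in_target(e$dest_chrom, e$dest_pos))
      stop("event destination inside another event target")
  }

  with_seed(seed, {
    pieces <- lapply(names(genome$placed), function(id)
      .mk_piece(id, 1L, genome_seqlen(genome, id)))
    names(pieces) <- names(genome$placed)
    n_unplaced <- 0L

    # resolve frameshift indels to concrete positions first (they are tiny
    # and must not sit inside a structural target)
    shift_pos <- list()
    for (e in shifts) {
      if (is.null(annotation) || !(e$gene %in% names(annotation$transcripts)))
        stop("frameshift_indel: unknown gene ", e$gene)
      tx <- annotation$transcripts[[e$gene]]
      # midpoint of the CDS in transcript coordinates, so the scrambled
      # tail is a substantial fraction of the protein
      t_mid <- (tx$cds[1L] + tx$cds[2L]) %/% 2L
      giv <- tx_to_genome(tx, t_mid, t_mid)
      pos <- giv$start[1L]
      ex <- tx$exons[tx$exons$start <= pos & tx$exons$end >= pos, ]
      pos <- min(max(pos, ex$start[1L] + 10L), ex$end[1L] - 10L)
      if (in_target(tx$chrom, pos))
        stop("frameshift_indel inside a structural event target")
      shift_pos[[length(shift_pos) + 1L]] <-
        list(chrom = tx$chrom, pos = pos, indel = e$indel, gene = e$gene)
    }

    for (sp in shift_pos) {
      if (sp$indel < 0L) {
        run <- .find_run(pieces, sp$chrom, sp$pos, sp$pos - sp$indel - 1L)
        pieces <- run$pieces
        pieces[[run$bc]] <- .drop_rows(pieces[[run$bc]], run$idx)
      } else {
        ins <- .mk_piece(NA_character_, NA, NA, kind = "ins",
                         ins_seq = random_dna(sp$indel))
        ins$src_start <- ins$src_end <- NA_integer_
        pieces <- .insert_at_dest(pieces, ins, sp$chrom, sp$pos)
      }
    }

    for (e in structural) {
      run <- .find_run(pieces, e$chrom, e$start, e$end)
      pieces <- run$pieces
      bc <- run$bc; idx <- run$idx
      df <- pieces[[bc]]
      seg <- df[idx, , drop = FALSE]
      if (e$kind == "deletion") {
        if (isTRUE(e$gap)) {
          seg$kind <- "gap"
          pieces[[bc]][idx, ] <- seg
        } else {
          pieces[[bc]] <- .drop_rows(df, idx)
        }
      } else if (e$kind == "inversion") {
        seg <- seg[rev(seq_len(nrow(seg))), , drop = FALSE]
        seg$strand <- ifelse(seg$strand == "+", "-", "+")
        pieces[[bc]][idx, ] <- seg
      } else if (e$kind == "translocation") {
        pieces[[bc]] <- .drop_rows(df, idx)
        pieces <- .insert_at_dest(pieces, seg, e$dest_chrom, e$dest_pos)
      } else if (e$kind == "duplication") {
        dup_id <- max(0L, unlist(lapply(pieces, `[[`, "dup"))) + 1L
        copy <- seg
        copy$dup <- dup_id
        pieces <- .insert_at_dest(pieces, copy, e$dest_chrom, e$dest_pos)
      } else if (e$kind == "unplace") {
        pieces[[bc]] <- .drop_rows(df, idx)
        n_unplaced <- n_unplaced + 1L
        pieces[[paste0("unplaced_", n_unplaced)]] <- seg
      }
    }

    # render sequences and build the coordinate map
    empty <- vapply(pieces, nrow, integer(1)) == 0L
    if (any(empty))
      stop("event list empties sequence ", names(pieces)[empty][1L])
    seqs <- character(length(pieces))
    names(seqs) <- names(pieces)
    map_rows <- vector("list", length(pieces))
    for (bc in names(pieces)) {
      df <- pieces[[bc]]
      segs <- character(nrow(df))
      lens <- integer(nrow(df))
      for (i in seq_len(nrow(df))) {
        if (df$kind[i] == "ins") {
          segs[i] <- df$ins_seq[i]
        } else if (df$kind[i] == "gap") {
          segs[i] <- strrep("N", df$src_end[i] - df$src_start[i] + 1L)
        } else {
          s <- substr(genome_seq(genome, df$src_chrom[i]),
                      df$src_start[i], df$src_end[i])
          segs[i] <- if (df$strand[i] == "-") revcomp(s) else s
        }
        lens[i] <- nchar(segs[i])
      }
      b_end <- cumsum(lens)
      df$b_chrom <- bc
      df$b_start <- b_end - lens + 1L
      df$b_end <- b_end
      map_rows[[bc]] <- df
      seqs[[bc]] <- paste(segs, collapse = "")
    }
    map <- do.call(rbind, map_rows)
    rownames(map) <- NULL

    # genome-wide substitution noise
    for (e in noise) {
      if (e$rate <= 0) next
      for (bc in names(seqs)) {
        L <- nchar(seqs[[bc]])
        n <- stats::rbinom(1L, L, e$rate)
        if (n == 0L) next
        pos <- sample.int(L, n)
        x <- chars(seqs[[bc]])
        cur <- x[pos]
        ok <- cur != "N"
        x[pos[ok]] <- vapply(cur[ok], function(b)
          sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1),
          USE.NAMES = FALSE)
        seqs[[bc]] <- paste(x, collapse = "")
      }
    }

    placed_ids <- names(genome$placed)
    genome_b <- genome_assembly(
      seqs[placed_ids],
      c(genome$unplaced, seqs[setdiff(names(seqs), placed_ids)]),
      name = paste0(genome$name, "_B"))

    truth <- if (!is.null(annotation))
      gene_truth(annotation, events) else NULL
    list(genome = genome_b, map = map, truth = truth, events = events)
  })
}

#' Expected outcome category for every annotated gene under an event list
#'
#' Implements the simulator's decision table: genes untouched by any event
#' are expected `identical` (or `near_identical` when genome-wide
#' substitution noise is active); a deletion of transcript-terminal exons is
#' a `truncation`; internal-exon deletions and intra-genic
#' inversion/translocation breakpoints are `complex`; whole-gene
#' inversions/translocations/duplications only move the locus and stay
#' `identical`; a frameshift indel is expected to change the protein but not
#' the structure (`frameshift`); whole-gene deletions are `lost` and
#' unplaced genes `unplaced`.
#'
#' @param annotation `AnnotationSet` on the source genome.
#' @param events list of `EventSpec`.
#' @return data frame with subject_id, subject_type, event_kinds,
#'   expected_outcome.
#' @export
gene_truth <- function(annotation, events) {
  if (inherits(events, "EventSpec")) events <- list(events)
  noisy <- any(vapply(events, function(e)
    e$kind == "substitution_noise" && e$rate > 0, logical(1)))
  shift_genes <- unlist(lapply(events, function(e)
    if (e$kind == "frameshift_indel") e$gene else NULL))
  rows <- lapply(annotation$transcripts, function(tx) {
    sp <- tx_span(tx)
    kinds <- character(0)
    outcome <- NULL
    for (e in events) {
      if (!e$kind %in% c("inversion", "translocation", "deletion",
                         "duplication", "unplace")) next
      if (e$chrom != tx$chrom || e$start > sp[2L] || e$end < sp[1L]) next
      kinds <- c(kinds, e$kind)
      contains <- e$start <= sp[1L] && e$end >= sp[2L]
      this <- if (e$kind == "deletion") {
        if (contains) "lost" else {
          ex_hit <- which(tx$exons$start <= e$end & tx$exons$end >= e$start)
          if (length(ex_hit) == 0L) "identical"
          else {
            n <- nrow(tx$exons)
            # terminal run at either genomic end (either transcript end)
            terminal <- all(ex_hit == seq_len(length(ex_hit))) ||
              all(ex_hit == seq(n - length(ex_hit) + 1L, n))
            if (terminal && length(ex_hit) < n) "truncation" else "complex"
          }
        }
      } else if (e$kind == "unplace") {
        if (contains) "unplaced" else "complex"
      } else if (e$kind == "duplication") {
        "identical"
      } else {
        if (contains) "identical" else "complex"
      }
      outcome <- if (is.null(outcome)) this
        else if (identical(outcome, this)) this else "complex"
    }
    if (tx$id %in% shift_genes) {
      kinds <- c(kinds, "frameshift_indel")
      outcome <- if (is.null(outcome) || outcome == "identical")
        "frameshift" else "complex"
    }
    if (is.null(outcome)) outcome <- if (noisy) "near_identical" else "identical"
    if (noisy) kinds <- c(kinds, "substitution_noise")
    data.frame(subject_id = tx$id, subject_type = "gene",
               event_kinds = paste(unique(kinds), collapse = ","),
               expected_outcome = outcome, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
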