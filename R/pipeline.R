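# End-to-end orchestration: simulate/load -> align -> compare structures ->
# compare proteins -> map SNPs -> summarize, with every threshold carried
# in one config object and serialized into every report header.

#' Pipeline configuration
#'
#' All tunable thresholds in one place, at their conventional defaults:
#' 20-mer seeds, the 100 bp / 95% alignment retention filter, the 50 bp
#' comparability overlap and 20 bp boundary margin V, the 90% / <10-gap /
#' 10-aa protein limits, and the 90/90/95 SNP tiers.
#'
#' @param k seed size of the genome index.
#' @param min_len,min_identity alignment retention filter.
#' @param min_intron smallest genomic gap treated as an intron (bp).
#' @param margin boundary margin V (bp).
#' @param min_overlap comparability overlap (bp).
#' @param protein_min_identity,protein_gap_cols,protein_overhang_aa protein
#'   taxonomy thresholds.
#' @param snp_found_id,snp_found_cov,snp_mapped_id SNP tier thresholds.
#' @param gap_tol uncovered-run length (bp) above which a gene's mapping
#'   is considered to be missing sequence.
#' @param frag_tol extra union-over-primary coverage above which a gene
#'   counts as fragmented across loci.
#' @return a named list of class `pipeline_config`.
#' @export
pipeline_config <- function(k = 20, min_len = 100, min_identity = 0.95,
                            min_intron = 30, margin = 20, min_overlap = 50,
                            protein_min_identity = 0.90,
                            protein_gap_cols = 10,
                            protein_overhang_aa = 10,
                            snp_found_id = 0.90, snp_found_cov = 0.90,
                            snp_mapped_id = 0.95, gap_tol = 20,
                            frag_tol = 0.05) {
  cfg <- list(k = k, min_len = min_len, min_identity = min_identity,
              min_intron = min_intron, margin = margin,
              min_overlap = min_overlap,
              protein_min_identity = protein_min_identity,
              protein_gap_cols = protein_gap_cols,
              protein_overhang_aa = protein_overhang_aa,
              snp_found_id = snp_found_id, snp_found_cov = snp_found_cov,
              snp_mapped_id = snp_mapped_id, gap_tol = gap_tol,
              frag_tol = frag_tol)
  stopifnot(cfg$k >= 8, cfg$min_len >= 0,
            cfg$min_identity > 0, cfg$min_identity <= 1,
            cfg$margin >= 0, cfg$min_overlap >= 1,
            cfg$snp_found_id <= 1, cfg$snp_mapped_id <= 1)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Composite per-gene outcome of a mapping
#'
#' Combines alignment geometry, the structure class and the protein class
#' into one observed category per gene, the quantity compared against the
#' simulator's truth records: `lost` (no retained alignment), `complex`
#' (fragmented across loci/strands, an internal uncovered run, or a
#' complex structure class), `truncation` (uncovered run at a transcript
#' end, or a truncating structure/protein class), `extension`,
#' `identical`, `near_identical`, `protein_changed` (structure intact but
#' the conceptual translation differs beyond noise), or `unmatched` (no
#' comparable candidate in the local annotation).
#'
#' @param alns retained alignments (primaries flagged).
#' @param matches best-match table from [compare_annotations()].
#' @param protein_classes data frame from [compare_proteomes()].
#' @param query_lengths named integer vector of query lengths.
#' @param config a [pipeline_config()].
#' @return data frame (query, observed).
#' @export
observed_outcomes <- function(alns, matches, protein_classes,
                              query_lengths, config = pipeline_config()) {
  qids <- names(query_lengths)
  pclass <- stats::setNames(protein_classes$class,
                            sub("_dup[0-9]+$", "",
                                protein_classes$predicted))
  rows <- lapply(qids, function(qid) {
    qalns <- Filter(function(a) a$query_id == qid, alns)
    if (length(qalns) == 0L)
      return(data.frame(query = qid, observed = "lost",
                        stringsAsFactors = FALSE))
    L <- query_lengths[[qid]]
    prim <- Filter(function(a) a$is_primary, qalns)
    covered_of <- function(as) IRanges::reduce(IRanges::IRanges(
      start = unlist(lapply(as, function(a) a$blocks$qstart)),
      end = unlist(lapply(as, function(a) a$blocks$qend))))
    cov_p <- covered_of(prim)
    cov_u <- covered_of(qalns)
    frac_p <- sum(IRanges::width(cov_p)) / L
    frac_u <- sum(IRanges::width(cov_u)) / L
    obs <- NULL
    if (frac_u - frac_p > config$frag_tol) {
      obs <- "complex"                      # split across loci or strands
    } else {
      unc <- IRanges::setdiff(IRanges::IRanges(1L, L), cov_p)
      unc <- unc[IRanges::width(unc) > config$gap_tol]
      if (length(unc)) {
        internal <- IRanges::start(unc) > 1L & IRanges::end(unc) < L
        obs <- if (any(internal)) "complex" else "truncation"
      }
    }
    if (is.null(obs)) {
      lev <- matches$level[matches$query == qid]
      if (length(lev) == 0L || is.na(lev[1L])) {
        obs <- "unmatched"
      } else if (lev[1L] == 7L) {
        obs <- "complex"
      } else if (lev[1L] %in% c(3L, 4L)) {
        obs <- "extension"
      } else if (lev[1L] %in% c(5L, 6L)) {
        obs <- "truncation"
      } else {
        pc <- if (qid %in% names(pclass)) pclass[[qid]] else "identical"
        obs <- switch(pc,
                      identical = "identical",
                      near_identical = "near_identical",
                      truncation = "truncation",
                      extension = "extension",
                      "protein_changed")
      }
    }
    data.frame(query = qid, observed = obs, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# does an observed category satisfy an expected one?
.truth_ok <- function(expected, observed) {
  switch(expected,
         identical = observed == "identical",
         near_identical = observed %in% c("identical", "near_identical"),
         truncation = observed == "truncation",
         complex = observed == "complex",
         frameshift = !(observed %in% c("identical", "near_identical",
                                        "lost", "unmatched")),
         lost = observed %in% c("lost", "unmatched"),
         unplaced = observed %in% c("lost", "unmatched"),
         FALSE)
}

#' Score observed gene outcomes against simulator truth
#'
#' @param truth truth records (gene rows) from the simulator.
#' @param observed data frame from [observed_outcomes()].
#' @return list with `detail` (merged per-gene table with `ok`),
#'   `by_category` (recovery rate per expected category) and `recovery`
#'   (overall fraction).
#' @export
evaluate_against_truth <- function(truth, observed) {
  tg <- truth[truth$subject_type == "gene", , drop = FALSE]
  m <- merge(tg, observed, by.x = "subject_id", by.y = "query",
             all.x = TRUE)
  m$observed[is.na(m$observed)] <- "lost"
  m$ok <- mapply(.truth_ok, m$expected_outcome, m$observed)
  by_cat <- do.call(rbind, lapply(split(m, m$expected_outcome), function(d)
    data.frame(expected = d$expected_outcome[1L], n = nrow(d),
               ok = sum(d$ok), rate = mean(d$ok),
               stringsAsFactors = FALSE)))
  rownames(by_cat) <- NULL
  list(detail = m, by_category = by_cat, recovery = mean(m$ok))
}

#' Run the full annotation-comparison pipeline on a simulated system
#'
#' Maps the source assembly's transcript set onto the derived assembly,
#' compares the projections with the derived annotation, compares the
#' derived conceptual translations with the model proteins, maps planted
#' SNPs, and (when truth is present) scores every gene against its
#' expected outcome.
#'
#' @param sim a simulation from [simulate_benchmark()] /
#'   [simulate_with_genome()].
#' @param config a [pipeline_config()].
#' @param map_snps_to which assemblies to map SNPs onto (`"b"` default).
#' @param rescue_unplaced also search the unplaced pool of the derived
#'   assembly for SNPs not found on its chromosomes.
#' @return a report bundle (class `annotrack_report`): alignments,
#'   curves, matches, structure_summary, protein_classes,
#'   protein_summary, snp_status, snp_summary, observed, truth_eval,
#'   config.
#' @export
run_pipeline <- function(sim, config = pipeline_config(),
                         map_snps_to = c("b", "both", "none"),
                         rescue_unplaced = FALSE) {
  map_snps_to <- match.arg(map_snps_to)
  qlen <- stats::setNames(nchar(sim$mrnas), names(sim$mrnas))

  index_b <- kmer_index(sim$genome_b, config$k)
  alns <- align_transcripts(sim$mrnas, sim$genome_b, index = index_b,
                            min_len = config$min_len,
                            min_identity = config$min_identity,
                            min_intron = config$min_intron)

  curves <- list(
    coverage_all = coverage_curve(alns, qlen, "all"),
    coverage_best = coverage_curve(alns, qlen, "best"),
    agreement_all = agreement_curve(alns, sim$annotation_b, qlen, "all"),
    agreement_best = agreement_curve(alns, sim$annotation_b, qlen, "best"))

  matches <- compare_annotations(alns, sim$annotation_b,
                                 source_annotation = sim$annotation_a,
                                 margin = config$margin,
                                 min_overlap = config$min_overlap)
  structure_summary <- summarize_classes(matches)

  predicted <- translate_annotation(sim$annotation_b, sim$genome_b)
  protein_classes <- compare_proteomes(
    predicted, sim$proteins,
    min_identity = config$protein_min_identity,
    max_gap_cols = config$protein_gap_cols,
    overhang_aa = config$protein_overhang_aa)
  protein_summary <- summarize_protein_classes(protein_classes)

  snp_status <- snp_summary <- NULL
  if (!is.null(sim$snps) && map_snps_to != "none") {
    snp_status <- map_snps(sim$snps, sim$genome_b,
                           found_id = config$snp_found_id,
                           found_cov = config$snp_found_cov,
                           mapped_id = config$snp_mapped_id)
    if (rescue_unplaced && length(sim$genome_b$unplaced)) {
      un <- snp_status$rsid[snp_status$status == "unmapped"]
      if (length(un)) {
        rs <- map_snps(sim$snps[sim$snps$rsid %in% un, , drop = FALSE],
                       sim$genome_b, sequences = "unplaced",
                       found_id = config$snp_found_id,
                       found_cov = config$snp_found_cov,
                       mapped_id = config$snp_mapped_id)
        rescued <- rs$rsid[rs$status != "unmapped"]
        snp_status$status[snp_status$rsid %in% rescued] <- "found"
      }
    }
    snp_summary <- data.frame(
      status = c("mapped", "found", "unmapped"),
      n = c(sum(snp_status$status == "mapped"),
            sum(snp_status$status == "found"),
            sum(snp_status$status == "unmapped")),
      stringsAsFactors = FALSE)
  }

  observed <- observed_outcomes(alns, matches, protein_classes, qlen,
                                config)
  truth_eval <- if (!is.null(sim$truth))
    evaluate_against_truth(sim$truth, observed) else NULL

  structure(list(alignments = alns, curves = curves, matches = matches,
                 structure_summary = structure_summary,
                 protein_classes = protein_classes,
                 protein_summary = protein_summary,
                 snp_status = snp_status, snp_summary = snp_summary,
                 observed = observed, truth_eval = truth_eval,
                 config = config, seed = sim$seed),
            class = "annotrack_report")
}

#' @export
print.annotrack_report <- function(x, ...) {
  cat("annotrack report\n")
  cat(sprintf("  alignments: %d (%d primary)\n", length(x$alignments),
              sum(vapply(x$alignments, `[[`, logical(1), "is_primary"))))
  cat(sprintf("  structure classes (total %d): %s\n",
              attr(x$structure_summary, "total"),
              paste(x$structure_summary$n, collapse = "/")))
  cat(sprintf("  protein classes  (total %d): %s\n",
              attr(x$protein_summary, "total"),
              paste(x$protein_summary$n, collapse = "/")))
  if (!is.null(x$snp_summary))
    cat(sprintf("  SNPs mapped/found/unmapped: %s\n",
                paste(x$snp_summary$n, collapse = "/")))
  if (!is.null(x$truth_eval))
    cat(sprintf("  truth recovery: %.3f\n", x$truth_eval$recovery))
  invisible(x)
}

.config_header <- function(config) {
  paste0("# annotrack ",
         as.character(utils::packageVersion("annotrack")), "; ",
         paste(names(config), unlist(config), sep = "=", collapse = " "))
}

.write_tsv <- function(df, path, header) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  writeLines(paste(colnames(df), collapse = "\t"), con)
  if (nrow(df))
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a report bundle to TSV (and optional JSON) files
#'
#' Fixed row orders, percentages with one decimal, a `#` header line
#' carrying the package version and every threshold.
#'
#' @param bundle an `annotrack_report`.
#' @param dir output directory (created if needed).
#' @param json also write a JSON mirror of the summaries.
#' @return the directory, invisibly.
#' @export
render_tables <- function(bundle, dir, json = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  hdr <- .config_header(bundle$config)
  .write_tsv(alignment_table(bundle$alignments),
             file.path(dir, "alignments.tsv"), hdr)
  .write_tsv(bundle$matches, file.path(dir, "matches.tsv"), hdr)
  .write_tsv(bundle$structure_summary,
             file.path(dir, "structure_summary.tsv"), hdr)
  .write_tsv(bundle$protein_classes,
             file.path(dir, "protein_classes.tsv"), hdr)
  .write_tsv(bundle$protein_summary,
             file.path(dir, "protein_summary.tsv"), hdr)
  cv <- do.call(rbind, lapply(names(bundle$curves), function(n)
    cbind(curve = n, bundle$curves[[n]])))
  .write_tsv(cv, file.path(dir, "curves.tsv"), hdr)
  if (!is.null(bundle$snp_status))
    .write_tsv(bundle$snp_status, file.path(dir, "snp_status.tsv"), hdr)
  if (!is.null(bundle$truth_eval))
    .write_tsv(bundle$truth_eval$detail,
               file.path(dir, "truth_eval.tsv"), hdr)
  if (json) {
    summaries <- list(structure = bundle$structure_summary,
                      protein = bundle$protein_summary,
                      snp = bundle$snp_summary,
                      config = unclass(bundle$config))
    jsonlite::write_json(summaries, file.path(dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(dir)
}
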