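# Shared simulated fixtures, built once per test run.

.fx_cache <- new.env(parent = emptyenv())

fx_memo <- function(name, build) {
  if (!exists(name, envir = .fx_cache)) assign(name, build(), envir = .fx_cache)
  get(name, envir = .fx_cache)
}

# small clean system: 2 x 100 kb, 12 genes, no events
fx_small <- function() fx_memo("small", function() {
  g0 <- generate_genome(n_chrom = 2, chrom_length = 1e5, seed = 101)
  plant_genes(g0, n_genes = 12, intron_len_range = c(60, 800), seed = 102)
})

fx_small_index <- function() fx_memo("small_index", function() {
  kmer_index(fx_small()$genome, 20)
})

fx_small_alns <- function() fx_memo("small_alns", function() {
  pg <- fx_small()
  align_transcripts(pg$mrnas, pg$genome, index = fx_small_index())
})

# small mixed-event system with its pipeline report
fx_events <- function() fx_memo("events", function() {
  simulate_benchmark(
    n_chrom = 2, chrom_length = 2.5e5, n_genes = 24,
    events = function(pg) benchmark_event_plan(pg, per_category = 2,
      categories = c("terminal_deletion", "internal_deletion",
                     "inversion_breakpoint", "translocation",
                     "duplication", "frameshift"), seed = 77)$events,
    n_snps = 20, seed = 76)
})

fx_events_report <- function() fx_memo("events_report", function() {
  run_pipeline(fx_events())
})
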