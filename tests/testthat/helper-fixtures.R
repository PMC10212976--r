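# Shared fixture builders (all in-code; no binary files).

make_unit <- function(length = 100, strand = "+", start = 0,
                      chrom = "rDNA", regions = NULL) {
  transcription_unit(chrom, start, start + length, strand, regions = regions)
}

# GRanges reads from 0-based half-open intervals
make_reads <- function(starts0, ends0, strand = "+", chrom = "rDNA",
                       weight = 1) {
  n <- length(starts0)
  gr <- GenomicRanges::GRanges(rep(chrom, n),
                               IRanges::IRanges(start = starts0 + 1L,
                                                end = ends0),
                               rep(strand, n))
  S4Vectors::mcols(gr)$weight <- rep_len(weight, length(gr))
  gr
}

# reads with given 3'-end unit positions on a plus-strand unit at genomic 0
reads_at <- function(positions, unit, len = 5L) {
  span <- pmin(len, positions + 1L)
  make_reads(unit$start + positions - span + 1L,
             unit$start + positions + 1L,
             strand = unit$strand, chrom = unit$chrom)
}

write_bed6 <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  path
}

# a small two-condition simulated world used by several tests
small_world <- function(n_reads = 20000, seed = 7, attenuation = 0.5) {
  model <- build_dwell_profile(600, 0.025,
                               pause_positions = c(100, 300, 480),
                               pause_multipliers = c(10, 10, 10))
  simulate_condition_pair(model, pause_attenuation = attenuation,
                          n_replicates = 2, n_reads = n_reads, seed = seed)
}
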