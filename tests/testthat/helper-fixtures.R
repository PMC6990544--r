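# Small fixtures built in code.

uniform_map <- function(n_chrom = 1L, n_snp = 100L, spacing_kb = 50,
                        start_bp = 1) {
  maps <- lapply(seq_len(n_chrom), function(ch) {
    data.frame(
      chrom = as.character(ch),
      snp_id = sprintf("c%d_s%d", ch, seq_len(n_snp)),
      cm = 0,
      bp = seq(start_bp, by = spacing_kb * 1000, length.out = n_snp)
    )
  })
  map <- do.call(rbind, maps)
  class(map) <- c("snp_map", "data.frame")
  map
}

# dataset from an explicit call matrix on a uniform map
calls_dataset <- function(calls, spacing_kb = 50, n_chrom = 1L) {
  calls <- rbind(calls)
  storage.mode(calls) <- "integer"
  stopifnot(ncol(calls) %% n_chrom == 0)
  map <- uniform_map(n_chrom, ncol(calls) / n_chrom, spacing_kb)
  genotype_dataset(map, sprintf("i%d", seq_len(nrow(calls))), calls)
}

# permissive detection settings: everything detectable
permissive_params <- function(window_snp = 20L) {
  roh_params(window_snp = window_snp, window_het = 0L, window_missing = 1L,
             window_threshold = 0.05, min_snp = 2L, min_kb = 100,
             max_density = 1e6, max_gap_kb = 1e9, max_het = 0L)
}

write_fixture_files <- function(map_lines, ped_lines) {
  prefix <- tempfile()
  writeLines(map_lines, paste0(prefix, ".map"))
  writeLines(ped_lines, paste0(prefix, ".ped"))
  prefix
}
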