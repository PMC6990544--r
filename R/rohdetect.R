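#' ROH detection parameters
#'
#' The nine settings of the scanning-window ROH detection algorithm,
#' mirroring PLINK's `--homozyg` family. Defaults are PLINK's.
#'
#' @param window_snp scanning window size in SNPs
#'   (`--homozyg-window-snp`).
#' @param window_het maximum heterozygous calls tolerated per window
#'   (`--homozyg-window-het`).
#' @param window_missing maximum missing calls tolerated per window
#'   (`--homozyg-window-missing`).
#' @param window_threshold hit-rate threshold in (0, 1\]: minimum
#'   proportion of homozygous windows a SNP must appear in
#'   (`--homozyg-window-threshold`).
#' @param min_snp minimum SNPs per final ROH (`--homozyg-snp`); see
#'   [lencz_min_snp()] for a principled choice.
#' @param min_kb minimum ROH length in kb (`--homozyg-kb`).
#' @param max_density maximum average spacing in kb per SNP
#'   (`--homozyg-density`): a segment is dropped if
#'   `length_kb / n_snp > max_density`.
#' @param max_gap_kb maximum interval between adjacent SNPs in a segment,
#'   in kb (`--homozyg-gap`).
#' @param max_het maximum heterozygous calls in a final segment
#'   (`--homozyg-het`); `Inf` disables the constraint.
#'
#' @return A list of class `roh_params`. Attribute `user_set` records
#'   which settings were supplied explicitly (the rest fell back to
#'   defaults), so drivers can log defaulted parameters.
#' @seealso [baseline_params()] for the recommended evaluation baseline.
#' @export
roh_params <- function(window_snp = 50L, window_het = 1L,
                       window_missing = 5L, window_threshold = 0.05,
                       min_snp = 100L, min_kb = 1000,
                       max_density = 50, max_gap_kb = 1000,
                       max_het = Inf) {
  user_set <- names(as.list(match.call()))[-1L]
  stopifnot(
    window_snp >= 1, window_het >= 0, window_missing >= 0,
    window_threshold > 0, window_threshold <= 1,
    min_snp >= 0, min_kb > 0, max_density > 0, max_gap_kb > 0,
    max_het >= 0
  )
  structure(
    list(window_snp = as.integer(window_snp),
         window_het = as.integer(window_het),
         window_missing = as.integer(window_missing),
         window_threshold = window_threshold,
         min_snp = as.integer(min_snp),
         min_kb = min_kb,
         max_density = max_density,
         max_gap_kb = max_gap_kb,
         max_het = max_het),
    class = "roh_params",
    user_set = user_set
  )
}

#' @export
print.roh_params <- function(x, ...) {
  cat("roh_params:\n")
  for (nm in names(x)) cat(sprintf("  %-17s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

HOM_CODES <- c(0L, 2L)

#' Scanning-window hit rates for one chromosome
#'
#' Step one of the algorithm. A window of `window_snp` consecutive SNPs
#' slides along the chromosome one SNP at a time; only windows fully on
#' the chromosome count. A window is homozygous iff it contains at most
#' `window_het` heterozygous and at most `window_missing` missing calls.
#' Each SNP's hit rate is the number of homozygous windows containing it
#' divided by the number of windows containing it (fewer near chromosome
#' ends). A chromosome shorter than the window has zero windows and
#' all-zero hit rates.
#'
#' @param calls one individual's calls on one chromosome (0/1/2/NA), in
#'   map order.
#' @param p a [roh_params] object.
#'
#' @return Numeric vector of per-SNP hit rates in \[0, 1\].
#' @export
window_hit_rates <- function(calls, p) {
  n <- length(calls)
  L <- p$window_snp
  if (n < L) return(numeric(n))
  het <- cumsum(c(0L, !is.na(calls) & calls == 1L))
  mis <- cumsum(c(0L, is.na(calls)))
  n_win <- n - L + 1L
  i <- seq_len(n_win)
  hom_win <- (het[i + L] - het[i]) <= p$window_het &
             (mis[i + L] - mis[i]) <= p$window_missing
  cw <- cumsum(c(0, hom_win))
  s <- seq_len(n)
  lo <- pmax(1L, s - L + 1L)
  hi <- pmin(n_win, s)
  n_cover <- hi - lo + 1L
  n_hom <- cw[hi + 1L] - cw[lo]
  ifelse(n_cover > 0L, n_hom / n_cover, 0)
}

# Trim an index range [a, b] so both ends are homozygous non-missing
# calls; returns NULL if the range empties.
trim_to_homozygous <- function(a, b, calls) {
  hom <- !is.na(calls) & calls %in% HOM_CODES
  while (a <= b && !hom[a]) a <- a + 1L
  while (b >= a && !hom[b]) b <- b - 1L
  if (a > b) NULL else c(a, b)
}

#' Candidate ROH segments from hit rates
#'
#' Step two of the algorithm: maximal runs of consecutive SNPs whose hit
#' rate meets the threshold (comparison is `>=`, so a SNP appearing in
#' exactly `threshold * windows` homozygous windows qualifies). Each run
#' is trimmed so its first and last SNPs are homozygous non-missing
#' calls; runs emptied by trimming are dropped.
#'
#' @param hit_rates per-SNP hit rates from [window_hit_rates()].
#' @param calls the matching call vector.
#' @param p a [roh_params] object.
#'
#' @return A list of integer 2-vectors `(start_index, end_index)`.
#' @export
candidate_segments <- function(hit_rates, calls, p) {
  pass <- hit_rates >= p$window_threshold - 1e-9
  if (!any(pass)) return(list())
  r <- rle(pass)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- list()
  for (k in which(r$values)) {
    rng <- trim_to_homozygous(starts[k], ends[k], calls)
    if (!is.null(rng)) out[[length(out) + 1L]] <- rng
  }
  out
}

# Split an index range at every adjacent-SNP interval wider than
# max_gap_kb; returns a list of ranges.
split_at_gaps <- function(a, b, bp, max_gap_kb) {
  if (a == b) return(list(c(a, b)))
  gaps <- which(diff(bp[a:b]) / 1000 > max_gap_kb)  # gap after SNP a+gaps-1
  if (!length(gaps)) return(list(c(a, b)))
  bounds <- c(a - 1L, a - 1L + gaps, b)
  lapply(seq_len(length(bounds) - 1L),
         function(k) c(bounds[k] + 1L, bounds[k + 1L]))
}

# While a piece holds more heterozygous calls than max_het, split at the
# first (leftmost) het, excising it, and recurse on the right part.
split_at_het <- function(a, b, calls, max_het) {
  if (is.infinite(max_het)) return(list(c(a, b)))
  out <- list()
  repeat {
    hets <- which(!is.na(calls[a:b]) & calls[a:b] == 1L)
    if (length(hets) <= max_het) {
      out[[length(out) + 1L]] <- c(a, b)
      return(out)
    }
    h <- a + hets[1L] - 1L
    if (h > a) out[[length(out) + 1L]] <- c(a, h - 1L)
    if (h == b) return(out)
    a <- h + 1L
  }
}

#' Finalize candidate segments into ROH calls
#'
#' Step three of the algorithm, applied to each candidate range:
#' (1) split at every adjacent-SNP interval wider than `max_gap_kb`;
#' (2) within each piece, while heterozygous calls exceed `max_het`,
#' split at heterozygous SNPs, excising them (the het call belongs to
#' neither flank); (3) re-trim piece ends to homozygous non-missing
#' calls; (4) discard pieces failing the density test
#' (`length_kb / n_snp > max_density`), the minimum length
#' (`length_kb < min_kb`) or the minimum SNP count (`n_snp < min_snp`).
#' No lower bound of `window_snp` is imposed, so final segments may be
#' shorter than the scanning window. Missing calls inside a final segment
#' are tolerated without limit (only `window_missing` constrains them).
#' Segment length is the inclusive bp span,
#' `(end_bp - start_bp + 1) / 1000` kb.
#'
#' @param ranges list of index ranges from [candidate_segments()].
#' @param calls the matching call vector.
#' @param map_slice the [snp_map] rows for this chromosome.
#' @param p a [roh_params] object.
#'
#' @return A data frame of final segments with columns `start_idx`,
#'   `end_idx`, `start_bp`, `end_bp`, `n_snp`, `length_kb`, `n_het`,
#'   `n_missing` (zero rows if none survive).
#' @export
finalize_segments <- function(ranges, calls, map_slice, p) {
  bp <- map_slice$bp
  rows <- list()
  for (rng in ranges) {
    pieces <- split_at_gaps(rng[1L], rng[2L], bp, p$max_gap_kb)
    pieces <- unlist(
      lapply(pieces, function(q) split_at_het(q[1L], q[2L], calls, p$max_het)),
      recursive = FALSE
    )
    for (q in pieces) {
      q <- trim_to_homozygous(q[1L], q[2L], calls)
      if (is.null(q)) next
      a <- q[1L]; b <- q[2L]
      n_snp <- b - a + 1L
      length_kb <- (bp[b] - bp[a] + 1) / 1000
      if (length_kb / n_snp > p$max_density) next
      if (length_kb < p$min_kb) next
      if (n_snp < p$min_snp) next
      seg_calls <- calls[a:b]
      rows[[length(rows) + 1L]] <- data.frame(
        start_idx = a, end_idx = b,
        start_bp = bp[a], end_bp = bp[b],
        n_snp = n_snp, length_kb = length_kb,
        n_het = sum(!is.na(seg_calls) & seg_calls == 1L),
        n_missing = sum(is.na(seg_calls))
      )
    }
  }
  if (!length(rows)) {
    return(data.frame(start_idx = integer(), end_idx = integer(),
                      start_bp = numeric(), end_bp = numeric(),
                      n_snp = integer(), length_kb = numeric(),
                      n_het = integer(), n_missing = integer()))
  }
  out <- do.call(rbind, rows)
  out[order(out$start_bp), , drop = FALSE]
}

#' Detect runs of homozygosity
#'
#' Runs the full three-step scanning-window algorithm
#' ([window_hit_rates()], [candidate_segments()], [finalize_segments()])
#' for every individual and chromosome of a quality-controlled dataset.
#'
#' @param ds a [genotype_dataset], already restricted to autosomes.
#' @param p a [roh_params] object.
#'
#' @return A data frame of class `roh_segments`, one row per detected
#'   ROH, ordered by individual (input order), chromosome (map order) and
#'   start position, with columns `iid`, `chrom`, `snp1`, `snp2` (first /
#'   last SNP id), `start_bp`, `end_bp`, `length_kb`, `n_snp`, `n_het`,
#'   `n_missing`.
#' @export
#'
#' @examples
#' map <- snp_map("1", paste0("s", 1:60), seq(50000, by = 50000, length.out = 60))
#' hom <- homozygous_individual(map)
#' p <- roh_params(window_snp = 20, window_het = 0, window_missing = 1,
#'                 window_threshold = 0.05, min_snp = 10, min_kb = 500,
#'                 max_density = 200, max_gap_kb = 2000, max_het = 0)
#' detect_roh(hom, p)
detect_roh <- function(ds, p) {
  stopifnot(inherits(ds, "genotype_dataset"), inherits(p, "roh_params"))
  chroms <- unique(ds$map$chrom)
  rows <- list()
  for (iid in ds$ids) {
    for (ch in chroms) {
      idx <- which(ds$map$chrom == ch)
      calls <- ds$calls[iid, idx]
      map_slice <- ds$map[idx, , drop = FALSE]
      hr <- window_hit_rates(calls, p)
      cand <- candidate_segments(hr, calls, p)
      segs <- finalize_segments(cand, calls, map_slice, p)
      if (nrow(segs)) {
        rows[[length(rows) + 1L]] <- data.frame(
          iid = iid, chrom = ch,
          snp1 = map_slice$snp_id[segs$start_idx],
          snp2 = map_slice$snp_id[segs$end_idx],
          start_bp = segs$start_bp, end_bp = segs$end_bp,
          length_kb = segs$length_kb, n_snp = segs$n_snp,
          n_het = segs$n_het, n_missing = segs$n_missing,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(iid = character(), chrom = character(), snp1 = character(),
               snp2 = character(), start_bp = numeric(), end_bp = numeric(),
               length_kb = numeric(), n_snp = integer(), n_het = integer(),
               n_missing = integer(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("roh_segments", "data.frame")
  out
}

#' Write detected segments as a .hom-style table
#'
#' Tab-delimited table in the style of PLINK's `.hom` output: individual,
#' chromosome, first/last SNP id, start/end bp, length in kb, SNP count,
#' heterozygous and missing counts.
#'
#' @param segments a `roh_segments` data frame from [detect_roh()].
#' @param path output file path.
#'
#' @return Invisibly, `path`.
#' @export
write_hom <- function(segments, path) {
  out <- data.frame(
    IID = segments$iid, CHR = segments$chrom,
    SNP1 = segments$snp1, SNP2 = segments$snp2,
    POS1 = segments$start_bp, POS2 = segments$end_bp,
    KB = segments$length_kb, NSNP = segments$n_snp,
    NHET = segments$n_het, NMIS = segments$n_missing
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
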