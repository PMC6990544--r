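#' Autosomal genome length from a SNP map
#'
#' The analysable length of each chromosome is the span between its first
#' and last SNP, measured as the inclusive bp interval
#' `(last_bp - first_bp + 1) / 1000` kb — the same convention as ROH
#' segment lengths, so that a chromosome fully inside a ROH is covered
#' exactly and `covered_kb <= l_aut_kb` holds as an identity. The
#' autosomal total `L_aut` is the sum over chromosomes. A chromosome
#' carrying a single SNP contributes only its own position (0.001 kb) and
#' raises a warning.
#'
#' @param map a [snp_map] (post quality control).
#'
#' @return A list with `per_chromosome` (data frame: `chrom`, `n_snp`,
#'   `l_kb`) and `total_kb`.
#' @export
autosome_length <- function(map) {
  validate_snp_map(map)
  chroms <- unique(map$chrom)
  per <- do.call(rbind, lapply(chroms, function(ch) {
    bp <- map$bp[map$chrom == ch]
    data.frame(chrom = ch, n_snp = length(bp),
               l_kb = (bp[length(bp)] - bp[1L] + 1) / 1000,
               stringsAsFactors = FALSE)
  }))
  if (any(per$n_snp == 1L)) {
    warning("chromosome(s) with a single SNP contribute 0 kb: ",
            paste(per$chrom[per$n_snp == 1L], collapse = ", "),
            call. = FALSE)
  }
  list(per_chromosome = per, total_kb = sum(per$l_kb))
}

#' Genome coverage of a ROH parameterization
#'
#' How much of the autosomal genome is detectable as ROH at the given
#' settings: an individual with a completely homozygous genotype is
#' simulated on the map, ROH detection is run on it with exactly the
#' parameters under evaluation, and the total ROH length found is the
#' maximal detectable ROH length for any individual on this map. Genome
#' coverage is that length as a percentage of `L_aut`, and is the
#' recommended validity check to report alongside any ROH analysis.
#'
#' @param map a [snp_map] (post quality control).
#' @param p a [roh_params] object.
#'
#' @return A list of class `coverage_report`: `l_aut_kb`, `covered_kb`
#'   (maximal detectable ROH length), `coverage_pct`, and
#'   `per_chromosome` (data frame: `chrom`, `l_kb`, `covered_kb`).
#' @export
covered_length <- function(map, p) {
  hom <- homozygous_individual(map)
  segs <- detect_roh(hom, p)
  aut <- suppressWarnings(autosome_length(map))
  per <- aut$per_chromosome[, c("chrom", "l_kb")]
  per$covered_kb <- vapply(per$chrom, function(ch) {
    sum(segs$length_kb[segs$chrom == ch])
  }, numeric(1L))
  covered <- sum(per$covered_kb)
  structure(
    list(l_aut_kb = aut$total_kb,
         covered_kb = covered,
         coverage_pct = if (aut$total_kb > 0) 100 * covered / aut$total_kb
                        else NA_real_,
         per_chromosome = per),
    class = "coverage_report"
  )
}

#' @export
print.coverage_report <- function(x, ...) {
  cat(sprintf("genome coverage: %.1f%% (%.0f of %.0f kb detectable)\n",
              x$coverage_pct, x$covered_kb, x$l_aut_kb))
  invisible(x)
}

#' Genomic inbreeding estimates F_ROH,aut and F_ROH,cov
#'
#' `F_ROH = L_ROH / L_aut`, where `L_ROH` is the total length of all ROHs
#' in an individual's genome. `f_roh_aut` normalizes by the full autosomal
#' span; `f_roh_cov` normalizes by the covered (detectable) span from
#' [covered_length()], correcting the downward bias of `f_roh_aut` when
#' the parameterization cannot detect ROH on part of the genome. Since
#' `covered_kb <= l_aut_kb`, always `f_roh_cov >= f_roh_aut`.
#'
#' @param segments a `roh_segments` data frame from [detect_roh()] (any
#'   number of individuals).
#' @param l_aut_kb autosomal length in kb from [autosome_length()].
#' @param covered_kb maximal detectable ROH length in kb from
#'   [covered_length()]; if 0, `f_roh_cov` is `NA`.
#' @param ids individuals to report; defaults to those present in
#'   `segments`. Pass the full id vector so segment-free individuals get
#'   estimates of 0.
#'
#' @return A data frame with columns `iid`, `l_roh_kb`, `f_roh_aut`,
#'   `f_roh_cov`.
#' @export
f_roh <- function(segments, l_aut_kb, covered_kb, ids = NULL) {
  stopifnot(l_aut_kb > 0, covered_kb >= 0)
  if (is.null(ids)) ids <- unique(segments$iid)
  l_roh <- vapply(ids, function(i) {
    sum(segments$length_kb[segments$iid == i])
  }, numeric(1L))
  data.frame(
    iid = as.character(ids),
    l_roh_kb = l_roh,
    f_roh_aut = l_roh / l_aut_kb,
    f_roh_cov = if (covered_kb > 0) l_roh / covered_kb else NA_real_,
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Per-SNP ROH incidence
#'
#' For each SNP of the map, the percentage of individuals having a
#' detected segment whose bp span contains the SNP. Used to scan for
#' homozygosity islands and to visualize where a parameterization loses
#' ROH.
#'
#' @param segments a `roh_segments` data frame (all individuals).
#' @param map the [snp_map] the segments were detected on.
#' @param n_individuals number of individuals in the population.
#'
#' @return A data frame with columns `chrom`, `snp_id`, `bp`,
#'   `incidence_pct`.
#' @export
snp_incidence <- function(segments, map, n_individuals) {
  stopifnot(n_individuals >= 1)
  count <- numeric(nrow(map))
  if (nrow(segments)) {
    for (k in seq_len(nrow(segments))) {
      hit <- map$chrom == segments$chrom[k] &
        map$bp >= segments$start_bp[k] & map$bp <= segments$end_bp[k]
      count <- count + hit  # segments never overlap within an individual
    }
  }
  data.frame(
    chrom = map$chrom, snp_id = map$snp_id, bp = map$bp,
    incidence_pct = 100 * count / n_individuals,
    stringsAsFactors = FALSE
  )
}

#' Write per-SNP incidence as a BED-like table
#'
#' Columns: chromosome, 0-based start (`bp - 1`), 1-based end (`bp`),
#' incidence percent. Convenient for genome-browser style plotting.
#'
#' @param incidence output of [snp_incidence()].
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_incidence_bed <- function(incidence, path) {
  out <- data.frame(incidence$chrom,
                    format(incidence$bp - 1, scientific = FALSE, trim = TRUE),
                    format(incidence$bp, scientific = FALSE, trim = TRUE),
                    incidence$incidence_pct)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Minimum SNPs per ROH (Lencz/Purfield formula)
#'
#' `L = ln(alpha / (n_s * n_i)) / ln(1 - het)`: the minimal number of
#' consecutive homozygous SNPs such that the expected number of
#' chance (false positive) ROH across the whole dataset is bounded by
#' `alpha`. The real-valued result is rounded up (a "minimal number of
#' SNPs" must be an integer; the ceiling is the conservative closure),
#' with a floor of 1.
#'
#' @param n_s number of genotyped SNPs per individual.
#' @param n_i number of genotyped individuals.
#' @param alpha tolerated expected number of false-positive ROH
#'   (default 0.05).
#' @param het mean heterozygosity across SNPs, strictly inside (0, 1).
#'
#' @return Integer minimum SNP count.
#' @export
#'
#' @examples
#' lencz_min_snp(n_s = 50000, n_i = 100, alpha = 0.05, het = 0.30)
lencz_min_snp <- function(n_s, n_i, alpha = 0.05, het) {
  stopifnot(n_s >= 1, n_i >= 1, alpha > 0, alpha < 1)
  if (het <= 0 || het >= 1) {
    stop("het must be strictly between 0 and 1", call. = FALSE)
  }
  L <- log(alpha / (n_s * n_i)) / log(1 - het)
  max(1L, as.integer(ceiling(L)))
}

#' Scanning-window threshold from the desired outer-SNP exclusion
#'
#' `t = floor((N_out + 1) / L, 3)`: the hit-rate threshold that discards
#' `n_out` outer SNPs on each side of a homozygous segment (outer SNPs
#' are more likely homozygous by chance than by descent), where `L` is
#' the scanning window size and flooring is to three decimal places. The
#' `+ 1` marks the first SNP tolerated in the final ROH. For a window of
#' 100 SNPs and 4 excluded outer SNPs the threshold is 0.05.
#'
#' @param window_size scanning window size in SNPs (`L`).
#' @param n_out outer SNPs per side to exclude from the final ROH.
#'
#' @return The threshold, a multiple of 0.001 in (0, 1\].
#' @export
#'
#' @examples
#' window_threshold(window_size = 100, n_out = 4)  # 0.05
window_threshold <- function(window_size, n_out) {
  stopifnot(window_size >= 1, n_out >= 0, n_out < window_size)
  t <- floor((n_out + 1) * 1000 / window_size + 1e-9) / 1000
  if (t <= 0) {
    stop("threshold floors to 0 for window_size ", window_size,
         "; increase n_out or shrink the window", call. = FALSE)
  }
  t
}
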