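#' Pruning parameters
#'
#' Settings for minor-allele-frequency filtering and windowed pairwise
#' linkage-disequilibrium pruning, mirroring PLINK's `--maf` and
#' `--indep-pairwise <window> <step> <r2>`.
#'
#' @param maf_min minimum minor allele frequency in \[0, 0.5\]; SNPs with
#'   MAF strictly below it are removed (a SNP exactly at the threshold is
#'   retained, as with `--maf`).
#' @param ld_window_snps LD-pruning window size in SNPs (default 50).
#' @param ld_step_snps window step in SNPs (default 5); must be smaller
#'   than the window.
#' @param r2_max r-squared threshold in (0, 1\]; within a window, one
#'   member of every SNP pair with r-squared above it is removed.
#'
#' @return A list of class `prune_params`.
#' @export
prune_params <- function(maf_min = 0, ld_window_snps = 50L,
                         ld_step_snps = 5L, r2_max = 1) {
  stopifnot(
    maf_min >= 0, maf_min <= 0.5,
    ld_step_snps > 0, ld_window_snps > ld_step_snps,
    r2_max > 0, r2_max <= 1
  )
  structure(
    list(maf_min = maf_min,
         ld_window_snps = as.integer(ld_window_snps),
         ld_step_snps = as.integer(ld_step_snps),
         r2_max = r2_max),
    class = "prune_params"
  )
}

#' Per-SNP allele frequencies
#'
#' Computes, over non-missing calls, the frequency of each SNP's A allele
#' and the minor allele frequency `MAF = min(f, 1 - f)`. A SNP with no
#' non-missing calls has undefined frequency (`NA`).
#'
#' @param ds a [genotype_dataset].
#'
#' @return A data frame with columns `snp_id`, `n_called`, `f_a`
#'   (A-allele frequency) and `maf`.
#' @export
allele_frequencies <- function(ds) {
  n_called <- colSums(!is.na(ds$calls))
  # A-allele count: 2 per HOM_A (code 0), 1 per HET (code 1)
  a_count <- 2 * n_called - colSums(ds$calls, na.rm = TRUE)
  b_count <- 2 * n_called - a_count
  # integer numerator keeps MAF exact at thresholds like 0.05 or 0.20
  data.frame(
    snp_id = ds$map$snp_id,
    n_called = as.integer(n_called),
    f_a = ifelse(n_called > 0, a_count / (2 * n_called), NA_real_),
    maf = ifelse(n_called > 0, pmin(a_count, b_count) / (2 * n_called),
                 NA_real_),
    stringsAsFactors = FALSE
  )
}

#' Minor-allele-frequency filter
#'
#' Removes SNPs with minor allele frequency strictly below `maf_min`
#' (PLINK `--maf` semantics: a SNP exactly at the threshold is retained).
#' SNPs whose MAF is undefined because every call is missing are removed
#' whenever `maf_min > 0`.
#'
#' @param ds a [genotype_dataset].
#' @param maf_min MAF threshold in \[0, 0.5\].
#'
#' @return The filtered [genotype_dataset].
#' @export
maf_filter <- function(ds, maf_min) {
  stopifnot(maf_min >= 0, maf_min <= 0.5)
  maf <- allele_frequencies(ds)$maf
  keep <- !is.na(maf) & maf >= maf_min
  if (maf_min == 0) keep <- keep | is.na(maf)  # vacuous threshold
  subset_snps(ds, keep)
}

#' Pairwise r-squared of two SNPs
#'
#' Squared Pearson correlation of genotype dosages (0/1/2), the composite
#' LD statistic PLINK's `--indep-pairwise` uses on unphased data, computed
#' over individuals non-missing at both SNPs.
#'
#' @param g1,g2 genotype vectors coded 0/1/2/NA, same length.
#'
#' @return r-squared in \[0, 1\], or `NA` if fewer than 2 complete pairs
#'   remain or either SNP is constant on the complete-pairs subset.
#' @export
r_squared <- function(g1, g2) {
  stopifnot(length(g1) == length(g2))
  ok <- !is.na(g1) & !is.na(g2)
  if (sum(ok) < 2L) return(NA_real_)
  x <- g1[ok]
  y <- g2[ok]
  if (stats::var(x) == 0 || stats::var(y) == 0) return(NA_real_)
  stats::cor(x, y)^2
}

#' Windowed pairwise LD pruning
#'
#' Greedy windowed pruning per chromosome, as in PLINK
#' `--indep-pairwise`: a window of `ld_window_snps` consecutive currently
#' kept SNPs slides in steps of `ld_step_snps`; within a window, for every
#' pair with r-squared above `r2_max` one member is removed. Passes repeat
#' until no window contains a violating pair. Victim rule: the member with
#' the smaller MAF (computed once on the input dataset) is removed; ties
#' remove the later SNP in map order. Undefined r-squared (monomorphic or
#' all-missing SNPs) never triggers removal.
#'
#' @param ds a [genotype_dataset].
#' @param p a [prune_params] object.
#'
#' @return The [genotype_dataset] restricted to kept SNPs.
#' @export
indep_pairwise <- function(ds, p) {
  stopifnot(inherits(p, "prune_params"))
  maf <- allele_frequencies(ds)$maf
  keep <- rep(TRUE, n_snps(ds))
  for (ch in unique(ds$map$chrom)) {
    idx_ch <- which(ds$map$chrom == ch)
    repeat {
      removed_any <- FALSE
      cur <- idx_ch[keep[idx_ch]]
      if (length(cur) < 2L) break
      starts <- seq(1L, length(cur), by = p$ld_step_snps)
      for (s in starts) {
        win <- cur[s:min(s + p$ld_window_snps - 1L, length(cur))]
        if (length(win) < 2L) next
        for (ii in seq_len(length(win) - 1L)) {
          i <- win[ii]
          if (!keep[i]) next
          for (jj in seq(ii + 1L, length(win))) {
            j <- win[jj]
            if (!keep[j]) next
            r2 <- r_squared(ds$calls[, i], ds$calls[, j])
            if (!is.na(r2) && r2 > p$r2_max + 1e-12) {
              victim <- ld_prune_victim(i, j, maf)
              keep[victim] <- FALSE
              removed_any <- TRUE
              if (victim == i) break  # i gone; move to next i
            }
          }
        }
      }
      if (!removed_any) break
    }
  }
  subset_snps(ds, keep)
}

# Victim rule: smaller MAF loses; tie (or both MAF undefined) -> later SNP
# in map order. Indices i < j in map order.
ld_prune_victim <- function(i, j, maf) {
  mi <- maf[i]
  mj <- maf[j]
  if (is.na(mi) || is.na(mj) || mi == mj) return(max(i, j))
  if (mi < mj) i else j
}
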