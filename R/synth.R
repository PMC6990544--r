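#' Specification for a synthetic SNP-array population
#'
#' Describes a population with known ROH truth: per-chromosome SNP maps
#' with controllable spacing, planted homozygous segments per individual,
#' Hardy-Weinberg background genotypes and independent missingness. The
#' defaults emulate a medium-density array (one SNP per ~50 kb).
#'
#' @param n_chromosomes number of autosomes.
#' @param snps_per_chromosome SNPs per chromosome.
#' @param n_individuals individuals to simulate.
#' @param spacing_kb mean inter-SNP spacing in kb (default 50, the
#'   medium-density scale).
#' @param spacing_model `"uniform"` (constant spacing) or `"gamma"`
#'   (gamma-distributed spacing with the stated mean, shape 4, producing
#'   realistic irregularity and occasional wide gaps).
#' @param planted_segments data frame with columns `individual` (index in
#'   1..n_individuals), `chrom` (index in 1..n_chromosomes), `start_snp`
#'   (1-based SNP index on that chromosome) and `n_snp`; segments must lie
#'   within chromosome bounds and not overlap within an individual. `NULL`
#'   for none.
#' @param background_het if non-`NULL`, the per-SNP heterozygosity rate
#'   outside planted segments; implemented by fixing every SNP's allele
#'   frequency at the `f` solving `2 f (1 - f) = background_het`
#'   (requires `background_het <= 0.5`). When `NULL`, allele frequencies
#'   are drawn per SNP from `maf_range`.
#' @param missing_rate independent per-call missingness probability.
#' @param maf_range uniform range for per-SNP minor allele frequency,
#'   within \[0, 0.5\].
#' @param seed integer seed making generation deterministic.
#'
#' @return A list of class `synth_spec`.
#' @export
synth_spec <- function(n_chromosomes = 3L, snps_per_chromosome = 1000L,
                       n_individuals = 20L, spacing_kb = 50,
                       spacing_model = c("uniform", "gamma"),
                       planted_segments = NULL, background_het = NULL,
                       missing_rate = 0.01, maf_range = c(0.05, 0.5),
                       seed = 1L) {
  spacing_model <- match.arg(spacing_model)
  stopifnot(
    n_chromosomes >= 1, snps_per_chromosome >= 2, n_individuals >= 1,
    spacing_kb > 0, missing_rate >= 0, missing_rate <= 1,
    length(maf_range) == 2L, maf_range[1L] >= 0, maf_range[2L] <= 0.5,
    maf_range[1L] <= maf_range[2L]
  )
  if (!is.null(background_het)) {
    stopifnot(background_het > 0, background_het <= 0.5)
  }
  if (!is.null(planted_segments)) {
    ps <- planted_segments
    stopifnot(all(c("individual", "chrom", "start_snp", "n_snp") %in%
                    names(ps)))
    if (any(ps$individual < 1 | ps$individual > n_individuals) ||
        any(ps$chrom < 1 | ps$chrom > n_chromosomes) ||
        any(ps$start_snp < 1) || any(ps$n_snp < 1) ||
        any(ps$start_snp + ps$n_snp - 1 > snps_per_chromosome)) {
      stop("planted segment outside chromosome bounds", call. = FALSE)
    }
    for (key in split(ps, interaction(ps$individual, ps$chrom, drop = TRUE))) {
      if (nrow(key) < 2L) next
      key <- key[order(key$start_snp), ]
      ends <- key$start_snp + key$n_snp - 1L
      if (any(key$start_snp[-1L] <= ends[-nrow(key)])) {
        stop("planted segments overlap within an individual", call. = FALSE)
      }
    }
  }
  structure(
    list(n_chromosomes = as.integer(n_chromosomes),
         snps_per_chromosome = as.integer(snps_per_chromosome),
         n_individuals = as.integer(n_individuals),
         spacing_kb = spacing_kb, spacing_model = spacing_model,
         planted_segments = planted_segments,
         background_het = background_het,
         missing_rate = missing_rate, maf_range = maf_range,
         seed = as.integer(seed)),
    class = "synth_spec"
  )
}

# Run expr under a local RNG state seeded with `seed`.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

synth_map <- function(spec) {
  maps <- lapply(seq_len(spec$n_chromosomes), function(ch) {
    n <- spec$snps_per_chromosome
    sp_bp <- if (spec$spacing_model == "uniform") {
      rep(round(spec$spacing_kb * 1000), n - 1L)
    } else {
      pmax(1, round(stats::rgamma(n - 1L, shape = 4,
                                  scale = spec$spacing_kb / 4) * 1000))
    }
    data.frame(
      chrom = as.character(ch),
      snp_id = sprintf("chr%d_snp%d", ch, seq_len(n)),
      cm = 0,
      bp = cumsum(c(1, sp_bp)),
      stringsAsFactors = FALSE
    )
  })
  map <- do.call(rbind, maps)
  class(map) <- c("snp_map", "data.frame")
  map
}

#' Simulate a completely homozygous individual
#'
#' One individual whose every call is homozygous (HOM-A) with no missing
#' data, built on a given map. Running ROH detection on this individual
#' measures the maximal detectable ROH length for the parameterization
#' (see [covered_length()]).
#'
#' @param map a [snp_map].
#'
#' @return A [genotype_dataset] with a single individual `"HOM"`.
#' @export
homozygous_individual <- function(map) {
  validate_snp_map(map)
  calls <- matrix(0L, nrow = 1L, ncol = nrow(map))
  genotype_dataset(map, "HOM", calls)
}

#' Generate a synthetic population with known ROH truth
#'
#' Deterministic for a given seed. The map is built per chromosome from
#' the spacing model. Each SNP receives an allele frequency (drawn from
#' `maf_range`, or fixed by `background_het`); outside planted segments,
#' calls are drawn per SNP from Hardy-Weinberg at that frequency (no
#' background LD, so each test's assumptions stay isolated). Inside a
#' planted segment every call is homozygous, the homozygote chosen once
#' per (individual, SNP) with probability equal to the allele frequency.
#' Missingness is then applied independently everywhere. Truth records
#' each planted segment's bp span (exact on any spacing model, since
#' segments are specified in SNP indices and converted via the map) and
#' each individual's true total ROH kb and `f_roh_aut`.
#'
#' @param spec a [synth_spec].
#'
#' @return A list with `dataset` (a [genotype_dataset]), `truth` (list
#'   with `segments`: data frame `iid`, `chrom`, `start_bp`, `end_bp`,
#'   `start_snp`, `n_snp`, `length_kb`; and `per_individual`: data frame
#'   `iid`, `l_roh_kb`, `f_roh_aut`), and `maf` (the per-SNP allele
#'   frequencies used).
#' @export
synth_generate <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  with_seed(spec$seed, {
    map <- synth_map(spec)
    n_snp <- nrow(map)
    n_ind <- spec$n_individuals
    f <- if (!is.null(spec$background_het)) {
      rep((1 - sqrt(1 - 2 * spec$background_het)) / 2, n_snp)
    } else {
      stats::runif(n_snp, spec$maf_range[1L], spec$maf_range[2L])
    }
    # Hardy-Weinberg background, f = frequency of the A allele (MAF since
    # f <= 0.5): P(HOM_A) = f^2, P(HET) = 2f(1-f), P(HOM_B) = (1-f)^2
    u <- matrix(stats::runif(n_ind * n_snp), nrow = n_ind, ncol = n_snp)
    p_hom_a <- matrix(f^2, n_ind, n_snp, byrow = TRUE)
    p_het <- matrix(2 * f * (1 - f), n_ind, n_snp, byrow = TRUE)
    calls <- matrix(2L, n_ind, n_snp)
    calls[u < p_hom_a + p_het] <- 1L
    calls[u < p_hom_a] <- 0L

    truth_rows <- list()
    chrom_offset <- c(0L, cumsum(rep(spec$snps_per_chromosome,
                                     spec$n_chromosomes)))
    ids <- sprintf("ind%02d", seq_len(n_ind))
    ps <- spec$planted_segments
    if (!is.null(ps) && nrow(ps)) {
      for (k in seq_len(nrow(ps))) {
        i <- ps$individual[k]
        cols <- chrom_offset[ps$chrom[k]] + ps$start_snp[k] +
          seq_len(ps$n_snp[k]) - 1L
        calls[i, cols] <- ifelse(stats::runif(length(cols)) < f[cols], 0L, 2L)
        truth_rows[[k]] <- data.frame(
          iid = ids[i], chrom = as.character(ps$chrom[k]),
          start_bp = map$bp[cols[1L]], end_bp = map$bp[cols[length(cols)]],
          start_snp = ps$start_snp[k], n_snp = ps$n_snp[k],
          length_kb = (map$bp[cols[length(cols)]] - map$bp[cols[1L]] + 1) /
            1000,
          stringsAsFactors = FALSE
        )
      }
    }
    if (spec$missing_rate > 0) {
      calls[matrix(stats::runif(n_ind * n_snp), n_ind, n_snp) <
              spec$missing_rate] <- NA_integer_
    }
    ds <- genotype_dataset(map, ids, calls)

    seg_truth <- if (length(truth_rows)) do.call(rbind, truth_rows) else
      data.frame(iid = character(), chrom = character(),
                 start_bp = numeric(), end_bp = numeric(),
                 start_snp = integer(), n_snp = integer(),
                 length_kb = numeric(), stringsAsFactors = FALSE)
    l_aut <- suppressWarnings(autosome_length(map))$total_kb
    per_ind <- data.frame(
      iid = ids,
      l_roh_kb = vapply(ids, function(i) {
        sum(seg_truth$length_kb[seg_truth$iid == i])
      }, numeric(1L)),
      stringsAsFactors = FALSE, row.names = NULL
    )
    per_ind$f_roh_aut <- per_ind$l_roh_kb / l_aut
    list(dataset = ds,
         truth = list(segments = seg_truth, per_individual = per_ind),
         maf = f)
  })
}

#' Generate genotypes with block LD structure
#'
#' Fixture generator for LD-pruning tests: SNPs are arranged in blocks;
#' within a block each SNP is a noisy copy of a block template genotype.
#' A copy keeps the template call with probability `p = r2^(1/4)` and is
#' redrawn from Hardy-Weinberg otherwise: the dosage correlation between
#' two copies is then `p^2 = sqrt(r2)`, so their squared correlation —
#' the pruning statistic — is `r2` in expectation. Blocks are mutually
#' independent. `within_block_r2 = 1` yields identical columns per block;
#' `block_size = 1` yields independent SNPs.
#'
#' @param spec a [synth_spec] (its map, individual count, `maf_range` and
#'   seed are used; planted segments and missingness are ignored).
#' @param block_size SNPs per block (>= 1).
#' @param within_block_r2 target expected pairwise r-squared within a
#'   block, in \[0, 1\].
#'
#' @return A [genotype_dataset].
#' @export
ld_block_map <- function(spec, block_size, within_block_r2) {
  stopifnot(inherits(spec, "synth_spec"), block_size >= 1,
            within_block_r2 >= 0, within_block_r2 <= 1)
  keep_prob <- within_block_r2^0.25
  with_seed(spec$seed + 1L, {
    map <- synth_map(spec)
    n_snp <- nrow(map)
    n_ind <- spec$n_individuals
    calls <- matrix(NA_integer_, n_ind, n_snp)
    draw_hw <- function(n, f) {
      u <- stats::runif(n)
      ifelse(u < f^2, 0L, ifelse(u < f^2 + 2 * f * (1 - f), 1L, 2L))
    }
    for (ch in unique(map$chrom)) {
      idx <- which(map$chrom == ch)
      block_of <- (seq_along(idx) - 1L) %/% block_size
      for (b in unique(block_of)) {
        cols <- idx[block_of == b]
        f <- stats::runif(1L, spec$maf_range[1L], spec$maf_range[2L])
        template <- draw_hw(n_ind, f)
        for (j in cols) {
          fresh <- draw_hw(n_ind, f)
          copy <- stats::runif(n_ind) < keep_prob
          calls[, j] <- ifelse(copy, template, fresh)
        }
      }
    }
    genotype_dataset(map, sprintf("ind%02d", seq_len(n_ind)), calls)
  })
}
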