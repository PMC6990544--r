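test_that("window hit rates are 1 on fully homozygous chromosomes", {
  p <- roh_params(window_snp = 100L, window_het = 0L, window_missing = 1L)
  hr <- window_hit_rates(rep(0L, 300), p)
  expect_equal(hr, rep(1, 300))
})

test_that("chromosomes shorter than the window yield all-zero hit rates", {
  p <- roh_params(window_snp = 100L)
  expect_equal(window_hit_rates(rep(0L, 50), p), rep(0, 50))
})

test_that("hit rate counts homozygous windows among those covering a SNP", {
  # 300 SNPs, window 100: SNP 150 is interior, covered by the 100 windows
  # starting at 51..150. Hets at 50 and 155 leave exactly the 5 windows
  # starting at 51..55 homozygous -> hit rate 5/100 = 0.05, which meets
  # the 0.05 threshold; moving the right het to 154 leaves 4 -> 0.04.
  p <- roh_params(window_snp = 100L, window_het = 0L, window_missing = 0L,
                  window_threshold = 0.05)
  calls <- rep(0L, 300)
  calls[c(50, 155)] <- 1L
  hr <- window_hit_rates(calls, p)
  expect_equal(hr[150], 0.05)
  expect_true(hr[150] >= p$window_threshold)

  calls154 <- rep(0L, 300)
  calls154[c(50, 154)] <- 1L
  expect_equal(window_hit_rates(calls154, p)[150], 0.04)

  expect_equal(hr, bf_hit_rates(calls, p))  # edge denominators included
})

test_that("window tolerances admit het and missing calls as configured", {
  calls <- rep(0L, 60)
  calls[30] <- 1L
  strict <- roh_params(window_snp = 20L, window_het = 0L,
                       window_missing = 0L)
  lax <- roh_params(window_snp = 20L, window_het = 1L, window_missing = 0L)
  expect_equal(window_hit_rates(calls, strict)[30], 0)
  expect_equal(window_hit_rates(calls, lax)[30], 1)

  calls[30] <- NA
  expect_equal(window_hit_rates(calls, strict)[30], 0)
  miss_ok <- roh_params(window_snp = 20L, window_het = 0L,
                        window_missing = 1L)
  expect_equal(window_hit_rates(calls, miss_ok)[30], 1)
})

test_that("candidate segments are maximal passing runs trimmed to homozygous ends", {
  p <- permissive_params(window_snp = 5L)
  expect_equal(candidate_segments(rep(0.01, 50), rep(0L, 50), p), list())

  hr <- rep(1, 120)
  expect_equal(candidate_segments(hr, rep(2L, 120), p), list(c(1L, 120L)))

  # heterozygous/missing ends are trimmed to the outermost homozygous call
  calls <- rep(0L, 30)
  calls[c(1, 2, 29)] <- 1L
  calls[30] <- NA
  got <- candidate_segments(rep(1, 30), calls, p)
  expect_equal(got, list(c(3L, 28L)))
})

test_that("finalize splits at wide gaps and re-evaluates the pieces", {
  # 40 SNPs at 50 kb spacing, one 1500-kb gap after SNP 20
  bp <- c(seq(1, by = 50000, length.out = 20),
          seq(1 + 19 * 50000 + 1.5e6, by = 50000, length.out = 20))
  map <- snp_map("1", paste0("s", 1:40), bp)
  calls <- rep(0L, 40)
  p <- roh_params(window_snp = 5L, window_het = 0L, window_missing = 1L,
                  window_threshold = 0.05, min_snp = 2L, min_kb = 100,
                  max_density = 1e6, max_gap_kb = 1000, max_het = 0L)
  segs <- finalize_segments(list(c(1L, 40L)), calls, map, p)
  expect_equal(nrow(segs), 2L)
  expect_equal(segs$start_idx, c(1L, 21L))
  expect_equal(segs$end_idx, c(20L, 40L))

  # raising max_gap_kb above the gap keeps the run whole
  p2 <- roh_params(window_snp = 5L, window_het = 0L, window_missing = 1L,
                   window_threshold = 0.05, min_snp = 2L, min_kb = 100,
                   max_density = 1e6, max_gap_kb = 2000, max_het = 0L)
  expect_equal(nrow(finalize_segments(list(c(1L, 40L)), calls, map, p2)), 1L)
})

test_that("finalize applies density, length and SNP-count filters", {
  # 10 SNPs spanning 2000 kb -> 200 kb/SNP
  map <- uniform_map(n_snp = 10L, spacing_kb = 2000 / 9)
  calls <- rep(0L, 10)
  base <- list(window_snp = 5L, window_het = 0L, window_missing = 1L,
               window_threshold = 0.05, min_snp = 2L, min_kb = 100,
               max_gap_kb = 1e6, max_het = 0L)
  dense <- do.call(roh_params, c(base, max_density = 150))
  expect_equal(nrow(finalize_segments(list(c(1L, 10L)), calls, map, dense)), 0L)
  loose <- do.call(roh_params, c(base, max_density = 250))
  expect_equal(nrow(finalize_segments(list(c(1L, 10L)), calls, map, loose)), 1L)

  # 900-kb piece against min_kb 1000
  map2 <- uniform_map(n_snp = 10L, spacing_kb = 100)
  short <- do.call(roh_params, c(base[setdiff(names(base), "min_kb")],
                                 min_kb = 1000, max_density = 1e6))
  expect_equal(nrow(finalize_segments(list(c(1L, 10L)), rep(0L, 10),
                                      map2, short)), 0L)

  # min_snp
  many <- do.call(roh_params, c(base[setdiff(names(base), "min_snp")],
                                min_snp = 11L, max_density = 1e6))
  expect_equal(nrow(finalize_segments(list(c(1L, 10L)), calls, map, many)), 0L)
})

test_that("heterozygous excess splits excise the offending call", {
  map <- uniform_map(n_snp = 41L, spacing_kb = 50)
  calls <- rep(0L, 41)
  calls[21] <- 1L
  p <- roh_params(window_snp = 5L, window_het = 1L, window_missing = 1L,
                  window_threshold = 0.05, min_snp = 2L, min_kb = 100,
                  max_density = 1e6, max_gap_kb = 1e6, max_het = 0L)
  segs <- finalize_segments(list(c(1L, 41L)), calls, map, p)
  expect_equal(segs$start_idx, c(1L, 22L))
  expect_equal(segs$end_idx, c(20L, 41L))
  expect_equal(segs$n_het, c(0L, 0L))

  # max_het 1 tolerates the call without splitting
  p1 <- roh_params(window_snp = 5L, window_het = 1L, window_missing = 1L,
                   window_threshold = 0.05, min_snp = 2L, min_kb = 100,
                   max_density = 1e6, max_gap_kb = 1e6, max_het = 1L)
  segs1 <- finalize_segments(list(c(1L, 41L)), calls, map, p1)
  expect_equal(nrow(segs1), 1L)
  expect_equal(segs1$n_het, 1L)
})

test_that("fully homozygous individuals yield one full-span ROH per chromosome", {
  map <- uniform_map(n_chrom = 3L, n_snp = 60L, spacing_kb = 50)
  ds <- homozygous_individual(map)
  segs <- detect_roh(ds, permissive_params())
  expect_equal(nrow(segs), 3L)
  expect_equal(segs$n_snp, rep(60L, 3))
  for (k in 1:3) {
    bp <- map$bp[map$chrom == segs$chrom[k]]
    expect_equal(segs$start_bp[k], bp[1])
    expect_equal(segs$end_bp[k], bp[60])
  }
})

test_that("strictly alternating heterozygous calls yield zero ROH", {
  calls <- rep(c(0L, 1L), 100)
  ds <- calls_dataset(calls)
  segs <- detect_roh(ds, permissive_params())
  expect_equal(nrow(segs), 0L)
})

test_that("detection matches the brute-force oracle on planted-segment data", {
  map <- uniform_map(n_chrom = 1L, n_snp = 180L, spacing_kb = 60)
  set.seed(21)
  calls <- sample(c(0L, 1L, 2L), 180, replace = TRUE,
                  prob = c(0.35, 0.3, 0.35))
  for (start in c(10, 70, 140)) {  # three planted homozygous segments
    calls[start:(start + 29)] <- sample(c(0L, 2L), 30, replace = TRUE)
  }
  ds <- genotype_dataset(map, "i1", rbind(calls))
  p <- roh_params(window_snp = 10L, window_het = 0L, window_missing = 1L,
                  window_threshold = 0.05, min_snp = 15L, min_kb = 1000,
                  max_density = 200, max_gap_kb = 2000, max_het = 0L)
  got <- detect_roh(ds, p)
  want <- bf_detect_roh(ds, p)
  expect_equal(nrow(got), 3L)
  expect_equal(got$start_bp, want$start_bp)
  expect_equal(got$end_bp, want$end_bp)
  expect_equal(got$n_snp, want$n_snp)
})

test_that("random small instances match the oracle segment for segment", {
  set.seed(2024)
  for (k in 1:40) {
    inst <- random_instance()
    got <- detect_roh(inst$ds, inst$p)
    want <- bf_detect_roh(inst$ds, inst$p)
    key <- function(d) if (nrow(d)) paste(d$iid, d$chrom, d$start_bp,
                                          d$end_bp, d$n_snp) else character(0)
    expect_identical(sort(key(got)), sort(key(want)),
                     info = paste("instance", k))
  }
})

test_that("detected segments never overlap and satisfy all final constraints", {
  set.seed(77)
  ps <- data.frame(individual = rep(1:10, each = 2),
                   chrom = rep(1:2, 10),
                   start_snp = sample(50:300, 20),
                   n_snp = sample(40:80, 20, replace = TRUE))
  gen <- synth_generate(synth_spec(
    n_chromosomes = 2L, snps_per_chromosome = 500L, n_individuals = 10L,
    planted_segments = ps, background_het = 0.32, missing_rate = 0.01,
    seed = 77L
  ))
  p <- baseline_params(min_snp = min_snp_for(gen$dataset))
  segs <- detect_roh(gen$dataset, p)
  expect_gt(nrow(segs), 0L)
  expect_true(all(segs$length_kb >= p$min_kb))
  expect_true(all(segs$n_snp >= p$min_snp))
  expect_true(all(segs$length_kb / segs$n_snp <= p$max_density))
  expect_true(all(segs$n_het <= p$max_het))
  expect_equal(segs$length_kb, (segs$end_bp - segs$start_bp + 1) / 1000)
  for (grp in split(segs, paste(segs$iid, segs$chrom))) {
    if (nrow(grp) < 2L) next
    grp <- grp[order(grp$start_bp), ]
    expect_true(all(grp$start_bp[-1L] > grp$end_bp[-nrow(grp)]))
    # adjacent-SNP gaps inside each segment respect max_gap_kb
  }
  for (k in seq_len(min(nrow(segs), 20L))) {
    idx <- which(gen$dataset$map$chrom == segs$chrom[k] &
                   gen$dataset$map$bp >= segs$start_bp[k] &
                   gen$dataset$map$bp <= segs$end_bp[k])
    expect_true(all(diff(gen$dataset$map$bp[idx]) / 1000 <= p$max_gap_kb))
  }
})

test_that("stringency and relaxation monotonicity hold", {
  set.seed(31)
  ps <- data.frame(individual = 1, chrom = 1,
                   start_snp = c(40, 200), n_snp = c(60, 90))
  gen <- synth_generate(synth_spec(
    n_chromosomes = 1L, snps_per_chromosome = 400L, n_individuals = 1L,
    planted_segments = ps, background_het = 0.32, missing_rate = 0.01,
    seed = 31L
  ))
  ds <- gen$dataset
  total_kb <- function(p) sum(detect_roh(ds, p)$length_kb)
  mk <- function(...) {
    args <- list(window_snp = 20L, window_het = 0L, window_missing = 1L,
                 window_threshold = 0.05, min_snp = 20L, min_kb = 1000,
                 max_density = 200, max_gap_kb = 2000, max_het = 0L)
    args[names(list(...))] <- list(...)
    do.call(roh_params, args)
  }
  # raising window size or threshold never increases total ROH length
  len_w <- vapply(c(10L, 20L, 40L, 60L),
                  function(w) total_kb(mk(window_snp = w)), numeric(1))
  expect_true(all(diff(len_w) <= 1e-9))
  len_t <- vapply(c(0.05, 0.25, 0.5, 0.95),
                  function(t) total_kb(mk(window_threshold = t)), numeric(1))
  expect_true(all(diff(len_t) <= 1e-9))
  # relaxing gap or density never decreases it
  len_g <- vapply(c(50, 200, 1000, 2000),
                  function(g) total_kb(mk(max_gap_kb = g)), numeric(1))
  expect_true(all(diff(len_g) >= -1e-9))
  len_d <- vapply(c(20, 60, 200, 500),
                  function(d) total_kb(mk(max_density = d)), numeric(1))
  expect_true(all(diff(len_d) >= -1e-9))
})

test_that("write_hom emits a readable .hom-style table", {
  map <- uniform_map(n_snp = 60L)
  segs <- detect_roh(homozygous_individual(map), permissive_params())
  f <- tempfile(fileext = ".hom")
  write_hom(segs, f)
  back <- read.delim(f)
  expect_equal(nrow(back), nrow(segs))
  expect_equal(back$KB, segs$length_kb)
  expect_equal(names(back), c("IID", "CHR", "SNP1", "SNP2", "POS1", "POS2",
                              "KB", "NSNP", "NHET", "NMIS"))
})
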