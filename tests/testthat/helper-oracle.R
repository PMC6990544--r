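# Naive reference implementations, written with plain loops and direct
# enumeration, independent of the package's vectorized code paths. The
# detection oracle enumerates every window and every split explicitly.

bf_hit_rates <- function(calls, p) {
  n <- length(calls)
  L <- p$window_snp
  rates <- numeric(n)
  if (n < L) return(rates)
  is_hom_window <- function(w) {
    n_het <- 0L
    n_mis <- 0L
    for (c in w) {
      if (is.na(c)) n_mis <- n_mis + 1L
      else if (c == 1L) n_het <- n_het + 1L
    }
    n_het <= p$window_het && n_mis <= p$window_missing
  }
  for (s in seq_len(n)) {
    n_cover <- 0L
    n_hom <- 0L
    for (start in seq_len(n - L + 1L)) {
      if (start <= s && s <= start + L - 1L) {
        n_cover <- n_cover + 1L
        if (is_hom_window(calls[start:(start + L - 1L)])) {
          n_hom <- n_hom + 1L
        }
      }
    }
    if (n_cover > 0L) rates[s] <- n_hom / n_cover
  }
  rates
}

bf_is_hom_call <- function(c) !is.na(c) && (c == 0L || c == 2L)

bf_trim <- function(a, b, calls) {
  while (a <= b && !bf_is_hom_call(calls[a])) a <- a + 1L
  while (b >= a && !bf_is_hom_call(calls[b])) b <- b - 1L
  if (a > b) NULL else c(a, b)
}

# One individual, one chromosome: full three-step enumeration.
bf_detect_chrom <- function(calls, bp, p) {
  n <- length(calls)
  rates <- bf_hit_rates(calls, p)
  pass <- rates >= p$window_threshold
  # maximal passing runs, by direct scan
  runs <- list()
  s <- NA
  for (i in seq_len(n)) {
    if (pass[i] && is.na(s)) s <- i
    if (!pass[i] && !is.na(s)) {
      runs[[length(runs) + 1L]] <- c(s, i - 1L)
      s <- NA
    }
  }
  if (!is.na(s)) runs[[length(runs) + 1L]] <- c(s, n)
  runs <- Filter(Negate(is.null), lapply(runs, function(r) {
    bf_trim(r[1L], r[2L], calls)
  }))
  # gap split
  pieces <- list()
  for (r in runs) {
    a <- r[1L]
    for (i in seq(r[1L], r[2L])) {
      if (i < r[2L] && (bp[i + 1L] - bp[i]) / 1000 > p$max_gap_kb) {
        pieces[[length(pieces) + 1L]] <- c(a, i)
        a <- i + 1L
      }
    }
    pieces[[length(pieces) + 1L]] <- c(a, r[2L])
  }
  # het split: while over the limit, excise the first het
  final <- list()
  queue <- pieces
  while (length(queue)) {
    q <- queue[[1L]]
    queue <- queue[-1L]
    hets <- which(!is.na(calls[q[1L]:q[2L]]) & calls[q[1L]:q[2L]] == 1L)
    if (length(hets) <= p$max_het) {
      final[[length(final) + 1L]] <- q
    } else {
      h <- q[1L] + hets[1L] - 1L
      if (h > q[1L]) final[[length(final) + 1L]] <- c(q[1L], h - 1L)
      if (h < q[2L]) queue <- c(list(c(h + 1L, q[2L])), queue)
    }
  }
  # re-trim and filter
  out <- list()
  for (q in final) {
    q <- bf_trim(q[1L], q[2L], calls)
    if (is.null(q)) next
    n_snp <- q[2L] - q[1L] + 1L
    length_kb <- (bp[q[2L]] - bp[q[1L]] + 1) / 1000
    if (length_kb / n_snp > p$max_density) next
    if (length_kb < p$min_kb) next
    if (n_snp < p$min_snp) next
    out[[length(out) + 1L]] <- data.frame(
      start_idx = q[1L], end_idx = q[2L], start_bp = bp[q[1L]],
      end_bp = bp[q[2L]], n_snp = n_snp, length_kb = length_kb
    )
  }
  if (!length(out)) {
    return(data.frame(start_idx = integer(), end_idx = integer(),
                      start_bp = numeric(), end_bp = numeric(),
                      n_snp = integer(), length_kb = numeric()))
  }
  do.call(rbind, out)
}

bf_detect_roh <- function(ds, p) {
  rows <- list()
  for (iid in ds$ids) {
    for (ch in unique(ds$map$chrom)) {
      idx <- which(ds$map$chrom == ch)
      segs <- bf_detect_chrom(ds$calls[iid, idx], ds$map$bp[idx], p)
      if (nrow(segs)) {
        segs$iid <- iid
        segs$chrom <- ch
        rows[[length(rows) + 1L]] <- segs
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(iid = character(), chrom = character(),
                      start_bp = numeric(), end_bp = numeric(),
                      n_snp = integer()))
  }
  do.call(rbind, rows)
}

# Exhaustive greedy LD pruning on a whole chromosome (window = all SNPs):
# repeatedly find the first kept pair in map order with r2 above the
# threshold and remove the victim (smaller MAF; tie -> later SNP).
bf_prune_chrom <- function(calls, maf, r2_max) {
  kept <- rep(TRUE, ncol(calls))
  repeat {
    removed <- FALSE
    idx <- which(kept)
    for (ii in seq_along(idx)) {
      for (jj in seq_along(idx)) {
        if (jj <= ii) next
        i <- idx[ii]; j <- idx[jj]
        r2 <- r_squared(calls[, i], calls[, j])
        if (!is.na(r2) && r2 > r2_max + 1e-12) {
          mi <- maf[i]; mj <- maf[j]
          victim <- if (is.na(mi) || is.na(mj) || mi == mj) j
                    else if (mi < mj) i else j
          kept[victim] <- FALSE
          removed <- TRUE
          break
        }
      }
      if (removed) break
    }
    if (!removed) return(kept)
  }
}

# Random small ROH detection instance for oracle-equivalence checks.
random_instance <- function() {
  n_chrom <- sample(1:3, 1L)
  n_snp <- sample(30:200, n_chrom, replace = TRUE)
  maps <- lapply(seq_len(n_chrom), function(ch) {
    data.frame(
      chrom = as.character(ch),
      snp_id = sprintf("c%d_s%d", ch, seq_len(n_snp[ch])),
      cm = 0,
      bp = cumsum(sample(c(1000, 20000, 50000, 80000, 1.5e6),
                         n_snp[ch], replace = TRUE,
                         prob = c(0.05, 0.3, 0.4, 0.2, 0.05)))
    )
  })
  map <- do.call(rbind, maps)
  class(map) <- c("snp_map", "data.frame")
  n_ind <- sample(1:3, 1L)
  calls <- matrix(
    sample(c(0L, 1L, 2L, NA), n_ind * nrow(map), replace = TRUE,
           prob = c(0.45, 0.12, 0.4, 0.03)),
    nrow = n_ind
  )
  # embed long homozygous stretches so segments actually form
  for (i in seq_len(n_ind)) {
    for (k in seq_len(sample(1:3, 1L))) {
      len <- min(sample(15:60, 1L), nrow(map) - 1L)
      start <- sample(seq_len(nrow(map) - len), 1L)
      calls[i, start:(start + len - 1L)] <-
        sample(c(0L, 2L), len, replace = TRUE)
    }
  }
  p <- roh_params(
    window_snp = sample(3:25, 1L),
    window_het = sample(0:1, 1L),
    window_missing = sample(0:2, 1L),
    window_threshold = sample(c(0.02, 0.05, 0.1, 0.25, 0.5, 1), 1L),
    min_snp = sample(2:15, 1L),
    min_kb = sample(c(100, 500, 1000), 1L),
    max_density = sample(c(30, 60, 120, 500), 1L),
    max_gap_kb = sample(c(100, 1000, 5000), 1L),
    max_het = sample(c(0, 1, Inf), 1L)
  )
  ds <- genotype_dataset(map, sprintf("i%d", seq_len(n_ind)), calls)
  list(ds = ds, p = p)
}
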