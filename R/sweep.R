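#' Baseline ROH detection settings for parameter evaluation
#'
#' The fixed settings held while one parameter is varied: a small
#' scanning window (20 SNPs), a large gap (2 Mb = 2000 kb), a high
#' density level (200 kb/SNP), a window threshold of 0.05, a minimal ROH
#' length of 1 Mb, at most one missing and no heterozygous calls in the
#' scanning window, and no heterozygous calls in the final ROH. The
#' minimal number of SNPs per ROH is supplied by the caller, typically
#' from [lencz_min_snp()] evaluated on the dataset at hand.
#'
#' @param min_snp minimal SNPs per ROH (e.g. from [lencz_min_snp()]).
#'
#' @return A [roh_params] object.
#' @export
baseline_params <- function(min_snp) {
  roh_params(
    window_snp = 20L, window_het = 0L, window_missing = 1L,
    window_threshold = 0.05, min_snp = min_snp, min_kb = 1000,
    max_density = 200, max_gap_kb = 2000, max_het = 0L
  )
}

#' Minimal SNPs per ROH for a dataset
#'
#' Convenience wrapper: evaluates [lencz_min_snp()] with `n_s` and `het`
#' (mean heterozygosity over non-missing calls, averaged across SNPs)
#' taken from the dataset.
#'
#' @param ds a [genotype_dataset].
#' @param alpha tolerated expected false-positive ROH count.
#'
#' @return Integer minimum SNP count.
#' @export
min_snp_for <- function(ds, alpha = 0.05) {
  het <- mean(colMeans(ds$calls == 1L, na.rm = TRUE), na.rm = TRUE)
  lencz_min_snp(n_s = n_snps(ds), n_i = n_individuals(ds),
                alpha = alpha, het = het)
}

sweepable_params <- c("maf", "ld_r2", "max_density", "max_gap_kb",
                      "window_snp", "window_threshold")

#' Single-parameter sensitivity sweep
#'
#' Reproduces the one-factor-at-a-time evaluation design: one setting is
#' varied over `values` while the rest stay at `base`; per value the
#' pipeline (optional pruning, ROH detection, genome coverage, F_ROH for
#' every individual) is re-run and population means tabulated. Coverage
#' is recomputed per value so `mean_f_roh_cov` always uses the matching
#' covered length. For the pruning arms (`maf`, `ld_r2`) pruning is
#' applied to a fresh copy of the dataset per value and the detection
#' settings stay at `base`, except that `min_snp` is recomputed from the
#' pruned dataset via [min_snp_for()] when `recompute_min_snp` is `TRUE`
#' (the SNP count `n_s` entering the Lencz formula changes with pruning);
#' an `ld_r2` value of 1 means no LD pruning. Means over individuals are
#' unweighted.
#'
#' @param ds a [genotype_dataset] (quality controlled, unpruned).
#' @param base a [roh_params] object, e.g. [baseline_params()].
#' @param parameter_name one of `"maf"`, `"ld_r2"`, `"max_density"`,
#'   `"max_gap_kb"`, `"window_snp"`, `"window_threshold"`.
#' @param values ordered vector of parameter values to evaluate.
#' @param recompute_min_snp recompute `min_snp` on each pruned dataset
#'   (pruning arms only); default `TRUE`, flagged in the output column
#'   `min_snp_used`.
#'
#' @return A data frame of class `roh_sweep`, one row per value, with
#'   columns `parameter`, `value`, `n_snp_used`, `min_snp_used`,
#'   `coverage_pct`, `mean_f_roh_aut`, `mean_f_roh_cov`, `n_segments`.
#' @export
roh_sweep <- function(ds, base, parameter_name, values,
                      recompute_min_snp = TRUE) {
  stopifnot(inherits(ds, "genotype_dataset"), inherits(base, "roh_params"))
  parameter_name <- match.arg(parameter_name, sweepable_params)
  if (!length(values)) stop("values must be non-empty", call. = FALSE)
  rows <- lapply(values, function(v) {
    ds_v <- ds
    p_v <- base
    if (parameter_name == "maf") {
      ds_v <- maf_filter(ds, v)
    } else if (parameter_name == "ld_r2") {
      if (v < 1) {  # r2 = 1 means no LD pruning
        ds_v <- indep_pairwise(ds, prune_params(r2_max = v))
      }
    } else {
      args <- unclass(p_v)
      args[[parameter_name]] <- v
      p_v <- tryCatch(do.call(roh_params, args),
                      error = function(e) stop("invalid value ", v, " for ",
                                               parameter_name, ": ",
                                               conditionMessage(e),
                                               call. = FALSE))
    }
    if (parameter_name %in% c("maf", "ld_r2") && recompute_min_snp) {
      args <- unclass(p_v)
      args$min_snp <- min_snp_for(ds_v)
      p_v <- do.call(roh_params, args)
    }
    segs <- detect_roh(ds_v, p_v)
    cov <- covered_length(ds_v$map, p_v)
    fr <- f_roh(segs, cov$l_aut_kb, cov$covered_kb, ids = ds_v$ids)
    data.frame(
      parameter = parameter_name, value = v,
      n_snp_used = n_snps(ds_v), min_snp_used = p_v$min_snp,
      coverage_pct = cov$coverage_pct,
      mean_f_roh_aut = mean(fr$f_roh_aut),
      mean_f_roh_cov = mean(fr$f_roh_cov),
      n_segments = nrow(segs),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  class(out) <- c("roh_sweep", "data.frame")
  out
}

#' Plot a sweep result
#'
#' Base-graphics hook: genome coverage (left axis) and the two mean F_ROH
#' estimators (right axis) against the swept parameter value.
#'
#' @param x a `roh_sweep` data frame.
#' @param ... passed to [plot()].
#' @return Invisibly, `x`.
#' @export
plot.roh_sweep <- function(x, ...) {
  op <- graphics::par(mar = c(5, 4, 2, 4))
  on.exit(graphics::par(op))
  plot(x$value, x$coverage_pct, type = "b", pch = 16,
       xlab = x$parameter[1L], ylab = "genome coverage (%)",
       ylim = c(0, 100), ...)
  graphics::par(new = TRUE)
  ymax <- max(x$mean_f_roh_cov, x$mean_f_roh_aut, 0.01, na.rm = TRUE)
  plot(x$value, x$mean_f_roh_cov, type = "b", pch = 1, lty = 2,
       axes = FALSE, xlab = "", ylab = "", ylim = c(0, ymax))
  graphics::points(x$value, x$mean_f_roh_aut, type = "b", pch = 2, lty = 3)
  graphics::axis(4)
  graphics::mtext("mean F_ROH", side = 4, line = 2.5)
  graphics::legend("topright", bty = "n", pch = c(16, 1, 2),
                   legend = c("coverage", "F_ROH,cov", "F_ROH,aut"))
  invisible(x)
}

#' Write a sweep result as a tab-delimited table
#'
#' @param sweep a `roh_sweep` data frame.
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_sweep <- function(sweep, path) {
  utils::write.table(sweep, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
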