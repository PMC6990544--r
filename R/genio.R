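#' SNP map objects
#'
#' A `snp_map` is a data frame with one row per SNP and columns `chrom`
#' (chromosome label, character), `snp_id` (unique SNP identifier), `cm`
#' (genetic-map position, parsed from PLINK `.map` files but ignored by all
#' downstream computations) and `bp` (1-based physical position in base
#' pairs). Within each chromosome, `bp` must be strictly increasing in row
#' order; `snp_id` values must be unique.
#'
#' @param chrom character or integer vector of chromosome labels.
#' @param snp_id character vector of SNP identifiers.
#' @param bp integer vector of 1-based base-pair positions.
#' @param cm numeric vector of genetic-map positions (default 0).
#'
#' @return A data frame of class `snp_map`.
#' @export
snp_map <- function(chrom, snp_id, bp, cm = 0) {
  map <- data.frame(
    chrom = as.character(chrom),
    snp_id = as.character(snp_id),
    cm = as.numeric(cm),
    bp = as.numeric(bp),
    stringsAsFactors = FALSE
  )
  validate_snp_map(map)
  class(map) <- c("snp_map", "data.frame")
  map
}

validate_snp_map <- function(map) {
  if (nrow(map) == 0L) {
    stop("SNP map contains no SNPs", call. = FALSE)
  }
  if (anyDuplicated(map$snp_id)) {
    dup <- map$snp_id[duplicated(map$snp_id)][1L]
    stop("duplicate SNP id in map: ", dup, call. = FALSE)
  }
  if (any(!is.finite(map$bp)) || any(map$bp < 1)) {
    stop("bp positions must be positive integers (1-based)", call. = FALSE)
  }
  for (ch in unique(map$chrom)) {
    bp <- map$bp[map$chrom == ch]
    if (any(diff(bp) <= 0)) {
      stop("bp positions not strictly increasing on chromosome ", ch,
           call. = FALSE)
    }
  }
  invisible(map)
}

#' Read a PLINK text .map file
#'
#' Parses the 4-column whitespace-delimited PLINK `.map` format
#' (chromosome, SNP id, genetic position in cM, physical position in bp).
#' File order is preserved; the genetic-map column is parsed but ignored by
#' all downstream computations. SNPs on unassigned chromosomes (e.g. label
#' `"0"`) are retained at read time and removed only by
#' [drop_unassigned()].
#'
#' @param path path to a `.map` file.
#'
#' @return A [snp_map] data frame.
#' @export
#'
#' @examples
#' f <- tempfile(fileext = ".map")
#' writeLines(c("1 snp1 0 1000", "1 snp2 0 2000", "1 snp3 0 3000"), f)
#' read_map(f)
read_map <- function(path) {
  if (!file.exists(path)) stop("map file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(trimws(lines), "[ \t]+")
  n_fld <- lengths(fields)
  bad <- which(n_fld != 4L)
  if (length(bad)) {
    stop("malformed .map line ", bad[1L], ": expected 4 columns, found ",
         n_fld[bad[1L]], call. = FALSE)
  }
  m <- do.call(rbind, fields)
  cm <- suppressWarnings(as.numeric(m[, 3L]))
  bp <- suppressWarnings(as.numeric(m[, 4L]))
  if (anyNA(cm) || anyNA(bp)) {
    bad <- which(is.na(cm) | is.na(bp))[1L]
    stop("malformed .map line ", bad, ": non-numeric position", call. = FALSE)
  }
  snp_map(chrom = m[, 1L], snp_id = m[, 2L], bp = bp, cm = cm)
}

#' Genotype dataset objects
#'
#' A `genotype_dataset` bundles a [snp_map], individual identifiers and a
#' genotype-call matrix. Calls are coded per SNP as `0` (homozygous for the
#' A allele), `1` (heterozygous), `2` (homozygous for the B allele) and
#' `NA` (missing). The A/B labels are assigned per SNP by first observation
#' in the source file (see [read_ped()]); all downstream statistics (ROH
#' detection, MAF, r-squared) are invariant to which allele is labelled A.
#'
#' @param map a [snp_map].
#' @param ids character vector of unique individual identifiers.
#' @param calls integer matrix, individuals in rows, SNPs in columns,
#'   values in `{0, 1, 2, NA}`.
#' @param alleles optional character matrix (SNPs x 2) of A/B allele
#'   letters used when writing `.ped` files; defaults to `"A"`/`"B"`.
#'
#' @return A list of class `genotype_dataset` with elements `map`, `ids`,
#'   `calls`, `alleles`.
#' @export
genotype_dataset <- function(map, ids, calls, alleles = NULL) {
  validate_snp_map(map)
  if (!inherits(map, "snp_map")) class(map) <- c("snp_map", "data.frame")
  ids <- as.character(ids)
  if (anyDuplicated(ids)) stop("individual ids must be unique", call. = FALSE)
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (ncol(calls) != nrow(map)) {
    stop("calls has ", ncol(calls), " SNP columns but map has ", nrow(map),
         " SNPs", call. = FALSE)
  }
  if (nrow(calls) != length(ids)) {
    stop("calls has ", nrow(calls), " rows but ", length(ids),
         " individual ids given", call. = FALSE)
  }
  if (!all(calls %in% c(0L, 1L, 2L, NA))) {
    stop("calls must be coded 0/1/2/NA", call. = FALSE)
  }
  if (is.null(alleles)) {
    alleles <- matrix(rep(c("A", "B"), each = nrow(map)), ncol = 2L)
  }
  dimnames(calls) <- list(ids, map$snp_id)
  structure(
    list(map = map, ids = ids, calls = calls, alleles = alleles),
    class = "genotype_dataset"
  )
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat("genotype_dataset:", length(x$ids), "individuals x", nrow(x$map),
      "SNPs on", length(unique(x$map$chrom)), "chromosome(s)\n")
  invisible(x)
}

#' Number of SNPs / individuals in a dataset
#'
#' @param ds a [genotype_dataset].
#' @return An integer count.
#' @export
n_snps <- function(ds) nrow(ds$map)

#' @rdname n_snps
#' @export
n_individuals <- function(ds) length(ds$ids)

# Restrict a dataset to a subset of SNP columns, keeping map/calls aligned.
subset_snps <- function(ds, keep) {
  if (is.logical(keep)) keep <- which(keep)
  if (length(keep) == 0L) {
    stop("filter removed every SNP; empty dataset", call. = FALSE)
  }
  map <- ds$map[keep, , drop = FALSE]
  rownames(map) <- NULL
  class(map) <- c("snp_map", "data.frame")
  structure(
    list(
      map = map,
      ids = ds$ids,
      calls = ds$calls[, keep, drop = FALSE],
      alleles = ds$alleles[keep, , drop = FALSE]
    ),
    class = "genotype_dataset"
  )
}

#' Read a PLINK text .ped file
#'
#' Parses the PLINK `.ped` format: 6 identifier columns (family,
#' individual, father, mother, sex, phenotype) followed by two allele
#' columns per SNP. The allele pair `0 0` denotes a missing call. Per SNP,
#' the first allele letter observed while scanning the file is labelled A
#' and the second B (deterministic single-pass rule); more than two
#' distinct non-missing alleles at a SNP is an error. Only the individual
#' id (column 2) is retained.
#'
#' @param path path to a `.ped` file.
#' @param map the [snp_map] read from the matching `.map` file.
#'
#' @return A [genotype_dataset].
#' @export
read_ped <- function(path, map) {
  if (!file.exists(path)) stop("ped file not found: ", path, call. = FALSE)
  validate_snp_map(map)
  n_snp <- nrow(map)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("ped file is empty: ", path, call. = FALSE)
  fields <- strsplit(trimws(lines), "[ \t]+")
  n_fld <- lengths(fields)
  expected <- 6L + 2L * n_snp
  bad <- which(n_fld != expected)
  if (length(bad)) {
    stop("ped line ", bad[1L], " has ", n_fld[bad[1L]],
         " fields; expected ", expected, " for ", n_snp, " map SNPs",
         call. = FALSE)
  }
  ids <- vapply(fields, `[[`, character(1L), 2L)
  n_ind <- length(ids)
  # allele matrices: a1/a2 are individuals x SNPs
  geno <- do.call(rbind, lapply(fields, function(f) f[-(1:6)]))
  a1 <- geno[, seq(1L, 2L * n_snp, by = 2L), drop = FALSE]
  a2 <- geno[, seq(2L, 2L * n_snp, by = 2L), drop = FALSE]
  calls <- matrix(NA_integer_, nrow = n_ind, ncol = n_snp)
  alleles <- matrix(NA_character_, nrow = n_snp, ncol = 2L)
  for (j in seq_len(n_snp)) {
    x1 <- a1[, j]
    x2 <- a2[, j]
    miss <- x1 == "0" | x2 == "0"
    obs <- c(rbind(x1[!miss], x2[!miss]))  # file order within/across lines
    uniq <- unique(obs)
    if (length(uniq) > 2L) {
      stop("SNP ", map$snp_id[j], " has more than 2 alleles: ",
           paste(uniq, collapse = "/"), call. = FALSE)
    }
    alleles[j, seq_along(uniq)] <- uniq
    if (length(uniq)) {
      d1 <- ifelse(x1 == uniq[1L], 0L, 1L)
      d2 <- ifelse(x2 == uniq[1L], 0L, 1L)
      calls[, j] <- d1 + d2
    }
    calls[miss, j] <- NA_integer_
  }
  alleles[is.na(alleles[, 1L]), 1L] <- "A"
  alleles[is.na(alleles[, 2L]), 2L] <- "B"
  genotype_dataset(map, ids, calls, alleles)
}

#' Write a dataset as PLINK text .ped/.map files
#'
#' Writes the companion files `<prefix>.ped` and `<prefix>.map`. Missing
#' calls are written as `0 0`. Heterozygous calls are written with the A
#' allele first, so a subsequent [read_ped()] reproduces the call coding
#' exactly whenever the first non-missing call at each SNP is HOM-A or
#' heterozygous; a SNP whose first non-missing call is HOM-B re-reads with
#' the A/B labels swapped (0 and 2 exchanged), which no downstream
#' statistic can observe.
#'
#' @param ds a [genotype_dataset].
#' @param prefix output path prefix (without extension).
#'
#' @return Invisibly, a character vector with the two paths written.
#' @export
write_ped <- function(ds, prefix) {
  map_path <- paste0(prefix, ".map")
  ped_path <- paste0(prefix, ".ped")
  utils::write.table(
    data.frame(ds$map$chrom, ds$map$snp_id, ds$map$cm,
               format(ds$map$bp, scientific = FALSE, trim = TRUE)),
    map_path, quote = FALSE, sep = "\t",
    row.names = FALSE, col.names = FALSE
  )
  n_snp <- nrow(ds$map)
  a <- ds$alleles
  lines <- vapply(seq_along(ds$ids), function(i) {
    g <- ds$calls[i, ]
    x1 <- ifelse(is.na(g), "0", ifelse(g == 2L, a[, 2L], a[, 1L]))
    x2 <- ifelse(is.na(g), "0", ifelse(g == 0L, a[, 1L], a[, 2L]))
    paste(ds$ids[i], ds$ids[i], 0, 0, 0, -9,
          paste(c(rbind(x1, x2)), collapse = " "))
  }, character(1L))
  writeLines(lines, ped_path)
  invisible(c(ped = ped_path, map = map_path))
}

#' Drop SNPs on unassigned chromosomes
#'
#' Quality-control step retaining only SNPs whose chromosome label is in
#' `autosome_labels`; SNPs with unassigned chromosomal information (e.g.
#' chromosome `"0"`) are discarded. Map and call matrix stay aligned.
#'
#' @param ds a [genotype_dataset].
#' @param autosome_labels character vector of chromosome labels to keep.
#'   Defaults to every label in the map except `"0"`.
#'
#' @return The filtered [genotype_dataset]; an error if nothing remains.
#' @export
drop_unassigned <- function(ds, autosome_labels = NULL) {
  if (is.null(autosome_labels)) {
    autosome_labels <- setdiff(unique(ds$map$chrom), "0")
  }
  autosome_labels <- as.character(autosome_labels)
  if (!length(autosome_labels)) {
    stop("autosome_labels must be non-empty", call. = FALSE)
  }
  subset_snps(ds, ds$map$chrom %in% autosome_labels)
}

#' Remove SNPs with a low call rate
#'
#' Removes every SNP whose call rate (non-missing calls divided by number
#' of individuals) is strictly below `min_rate`; the conventional
#' quality-control threshold is 0.95 (SNPs with call rate < 95% removed).
#'
#' @param ds a [genotype_dataset].
#' @param min_rate minimum call rate in (0, 1]; default 0.95.
#'
#' @return The filtered [genotype_dataset].
#' @export
call_rate_filter <- function(ds, min_rate = 0.95) {
  stopifnot(min_rate >= 0, min_rate <= 1)
  rate <- colMeans(!is.na(ds$calls))
  subset_snps(ds, rate >= min_rate)
}
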