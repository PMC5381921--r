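#' Construct a genotype matrix object
#'
#' Container for SNP genotypes on the 0/0.5/1 coding (0 = rare-allele
#' homozygote, 0.5 = heterozygote, 1 = common-allele homozygote), together
#' with the SNP map and individual identifiers. Missing genotypes are `NA`.
#'
#' @param values numeric matrix, individuals in rows, SNPs in columns; every
#'   non-missing entry must be 0, 0.5 or 1.
#' @param snp_map data frame with columns `name`, `chr`, `bp`; one row per
#'   column of `values`, SNPs sorted by position within each chromosome.
#' @param ids character vector of individual identifiers (one per row).
#' @return An object of class `genotype_matrix`: a list with elements
#'   `values`, `snp_map` (with an `index` column of ordinal positions) and
#'   `ids`.
#' @export
genotype_matrix <- function(values, snp_map, ids = rownames(values)) {
  values <- as.matrix(values)
  if (is.null(ids)) ids <- paste0("id", seq_len(nrow(values)))
  snp_map <- as.data.frame(snp_map, stringsAsFactors = FALSE)
  if (!all(c("name", "chr", "bp") %in% names(snp_map)))
    stop("snp_map must have columns 'name', 'chr', 'bp'")
  if (nrow(snp_map) != ncol(values))
    stop("map has ", nrow(snp_map), " SNPs but matrix has ", ncol(values),
         " columns", call. = FALSE)
  if (length(ids) != nrow(values))
    stop("ids length does not match the number of individuals")
  if (anyDuplicated(snp_map$name))
    stop("SNP names must be unique")
  v <- values[!is.na(values)]
  if (length(v) && !all(v %in% c(0, 0.5, 1)))
    stop("unknown genotype code: values must be in {0, 0.5, 1, NA}")
  # within-chromosome position order is required; chromosome blocks keep
  # their order of appearance
  for (ch in unique(snp_map$chr)) {
    bp <- snp_map$bp[snp_map$chr == ch]
    if (is.unsorted(bp, strictly = FALSE))
      stop("SNPs on chromosome ", ch, " are not sorted by bp position")
  }
  snp_map$index <- seq_len(nrow(snp_map))
  dimnames(values) <- list(ids, snp_map$name)
  structure(list(values = values, snp_map = snp_map, ids = as.character(ids)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$values), "individuals x", ncol(x$values),
      "SNPs on", length(unique(x$snp_map$chr)), "chromosome(s)\n")
  miss <- mean(is.na(x$values))
  cat(sprintf("  missing: %.2f%%\n", 100 * miss))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$values)

#' Orient genotypes so that 1 codes the common-allele homozygote
#'
#' Flips each SNP (g -> 1 - g) whenever the sample frequency of the allele
#' coded 1 falls below 0.5, so that after orientation the genotype mean is
#' the major-allele frequency. Exact ties (frequency 0.5) are left as read,
#' i.e. broken toward the allele listed first in the map file.
#'
#' @param geno a `genotype_matrix`.
#' @return The re-oriented `genotype_matrix`; a logical attribute `flipped`
#'   on the map records which SNPs were flipped.
#' @export
orient_major <- function(geno) {
  p <- colMeans(geno$values, na.rm = TRUE)
  flip <- !is.na(p) & p < 0.5
  if (any(flip)) geno$values[, flip] <- 1 - geno$values[, flip]
  attr(geno$snp_map, "flipped") <- flip
  geno
}

#' Per-SNP major-allele frequency
#'
#' On the 0/0.5/1 coding the genotype mean equals the frequency of the
#' allele coded 1; after [orient_major()] this is the major allele, so the
#' result lies in \[0.5, 1\].
#'
#' @param geno a `genotype_matrix`.
#' @return named numeric vector of per-SNP allele frequencies.
#' @export
allele_freqs <- function(geno) {
  nobs <- colSums(!is.na(geno$values))
  if (any(nobs == 0))
    stop("SNP(s) with all genotypes missing: ",
         paste(utils::head(geno$snp_map$name[nobs == 0], 3), collapse = ", "),
         "; filter with qc_filter() first", call. = FALSE)
  colMeans(geno$values, na.rm = TRUE)
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Exact conditional test: given the allele counts, the heterozygote count
#' follows a known conditional distribution under HWE; the p-value is the
#' total probability of all heterozygote configurations no more probable
#' than the observed one (no mid-p correction).
#'
#' @param n_hom_major,n_het,n_hom_minor genotype counts.
#' @param method `"exact"` (default) or `"chisq"` for the 1-df chi-square
#'   test with expected HWE proportions.
#' @return p-value in (0, 1].
#' @export
hwe_exact_pvalue <- function(n_hom_major, n_het, n_hom_minor,
                             method = c("exact", "chisq")) {
  method <- match.arg(method)
  if (any(c(n_hom_major, n_het, n_hom_minor) < 0))
    stop("genotype counts must be non-negative")
  n <- n_hom_major + n_het + n_hom_minor
  if (n == 0) stop("at least one genotype is required")
  n_a <- 2 * n_hom_minor + n_het      # minor-allele count (symmetry: either)
  n_b <- 2 * n_hom_major + n_het
  if (n_a == 0 || n_b == 0) return(1)  # monomorphic: single table possible
  if (method == "chisq") {
    p <- n_b / (2 * n)
    e <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
    x2 <- sum((c(n_hom_major, n_het, n_hom_minor) - e)^2 / e)
    return(stats::pchisq(x2, df = 1, lower.tail = FALSE))
  }
  rare <- min(n_a, n_b)
  # possible heterozygote counts share the parity of the rare-allele count
  hets <- seq(rare %% 2, rare, by = 2)
  # log conditional probability of each heterozygote count given allele counts
  logp <- lgamma(n + 1) - lgamma((n_a - hets) / 2 + 1) - lgamma(hets + 1) -
    lgamma((n_b - hets) / 2 + 1) + hets * log(2) +
    lgamma(n_a + 1) + lgamma(n_b + 1) - lgamma(2 * n + 1)
  pr <- exp(logp - max(logp))
  pr <- pr / sum(pr)
  obs <- pr[match(n_het, hets)]
  min(1, sum(pr[pr <= obs + 1e-12]))
}

#' Marker quality control
#'
#' Removes a SNP when its minor allele frequency, call rate, or exact HWE
#' p-value falls strictly below the corresponding threshold (a SNP at
#' exactly the threshold is retained). The individual set is unchanged.
#'
#' @param geno a `genotype_matrix` (oriented or not; MAF is side-agnostic).
#' @param maf_min minimum minor allele frequency (default 0.01).
#' @param call_rate_min minimum per-SNP call rate (default 0.95).
#' @param hwe_p_min minimum HWE exact p-value (default 1e-6).
#' @param ind_call_rate_min optional minimum per-individual call rate;
#'   `NULL` (default) applies no per-individual filter.
#' @return list with the filtered `genotype_matrix` (`geno`) and a
#'   `qc_report` (`report`) holding per-SNP statistics, per-criterion
#'   removal counts and the surviving SNP count.
#' @export
qc_filter <- function(geno, maf_min = 0.01, call_rate_min = 0.95,
                      hwe_p_min = 1e-6, ind_call_rate_min = NULL) {
  stopifnot(inherits(geno, "genotype_matrix"))
  thr <- c(maf_min, call_rate_min, hwe_p_min)
  if (any(thr < 0 | thr > 1)) stop("thresholds must lie in [0, 1]")
  v <- geno$values
  nobs <- colSums(!is.na(v))
  call_rate <- nobs / nrow(v)
  p1 <- colMeans(v, na.rm = TRUE)          # frequency of the allele coded 1
  maf <- pmin(p1, 1 - p1)
  maf[nobs == 0] <- 0
  hwe <- vapply(seq_len(ncol(v)), function(k) {
    g <- v[, k]
    g <- g[!is.na(g)]
    if (!length(g)) return(0)
    hwe_exact_pvalue(sum(g == 1), sum(g == 0.5), sum(g == 0))
  }, numeric(1))
  fail_maf <- maf < maf_min
  fail_cr <- call_rate < call_rate_min
  fail_hwe <- hwe < hwe_p_min
  keep <- !(fail_maf | fail_cr | fail_hwe)
  out <- geno
  out$values <- v[, keep, drop = FALSE]
  out$snp_map <- geno$snp_map[keep, , drop = FALSE]
  out$snp_map$index <- seq_len(nrow(out$snp_map))
  if (!is.null(ind_call_rate_min)) {
    icr <- rowMeans(!is.na(out$values))
    ikeep <- icr >= ind_call_rate_min
    out$values <- out$values[ikeep, , drop = FALSE]
    out$ids <- out$ids[ikeep]
  }
  report <- structure(list(
    snp_stats = data.frame(name = geno$snp_map$name, chr = geno$snp_map$chr,
                           maf = maf, call_rate = call_rate, hwe_p = hwe,
                           kept = keep, stringsAsFactors = FALSE),
    n_input = ncol(v),
    n_removed = sum(!keep),
    n_surviving = sum(keep),
    removed_by = c(maf = sum(fail_maf), call_rate = sum(fail_cr),
                   hwe = sum(fail_hwe)),
    thresholds = c(maf_min = maf_min, call_rate_min = call_rate_min,
                   hwe_p_min = hwe_p_min)
  ), class = "qc_report")
  list(geno = out, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("SNP quality control:", x$n_input, "in,", x$n_surviving, "kept,",
      x$n_removed, "removed\n")
  cat(sprintf("  failing MAF < %g: %d\n", x$thresholds["maf_min"],
              x$removed_by["maf"]))
  cat(sprintf("  failing call rate < %g: %d\n", x$thresholds["call_rate_min"],
              x$removed_by["call_rate"]))
  cat(sprintf("  failing HWE p < %g: %d\n", x$thresholds["hwe_p_min"],
              x$removed_by["hwe"]))
  invisible(x)
}

#' Read genotypes from TSV or PLINK binary files
#'
#' Two dialects are supported. `format = "tsv"` expects `<path>.geno.tsv`
#' (header `id` then one column per SNP; codes 0, 0.5, 1, NA) and
#' `<path>.snps.tsv` (columns `name`, `chr`, `bp`). `format = "plink-bed"`
#' expects the `<path>.bed/.bim/.fam` trio (SNP-major bed). In both cases
#' genotypes are re-oriented so that 1 codes the common-allele homozygote.
#'
#' @param path file prefix (without extension).
#' @param format `"tsv"` or `"plink-bed"`.
#' @return an oriented `genotype_matrix`.
#' @export
read_genotypes <- function(path, format = c("tsv", "plink-bed")) {
  format <- match.arg(format)
  geno <- if (format == "tsv") read_genotypes_tsv(path) else read_plink(path)
  orient_major(geno)
}

read_genotypes_tsv <- function(prefix) {
  gfile <- paste0(prefix, ".geno.tsv")
  mfile <- paste0(prefix, ".snps.tsv")
  if (!file.exists(gfile) || !file.exists(mfile))
    stop("expected ", gfile, " and ", mfile)
  g <- utils::read.delim(gfile, check.names = FALSE, stringsAsFactors = FALSE)
  map <- utils::read.delim(mfile, stringsAsFactors = FALSE)
  ids <- as.character(g[[1]])
  values <- as.matrix(g[, -1, drop = FALSE])
  storage.mode(values) <- "double"
  bad <- values[!is.na(values)]
  if (length(bad) && !all(bad %in% c(0, 0.5, 1)))
    stop("unknown genotype code in ", gfile)
  genotype_matrix(values, map, ids)
}

#' Read a PLINK .bed/.bim/.fam trio
#'
#' Minimal SNP-major bed reader. The two-bit codes are translated to
#' A1-allele dosage and rescaled to the 0/0.5/1 coding (before orientation,
#' 1 means homozygous for A1, the allele listed first in the .bim file).
#'
#' @param prefix path prefix of the `.bed/.bim/.fam` files.
#' @return a `genotype_matrix` (not yet oriented).
#' @export
read_plink <- function(prefix) {
  bed <- paste0(prefix, ".bed")
  bim <- paste0(prefix, ".bim")
  fam <- paste0(prefix, ".fam")
  for (f in c(bed, bim, fam)) if (!file.exists(f)) stop("missing file: ", f)
  bimd <- utils::read.table(bim, stringsAsFactors = FALSE,
                            col.names = c("chr", "name", "cm", "bp", "a1", "a2"))
  famd <- utils::read.table(fam, stringsAsFactors = FALSE)
  n <- nrow(famd)
  m <- nrow(bimd)
  bytes_per_snp <- ceiling(n / 4)
  raw <- readBin(bed, "raw", n = 3 + m * bytes_per_snp)
  if (length(raw) < 3 + m * bytes_per_snp)
    stop("bed file shorter than implied by .bim/.fam dimensions")
  if (!identical(as.integer(raw[1:3]), c(0x6cL, 0x1bL, 0x01L)))
    stop("not a SNP-major PLINK bed file")
  body <- matrix(raw[-(1:3)], nrow = bytes_per_snp, ncol = m)
  # unpack 2-bit codes: 00 hom A1, 10 het, 11 hom A2, 01 missing
  lut <- matrix(NA_real_, 4, 1)
  code_of <- function(bits) c(`0` = 1, `1` = NA_real_, `2` = 0.5, `3` = 0)[bits + 1]
  values <- matrix(NA_real_, n, m)
  ints <- matrix(as.integer(body), nrow = bytes_per_snp, ncol = m)
  for (shift in 0:3) {
    idx <- seq(shift + 1, by = 4, length.out = bytes_per_snp)
    idx <- idx[idx <= n]
    if (!length(idx)) next
    two <- (ints %/% 4L^shift) %% 4L
    values[idx, ] <- code_of(as.vector(two[seq_along(idx), , drop = FALSE]))
  }
  # values currently: 1 = hom A1, 0 = hom A2, 0.5 = het
  genotype_matrix(values, bimd[, c("name", "chr", "bp")], as.character(famd[[2]]))
}

#' Write a genotype matrix as a PLINK .bed/.bim/.fam trio
#'
#' The allele coded 1 is written as A1 (labelled "A"), the other as A2
#' ("B"); g = 1 becomes homozygous A1.
#'
#' @param geno a `genotype_matrix`.
#' @param prefix output path prefix.
#' @return the prefix, invisibly.
#' @export
write_plink <- function(geno, prefix) {
  map <- geno$snp_map
  utils::write.table(
    data.frame(map$chr, map$name, 0, map$bp, "A", "B"),
    paste0(prefix, ".bim"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  utils::write.table(
    data.frame(geno$ids, geno$ids, 0, 0, 0, -9),
    paste0(prefix, ".fam"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  n <- nrow(geno$values)
  bytes_per_snp <- ceiling(n / 4)
  # inverse of the reader's code map
  enc <- function(g) {
    out <- rep(1L, length(g))            # 01 missing
    out[!is.na(g) & g == 1] <- 0L        # hom A1
    out[!is.na(g) & g == 0.5] <- 2L      # het
    out[!is.na(g) & g == 0] <- 3L        # hom A2
    out
  }
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  pad <- 4 * bytes_per_snp - n
  for (k in seq_len(ncol(geno$values))) {
    codes <- c(enc(geno$values[, k]), rep(0L, pad))
    byte4 <- matrix(codes, nrow = 4)
    writeBin(as.raw(byte4[1, ] + 4L * byte4[2, ] + 16L * byte4[3, ] +
                      64L * byte4[4, ]), con)
  }
  invisible(prefix)
}

#' Write a genotype matrix as the TSV pair
#'
#' @param geno a `genotype_matrix`.
#' @param prefix output path prefix; writes `<prefix>.geno.tsv` and
#'   `<prefix>.snps.tsv`.
#' @return the prefix, invisibly.
#' @export
write_genotypes_tsv <- function(geno, prefix) {
  g <- data.frame(id = geno$ids, geno$values, check.names = FALSE,
                  stringsAsFactors = FALSE)
  utils::write.table(g, paste0(prefix, ".geno.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(geno$snp_map[, c("name", "chr", "bp")],
                     paste0(prefix, ".snps.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(prefix)
}

#' Read a phenotype table
#'
#' @param path TSV file with an `id` column and one numeric column per trait.
#' @return data frame with character `id` and numeric trait columns.
#' @export
read_phenotypes <- function(path) {
  ph <- utils::read.delim(path, stringsAsFactors = FALSE)
  ph[[1]] <- as.character(ph[[1]])
  names(ph)[1] <- "id"
  ph
}
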