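#' Per-chromosome SNP counts of the post-QC 50K bovine panel
#'
#' The 29 autosomal SNP counts (40,646 markers in total) of the Illumina
#' Bovine 50K array after the default marker QC, as used for the full-scale
#' window arithmetic; the synthetic generator's "cattle-small" default map
#' is a proportional scale-down of these counts.
#'
#' @return named integer vector of length 29 ("BTA1" ... "BTA29").
#' @export
bta_snp_counts <- function() {
  stats::setNames(
    c(2630L, 2126L, 1999L, 1967L, 1714L, 2002L, 1749L, 1860L, 1621L, 1699L,
      1762L, 1344L, 1391L, 1418L, 1342L, 1278L, 1262L, 1060L, 1086L, 1268L,
      1113L, 1013L, 868L, 1003L, 796L, 873L, 786L, 771L, 845L),
    paste0("BTA", 1:29))
}

#' IBS genomic kinship between two individuals
#'
#' f = (1/n) * sum_k (g_ik - p_k)(g_jk - p_k) / (p_k (1 - p_k)) over the
#' SNPs non-missing in both individuals, with g on the 0/0.5/1 coding and
#' p the major-allele frequency. Relationship-matrix entries are 2f.
#'
#' @param g_i,g_j genotype vectors over \{0, 0.5, 1, NA\}.
#' @param p per-SNP allele frequencies, strictly inside (0, 1).
#' @return the kinship coefficient f (a scalar).
#' @export
kinship_pair <- function(g_i, g_j, p) {
  stopifnot(length(g_i) == length(g_j), length(p) == length(g_i))
  use <- !is.na(g_i) & !is.na(g_j) & p > 0 & p < 1
  n <- sum(use)
  if (n == 0) stop("no usable SNPs (all missing or monomorphic)")
  sum((g_i[use] - p[use]) * (g_j[use] - p[use]) / (p[use] * (1 - p[use]))) / n
}

#' Build a genomic relationship matrix
#'
#' Off-diagonal entries are 2 f_ij and diagonal entries 2 f_ii from the IBS
#' kinship on the 0/0.5/1 coding; under this coding Var(g) = p(1-p)/2, so
#' E\[2 f_ii\] = 1 + F, matching the usual "1 plus inbreeding" diagonal.
#' Missing genotypes are imputed with the SNP's allele frequency before the
#' cross-product. Allele frequencies are always the whole-sample
#' frequencies of `geno` (never per-window re-estimates). Monomorphic SNPs
#' are dropped from the divisor.
#'
#' @param geno a `genotype_matrix` (oriented).
#' @param snp_subset optional integer vector of ordinal SNP indices (e.g. a
#'   window); default all SNPs.
#' @param kind label, `"whole"` or `"regional"`.
#' @param ridge value added to the diagonal to guard against singularity in
#'   downstream REML (default 1e-6).
#' @return an n x n matrix of class `kinship_matrix` with attributes
#'   `n_snps` (SNPs actually used), `snp_indices`, `kind`, and `loadings`
#'   (the scaled n x m' matrix L with K = L L' + ridge*I, used by the
#'   low-rank REML path and by variance partitioning).
#' @export
build_grm <- function(geno, snp_subset = NULL, kind = "whole", ridge = 1e-6) {
  stopifnot(inherits(geno, "genotype_matrix"))
  if (is.null(snp_subset)) snp_subset <- seq_len(ncol(geno$values))
  if (!length(snp_subset)) stop("empty SNP subset")
  p_all <- colMeans(geno$values, na.rm = TRUE)
  p <- p_all[snp_subset]
  poly <- p > 0 & p < 1 & !is.na(p)
  if (!any(poly)) stop("no polymorphic SNPs in subset; cannot build GRM")
  idx <- snp_subset[poly]
  p <- p[poly]
  g <- geno$values[, idx, drop = FALSE]
  for (k in seq_along(idx)) {              # mean-impute with p_k
    mk <- is.na(g[, k])
    if (any(mk)) g[mk, k] <- p[k]
  }
  z <- sweep(sweep(g, 2, p, "-"), 2, sqrt(p * (1 - p)), "/")
  m <- length(idx)
  L <- z * sqrt(2 / m)
  K <- tcrossprod(L)
  K <- (K + t(K)) / 2
  if (ridge > 0) K <- K + diag(ridge, nrow(K))
  dimnames(K) <- list(geno$ids, geno$ids)
  structure(K, n_snps = m, snp_indices = idx, kind = kind, ridge = ridge,
            loadings = L, class = c("kinship_matrix", "matrix", "array"))
}

#' @export
print.kinship_matrix <- function(x, ...) {
  cat(sprintf("kinship_matrix (%s): %d x %d from %d SNPs; mean diag %.3f\n",
              attr(x, "kind"), nrow(x), ncol(x), attr(x, "n_snps"),
              mean(diag(x))))
  invisible(x)
}

#' Sliding-window scheme with 50 percent overlap
#'
#' Windows of `size` consecutive SNPs start at ordinals 1, 1+shift,
#' 1+2*shift, ... on each chromosome while a full window fits; when the
#' last full window on that grid does not end at the chromosome's final
#' SNP, one extra end-anchored window covering the last `size` SNPs is
#' appended. A chromosome with fewer than `size` SNPs contributes a single
#' window of all its SNPs. Windows never span chromosomes.
#'
#' @param snp_map either the `snp_map` of a `genotype_matrix` or a named
#'   vector of per-chromosome SNP counts.
#' @param size window size in SNPs (>= 2).
#' @param shift step between window starts; default `size / 2`.
#' @return data frame of class `window_table`: `window`, `chr`, `first`,
#'   `last` (global ordinal indices, inclusive), `size`, and, when a full
#'   map is given, first/last SNP names and bp.
#' @export
make_windows <- function(snp_map, size, shift = size / 2) {
  stopifnot(size >= 2, shift >= 1)
  shift <- as.integer(shift)
  size <- as.integer(size)
  if (is.data.frame(snp_map)) {
    chrs <- unique(snp_map$chr)
    counts <- stats::setNames(
      vapply(chrs, function(ch) sum(snp_map$chr == ch), integer(1)), chrs)
  } else {
    counts <- snp_map
    if (is.null(names(counts))) names(counts) <- paste0("chr", seq_along(counts))
    snp_map <- NULL
  }
  if (any(counts <= 0)) stop("non-positive chromosome SNP count")
  offset <- c(0L, cumsum(as.integer(counts)))[seq_along(counts)]
  rows <- lapply(seq_along(counts), function(ci) {
    m <- as.integer(counts[ci])
    if (m < size) {
      starts <- 1L
      ends <- m
    } else {
      starts <- seq.int(1L, m - size + 1L, by = shift)
      ends <- starts + size - 1L
      if (ends[length(ends)] < m) {       # end-anchored closing window
        starts <- c(starts, m - size + 1L)
        ends <- c(ends, m)
      }
    }
    data.frame(chr = names(counts)[ci], first = starts + offset[ci],
               last = ends + offset[ci], size = ends - starts + 1L,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- data.frame(window = seq_len(nrow(out)), out,
                    stringsAsFactors = FALSE)
  if (!is.null(snp_map)) {
    out$first_snp <- snp_map$name[out$first]
    out$last_snp <- snp_map$name[out$last]
    out$first_bp <- snp_map$bp[out$first]
    out$last_bp <- snp_map$bp[out$last]
  }
  class(out) <- c("window_table", "data.frame")
  out
}

#' Write a GRM in the GCTA text convention
#'
#' Lower-triangle id-pair rows: index i, index j (j <= i), SNP count, value;
#' ids in a companion `.grm.id` file.
#'
#' @param K a `kinship_matrix`.
#' @param prefix output prefix; writes `<prefix>.grm.gz`-style plain
#'   `<prefix>.grm.txt` and `<prefix>.grm.id`.
#' @return the prefix, invisibly.
#' @export
write_grm <- function(K, prefix) {
  n <- nrow(K)
  ij <- which(lower.tri(K, diag = TRUE), arr.ind = TRUE)
  ij <- ij[order(ij[, 1], ij[, 2]), , drop = FALSE]
  df <- data.frame(i = ij[, 1], j = ij[, 2],
                   n_snps = attr(K, "n_snps"), value = K[ij])
  utils::write.table(df, paste0(prefix, ".grm.txt"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(data.frame(rownames(K), rownames(K)),
                     paste0(prefix, ".grm.id"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' Read a GRM written by [write_grm()]
#'
#' @param prefix path prefix of the `.grm.txt` / `.grm.id` pair.
#' @return a `kinship_matrix` (without loadings).
#' @export
read_grm <- function(prefix) {
  df <- utils::read.table(paste0(prefix, ".grm.txt"))
  ids <- utils::read.table(paste0(prefix, ".grm.id"),
                           stringsAsFactors = FALSE)[[2]]
  n <- max(df[[1]])
  K <- matrix(0, n, n, dimnames = list(ids, ids))
  K[cbind(df[[1]], df[[2]])] <- df[[4]]
  K[cbind(df[[2]], df[[1]])] <- df[[4]]
  structure(K, n_snps = df[[3]][1], kind = "whole", ridge = 0,
            class = c("kinship_matrix", "matrix", "array"))
}
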