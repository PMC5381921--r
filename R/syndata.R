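#' Simulation configuration for synthetic dairy-style datasets
#'
#' Defines the structure the analysis assumes: many chromosomes of
#' linkage-equilibrium SNPs (optionally with first-order LD), a polygenic
#' background shared across traits with a positive between-trait
#' correlation, one small genomic window carrying a pleiotropic regional
#' QTL whose between-trait correlation matrix can encode antagonism
#' (opposite signs), and independent residual noise. The default
#' "cattle-small" configuration scales the 29-autosome 50K panel down
#' proportionally to about 2,000 SNPs and 1,000 individuals, with variance
#' magnitudes mirroring milk (MLK), fat (FAT) and protein (PRT) yield
#' de-regressed proofs.
#'
#' @param n_individuals number of individuals.
#' @param chromosome_snp_counts named integer vector of per-chromosome SNP
#'   counts.
#' @param allele_freq_range minor-allele-frequency range, inside (0, 0.5];
#'   the lower bound defaults to 0.05 (comfortably past the 1 percent QC
#'   cut).
#' @param traits character vector of trait names.
#' @param whole_var per-trait whole-genome (polygenic) variance, trait
#'   units squared.
#' @param resid_var per-trait residual variance.
#' @param polygenic_corr between-trait correlation matrix of the polygenic
#'   SNP effects (symmetric PSD, unit diagonal).
#' @param regional_window `list(chr = , start = , size = )` giving the
#'   chromosome (index or name), first within-chromosome SNP ordinal and
#'   SNP count of the regional QTL window, or `NULL` for a null dataset.
#' @param regional_var per-trait regional variance (all zero also gives a
#'   null dataset).
#' @param regional_corr between-trait correlation matrix of the regional
#'   SNP effects; its sign pattern encodes antagonistic pleiotropy.
#' @param trait_means per-trait phenotype mean.
#' @param missing_rate genotype missingness proportion.
#' @param ld first-order (adjacent-SNP) LD parameter in \[0, 1): the AR(1)
#'   correlation of the latent Gaussian used to draw haplotypes; 0 =
#'   linkage equilibrium (default).
#' @param seed integer RNG seed; every generator call is a pure function
#'   of the configuration.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(n_individuals = 1000,
                       chromosome_snp_counts = cattle_small_counts(),
                       allele_freq_range = c(0.05, 0.5),
                       traits = c("MLK", "FAT", "PRT"),
                       whole_var = c(MLK = 5000, FAT = 490, PRT = 390),
                       resid_var = c(MLK = 5000, FAT = 500, PRT = 400),
                       polygenic_corr = uniform_corr(length(traits), 0.85),
                       regional_window = list(chr = 14, start = 1, size = 20),
                       regional_var = c(MLK = 240, FAT = 43, PRT = 6),
                       regional_corr = antagonistic_corr(),
                       trait_means = rep(0, length(traits)),
                       missing_rate = 0.01, ld = 0, seed = 1) {
  nt <- length(traits)
  stopifnot(n_individuals >= 2, length(chromosome_snp_counts) >= 1)
  if (any(chromosome_snp_counts <= 0))
    stop("chromosome SNP counts must be positive")
  stopifnot(length(allele_freq_range) == 2,
            allele_freq_range[1] > 0, allele_freq_range[2] <= 0.5,
            allele_freq_range[1] <= allele_freq_range[2])
  whole_var <- check_var(whole_var, nt, "whole_var")
  resid_var <- check_var(resid_var, nt, "resid_var")
  regional_var <- check_var(regional_var, nt, "regional_var")
  check_corr(polygenic_corr, nt, "polygenic_corr")
  check_corr(regional_corr, nt, "regional_corr")
  stopifnot(missing_rate >= 0, missing_rate < 1, ld >= 0, ld < 1)
  if (is.null(names(chromosome_snp_counts)))
    names(chromosome_snp_counts) <-
      paste0("chr", seq_along(chromosome_snp_counts))
  structure(list(
    n_individuals = as.integer(n_individuals),
    chromosome_snp_counts = stats::setNames(
      as.integer(chromosome_snp_counts), names(chromosome_snp_counts)),
    allele_freq_range = allele_freq_range, traits = traits,
    whole_var = whole_var, resid_var = resid_var,
    polygenic_corr = polygenic_corr, regional_window = regional_window,
    regional_var = regional_var, regional_corr = regional_corr,
    trait_means = stats::setNames(trait_means, traits),
    missing_rate = missing_rate, ld = ld, seed = seed
  ), class = "sim_config")
}

check_var <- function(v, nt, what) {
  if (length(v) == 1) v <- rep(v, nt)
  if (length(v) != nt) stop(what, " must have one value per trait")
  if (any(v < 0)) stop(what, " must be non-negative")
  v
}

check_corr <- function(R, nt, what) {
  if (!is.matrix(R) || nrow(R) != nt || ncol(R) != nt)
    stop(what, " must be a ", nt, "x", nt, " matrix")
  if (max(abs(R - t(R))) > 1e-10 || max(abs(diag(R) - 1)) > 1e-10)
    stop(what, " must be symmetric with unit diagonal")
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop(what, " is not positive semi-definite (min eigenvalue ",
         signif(min(ev), 3), ")")
  invisible(R)
}

#' Proportionally scaled-down per-chromosome SNP counts
#'
#' The 29 counts of [bta_snp_counts()] scaled to a total of about
#' `total` SNPs, preserving the relative chromosome lengths.
#'
#' @param total approximate total SNP count (default 2000).
#' @return named integer vector of length 29.
#' @export
cattle_small_counts <- function(total = 2000) {
  full <- bta_snp_counts()
  pmax(10L, as.integer(round(full * total / sum(full))))
}

#' Equicorrelation matrix
#' @param k dimension.
#' @param rho common off-diagonal correlation.
#' @return k x k correlation matrix.
#' @export
uniform_corr <- function(k, rho) {
  R <- matrix(rho, k, k)
  diag(R) <- 1
  R
}

#' Default antagonistic regional correlation matrix (3 traits)
#'
#' The middle trait (FAT-like) is strongly negatively correlated with the
#' other two at the regional QTL, while the flanking traits correlate
#' positively — the signature of a pleiotropic locus pushing fat yield
#' against milk and protein yield. Verified positive semi-definite.
#'
#' @return a 3 x 3 correlation matrix.
#' @export
antagonistic_corr <- function() {
  matrix(c(1, -0.94, 0.98,
           -0.94, 1, -0.88,
           0.98, -0.88, 1), 3, 3)
}

# run code under a local RNG stream, restoring the caller's state
with_sim_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  code
}

#' Simulate genotypes under Hardy-Weinberg proportions
#'
#' Draws a per-SNP minor allele frequency uniformly inside the configured
#' range, then genotypes in Hardy-Weinberg proportions, as two independent
#' haplotypes per individual. With `ld > 0` the haplotype alleles follow a
#' Gaussian-copula AR(1) along each chromosome, inducing monotone
#' adjacent-SNP dosage correlation; with `ld = 0` (default) SNPs are in
#' linkage equilibrium. Base-pair positions accumulate random inter-SNP
#' spacings of 20-80 kb (about 50 kb on average, as on a 50K array).
#'
#' @param config a `sim_config`.
#' @return an oriented-by-construction `genotype_matrix` (1 = common-allele
#'   homozygote at the drawn frequency); missing entries are injected at
#'   `missing_rate`, and the pre-masking matrix is kept in the attribute
#'   `complete_values` for exact truth computation.
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_sim_seed(config$seed, {
    n <- config$n_individuals
    counts <- config$chromosome_snp_counts
    blocks <- vector("list", length(counts))
    maps <- vector("list", length(counts))
    for (ci in seq_along(counts)) {
      m <- counts[ci]
      maf <- stats::runif(m, config$allele_freq_range[1],
                          config$allele_freq_range[2])
      if (config$ld == 0) {
        minor <- matrix(stats::rbinom(n * m, 2, rep(maf, each = n)), n, m)
      } else {
        minor <- matrix(0L, n, m)
        for (h in 1:2) {
          z <- matrix(0, n, m)
          z[, 1] <- stats::rnorm(n)
          if (m > 1) for (k in 2:m)
            z[, k] <- config$ld * z[, k - 1] +
              sqrt(1 - config$ld^2) * stats::rnorm(n)
          minor <- minor + (z < rep(stats::qnorm(maf), each = n))
        }
      }
      blocks[[ci]] <- 1 - minor / 2
      bp <- cumsum(round(stats::runif(m, 20000, 80000)))
      maps[[ci]] <- data.frame(
        name = sprintf("%s_snp%04d", names(counts)[ci], seq_len(m)),
        chr = names(counts)[ci], bp = bp, stringsAsFactors = FALSE)
    }
    values <- do.call(cbind, blocks)
    complete <- values
    if (config$missing_rate > 0) {
      mask <- stats::runif(length(values)) < config$missing_rate
      values[mask] <- NA_real_
    }
    geno <- genotype_matrix(values, do.call(rbind, maps),
                            sprintf("ind%04d", seq_len(n)))
    attr(geno, "complete_values") <- complete
    geno
  })
}

# resolve the configured regional window to global SNP indices
resolve_window <- function(geno, window) {
  if (is.null(window)) return(integer(0))
  chrs <- unique(geno$snp_map$chr)
  ch <- if (is.numeric(window$chr)) {
    if (window$chr < 1 || window$chr > length(chrs))
      stop("regional window chromosome out of range")
    chrs[window$chr]
  } else {
    if (!window$chr %in% chrs) stop("regional window chromosome not in map")
    window$chr
  }
  on_chr <- which(geno$snp_map$chr == ch)
  idx <- window$start + seq_len(window$size) - 1
  if (window$start < 1 || max(idx) > length(on_chr))
    stop("regional window exceeds chromosome bounds (", length(on_chr),
         " SNPs on ", ch, ")")
  on_chr[idx]
}

#' Simulate multi-trait phenotypes with a regional QTL
#'
#' Whole-genome effects are built from per-SNP effects over all non-window
#' SNPs, drawn multivariate normal across traits with correlation
#' `polygenic_corr`; regional effects come from the window SNPs with
#' correlation `regional_corr`. Each trait's genetic-value vector is
#' centred and rescaled so its realized sample variance equals the target
#' exactly, removing one source of Monte-Carlo noise from recovery
#' studies; residuals are drawn independently and not rescaled. The
#' phenotype is mean + whole + regional + residual, exactly.
#'
#' @param geno a `genotype_matrix` from [simulate_genotypes()].
#' @param config the matching `sim_config`.
#' @return list with `phenotypes` (data frame: `id` plus one column per
#'   trait) and `truth` (a `truth_record`: matrices `whole`, `regional`,
#'   `resid`; `window_snps` global indices; `realized` per-trait variance
#'   components).
#' @export
simulate_traits <- function(geno, config) {
  stopifnot(inherits(geno, "genotype_matrix"), inherits(config, "sim_config"))
  g <- attr(geno, "complete_values")
  if (is.null(g)) {                     # mean-impute any missingness
    g <- geno$values
    p <- colMeans(g, na.rm = TRUE)
    for (k in seq_len(ncol(g))) {
      mk <- is.na(g[, k])
      if (any(mk)) g[mk, k] <- p[k]
    }
  }
  if (ncol(g) != sum(config$chromosome_snp_counts))
    stop("genotype matrix is inconsistent with the configuration map")
  n <- nrow(g)
  nt <- length(config$traits)
  win <- resolve_window(geno, config$regional_window)
  with_sim_seed(if (is.null(config$seed)) NULL else config$seed + 1L, {
    Zc <- sweep(g, 2, colMeans(g), "-")
    gen_block <- function(snps, target_var, corr) {
      out <- matrix(0, n, nt)
      if (!length(snps) || all(target_var == 0)) return(out)
      B <- matrix(stats::rnorm(length(snps) * nt), length(snps), nt) %*%
        chol_psd(corr)
      raw <- Zc[, snps, drop = FALSE] %*% B
      for (t in seq_len(nt)) {
        v <- raw[, t] - mean(raw[, t])
        sv <- stats::var(v)
        out[, t] <- if (target_var[t] > 0 && sv > 0)
          v * sqrt(target_var[t] / sv) else 0
      }
      out
    }
    non_win <- setdiff(seq_len(ncol(g)), win)
    U <- gen_block(non_win, config$whole_var, config$polygenic_corr)
    W <- gen_block(win, config$regional_var, config$regional_corr)
    E <- sapply(seq_len(nt), function(t)
      stats::rnorm(n, 0, sqrt(config$resid_var[t])))
    E <- matrix(E, n, nt)
    Y <- sweep(U + W + E, 2, config$trait_means, "+")
    colnames(Y) <- colnames(U) <- colnames(W) <- colnames(E) <- config$traits
    phen <- data.frame(id = geno$ids, Y, stringsAsFactors = FALSE)
    truth <- structure(list(
      whole = U, regional = W, resid = E, mu = config$trait_means,
      window_snps = win,
      realized = data.frame(
        trait = config$traits,
        whole_var = apply(U, 2, stats::var),
        regional_var = apply(W, 2, stats::var),
        resid_var = apply(E, 2, stats::var))
    ), class = "truth_record")
    list(phenotypes = phen, truth = truth)
  })
}

# Cholesky factor tolerant of semi-definite correlation matrices
chol_psd <- function(R) {
  ch <- tryCatch(chol(R), error = function(e) NULL)
  if (!is.null(ch)) return(ch)
  e <- eigen(R, symmetric = TRUE)
  ev <- pmax(e$values, 0)
  t(e$vectors %*% diag(sqrt(ev), length(ev)))
}

#' Simulate a complete dataset
#'
#' Convenience wrapper: genotypes plus traits in one call.
#'
#' @param config a `sim_config`.
#' @return list `geno`, `phenotypes`, `truth`.
#' @export
simulate_dataset <- function(config) {
  geno <- simulate_genotypes(config)
  tr <- simulate_traits(geno, config)
  c(list(geno = geno), tr)
}

#' Write a simulated dataset to an output directory
#'
#' Emits the genotype TSV pair, the PLINK-dialect trio, the phenotype TSV
#' (`id` + one column per trait), truth tables, and a run manifest
#' recording the seed and configuration.
#'
#' @param sim result of [simulate_dataset()].
#' @param config the `sim_config` used.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_genotypes_tsv(sim$geno, file.path(dir, "genotypes"))
  write_plink(sim$geno, file.path(dir, "genotypes"))
  utils::write.table(sim$phenotypes, file.path(dir, "phenotypes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  tr <- sim$truth
  utils::write.table(data.frame(id = sim$geno$ids, tr$whole),
                     file.path(dir, "truth_whole_effects.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(id = sim$geno$ids, tr$regional),
                     file.path(dir, "truth_regional_effects.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(tr$realized, file.path(dir, "truth_varcomp.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- c(
    sprintf("seed: %s", config$seed),
    sprintf("n_individuals: %d", config$n_individuals),
    sprintf("n_snps: %d", sum(config$chromosome_snp_counts)),
    sprintf("traits: %s", paste(config$traits, collapse = ",")),
    sprintf("missing_rate: %g", config$missing_rate),
    sprintf("generated: regherit %s",
            as.character(utils::packageVersion("regherit"))))
  writeLines(manifest, file.path(dir, "manifest.txt"))
  invisible(dir)
}
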