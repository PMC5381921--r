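#' GRAMMAR residuals: phenotypes adjusted for whole-genome values
#'
#' First step of the GRAMMAR two-stage association: fit the whole-genome
#' mixed model y = 1 mu + Zu + e and return e-hat = y - 1 mu-hat - u-hat.
#' No variance re-scaling (no GRAMMAR-gamma correction) is applied, so the
#' second-stage tests are mildly conservative, as in the original method.
#'
#' @param y numeric phenotype vector.
#' @param G whole-genome `kinship_matrix`.
#' @param null_fit optional pre-computed `varcomp_fit` of the G + I model.
#' @return numeric residual vector with the fit attached as attribute
#'   `fit`.
#' @export
grammar_residuals <- function(y, G, null_fit = NULL) {
  if (is.null(null_fit)) null_fit <- reml_fit(y, list(whole = G))
  e <- y - null_fit$mu - null_fit$blup$whole
  attr(e, "fit") <- null_fit
  e
}

#' Single-SNP F-test of GRAMMAR residuals on genotype dosage
#'
#' Simple least squares of the residuals on one SNP's dosage over the
#' complete cases; the slope is tested with F on (1, n_complete - 2) df.
#' The p-value is computed in log space, so extremely strong signals do
#' not underflow.
#'
#' @param residuals numeric vector from [grammar_residuals()].
#' @param snp_genotypes genotype vector over \{0, 0.5, 1, NA\}.
#' @return named vector: `beta`, `f`, `neglog10p`, `n_used`; all `NA`
#'   (with `n_used` set) for untestable SNPs (constant dosage or fewer
#'   than 3 complete pairs).
#' @export
snp_ftest <- function(residuals, snp_genotypes) {
  ok <- !is.na(residuals) & !is.na(snp_genotypes)
  nc <- sum(ok)
  out <- c(beta = NA_real_, f = NA_real_, neglog10p = NA_real_, n_used = nc)
  if (nc < 3) return(out)
  x <- snp_genotypes[ok]
  e <- residuals[ok]
  sxx <- sum((x - mean(x))^2)
  if (sxx <= 0) return(out)
  sxy <- sum((x - mean(x)) * (e - mean(e)))
  beta <- sxy / sxx
  ssr <- beta * sxy
  rss <- sum((e - mean(e))^2) - ssr
  df2 <- nc - 2
  if (rss <= .Machine$double.eps * sum(e^2)) {   # perfect fit
    return(c(beta = beta, f = Inf, neglog10p = Inf, n_used = nc))
  }
  f <- ssr / (rss / df2)
  nl10 <- -stats::pf(f, 1, df2, lower.tail = FALSE, log.p = TRUE) / log(10)
  c(beta = beta, f = f, neglog10p = nl10, n_used = nc)
}

#' Genome-wide Bonferroni cutoff on the -log10 p scale
#'
#' @param alpha genome-wide level in (0, 1).
#' @param n_snps number of SNPs tested.
#' @return -log10(alpha / n_snps).
#' @export
bonferroni_neglog10 <- function(alpha, n_snps) {
  stopifnot(alpha > 0, alpha < 1, n_snps >= 1)
  -log10(alpha / n_snps)
}

#' GRAMMAR genome-wide single-SNP association
#'
#' Computes whole-genome-adjusted residuals once, then regresses them on
#' every SNP with per-SNP complete cases, flagging genome-wide
#' significance against Bonferroni cutoffs over the tested SNP count.
#'
#' @param y numeric phenotype vector.
#' @param G whole-genome `kinship_matrix`.
#' @param geno QC-passed `genotype_matrix`.
#' @param alpha genome-wide levels for the significance flags.
#' @param null_fit optional pre-computed G + I fit.
#' @param trait trait label carried into the result.
#' @return a `grammar_result` data frame: one row per SNP (`snp`, `chr`,
#'   `bp`, `beta`, `f`, `neglog10p`, `n_used`, `sig_5pct`, `sig_1pct`) with
#'   attributes `thresholds`, `n_tested`, `trait`, `residuals`.
#' @export
run_grammar <- function(y, G, geno, alpha = c(0.05, 0.01), null_fit = NULL,
                        trait = "trait") {
  stopifnot(inherits(geno, "genotype_matrix"), length(y) == nrow(geno$values))
  e <- grammar_residuals(y, G, null_fit)
  v <- geno$values
  m <- ncol(v)
  # vectorized complete-case simple regression across SNPs
  obs <- !is.na(v)
  ee <- e * 1            # strip attributes
  nc <- colSums(obs)
  v0 <- v
  v0[!obs] <- 0
  e_mat_sum <- drop(crossprod(obs, ee))          # sum of e over complete cases
  x_sum <- colSums(v0)
  xx_sum <- colSums(v0^2)
  xe_sum <- drop(crossprod(v0, ee))
  ee_sum <- drop(crossprod(obs, ee^2))
  sxx <- xx_sum - x_sum^2 / nc
  sxy <- xe_sum - x_sum * e_mat_sum / nc
  syy <- ee_sum - e_mat_sum^2 / nc
  testable <- nc >= 3 & sxx > 0
  beta <- ifelse(testable, sxy / sxx, NA_real_)
  ssr <- beta * sxy
  rss <- syy - ssr
  df2 <- nc - 2
  f <- ifelse(testable & rss > .Machine$double.eps * ee_sum,
              ssr / (rss / df2), NA_real_)
  perfect <- testable & !is.na(beta) & rss <= .Machine$double.eps * ee_sum
  f[perfect] <- Inf
  nl10 <- rep(NA_real_, m)
  fin <- !is.na(f) & is.finite(f)
  nl10[fin] <- -stats::pf(f[fin], 1, df2[fin], lower.tail = FALSE,
                          log.p = TRUE) / log(10)
  nl10[perfect] <- Inf
  thr <- vapply(alpha, bonferroni_neglog10, numeric(1), n_snps = sum(testable))
  names(thr) <- paste0("alpha_", alpha)
  res <- data.frame(snp = geno$snp_map$name, chr = geno$snp_map$chr,
                    bp = geno$snp_map$bp, beta = beta, f = f,
                    neglog10p = nl10, n_used = nc,
                    sig_5pct = !is.na(nl10) & nl10 > thr[1],
                    sig_1pct = !is.na(nl10) & nl10 > thr[2],
                    stringsAsFactors = FALSE)
  structure(res, class = c("grammar_result", "data.frame"),
            thresholds = thr, n_tested = sum(testable), trait = trait,
            residuals = as.numeric(e))
}

#' @export
print.grammar_result <- function(x, ...) {
  thr <- attr(x, "thresholds")
  cat(sprintf("GRAMMAR scan: trait %s, %d SNPs tested\n", attr(x, "trait"),
              attr(x, "n_tested")))
  cat(sprintf("  genome-wide -log10 P cutoffs: 5%% > %.2f, 1%% > %.2f\n",
              thr[1], thr[2]))
  cat(sprintf("  significant: %d at 5%%, %d at 1%%\n", sum(x$sig_5pct),
              sum(x$sig_1pct)))
  top <- x[order(-x$f), ][1, ]
  cat(sprintf("  top SNP %s (%s:%d): F = %.2f, -log10 P = %.2f\n", top$snp,
              top$chr, top$bp, top$f, top$neglog10p))
  invisible(x)
}
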