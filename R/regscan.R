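#' Boundary-mixture p-value for a regional-variance LRT
#'
#' Because the regional variance is tested on the boundary of its parameter
#' space, the null distribution of LRT = -2 ln(L0/L1) is a 50:50 mixture of
#' a point mass at zero and a chi-square with 1 df: p = 1 when LRT = 0,
#' otherwise p = 0.5 * Pr(chi2_1 > LRT). Statistics below 1e-8 are treated
#' as the point mass.
#'
#' @param lrt non-negative likelihood-ratio statistic (vectorized).
#' @return p-value(s) in (0, 1].
#' @export
mixture_pvalue <- function(lrt) {
  if (any(lrt < 0)) stop("LRT must be non-negative")
  ifelse(lrt <= 1e-8, 1,
         0.5 * stats::pchisq(lrt, df = 1, lower.tail = FALSE))
}

#' Genome-wide LRT significance threshold
#'
#' Inverts the mixture null with a Bonferroni correction over the number of
#' windows tested: returns x solving 0.5 * Pr(chi2_1 > x) = alpha / n_windows.
#'
#' @param alpha genome-wide significance level in (0, 1).
#' @param n_windows number of windows tested.
#' @return the LRT cutoff (0 when the corrected level exceeds the mixture
#'   mass above zero).
#' @export
lrt_threshold <- function(alpha, n_windows) {
  stopifnot(alpha > 0, alpha < 1, n_windows >= 1)
  q <- 2 * alpha / n_windows
  if (q >= 1) return(0)
  stats::qchisq(q, df = 1, lower.tail = FALSE)
}

#' Genome-wide -log10 P from an LRT
#'
#' Bonferroni-adjusted mixture p-value on the -log10 scale, computed in log
#' space throughout so that extreme statistics (adjusted p far below the
#' double-precision underflow of a naive survival-function call) remain
#' exact: -log10(min(1, n_windows * 0.5 * Pr(chi2_1 > LRT))).
#'
#' @param lrt non-negative statistic (vectorized).
#' @param n_windows Bonferroni correction count.
#' @return genome-wide -log10 P (0 when the adjusted p-value caps at 1).
#' @export
genomewide_neglog10p <- function(lrt, n_windows) {
  if (any(lrt < 0)) stop("LRT must be non-negative")
  stopifnot(n_windows >= 1)
  lp <- log(0.5) + stats::pchisq(lrt, df = 1, lower.tail = FALSE,
                                 log.p = TRUE) + log(n_windows)
  lp[lrt <= 1e-8] <- 0                   # point mass: p = 1, adjusted p = 1
  -pmin(lp, 0) / log(10)
}

#' Regional share of the total genomic variance
#'
#' @param sigma_u2 whole-genome genomic variance (trait units^2).
#' @param sigma_w2 regional genomic variance.
#' @return 100 * sigma_w2 / (sigma_u2 + sigma_w2), in percent.
#' @export
regional_ratio <- function(sigma_u2, sigma_w2) {
  stopifnot(all(sigma_u2 >= 0), all(sigma_w2 >= 0))
  tot <- sigma_u2 + sigma_w2
  if (any(tot == 0))
    stop("both variance components are zero; ratio undefined")
  100 * sigma_w2 / tot
}

#' Regional heritability scan over SNP windows
#'
#' For each window, builds the regional GRM Q from its SNPs, fits the
#' alternative model y = 1 mu + Zu + Zw + e with Var(u) = G su2,
#' Var(w) = Q sw2, Var(e) = I se2 by AI-REML, and compares it with the
#' null model (G only, fitted once) through the boundary-mixture LRT.
#'
#' @param y numeric phenotype vector (one record per individual, same order
#'   as `geno`).
#' @param geno the QC-passed `genotype_matrix` used to build window GRMs.
#' @param G whole-genome `kinship_matrix` (includes the window SNPs).
#' @param windows a `window_table` from [make_windows()].
#' @param trait trait label carried into the result.
#' @param bonferroni_n Bonferroni correction count; default the number of
#'   windows scanned (override to reproduce rounded counts such as 800).
#' @param alpha genome-wide significance levels for the reported
#'   thresholds.
#' @param null_fit optional pre-computed null-model `varcomp_fit` (G + I);
#'   fitted here when absent.
#' @param ridge diagonal ridge for the window GRMs.
#' @param profile_u logical; when `TRUE`, the whole-genome variance is held
#'   fixed at its null-fit value during window fits (fast approximate
#'   mode). Default `FALSE`: full joint REML per window.
#' @param verbose log one line per window.
#' @return a `scan_result`: data frame with one row per window (LRT,
#'   mixture p, genome-wide -log10 P, variance components, regional ratio
#'   in percent, convergence flag) plus attributes `trait`, `null_fit`,
#'   `bonferroni_n` and `thresholds`.
#' @export
rhm_scan <- function(y, geno, G, windows, trait = "trait",
                     bonferroni_n = NULL, alpha = c(0.05, 0.01),
                     null_fit = NULL, ridge = 1e-6, profile_u = FALSE,
                     verbose = FALSE) {
  stopifnot(inherits(geno, "genotype_matrix"), length(y) == nrow(geno$values))
  if (is.null(bonferroni_n)) bonferroni_n <- nrow(windows)
  if (is.null(null_fit)) null_fit <- reml_fit(y, list(whole = G))
  l0 <- null_fit$loglik
  th0 <- null_fit$varcomp
  nwin <- nrow(windows)
  res <- data.frame(window = windows$window, chr = windows$chr,
                    first = windows$first, last = windows$last,
                    size = windows$size,
                    lrt = NA_real_, p_mixture = NA_real_,
                    neglog10p = NA_real_, sigma_u2 = NA_real_,
                    sigma_w2 = NA_real_, sigma_e2 = NA_real_,
                    ratio_pct = NA_real_, converged = NA,
                    stringsAsFactors = FALSE)
  if (!is.null(windows$first_snp)) {
    res$first_snp <- windows$first_snp
    res$last_snp <- windows$last_snp
    res$first_bp <- windows$first_bp
    res$last_bp <- windows$last_bp
  }
  for (wi in seq_len(nwin)) {
    idx <- windows$first[wi]:windows$last[wi]
    Q <- tryCatch(build_grm(geno, idx, kind = "regional", ridge = ridge),
                  error = function(e) NULL)
    if (is.null(Q)) {
      if (verbose) message("window ", wi, " skipped: degenerate regional GRM")
      next
    }
    start <- c(th0["whole"], 0.05 * sum(th0), th0["residual"])
    fit1 <- if (profile_u)
      reml_fit_profiled(y, G, Q, th0["whole"], start[c(2, 3)])
    else reml_fit(y, list(whole = G, regional = Q), start = start)
    lrt <- 2 * (fit1$loglik - l0)
    if (lrt < 0 && lrt > -1e-6) lrt <- 0   # numerical clamp, logged below
    if (lrt < 0) {
      # refit from default starts before giving up on the nesting
      fit_retry <- reml_fit(y, list(whole = G, regional = Q))
      if (fit_retry$loglik > fit1$loglik) fit1 <- fit_retry
      lrt <- max(0, 2 * (fit1$loglik - l0))
    }
    if (lrt <= 1e-8) lrt <- 0
    res$lrt[wi] <- lrt
    res$p_mixture[wi] <- mixture_pvalue(lrt)
    res$neglog10p[wi] <- genomewide_neglog10p(lrt, bonferroni_n)
    res$sigma_u2[wi] <- fit1$varcomp["whole"]
    res$sigma_w2[wi] <- fit1$varcomp["regional"]
    res$sigma_e2[wi] <- fit1$varcomp["residual"]
    tot <- fit1$varcomp["whole"] + fit1$varcomp["regional"]
    res$ratio_pct[wi] <- if (tot > 0) 100 * fit1$varcomp["regional"] / tot
      else NA_real_
    res$converged[wi] <- fit1$converged
    if (verbose)
      message(sprintf("window %d/%d  LRT %.3f  iters %d%s", wi, nwin, lrt,
                      fit1$iterations,
                      if (any(fit1$boundary)) " [boundary]" else ""))
  }
  thr <- vapply(alpha, lrt_threshold, numeric(1), n_windows = bonferroni_n)
  structure(res, class = c("scan_result", "data.frame"), trait = trait,
            null_fit = null_fit, bonferroni_n = bonferroni_n,
            thresholds = stats::setNames(thr, paste0("alpha_", alpha)),
            window_size = windows$size[1])
}

# profiled-u window fit: whole-genome variance fixed at its null estimate,
# only (regional, residual) free
reml_fit_profiled <- function(y, G, Q, sigma_u2, start2) {
  n <- length(y)
  offs <- sigma_u2 * unclass(G)
  f <- function(th) {
    V <- offs + th[1] * unclass(Q) + diag(th[2], n)
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) return(-Inf)
    Vinv <- chol2inv(ch)
    Vinv1 <- rowSums(Vinv)
    xVx <- sum(Vinv1)
    Py <- drop(Vinv %*% y) - Vinv1 * (sum(Vinv1 * y) / xVx)
    -0.5 * (2 * sum(log(diag(ch))) + log(xVx) + sum(y * Py) +
              (n - 1) * log(2 * pi))
  }
  opt <- stats::optim(pmax(start2, 1e-8), function(p) -f(p),
                      method = "L-BFGS-B",
                      lower = c(0, 1e-10 * stats::var(y)))
  th <- c(sigma_u2, opt$par)
  fit <- list(varcomp = stats::setNames(th, c("whole", "regional", "residual")),
              loglik = -opt$value, converged = opt$convergence == 0,
              iterations = opt$counts[1],
              boundary = c(whole = FALSE, regional = opt$par[1] <= 1e-8),
              n = n)
  class(fit) <- "varcomp_fit"
  fit
}

#' @export
print.scan_result <- function(x, ...) {
  thr <- attr(x, "thresholds")
  if (is.null(thr) || is.null(attr(x, "bonferroni_n"))) {
    # subset rows lose the scan metadata; print as a plain table
    return(NextMethod())
  }
  cat(sprintf("regional heritability scan: trait %s, %d windows (size %s), Bonferroni N = %d\n",
              attr(x, "trait"), nrow(x), attr(x, "window_size"),
              attr(x, "bonferroni_n")))
  cat("  LRT thresholds:",
      paste(sprintf("%s > %.2f", names(thr), thr), collapse = ", "), "\n")
  top <- x[order(-x$lrt), ][1, ]
  cat(sprintf("  top window %d on %s: LRT %.2f, -log10P %.2f, ratio %.1f%%\n",
              top$window, top$chr, top$lrt, top$neglog10p, top$ratio_pct))
  invisible(x)
}

#' Write a scan result with a metadata header
#'
#' @param scan a `scan_result`.
#' @param path output TSV path; threshold metadata is written as `#`
#'   comment lines before the header.
#' @return the path, invisibly.
#' @export
write_scan <- function(scan, path) {
  thr <- attr(scan, "thresholds")
  hdr <- c(sprintf("# trait: %s", attr(scan, "trait")),
           sprintf("# bonferroni_n: %d", attr(scan, "bonferroni_n")),
           sprintf("# threshold %s: %.4f", names(thr), thr))
  con <- file(path, "w")
  writeLines(hdr, con)
  close(con)
  suppressWarnings(utils::write.table(as.data.frame(scan), path, sep = "\t",
                                      quote = FALSE, row.names = FALSE,
                                      append = TRUE))
  invisible(path)
}
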