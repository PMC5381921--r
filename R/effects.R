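#' Correlations among whole-genome and regional BLUP effects across traits
#'
#' Pearson correlations among the whole-genome (u-hat) and regional
#' (w-hat) effect predictions of several traits fitted at a common window,
#' with two-sided p-values from the t approximation on n - 2 df. A vector
#' with zero variance (for example a regional effect whose variance
#' estimate sits at the zero boundary) yields `NA` entries rather than
#' zero, so degenerate fits are visible, not masked.
#'
#' @param fits named list of `varcomp_fit` objects, one per trait, all from
#'   the same individuals and the same window (components `whole` and
#'   `regional`).
#' @return an `effect_correlations` object: `r` (labelled correlation
#'   matrix over whole.<trait> then regional.<trait>), `p` (matching
#'   p-value matrix), `n`.
#' @export
effect_correlations <- function(fits) {
  stopifnot(is.list(fits), length(fits) >= 1)
  if (is.null(names(fits))) names(fits) <- paste0("trait", seq_along(fits))
  n <- fits[[1]]$n
  for (f in fits) {
    stopifnot(inherits(f, "varcomp_fit"))
    if (f$n != n) stop("fits do not share the same individuals")
    if (!all(c("whole", "regional") %in% names(f$blup)))
      stop("each fit needs 'whole' and 'regional' BLUP components")
  }
  cols <- c(lapply(fits, function(f) f$blup$whole),
            lapply(fits, function(f) f$blup$regional))
  names(cols) <- c(paste0("whole.", names(fits)),
                   paste0("regional.", names(fits)))
  E <- do.call(cbind, cols)
  k <- ncol(E)
  sds <- apply(E, 2, stats::sd)
  r <- matrix(NA_real_, k, k, dimnames = list(colnames(E), colnames(E)))
  ok <- sds > 0
  if (any(ok)) r[ok, ok] <- stats::cor(E[, ok, drop = FALSE])
  diag(r) <- 1
  tstat <- abs(r) * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(tstat, df = n - 2, lower.tail = FALSE)
  diag(p) <- NA_real_
  structure(list(r = r, p = p, n = n, traits = names(fits)),
            class = "effect_correlations")
}

#' @export
print.effect_correlations <- function(x, digits = 3, ...) {
  cat("correlations between whole-genome and regional effects (n =",
      x$n, ")\n")
  print(round(x$r, digits))
  invisible(x)
}

#' Write an effect-correlation table and its p-values as TSV
#'
#' @param ec an `effect_correlations` object.
#' @param prefix output prefix; writes `<prefix>.r.tsv` and
#'   `<prefix>.p.tsv`.
#' @return the prefix, invisibly.
#' @export
write_effect_correlations <- function(ec, prefix) {
  utils::write.table(data.frame(effect = rownames(ec$r), ec$r,
                                check.names = FALSE),
                     paste0(prefix, ".r.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(data.frame(effect = rownames(ec$p), ec$p,
                                check.names = FALSE),
                     paste0(prefix, ".p.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(prefix)
}

#' Partition individuals by genotype class at a named SNP
#'
#' Labels individuals as major homozygote (MM, g = 1), heterozygote
#' (Mm, g = 0.5), minor homozygote (mm, g = 0) or missing at one SNP, and
#' attaches per-trait regional-effect values for plotting and per-class
#' means, as used to display antagonistic pleiotropy at a top associated
#' marker.
#'
#' @param geno a `genotype_matrix`.
#' @param snp_name SNP identifier present in the map.
#' @param regional_effects data frame (or named list) of per-individual
#'   regional-effect vectors, one column per trait.
#' @return a `genotype_partition`: data frame `id`, `class`, one column
#'   per trait, with attribute `class_means` (per-class trait means) and
#'   `snp`.
#' @export
genotype_partition <- function(geno, snp_name, regional_effects) {
  stopifnot(inherits(geno, "genotype_matrix"))
  k <- match(snp_name, geno$snp_map$name)
  if (is.na(k)) stop("SNP '", snp_name, "' not found in the map")
  g <- geno$values[, k]
  cls <- factor(rep("missing", length(g)),
                levels = c("MM", "Mm", "mm", "missing"))
  cls[!is.na(g) & g == 1] <- "MM"
  cls[!is.na(g) & g == 0.5] <- "Mm"
  cls[!is.na(g) & g == 0] <- "mm"
  eff <- as.data.frame(regional_effects)
  stopifnot(nrow(eff) == length(g))
  out <- data.frame(id = geno$ids, class = cls, eff,
                    stringsAsFactors = FALSE)
  means <- stats::aggregate(eff, by = list(class = cls), FUN = mean,
                            drop = FALSE)
  structure(out, class = c("genotype_partition", "data.frame"),
            class_means = means, snp = snp_name)
}

#' @export
print.genotype_partition <- function(x, ...) {
  cat("genotype partition at", attr(x, "snp"), "\n")
  print(table(x$class))
  cat("per-class regional-effect means:\n")
  print(attr(x, "class_means"))
  invisible(x)
}
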