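#' End-to-end analysis configuration
#'
#' @param sim a `sim_config` to generate the data, or `NULL` to read files.
#' @param genotype_prefix,genotype_format,phenotype_path input files, used
#'   when `sim` is `NULL`.
#' @param traits trait columns to analyse; default all phenotype columns.
#' @param window_sizes SNP window sizes for the regional scan (shift is
#'   always half the size).
#' @param alpha genome-wide significance levels.
#' @param bonferroni_n optional named override of the Bonferroni window
#'   count per size (e.g. `c("100" = 800)`), as when reproducing rounded
#'   counts.
#' @param maf_min,call_rate_min,hwe_p_min QC thresholds (see
#'   [qc_filter()]).
#' @param ridge diagonal ridge for GRMs.
#' @param profile_u fix the whole-genome variance at its null-fit value in
#'   window fits (fast mode); default `FALSE` (joint REML).
#' @param effects_window_size window size whose top window feeds the
#'   effect-correlation analysis (default 20).
#' @param out_dir output directory for TSV artifacts, or `NULL` to skip
#'   writing.
#' @param seed seed recorded in the manifest (and used for simulation when
#'   `sim` carries no seed).
#' @return a `run_config` list.
#' @export
run_config <- function(sim = NULL, genotype_prefix = NULL,
                       genotype_format = "tsv", phenotype_path = NULL,
                       traits = NULL, window_sizes = c(100, 20, 10),
                       alpha = c(0.05, 0.01), bonferroni_n = NULL,
                       maf_min = 0.01, call_rate_min = 0.95,
                       hwe_p_min = 1e-6, ridge = 1e-6, profile_u = FALSE,
                       effects_window_size = 20, out_dir = NULL,
                       seed = 1) {
  stopifnot(all(alpha > 0), all(alpha < 1), all(window_sizes >= 2))
  if (any(window_sizes %% 2 != 0))
    stop("window sizes must be even so the 50 percent shift is integral")
  if (is.null(sim) && (is.null(genotype_prefix) || is.null(phenotype_path)))
    stop("either a sim_config or input file paths are required")
  structure(list(sim = sim, genotype_prefix = genotype_prefix,
                 genotype_format = genotype_format,
                 phenotype_path = phenotype_path, traits = traits,
                 window_sizes = window_sizes, alpha = alpha,
                 bonferroni_n = bonferroni_n, maf_min = maf_min,
                 call_rate_min = call_rate_min, hwe_p_min = hwe_p_min,
                 ridge = ridge, profile_u = profile_u,
                 effects_window_size = effects_window_size,
                 out_dir = out_dir, seed = seed),
            class = "run_config")
}

#' Run the full regional-heritability analysis
#'
#' Stages, in order: obtain data (simulate or read), marker QC, whole-
#' genome GRM, window construction and regional scan per trait and window
#' size, GRAMMAR single-SNP association per trait, and the whole-vs-
#' regional effect-correlation analysis at the genome-wide top window of
#' the configured size. All tabular artifacts are written under
#' `config$out_dir` when set; the run is a pure function of the
#' configuration (fixed seed in, identical files out).
#'
#' @param config a `run_config`.
#' @param verbose log stage progress.
#' @return an `analysis_report` list: `qc`, `scans` (nested list by window
#'   size then trait), `grammar` (by trait), `effects`, `top_window`,
#'   `manifest`.
#' @export
run_analysis <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (verbose) message(...)
  if (!is.null(config$sim)) {
    say("simulating dataset")
    sim <- simulate_dataset(config$sim)
    geno <- sim$geno
    phen <- sim$phenotypes
  } else {
    say("reading inputs")
    geno <- read_genotypes(config$genotype_prefix, config$genotype_format)
    phen <- read_phenotypes(config$phenotype_path)
    sim <- NULL
  }
  traits <- config$traits
  if (is.null(traits)) traits <- setdiff(names(phen), "id")
  missing_tr <- setdiff(traits, names(phen))
  if (length(missing_tr)) {
    warning("traits absent from phenotypes, skipped: ",
            paste(missing_tr, collapse = ", "))
    traits <- setdiff(traits, missing_tr)
  }
  say("marker QC")
  qc <- qc_filter(geno, config$maf_min, config$call_rate_min,
                  config$hwe_p_min)
  geno_qc <- qc$geno
  say("whole-genome GRM (", ncol(geno_qc$values), " SNPs)")
  G <- build_grm(geno_qc, kind = "whole", ridge = config$ridge)
  scans <- list()
  null_fits <- list()
  for (tr in traits) {
    y <- phen[[tr]]
    null_fits[[tr]] <- reml_fit(y, list(whole = G))
  }
  for (size in config$window_sizes) {
    wins <- make_windows(geno_qc$snp_map, size)
    bn <- config$bonferroni_n[[as.character(size)]]
    key <- as.character(size)
    scans[[key]] <- list()
    for (tr in traits) {
      say("scan: size ", size, ", trait ", tr, " (", nrow(wins),
          " windows)")
      scans[[key]][[tr]] <- rhm_scan(
        phen[[tr]], geno_qc, G, wins, trait = tr,
        bonferroni_n = if (is.null(bn)) nrow(wins) else bn,
        alpha = config$alpha, null_fit = null_fits[[tr]],
        ridge = config$ridge, profile_u = config$profile_u)
    }
  }
  say("GRAMMAR single-SNP association")
  grammar <- stats::setNames(lapply(traits, function(tr)
    run_grammar(phen[[tr]], G, geno_qc, alpha = config$alpha,
                null_fit = null_fits[[tr]], trait = tr)), traits)
  # effect correlations at the top window of the configured size
  effects <- NULL
  top_window <- NULL
  ekey <- as.character(config$effects_window_size)
  if (ekey %in% names(scans) && length(traits) >= 1) {
    peak <- do.call(rbind, lapply(traits, function(tr) {
      s <- scans[[ekey]][[tr]]
      s[which.max(s$lrt), c("window", "first", "last", "lrt")]
    }))
    top_window <- peak[which.max(peak$lrt), ]
    say("effect correlations at window ", top_window$window,
        " (size ", ekey, ")")
    wfits <- stats::setNames(lapply(traits, function(tr) {
      Q <- build_grm(geno_qc, top_window$first:top_window$last,
                     kind = "regional", ridge = config$ridge)
      reml_fit(phen[[tr]], list(whole = G, regional = Q))
    }), traits)
    effects <- effect_correlations(wfits)
  }
  manifest <- list(
    seed = config$seed,
    r_version = as.character(getRversion()),
    package_version = as.character(utils::packageVersion("regherit")),
    n_individuals = nrow(geno_qc$values),
    n_snps_input = qc$report$n_input,
    n_snps_used = qc$report$n_surviving,
    traits = traits,
    window_sizes = config$window_sizes,
    windows_per_size = stats::setNames(
      vapply(config$window_sizes, function(s)
        nrow(make_windows(geno_qc$snp_map, s)), numeric(1)),
      config$window_sizes),
    config_hash = config_hash(config))
  report <- structure(list(qc = qc$report, scans = scans, grammar = grammar,
                           effects = effects, top_window = top_window,
                           null_fits = null_fits, manifest = manifest,
                           geno = geno_qc, phenotypes = phen, G = G,
                           sim = sim),
                      class = "analysis_report")
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

# stable hash of the analysis parameters: any change in the configuration
# changes the hash
config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  x <- config[setdiff(names(config), "out_dir")]
  dput(x, file = tmp, control = c("all", "hexNumeric"))
  unname(tools::md5sum(tmp))
}

#' Write the tabular artifacts of an analysis report
#'
#' @param report an `analysis_report`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(report$qc$snp_stats, file.path(dir, "qc_snps.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (size in names(report$scans))
    for (tr in names(report$scans[[size]]))
      write_scan(report$scans[[size]][[tr]],
                 file.path(dir, sprintf("scan_size%s_%s.tsv", size, tr)))
  for (tr in names(report$grammar))
    utils::write.table(as.data.frame(report$grammar[[tr]]),
                       file.path(dir, sprintf("grammar_%s.tsv", tr)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(report$effects))
    write_effect_correlations(report$effects, file.path(dir, "effects"))
  mf <- report$manifest
  writeLines(c(
    sprintf("seed: %s", mf$seed),
    sprintf("r_version: %s", mf$r_version),
    sprintf("package_version: %s", mf$package_version),
    sprintf("n_individuals: %d", mf$n_individuals),
    sprintf("n_snps_input: %d", mf$n_snps_input),
    sprintf("n_snps_used: %d", mf$n_snps_used),
    sprintf("traits: %s", paste(mf$traits, collapse = ",")),
    sprintf("windows_per_size: %s",
            paste(sprintf("%s=%d", names(mf$windows_per_size),
                          mf$windows_per_size), collapse = ",")),
    sprintf("config_hash: %s", mf$config_hash)),
    file.path(dir, "manifest.txt"))
  invisible(dir)
}

#' @export
print.analysis_report <- function(x, ...) {
  mf <- x$manifest
  cat("regional heritability analysis report\n")
  cat(sprintf("  %d individuals, %d/%d SNPs after QC, traits: %s\n",
              mf$n_individuals, mf$n_snps_used, mf$n_snps_input,
              paste(mf$traits, collapse = ", ")))
  for (size in names(x$scans)) {
    for (tr in names(x$scans[[size]])) {
      s <- x$scans[[size]][[tr]]
      thr <- attr(s, "thresholds")
      nsig <- sum(s$lrt > thr[length(thr)], na.rm = TRUE)
      top <- s[which.max(s$lrt), ]
      cat(sprintf(
        "  size %s, %s: top window %d (LRT %.1f, ratio %.1f%%), %d significant at %s\n",
        size, tr, top$window, top$lrt, top$ratio_pct, nsig,
        names(thr)[length(thr)]))
    }
  }
  if (!is.null(x$effects)) {
    cat("  effect correlations at top window", x$top_window$window, "\n")
    print(round(x$effects$r, 3))
  }
  invisible(x)
}
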