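test_that("simulated genotypes honour shape, coding and determinism", {
  cfg <- sim_config(n_individuals = 4, chromosome_snp_counts = c(c1 = 10),
                    traits = "t", whole_var = 1, resid_var = 1,
                    polygenic_corr = matrix(1, 1, 1),
                    regional_window = NULL, regional_var = 0,
                    regional_corr = matrix(1, 1, 1),
                    missing_rate = 0, seed = 3)
  g <- simulate_genotypes(cfg)
  expect_equal(dim(g), c(4L, 10L))
  expect_true(all(g$values %in% c(0, 0.5, 1)))
  expect_false(anyNA(g$values))
  expect_equal(g$snp_map$chr, rep("c1", 10))
  expect_true(all(diff(g$snp_map$bp) > 0))
  expect_false(anyDuplicated(g$snp_map$name) > 0)
  g2 <- simulate_genotypes(cfg)
  expect_identical(g$values, g2$values)
  expect_identical(g$snp_map, g2$snp_map)
})

test_that("genotype frequencies follow Hardy-Weinberg at the drawn allele
           frequency", {
  cfg <- sim_config(n_individuals = 10000,
                    chromosome_snp_counts = c(c1 = 1),
                    allele_freq_range = c(0.5, 0.5),
                    traits = "t", whole_var = 1, resid_var = 1,
                    polygenic_corr = matrix(1, 1, 1),
                    regional_window = NULL, regional_var = 0,
                    regional_corr = matrix(1, 1, 1),
                    missing_rate = 0, seed = 4)
  g <- simulate_genotypes(cfg)
  n <- 10000
  obs <- c(mean(g$values == 0), mean(g$values == 0.5), mean(g$values == 1))
  expe <- c(0.25, 0.5, 0.25)
  se <- sqrt(expe * (1 - expe) / n)
  expect_true(all(abs(obs - expe) < 3 * se))
})

test_that("missingness is injected at the configured rate", {
  cfg <- fast_config(seed = 8, n = 400, snps = c(c1 = 200))
  cfg$missing_rate <- 0.05
  g <- simulate_genotypes(cfg)
  expect_lt(abs(mean(is.na(g$values)) - 0.05), 0.005)
  expect_false(anyNA(attr(g, "complete_values")))
})

test_that("the optional LD parameter induces adjacent-dosage correlation", {
  base <- fast_config(seed = 9, n = 1500, snps = c(c1 = 60))
  g0 <- simulate_genotypes(base)
  ld <- fast_config(seed = 9, n = 1500, snps = c(c1 = 60), ld = 0.8)
  g1 <- simulate_genotypes(ld)
  adj_cor <- function(v) {
    mean(sapply(seq_len(ncol(v) - 1), function(k) cor(v[, k], v[, k + 1])))
  }
  expect_lt(abs(adj_cor(g0$values)), 0.05)
  expect_gt(adj_cor(g1$values), 0.25)
})

test_that("null mode produces exactly zero regional effects", {
  cfg <- fast_config(seed = 10, n = 50, snps = c(c1 = 40))
  sim <- simulate_dataset(cfg)
  expect_true(all(sim$truth$regional == 0))
  cfg2 <- fast_config(seed = 10, n = 50, snps = c(c1 = 40),
                      regional_window = list(chr = 1, start = 1, size = 10),
                      regional_var = 0)
  sim2 <- simulate_dataset(cfg2)
  expect_true(all(sim2$truth$regional == 0))
})

test_that("phenotype decomposes exactly and realized variances match the
           targets by construction", {
  cfg <- sim_config(n_individuals = 300,
                    chromosome_snp_counts = c(c1 = 150, c2 = 100),
                    regional_window = list(chr = 2, start = 11, size = 20),
                    missing_rate = 0.02, seed = 11)
  sim <- simulate_dataset(cfg)
  tr <- sim$truth
  y <- as.matrix(sim$phenotypes[, cfg$traits])
  recon <- sweep(tr$whole + tr$regional + tr$resid, 2, cfg$trait_means, "+")
  expect_equal(unname(y), unname(recon), tolerance = 1e-12)
  # genetic blocks are rescaled to the exact target variance
  expect_equal(unname(apply(tr$whole, 2, var)), unname(cfg$whole_var),
               tolerance = 1e-10)
  expect_equal(unname(apply(tr$regional, 2, var)), unname(cfg$regional_var),
               tolerance = 1e-10)
})

test_that("total phenotypic variance matches the component sum at large n", {
  cfg <- sim_config(n_individuals = 2000,
                    chromosome_snp_counts = c(c1 = 300),
                    traits = c("a", "b"), whole_var = c(400, 300),
                    resid_var = c(100, 200),
                    polygenic_corr = uniform_corr(2, 0.5),
                    regional_window = list(chr = 1, start = 101, size = 20),
                    regional_var = c(50, 25), regional_corr = diag(2),
                    missing_rate = 0, seed = 12)
  sim <- simulate_dataset(cfg)
  target <- cfg$whole_var + cfg$regional_var + cfg$resid_var
  got <- apply(as.matrix(sim$phenotypes[, c("a", "b")]), 2, var)
  expect_true(all(abs(got - target) / target < 0.1))
})

test_that("between-trait correlations of true effects track the configured
           matrices", {
  cfg <- sim_config(n_individuals = 2000,
                    chromosome_snp_counts = c(c1 = 400, c2 = 300),
                    regional_window = list(chr = 1, start = 1, size = 20),
                    missing_rate = 0, seed = 13)
  sim <- simulate_dataset(cfg)
  cw <- cor(sim$truth$whole)
  expect_true(all(abs(cw[upper.tri(cw)] - 0.85) < 0.05))
  cr <- cor(sim$truth$regional)
  expect_lt(cr["FAT", "MLK"], 0)
  expect_lt(cr["FAT", "PRT"], 0)
  expect_gt(cr["MLK", "PRT"], 0)
})

test_that("configuration validation rejects malformed inputs", {
  expect_error(sim_config(chromosome_snp_counts = c(c1 = 0)), "positive")
  expect_error(sim_config(allele_freq_range = c(0.2, 0.6)))
  bad <- uniform_corr(3, 0.85)
  bad[1, 2] <- 0.2   # asymmetric
  expect_error(sim_config(polygenic_corr = bad), "symmetric")
  notpsd <- matrix(c(1, 0.9, -0.9, 0.9, 1, 0.9, -0.9, 0.9, 1), 3, 3)
  expect_error(sim_config(regional_corr = notpsd), "positive semi-definite")
  cfg <- fast_config(seed = 1, n = 20, snps = c(c1 = 30))
  g <- simulate_genotypes(cfg)
  cfg$regional_window <- list(chr = 1, start = 25, size = 10)
  expect_error(simulate_traits(g, cfg), "bounds")
  cfg$regional_window <- list(chr = 5, start = 1, size = 5)
  expect_error(simulate_traits(g, cfg), "chromosome")
})

test_that("write_simulation emits the documented artifact set", {
  cfg <- fast_config(seed = 14, n = 20, snps = c(c1 = 15))
  sim <- simulate_dataset(cfg)
  dirp <- withr::local_tempdir()
  write_simulation(sim, cfg, dirp)
  expect_true(all(file.exists(file.path(dirp, c(
    "genotypes.geno.tsv", "genotypes.snps.tsv", "genotypes.bed",
    "genotypes.bim", "genotypes.fam", "phenotypes.tsv",
    "truth_whole_effects.tsv", "truth_regional_effects.tsv",
    "truth_varcomp.tsv", "manifest.txt")))))
  ph <- read_phenotypes(file.path(dirp, "phenotypes.tsv"))
  expect_equal(names(ph), c("id", "y1"))
  expect_equal(nrow(ph), 20)
})
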