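test_that("genotype_matrix validates coding, map consistency and sorting", {
  v <- matrix(c(0, 0.5, 1, 1), 2, 2)
  map <- data.frame(name = c("a", "b"), chr = "c1", bp = c(1, 2))
  g <- genotype_matrix(v, map, c("i1", "i2"))
  expect_s3_class(g, "genotype_matrix")
  expect_equal(dim(g), c(2L, 2L))
  expect_error(genotype_matrix(matrix(0.3, 2, 2), map), "genotype code")
  expect_error(genotype_matrix(v, map[1, , drop = FALSE]), "map has")
  badmap <- data.frame(name = c("a", "b"), chr = "c1", bp = c(5, 2))
  expect_error(genotype_matrix(v, badmap), "not sorted")
  dupmap <- data.frame(name = c("a", "a"), chr = "c1", bp = c(1, 2))
  expect_error(genotype_matrix(v, dupmap), "unique")
})

test_that("TSV round trip preserves values, map and ids", {
  g <- toy_geno()
  pre <- file.path(withr::local_tempdir(), "toy")
  write_genotypes_tsv(g, pre)
  g2 <- read_genotypes(pre, "tsv")
  expect_equal(unname(g2$values), unname(g$values))
  expect_equal(g2$snp_map$name, g$snp_map$name)
  expect_equal(g2$snp_map$bp, g$snp_map$bp)
  expect_equal(g2$ids, g$ids)
})

test_that("PLINK bed trio round trip equals the TSV-read matrix", {
  cfg <- fast_config(seed = 11, n = 37, snps = c(c1 = 23))
  cfg$missing_rate <- 0.05
  g <- simulate_genotypes(cfg)
  dirp <- withr::local_tempdir()
  write_plink(g, file.path(dirp, "t"))
  write_genotypes_tsv(g, file.path(dirp, "t"))
  gb <- read_genotypes(file.path(dirp, "t"), "plink-bed")
  gt <- read_genotypes(file.path(dirp, "t"), "tsv")
  expect_equal(unname(gb$values), unname(gt$values))
  expect_equal(gb$snp_map$name, gt$snp_map$name)
  expect_equal(gb$ids, gt$ids)
})

test_that("inconsistent map and matrix dimensions raise a format error", {
  dirp <- withr::local_tempdir()
  pre <- file.path(dirp, "bad")
  g <- toy_geno()
  write_genotypes_tsv(g, pre)
  # truncate the map to 2 SNPs while the matrix keeps 6 columns
  map <- utils::read.delim(paste0(pre, ".snps.tsv"))
  utils::write.table(map[1:2, ], paste0(pre, ".snps.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  expect_error(read_genotypes(pre, "tsv"), "map has")
})

test_that("orientation puts the major allele at 1 and is idempotent", {
  v <- matrix(c(0, 0, 0.5, 0,     # allele coded 1 is rare -> flip
                1, 1, 0.5, 1), 4, 2)
  map <- data.frame(name = c("a", "b"), chr = "c1", bp = c(1, 2))
  g <- orient_major(genotype_matrix(v, map))
  p <- allele_freqs(g)
  expect_true(all(p >= 0.5))
  expect_equal(unname(p["a"]), 0.875)
  g2 <- orient_major(g)
  expect_equal(g2$values, g$values)
})

test_that("allele frequencies equal the genotype mean on the 0/0.5/1 coding", {
  map1 <- data.frame(name = "s", chr = "c", bp = 1)
  expect_equal(unname(allele_freqs(
    genotype_matrix(matrix(c(1, 0.5, 0), 3, 1), map1))), 0.5)
  expect_equal(unname(allele_freqs(
    genotype_matrix(matrix(c(1, 1, 0.5, 1), 4, 1), map1))), 0.875)
  expect_equal(unname(allele_freqs(
    genotype_matrix(matrix(1, 3, 1), map1))), 1)
  gm <- genotype_matrix(matrix(NA_real_, 3, 1), map1)
  expect_error(allele_freqs(gm), "missing")
})

test_that("HWE exact p-value matches a full enumeration oracle", {
  # independent oracle: direct factorial arithmetic over all heterozygote
  # configurations compatible with the allele counts
  oracle <- function(aa, ab, bb) {
    n <- aa + ab + bb
    na <- 2 * bb + ab
    nb <- 2 * aa + ab
    if (na == 0 || nb == 0) return(1)
    hets <- seq(min(na, nb) %% 2, min(na, nb), by = 2)
    pr <- sapply(hets, function(h) {
      factorial(n) / (factorial((na - h) / 2) * factorial(h) *
                        factorial((nb - h) / 2)) * 2^h *
        factorial(na) * factorial(nb) / factorial(2 * n)
    })
    sum(pr[pr <= pr[match(ab, hets)] + 1e-12])
  }
  cases <- list(c(3, 5, 2), c(8, 1, 4), c(2, 2, 2), c(10, 0, 5),
                c(1, 9, 1), c(6, 6, 1), c(4, 0, 0), c(0, 4, 0))
  for (cs in cases) {
    expect_equal(hwe_exact_pvalue(cs[1], cs[2], cs[3]),
                 oracle(cs[1], cs[2], cs[3]), tolerance = 1e-10,
                 info = paste(cs, collapse = "/"))
  }
})

test_that("HWE p-value is symmetric in homozygote labels, sane at edges", {
  expect_equal(hwe_exact_pvalue(5, 0, 0), 1)
  expect_equal(hwe_exact_pvalue(3, 5, 2), hwe_exact_pvalue(2, 5, 3))
  expect_error(hwe_exact_pvalue(-1, 2, 3), "non-negative")
  expect_error(hwe_exact_pvalue(0, 0, 0), "at least one")
  # chi-square variant agrees with the exact test to first order at
  # moderate counts
  expect_lt(abs(hwe_exact_pvalue(40, 45, 15) -
                  hwe_exact_pvalue(40, 45, 15, method = "chisq")), 0.1)
})

test_that("qc_filter removes exactly the SNPs violating one criterion each", {
  set.seed(4)
  n <- 100
  clean <- function() sample(c(0, 0.5, 1), n, TRUE, prob = c(0.09, 0.42, 0.49))
  v <- cbind(rep(1, n),                              # monomorphic: MAF 0
             {x <- clean(); x[1:8] <- NA; x},        # call rate 0.92
             clean(), clean(),
             rep(0.5, n))                            # every individual het
  map <- data.frame(name = paste0("s", 1:5), chr = "c1", bp = 1:5)
  g <- genotype_matrix(v, map)
  out <- qc_filter(g)
  expect_equal(out$report$n_surviving, 2)
  expect_equal(out$geno$snp_map$name, c("s3", "s4"))
  expect_equal(unname(out$report$removed_by),
               c(1, 1, 1))   # one SNP per criterion
  expect_true(out$report$snp_stats$hwe_p[5] < 1e-6)
  # vacuous thresholds keep everything
  expect_equal(qc_filter(g, 0, 0, 0)$report$n_surviving, 5)
})

test_that("QC boundary is >= (a SNP at exactly the MAF threshold survives)", {
  n <- 100
  v <- cbind(c(rep(0.5, 2), rep(1, 98)),   # MAF exactly 0.01
             sample(c(0, 0.5, 1), n, TRUE))
  map <- data.frame(name = c("edge", "ok"), chr = "c1", bp = 1:2)
  g <- genotype_matrix(v, map)
  out <- qc_filter(g, maf_min = 0.01)
  expect_true("edge" %in% out$geno$snp_map$name)
})

test_that("qc_filter is idempotent", {
  cfg <- fast_config(seed = 21, n = 80, snps = c(c1 = 60))
  cfg$missing_rate <- 0.03
  g <- simulate_genotypes(cfg)
  a <- qc_filter(g)
  b <- qc_filter(a$geno)
  expect_equal(b$report$n_removed, 0)
  expect_equal(b$geno$values, a$geno$values)
})
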