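make_fit_pair <- function(seed, n = 150, regional_var = c(150, 150),
                          regional_corr = diag(2)) {
  cfg <- sim_config(n_individuals = n,
                    chromosome_snp_counts = c(c1 = 200),
                    traits = c("t1", "t2"),
                    whole_var = c(400, 400), resid_var = c(120, 120),
                    polygenic_corr = uniform_corr(2, 0.85),
                    regional_window = list(chr = 1, start = 91, size = 20),
                    regional_var = regional_var,
                    regional_corr = regional_corr,
                    missing_rate = 0, seed = seed)
  sim <- simulate_dataset(cfg)
  G <- build_grm(sim$geno)
  Q <- build_grm(sim$geno, sim$truth$window_snps, kind = "regional")
  fits <- lapply(c(t1 = "t1", t2 = "t2"), function(tr)
    reml_fit(sim$phenotypes[[tr]], list(whole = G, regional = Q)))
  list(sim = sim, fits = fits)
}

test_that("effect correlation matrix is symmetric with unit diagonal and
           matches the closed-form Pearson formula", {
  mp <- make_fit_pair(61)
  ec <- effect_correlations(mp$fits)
  expect_equal(diag(ec$r), rep(1, 4), ignore_attr = TRUE)
  expect_equal(ec$r, t(ec$r))
  expect_true(all(abs(ec$r) <= 1 + 1e-12, na.rm = TRUE))
  # closed-form check of one entry
  a <- mp$fits$t1$blup$whole
  b <- mp$fits$t2$blup$regional
  r_hand <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(ec$r["whole.t1", "regional.t2"], r_hand, tolerance = 1e-12)
  # p-value matches the t approximation
  n <- ec$n
  t0 <- abs(r_hand) * sqrt((n - 2) / (1 - r_hand^2))
  expect_equal(ec$p["whole.t1", "regional.t2"],
               2 * pt(t0, n - 2, lower.tail = FALSE), tolerance = 1e-12)
})

test_that("five-point hand-computed Pearson correlation is reproduced", {
  x <- c(1, 2, 3, 4, 10)
  y <- c(2, 1, 4, 3, 9)
  # Pearson by the sums formula
  n <- 5
  r_hand <- (n * sum(x * y) - sum(x) * sum(y)) /
    sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
  f1 <- structure(list(blup = list(whole = x, regional = y), n = n),
                  class = "varcomp_fit")
  ec <- effect_correlations(list(a = f1))
  expect_equal(ec$r["whole.a", "regional.a"], r_hand, tolerance = 1e-12)
})

test_that("zero-variance effect vectors yield NA entries, never zero", {
  n <- 50
  f1 <- structure(list(blup = list(whole = rnorm(n), regional = rep(0, n)),
                       n = n), class = "varcomp_fit")
  f2 <- structure(list(blup = list(whole = rnorm(n), regional = rnorm(n)),
                       n = n), class = "varcomp_fit")
  ec <- effect_correlations(list(a = f1, b = f2))
  expect_true(is.na(ec$r["regional.a", "whole.b"]))
  expect_equal(ec$r["regional.a", "regional.a"], 1)  # diagonal stays 1
  expect_false(any(ec$r[is.na(ec$r)] == 0, na.rm = TRUE))
})

test_that("antagonistic regional correlation is recovered with positive
           whole-genome correlation (sign pattern)", {
  mp <- make_fit_pair(62, n = 400,
                      regional_var = c(150, 150),
                      regional_corr = matrix(c(1, -0.9, -0.9, 1), 2, 2))
  ec <- effect_correlations(mp$fits)
  expect_lt(ec$r["regional.t1", "regional.t2"], 0)
  expect_gt(ec$r["whole.t1", "whole.t2"], 0)
})

test_that("genotype partition is exhaustive, mutually exclusive and its
           class means are monotone for a dosage-driven effect", {
  cfg <- fast_config(seed = 63, n = 120, snps = c(c1 = 50))
  cfg$missing_rate <- 0.05
  g <- simulate_genotypes(cfg)
  # use a SNP where all three genotype classes occur
  comp <- attr(g, "complete_values")
  k <- which(apply(comp, 2, function(x) all(c(0, 0.5, 1) %in% x)))[1]
  snp <- g$snp_map$name[k]
  dose <- comp[, k]
  w <- 3 * (dose - mean(dose))          # regional effect from this SNP
  gp <- genotype_partition(g, snp, data.frame(w = w))
  expect_equal(nrow(gp), 120)
  expect_equal(sum(table(gp$class)), 120)
  cm <- attr(gp, "class_means")
  m <- setNames(cm$w, cm$class)
  expect_true(m["MM"] > m["Mm"], info = "MM vs Mm")
  expect_true(m["Mm"] > m["mm"], info = "Mm vs mm")
})

test_that("single-class partition and unknown SNP errors", {
  v <- matrix(0.5, 5, 2)
  map <- data.frame(name = c("a", "b"), chr = "c", bp = 1:2)
  g <- genotype_matrix(v, map)
  gp <- genotype_partition(g, "a", data.frame(w = rnorm(5)))
  expect_equal(as.character(unique(gp$class)), "Mm")
  expect_error(genotype_partition(g, "zz", data.frame(w = rnorm(5))),
               "not found")
})

test_that("null data give boundary (NA) or weak whole-vs-regional
           correlations, never spurious strong ones", {
  rs <- numeric(8)
  for (r in 1:8) {
    mp <- make_fit_pair(700 + r, n = 100, regional_var = c(0, 0))
    ec <- effect_correlations(mp$fits)
    rs[r] <- ec$r["whole.t1", "regional.t1"]
  }
  # with no regional signal the regional variance typically collapses to
  # the boundary, so most entries are reported as NA rather than masked 0
  expect_gte(sum(is.na(rs)), length(rs) / 2)
  expect_true(all(abs(rs[!is.na(rs)]) < 0.9))
})
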