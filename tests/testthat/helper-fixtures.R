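# shared fixtures, all built in code

# deterministic 4 x 6 genotype matrix, already major-oriented, no missing
toy_geno <- function() {
  v <- rbind(c(1, 0.5, 1, 0,   1, 0.5),
             c(1, 1,   1, 0.5, 1, 1),
             c(0.5, 1, 0.5, 1, 1, 0.5),
             c(1, 0.5, 1, 1,   0, 1))
  map <- data.frame(name = paste0("s", 1:6),
                    chr = rep(c("c1", "c2"), each = 3),
                    bp = c(100, 200, 300, 100, 200, 300))
  genotype_matrix(v, map, paste0("i", 1:4))
}

# small single-trait simulation config for fast model tests
fast_config <- function(seed, n = 200, snps = c(chr1 = 250, chr2 = 150),
                        regional_var = 0, regional_window = NULL, ...) {
  sim_config(n_individuals = n, chromosome_snp_counts = snps,
             traits = "y1", whole_var = 400, resid_var = 100,
             polygenic_corr = matrix(1, 1, 1),
             regional_window = regional_window,
             regional_var = regional_var,
             regional_corr = matrix(1, 1, 1),
             missing_rate = 0, seed = seed, ...)
}

# independent brute-force restricted log-likelihood (projection-matrix
# formula via solve/determinant, no Cholesky reuse with the implementation)
brute_reml_loglik <- function(y, Klist, variances) {
  n <- length(y)
  V <- diag(variances[length(variances)], n)
  for (i in seq_along(Klist)) V <- V + variances[i] * unclass(Klist[[i]])
  X <- matrix(1, n, 1)
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  P <- Vi - Vi %*% X %*% solve(XtViX) %*% t(X) %*% Vi
  ld_V <- determinant(V, logarithm = TRUE)$modulus
  ld_X <- determinant(XtViX, logarithm = TRUE)$modulus
  as.numeric(-0.5 * (ld_V + ld_X + t(y) %*% P %*% y + (n - 1) * log(2 * pi)))
}

# mixed-model-equation solve at fixed variances; requires invertible K
mme_solve <- function(y, Klist, variances) {
  n <- length(y)
  nk <- length(Klist)
  se <- variances[nk + 1]
  X <- matrix(1, n, 1)
  blocks <- 1 + nk
  M <- matrix(0, 1 + nk * n, 1 + nk * n)
  rhs <- numeric(1 + nk * n)
  M[1, 1] <- sum(rep(1, n)) / se
  rhs[1] <- sum(y) / se
  for (i in seq_len(nk)) {
    ri <- 1 + (i - 1) * n + seq_len(n)
    M[1, ri] <- rep(1, n) / se
    M[ri, 1] <- rep(1, n) / se
    rhs[ri] <- y / se
    for (j in seq_len(nk)) {
      rj <- 1 + (j - 1) * n + seq_len(n)
      M[ri, rj] <- diag(n) / se
    }
    M[ri, ri] <- M[ri, ri] + solve(unclass(Klist[[i]])) / variances[i]
  }
  sol <- solve(M, rhs)
  list(mu = sol[1],
       u = lapply(seq_len(nk), function(i) sol[1 + (i - 1) * n + seq_len(n)]))
}
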