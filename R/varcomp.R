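#' Restricted log-likelihood of a variance-component model
#'
#' Evaluates the REML log-likelihood of y ~ N(1*mu, V) with the intercept
#' profiled out, where V = sum_i sigma2_i K_i + sigma2_e I. The constant
#' -((n-1)/2) log(2*pi) is included, so differences between nested models
#' are directly usable as likelihood-ratio statistics.
#'
#' @param y numeric phenotype vector.
#' @param K list of relationship matrices (residual identity excluded).
#' @param variances non-negative vector of length `length(K) + 1`; the last
#'   element is the residual variance.
#' @return the restricted log-likelihood (scalar).
#' @export
reml_loglik <- function(y, K, variances) {
  n <- length(y)
  if (!is.list(K)) K <- list(K)
  stopifnot(length(variances) == length(K) + 1, all(variances >= 0))
  V <- diag(variances[length(variances)], n)
  for (i in seq_along(K)) V <- V + variances[i] * unclass(K[[i]])
  ch <- tryCatch(chol(V), error = function(e)
    stop("V is not positive definite; increase the GRM ridge", call. = FALSE))
  Vinv <- chol2inv(ch)
  Vinv1 <- rowSums(Vinv)
  xVx <- sum(Vinv1)
  Py <- Vinv %*% y - Vinv1 * (sum(Vinv1 * y) / xVx)
  -0.5 * (2 * sum(log(diag(ch))) + log(xVx) + sum(y * Py) +
            (n - 1) * log(2 * pi))
}

#' Fit a variance-component mixed model by AI-REML
#'
#' Maximizes the restricted likelihood of y = 1*mu + sum_i Z u_i + e over
#' the non-negative orthant using average-information updates with
#' step-halving and an expectation-maximization fallback. Variance
#' components proposed negative are projected to zero; a component pinned
#' at zero is dropped from the update and the rest re-optimized, and is
#' released again only if its boundary gradient turns positive.
#'
#' @param y numeric phenotype vector (one record per individual).
#' @param K named list of relationship matrices, e.g.
#'   `list(whole = G, regional = Q)`.
#' @param start optional starting variances (length `length(K) + 1`,
#'   residual last). Default: residual takes half the phenotypic variance,
#'   the genomic components split the remainder equally.
#' @param max_iter maximum iterations (default 200).
#' @param tol_logl convergence tolerance on the log-likelihood change.
#' @param tol_par convergence tolerance on the relative parameter change.
#' @param verbose print one line per iteration.
#' @return object of class `varcomp_fit`: `varcomp` (named estimates,
#'   residual last), `loglik`, `mu`, `blup` (named list of BLUP vectors,
#'   one per component in `K`), `resid` (estimated residual vector e-hat),
#'   `fitted_decomposition` check, `converged`, `iterations`, `boundary`
#'   (logical, component fixed at zero), `identifiable`, `n`.
#' @export
reml_fit <- function(y, K, start = NULL, max_iter = 200,
                     tol_logl = 1e-6, tol_par = 1e-8, verbose = FALSE) {
  if (!is.list(K)) K <- list(K)
  if (is.null(names(K)) || any(names(K) == ""))
    names(K) <- paste0("K", seq_along(K))
  n <- length(y)
  nk <- length(K)
  vy <- stats::var(y)
  if (!is.finite(vy) || vy <= 0)
    stop("phenotype has zero variance; nothing to fit")
  Ku <- lapply(K, unclass)
  comp_names <- c(names(K), "residual")
  np <- nk + 1
  theta <- if (is.null(start)) c(rep(vy / 2 / nk, nk), vy / 2) else {
    stopifnot(length(start) == np, all(start >= 0))
    pmax(start, 0)
  }
  floor_e <- 1e-10 * vy                  # residual floor keeps V invertible
  theta[np] <- max(theta[np], floor_e)
  active <- rep(TRUE, np)
  active[seq_len(nk)] <- theta[seq_len(nk)] > 0

  eval_parts <- function(th) {
    V <- diag(th[np], n)
    for (i in seq_len(nk)) if (th[i] > 0) V <- V + th[i] * Ku[[i]]
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) return(NULL)
    Vinv <- chol2inv(ch)
    Vinv1 <- rowSums(Vinv)
    xVx <- sum(Vinv1)
    Py <- drop(Vinv %*% y) - Vinv1 * (sum(Vinv1 * y) / xVx)
    logl <- -0.5 * (2 * sum(log(diag(ch))) + log(xVx) + sum(y * Py) +
                      (n - 1) * log(2 * pi))
    list(Vinv = Vinv, Vinv1 = Vinv1, xVx = xVx, Py = Py, logl = logl)
  }
  Pv <- function(parts, v)
    drop(parts$Vinv %*% v) - parts$Vinv1 * (sum(parts$Vinv1 * v) / parts$xVx)

  parts <- eval_parts(theta)
  if (is.null(parts))
    stop("V is not positive definite at the starting values; ",
         "increase the GRM ridge", call. = FALSE)
  logl <- parts$logl
  converged <- FALSE
  iter <- 0
  em_used <- FALSE
  ai_cond <- NA_real_

  while (iter < max_iter) {
    iter <- iter + 1
    Py <- parts$Py
    KPy <- vector("list", np)
    trPK <- numeric(np)
    for (i in seq_len(np)) {
      if (i <= nk) {
        KPy[[i]] <- drop(Ku[[i]] %*% Py)
        trPK[i] <- sum(parts$Vinv * Ku[[i]]) -
          sum(parts$Vinv1 * drop(Ku[[i]] %*% parts$Vinv1)) / parts$xVx
      } else {
        KPy[[i]] <- Py
        trPK[i] <- sum(diag(parts$Vinv)) - sum(parts$Vinv1^2) / parts$xVx
      }
    }
    yPKPy <- vapply(seq_len(np), function(i) sum(Py * KPy[[i]]), numeric(1))
    grad <- -0.5 * (trPK - yPKPy)

    # release boundary components whose gradient points inward, then
    # restart the iteration so derivatives are recomputed consistently
    released <- FALSE
    for (i in seq_len(nk)) if (!active[i] && grad[i] > 1e-8) {
      active[i] <- TRUE
      theta[i] <- 1e-6 * vy
      released <- TRUE
    }
    if (released) {
      parts <- eval_parts(theta)
      logl <- parts$logl
      next
    }

    act <- which(active)
    PKPy <- lapply(KPy[act], function(v) Pv(parts, v))
    na <- length(act)
    AI <- matrix(0, na, na)
    for (a in seq_len(na)) for (b in a:na) {
      AI[a, b] <- AI[b, a] <- 0.5 * sum(KPy[[act[a]]] * PKPy[[b]])
    }
    ai_cond <- tryCatch(rcond(AI), error = function(e) 0)
    delta <- if (ai_cond > 1e-12)
      tryCatch(solve(AI, grad[act]), error = function(e) NULL) else NULL

    step_ok <- FALSE
    if (!is.null(delta)) {
      s <- 1
      for (h in 1:12) {
        prop <- theta
        prop[act] <- pmax(theta[act] + s * delta, 0)
        prop[np] <- max(prop[np], floor_e)
        p2 <- eval_parts(prop)
        if (!is.null(p2) && is.finite(p2$logl) &&
            p2$logl >= logl - 1e-10) {
          step_ok <- TRUE
          break
        }
        s <- s / 2
      }
    }
    if (!step_ok) {                      # EM fallback (always ascending)
      em_used <- TRUE
      prop <- theta
      for (i in act) prop[i] <- theta[i] + theta[i]^2 *
          (yPKPy[i] - trPK[i]) / n
      prop <- pmax(prop, 0)
      prop[np] <- max(prop[np], floor_e)
      p2 <- eval_parts(prop)
      if (is.null(p2)) break
    }
    dlogl <- p2$logl - logl
    dpar <- max(abs(prop - theta) / pmax(theta, 1e-6 * vy))
    theta <- prop
    parts <- p2
    logl <- p2$logl
    # pin components that collapsed to (numerical) zero
    for (i in seq_len(nk)) if (active[i] && theta[i] < 1e-8 * vy) {
      theta[i] <- 0
      active[i] <- FALSE
    }
    if (verbose)
      message(sprintf("iter %3d logL %.6f  theta: %s", iter, logl,
                      paste(signif(theta, 5), collapse = " ")))
    if (abs(dlogl) < tol_logl && dpar < tol_par) {
      converged <- TRUE
      break
    }
  }

  mu <- sum(parts$Vinv1 * y) / parts$xVx
  blup <- stats::setNames(vector("list", nk), names(K))
  for (i in seq_len(nk))
    blup[[i]] <- if (theta[i] > 0) theta[i] * drop(Ku[[i]] %*% parts$Py)
      else numeric(n) # zero vector at the boundary
  for (i in seq_len(nk)) names(blup[[i]]) <- names(y)
  resid_hat <- theta[np] * parts$Py
  structure(list(
    varcomp = stats::setNames(theta, comp_names),
    loglik = logl, mu = mu, blup = blup, resid = resid_hat,
    converged = converged, iterations = iter,
    boundary = stats::setNames(!active[seq_len(nk)] | theta[seq_len(nk)] == 0,
                               names(K)),
    identifiable = is.na(ai_cond) || ai_cond > 1e-10,
    em_used = em_used, n = n, component_names = names(K)
  ), class = "varcomp_fit")
}

#' @export
print.varcomp_fit <- function(x, ...) {
  cat("REML variance-component fit (n =", x$n, ")\n")
  print(signif(x$varcomp, 5))
  cat(sprintf("logL = %.4f  mu = %.4f  %s in %d iterations\n", x$loglik,
              x$mu, if (x$converged) "converged" else "NOT converged",
              x$iterations))
  if (any(x$boundary))
    cat("components at the zero boundary:",
        paste(names(which(x$boundary)), collapse = ", "), "\n")
  if (!x$identifiable)
    cat("warning: average-information matrix near-singular;",
        "components may not be separately identifiable\n")
  invisible(x)
}

#' Extract BLUP random-effect predictions from a fit
#'
#' BLUPs are u-hat_i = sigma2_i K_i V^-1 (y - 1 mu-hat); together with the
#' estimated residual they reconstruct y - 1 mu-hat exactly.
#'
#' @param fit a `varcomp_fit`.
#' @param component component name as used in the `K` list passed to
#'   [reml_fit()] (e.g. `"whole"`, `"regional"`); default all.
#' @return a named numeric vector (single component) or list of vectors.
#' @export
blup <- function(fit, component = NULL) {
  stopifnot(inherits(fit, "varcomp_fit"))
  if (is.null(component)) return(fit$blup)
  if (!component %in% names(fit$blup))
    stop("no component '", component, "' in this fit (components: ",
         paste(names(fit$blup), collapse = ", "), ")", call. = FALSE)
  fit$blup[[component]]
}
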