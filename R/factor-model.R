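#' Horn's parallel analysis for the number of latent factors
#'
#' Compares the eigenvalues of an observed trait correlation matrix with the
#' mean eigenvalues of correlation matrices computed from simulated
#' standard-normal datasets of the same dimension (`n_obs x P`). The returned
#' number of factors is the length of the leading run of observed eigenvalues
#' strictly exceeding the corresponding simulated means.
#'
#' The comparison rule is Horn's original mean rule (not an upper quantile);
#' both the rule input `n_sims` and the achieved eigenvalue pairs are
#' returned so a scree plot can be drawn from the attributes.
#'
#' @param corr `P x P` trait correlation matrix (symmetric, unit diagonal).
#' @param n_obs Number of observations behind `corr` (>= 3). When `corr` was
#'   computed from pairwise-complete data, use the median pairwise-complete
#'   count.
#' @param n_sims Number of simulated null datasets (default 20).
#' @param seed Integer seed; deterministic given `seed`.
#' @return Integer count `K`, with attributes `observed` and `simulated`
#'   (mean) eigenvalue vectors.
#' @export
parallel_analysis <- function(corr, n_obs, n_sims = 20, seed = 1L) {
  corr <- as.matrix(corr)
  P <- nrow(corr)
  if (!isSymmetric(unname(corr), tol = 1e-8)) stop("'corr' must be symmetric")
  if (n_obs < 3) stop("'n_obs' must be at least 3")
  obs <- eigen(corr, symmetric = TRUE, only.values = TRUE)$values
  set.seed(as.integer(seed))
  sim <- matrix(0, n_sims, P)
  for (s in seq_len(n_sims)) {
    x <- matrix(stats::rnorm(n_obs * P), n_obs, P)
    sim[s, ] <- eigen(stats::cor(x), symmetric = TRUE, only.values = TRUE)$values
  }
  sim_mean <- colMeans(sim)
  exceeds <- obs > sim_mean
  K <- if (exceeds[1]) which.min(c(exceeds, FALSE)) - 1L else 0L
  structure(as.integer(K), observed = obs, simulated = sim_mean)
}

# Profile-likelihood objective for ML factor analysis: given uniquenesses psi,
# the optimal loadings come from the top-K eigenpairs of
# diag(psi)^-1/2 S diag(psi)^-1/2 and the profiled discrepancy reduces to
# sum over the discarded eigenvalues of (theta - log(theta) - 1).
.fa_profile <- function(logpsi, S, K) {
  psi <- exp(logpsi)
  isq <- 1 / sqrt(psi)
  Sstar <- isq * sweep(S, 2, isq, `*`)
  th <- eigen(Sstar, symmetric = TRUE, only.values = TRUE)$values
  tail_th <- th[-seq_len(K)]
  kept <- th[seq_len(K)]
  # kept eigenvalues below 1 get a zero loading, so they contribute to the
  # discrepancy like discarded ones (removes a flat direction at the boundary)
  sum(tail_th - log(tail_th) - 1) + sum((kept - log(kept) - 1)[kept < 1])
}

.fa_loadings <- function(psi, S, K) {
  isq <- 1 / sqrt(psi)
  e <- eigen(isq * sweep(S, 2, isq, `*`), symmetric = TRUE)
  # an excess eigenvalue below 1e-7 explains negligible common variance and
  # is numerically indistinguishable from the no-factor boundary: snap to 0
  lam <- sqrt(pmax(e$values[seq_len(K)] - 1, 0))
  lam[e$values[seq_len(K)] - 1 < 1e-7] <- 0
  L <- sqrt(psi) * e$vectors[, seq_len(K), drop = FALSE] *
    rep(lam, each = nrow(S))
  L
}

#' Maximum-likelihood factor analysis of a correlation matrix
#'
#' Minimises the ML discrepancy
#' `log det(Sigma) + tr(S Sigma^-1) - log det(S) - P` with
#' `Sigma = L L' + Psi` over the uniquenesses `Psi`, profiling out the
#' loadings (top-`K` eigenpairs of `Psi^-1/2 S Psi^-1/2`). Optimisation is
#' quasi-Newton (L-BFGS-B) on log-uniquenesses with a floor of 0.005 to
#' contain Heywood cases; the start is the squared-multiple-correlation proxy
#' `1 - 1/diag(S^-1)`.
#'
#' @param corr `P x P` correlation matrix.
#' @param K Number of factors, `1 <= K < P`, and small enough that the model
#'   degrees of freedom `((P-K)^2 - P - K)/2` are non-negative.
#' @param n_obs Number of observations behind `corr` (stored; used by callers
#'   for inference, not by the fit itself).
#' @param psi_floor Lower bound on uniquenesses.
#' @param tol Convergence tolerance on the discrepancy.
#' @param max_iter Iteration cap for the optimiser.
#' @return A `loading_matrix`: list with `loadings` (`P x K`, unrotated),
#'   `uniquenesses`, `discrepancy`, `converged`, `trace` (best-so-far
#'   discrepancy per accepted iteration), `n_obs`, `trait_names`,
#'   `factor_names`.
#' @export
fit_ml_factors <- function(corr, K, n_obs, psi_floor = 0.005,
                           tol = 1e-8, max_iter = 1000) {
  S <- as.matrix(corr)
  P <- nrow(S)
  if (K < 1 || K >= P) stop("'K' must satisfy 1 <= K < P")
  dof <- ((P - K)^2 - P - K) / 2
  if (dof < 0)
    stop(sprintf("K = %d is not identifiable for P = %d (degrees of freedom %.1f < 0)",
                 K, P, dof))
  smc <- tryCatch(1 - 1 / diag(solve(S)), error = function(e) rep(0.5, P))
  start <- pmin(pmax(1 - smc, psi_floor), 0.999)
  trace <- numeric(0)
  best <- Inf
  fn <- function(lp) {
    val <- .fa_profile(lp, S, K)
    if (val < best - tol) {
      best <<- val
      trace <<- c(trace, val)
    }
    val
  }
  opt <- stats::optim(log(start), fn, method = "L-BFGS-B",
                      lower = log(psi_floor), upper = log(1),
                      control = list(maxit = max_iter, factr = 10,
                                     pgtol = 1e-12))
  psi <- exp(opt$par)
  L <- .fa_loadings(psi, S, K)
  Sigma <- tcrossprod(L) + diag(psi, P)
  disc <- as.numeric(determinant(Sigma)$modulus -
                       determinant(S)$modulus +
                       sum(diag(solve(Sigma, S))) - P)
  converged <- opt$convergence == 0
  if (!converged) {
    # line-search failures at flat optima are convergence in all but name:
    # accept when the (projected) finite-difference gradient is negligible
    h <- 1e-6
    g <- vapply(seq_along(opt$par), function(j) {
      lp <- opt$par; lp[j] <- lp[j] - h
      (opt$value - .fa_profile(lp, S, K)) / h
    }, numeric(1))
    at_upper <- opt$par > -1e-12
    g[at_upper & g < 0] <- 0
    at_lower <- opt$par < log(psi_floor) + 1e-12
    g[at_lower & g > 0] <- 0
    converged <- sqrt(sum(g^2)) < 1e-4
    if (!converged)
      warning(sprintf("ML factor analysis did not converge in %d iterations (final gradient norm %.3g)",
                      max_iter, sqrt(sum(g^2))))
  }
  trait_names <- if (!is.null(rownames(S))) rownames(S) else sprintf("trait%d", seq_len(P))
  new_loading_matrix(L, psi, trait_names, sprintf("ML%d", seq_len(K)),
                     discrepancy = disc, converged = converged,
                     trace = trace, n_obs = n_obs)
}

new_loading_matrix <- function(L, uniquenesses, trait_names, factor_names,
                               ...) {
  L <- as.matrix(L)
  dimnames(L) <- list(trait_names, factor_names)
  structure(list(loadings = L, uniquenesses = uniquenesses,
                 trait_names = trait_names, factor_names = factor_names, ...),
            class = "loading_matrix")
}

#' @export
print.loading_matrix <- function(x, digits = 3, ...) {
  cat(sprintf("loading_matrix: %d traits x %d factors\n",
              nrow(x$loadings), ncol(x$loadings)))
  if (!is.null(x$discrepancy))
    cat(sprintf("  ML discrepancy %.6g (%s)\n", x$discrepancy,
                if (isTRUE(x$converged)) "converged" else "NOT converged"))
  comm <- rowSums(x$loadings^2)
  cat(sprintf("  communalities: min %.3f, median %.3f, max %.3f\n",
              min(comm), stats::median(comm), max(comm)))
  invisible(x)
}

#' Varimax rotation with deterministic column conventions
#'
#' Rotates a loading matrix by an orthogonal matrix maximising the varimax
#' criterion `sum_k [sum_i l_ik^4 - (sum_i l_ik^2)^2 / P]` using Kaiser's
#' pairwise planar-rotation algorithm (optimal angle per column pair from
#' the closed-form quartic solution, swept until no pair improves), with
#' Kaiser row-normalisation on by default. Columns are then sign-fixed so
#' each column's largest-magnitude loading is positive and ordered by
#' decreasing sum of squared loadings. Row communalities are unchanged by
#' the orthogonal rotation; the accumulated rotation matrix is checked for
#' orthogonality to 1e-8.
#'
#' @param L A `loading_matrix` or a plain numeric matrix.
#' @param tol Convergence tolerance on the rotation angles per sweep.
#' @param kaiser_normalize Normalise rows to unit communality during rotation.
#' @param max_sweeps Cap on pairwise-rotation sweeps.
#' @return The rotated `loading_matrix` (same class as input; communalities,
#'   uniquenesses preserved). `K = 1` inputs are returned with the sign
#'   convention applied only.
#' @export
rotate_varimax <- function(L, tol = 1e-10, kaiser_normalize = TRUE,
                           max_sweeps = 1000) {
  obj <- if (inherits(L, "loading_matrix")) L else NULL
  M <- if (is.null(obj)) as.matrix(L) else obj$loadings
  K <- ncol(M)
  if (K >= 2) {
    h <- sqrt(rowSums(M^2))
    scal <- ifelse(h > 0, h, 1)
    W <- if (kaiser_normalize) M / scal else M
    P <- nrow(W)
    R <- diag(K)
    for (sweep in seq_len(max_sweeps)) {
      max_angle <- 0
      for (j in seq_len(K - 1)) for (k in (j + 1):K) {
        x <- W[, j]; y <- W[, k]
        u <- x^2 - y^2; v <- 2 * x * y
        A <- sum(u); B <- sum(v)
        num <- sum(2 * u * v) - 2 * A * B / P
        den <- sum(u^2 - v^2) - (A^2 - B^2) / P
        phi <- 0.25 * atan2(num, den)
        if (abs(phi) > tol) {
          cs <- cos(phi); sn <- sin(phi)
          W[, j] <- x * cs + y * sn
          W[, k] <- -x * sn + y * cs
          rj <- R[, j]; rk <- R[, k]
          R[, j] <- rj * cs + rk * sn
          R[, k] <- -rj * sn + rk * cs
        }
        max_angle <- max(max_angle, abs(phi))
      }
      if (max_angle <= tol) break
    }
    if (max(abs(crossprod(R) - diag(K))) > 1e-8)
      stop("varimax rotation failed: rotation matrix is not orthogonal")
    M <- if (kaiser_normalize) W * scal else W
  }
  # deterministic conventions: dominant loading positive, columns by SS loadings
  sgn <- apply(M, 2, function(col) sign(col[which.max(abs(col))]))
  sgn[sgn == 0] <- 1
  M <- sweep(M, 2, sgn, `*`)
  ord <- order(colSums(M^2), decreasing = TRUE)
  M <- M[, ord, drop = FALSE]
  if (is.null(obj)) {
    colnames(M) <- sprintf("ML%d", seq_len(K))
    return(M)
  }
  obj$loadings <- M
  dimnames(obj$loadings) <- list(obj$trait_names, obj$factor_names)
  obj
}

#' Least-squares factor scores
#'
#' Evaluates `F = (L'L)^-1 L' (Y - Ybar)` columnwise over individuals, with
#' `Ybar` the per-trait sample mean, giving latent factor values per
#' individual. Requires complete trait data; with missing entries, derive
#' latent-factor association statistics from observed-trait summary
#' statistics instead (see [latent_sumstats()]).
#'
#' @param traits A `trait_matrix` (complete) or `n x P` numeric matrix.
#' @param L A `loading_matrix` or `P x K` matrix with full column rank.
#' @return A `factor_scores` object: list with `scores` (`n x K`, column
#'   means zero) and `factor_names`.
#' @export
factor_scores <- function(traits, L) {
  Y <- if (inherits(traits, "trait_matrix")) traits$values else as.matrix(traits)
  if (anyNA(Y))
    stop("trait matrix has missing entries; use the summary-statistics path (latent_sumstats) instead")
  M <- if (inherits(L, "loading_matrix")) L$loadings else as.matrix(L)
  if (ncol(Y) != nrow(M)) stop("ncol(traits) must equal nrow(L)")
  G <- crossprod(M)
  if (rcond(G) < 1e-12) stop("L'L is singular; factor scores are not identified")
  Yc <- sweep(Y, 2, colMeans(Y))
  Fs <- Yc %*% M %*% solve(G)
  fn <- if (!is.null(colnames(M))) colnames(M) else sprintf("ML%d", seq_len(ncol(M)))
  colnames(Fs) <- fn
  structure(list(scores = Fs, factor_names = fn), class = "factor_scores")
}

#' Scaled factor contributions
#'
#' Row-normalised squared loadings `C_ij = L_ij^2 / sum_k L_ik^2`: the
#' proportion of trait i's factor-explained variance attributable to factor
#' j. Rows of all-zero loadings yield all-zero contribution rows (flagged
#' with a warning). Traits are ordered by their maximum-contributing factor
#' in the returned `trait_order`.
#'
#' @param L A `loading_matrix` or `P x K` matrix.
#' @return A `contribution_matrix`: list with `contributions` (`P x K`, rows
#'   sum to 1), `signs` (sign of each loading), `trait_order` (trait names
#'   sorted by top-contributing factor, then by decreasing contribution), and
#'   `zero_rows`.
#' @export
factor_contributions <- function(L) {
  M <- if (inherits(L, "loading_matrix")) L$loadings else as.matrix(L)
  sq <- M^2
  rs <- rowSums(sq)
  zero <- rs == 0
  if (any(zero))
    warning(sum(zero), " trait(s) have all-zero loadings; contribution rows set to zero")
  C <- sq
  C[!zero, ] <- sq[!zero, , drop = FALSE] / rs[!zero]
  C[zero, ] <- 0
  signs <- sign(M)
  signs[signs == 0] <- 1
  tn <- if (!is.null(rownames(M))) rownames(M) else sprintf("trait%d", seq_len(nrow(M)))
  top <- max.col(C, ties.method = "first")
  topval <- C[cbind(seq_len(nrow(C)), top)]
  ord <- order(top, -topval)
  dimnames(C) <- dimnames(M)
  structure(list(contributions = C, signs = signs,
                 trait_order = tn[ord], zero_rows = zero),
            class = "contribution_matrix")
}

#' @export
print.contribution_matrix <- function(x, ...) {
  cat(sprintf("contribution_matrix: %d traits x %d factors\n",
              nrow(x$contributions), ncol(x$contributions)))
  invisible(x)
}

#' Write / read a loading or contribution matrix as TSV
#'
#' Trait rows, factor columns, first column `trait`.
#' @param x A `loading_matrix`, `contribution_matrix`, or matrix.
#' @param path Output path.
#' @export
write_loadings <- function(x, path) {
  M <- if (inherits(x, "loading_matrix")) x$loadings
  else if (inherits(x, "contribution_matrix")) x$contributions
  else as.matrix(x)
  tn <- rownames(M)
  if (is.null(tn)) {
    tn <- if (inherits(x, "loading_matrix") && !is.null(x$trait_names))
      x$trait_names else sprintf("trait%d", seq_len(nrow(M)))
  }
  if (is.null(colnames(M))) colnames(M) <- sprintf("ML%d", seq_len(ncol(M)))
  d <- data.frame(trait = tn, M, check.names = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}

#' @rdname write_loadings
#' @return `read_loadings()` returns a plain numeric matrix with trait
#'   rownames and factor colnames.
#' @export
read_loadings <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                         stringsAsFactors = FALSE)
  M <- as.matrix(d[, -1, drop = FALSE])
  rownames(M) <- d[[1]]
  M
}

#' Scree data from a parallel analysis
#'
#' @param pa Result of [parallel_analysis()].
#' @param path Output TSV path (factor index, observed and simulated-mean
#'   eigenvalues).
#' @export
write_scree <- function(pa, path) {
  d <- data.frame(factor = seq_along(attr(pa, "observed")),
                  observed = attr(pa, "observed"),
                  simulated = attr(pa, "simulated"))
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}
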