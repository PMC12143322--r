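test_that("parallel analysis returns 0 factors for pure noise and finds planted structure", {
  expect_equal(as.integer(parallel_analysis(diag(8), 1000, seed = 1)), 0L)

  # 2x2 with strong correlation: leading eigenvalue 1.9 vs null ~ 1 + O(n^-1/2)
  c2 <- matrix(c(1, 0.9, 0.9, 1), 2)
  expect_equal(as.integer(parallel_analysis(c2, 1000, seed = 2)), 1L)

  L3 <- matrix(0, 12, 3)
  for (i in 1:12) L3[i, ((i - 1) %% 3) + 1] <- sqrt(0.6)
  S3 <- tcrossprod(L3) + diag(1 - rowSums(L3^2))
  rec <- vapply(1:10, function(s) {
    X <- matrix(stats::rnorm(5000 * 12), 5000, 12) %*% chol(S3)
    as.integer(parallel_analysis(stats::cor(X), 5000, seed = s))
  }, integer(1))
  expect_gte(mean(rec == 3), 0.9)

  expect_error(parallel_analysis(matrix(c(1, 0.2, 0.5, 1), 2), 100), "symmetric")
  expect_error(parallel_analysis(diag(3), 2), "n_obs")
})

test_that("parallel analysis K never decreases when a strong factor is added", {
  for (s in 1:5) {
    set.seed(s)
    L2 <- matrix(0, 12, 2); for (i in 1:12) L2[i, ((i - 1) %% 2) + 1] <- sqrt(0.6)
    L3 <- cbind(L2 * sqrt(0.75), c(rep(0, 8), rep(0.5, 4)))
    mk <- function(L) {
      S <- tcrossprod(L) + diag(pmax(1 - rowSums(L^2), 0.05))
      X <- matrix(stats::rnorm(3000 * 12), 3000, 12) %*% chol(stats::cov2cor(S))
      as.integer(parallel_analysis(stats::cor(X), 3000, seed = 100 + s))
    }
    expect_gte(mk(L3), mk(L2))
  }
})

test_that("ML factor analysis recovers an exactly factor-structured correlation", {
  L <- matrix(0, 8, 2)
  L[1:4, 1] <- c(0.8, 0.7, 0.6, 0.75); L[5:8, 2] <- c(0.7, 0.8, 0.65, 0.6)
  S <- tcrossprod(L) + diag(1 - rowSums(L^2))
  fit <- fit_ml_factors(S, 2, 1000)
  expect_lt(max(abs(rowSums(fit$loadings^2) - rowSums(L^2))), 1e-4)
  Sig <- tcrossprod(fit$loadings) + diag(fit$uniquenesses)
  resid <- Sig - S; diag(resid) <- 0
  expect_lt(max(abs(resid)), 1e-6)
  expect_true(fit$converged)
  # monitored discrepancy trace is non-increasing
  expect_true(all(diff(fit$trace) <= 0))
})

test_that("ML factor analysis on an identity correlation finds no common variance", {
  fit <- fit_ml_factors(diag(6), 1, 500)
  expect_lt(max(abs(fit$loadings)), 1e-4)
  expect_true(all(fit$uniquenesses > 0.99))
})

test_that("fitted discrepancy is optimal against random perturbations", {
  set.seed(21)
  L <- matrix(stats::rnorm(12, 0, 0.6), 6, 2)
  S <- stats::cov2cor(tcrossprod(L) + diag(0.4, 6))
  fit <- fit_ml_factors(S, 2, 2000)
  disc <- function(L, psi) {
    Sig <- tcrossprod(L) + diag(psi)
    as.numeric(determinant(Sig)$modulus - determinant(S)$modulus +
                 sum(diag(solve(Sig, S))) - nrow(S))
  }
  worse <- vapply(1:100, function(i) {
    disc(fit$loadings + matrix(stats::rnorm(12, 0, 0.02), 6, 2),
         pmax(fit$uniquenesses + stats::rnorm(6, 0, 0.02), 0.005))
  }, numeric(1))
  expect_true(all(worse >= fit$discrepancy - 1e-10))
})

test_that("ML fit agrees with the reference factanal implementation", {
  set.seed(22)
  L <- matrix(0, 9, 2); for (i in 1:9) L[i, ((i - 1) %% 2) + 1] <- stats::runif(1, 0.5, 0.8)
  S <- tcrossprod(L) + diag(1 - rowSums(L^2))
  X <- matrix(stats::rnorm(4000 * 9), 4000, 9) %*% chol(S)
  R <- stats::cor(X)
  mine <- fit_ml_factors(R, 2, 4000)
  ref <- stats::factanal(covmat = R, factors = 2, n.obs = 4000, rotation = "none")
  expect_lt(max(abs(mine$uniquenesses - ref$uniquenesses)), 1e-4)
  expect_lt(max(abs(rowSums(mine$loadings^2) -
                      rowSums(unclass(ref$loadings)^2))), 1e-4)
})

test_that("unidentifiable factor counts are rejected", {
  expect_error(fit_ml_factors(diag(4), 3, 100), "identifiable")
  expect_error(fit_ml_factors(diag(4), 0, 100), "K")
})

test_that("varimax is a fixed point on simple structure and recovers random rotations", {
  set.seed(23)
  L <- matrix(0, 10, 3)
  for (i in 1:10) L[i, sample(3, 1)] <- stats::runif(1, 0.5, 0.9)
  canon <- rotate_varimax(L)
  # fixed point: rotating simple structure returns it (up to column order/sign)
  expect_lt(max(abs(rotate_varimax(canon) - canon)), 1e-8)
  for (s in 1:10) {
    set.seed(s)
    Q <- qr.Q(qr(matrix(stats::rnorm(9), 3, 3)))
    expect_lt(max(abs(rotate_varimax(L %*% Q) - canon)), 1e-6)
  }
})

test_that("varimax preserves communalities and the loading Gram matrix", {
  set.seed(24)
  L <- matrix(stats::rnorm(30, 0, 0.5), 10, 3)
  Lv <- rotate_varimax(L)
  expect_lt(max(abs(rowSums(Lv^2) - rowSums(L^2))), 1e-10)
  expect_lt(max(abs(tcrossprod(Lv) - tcrossprod(L))), 1e-8)
  # K = 1 is returned with sign convention only
  L1 <- matrix(-c(0.5, 0.7, 0.3), 3, 1)
  expect_equal(rotate_varimax(L1), abs(L1), ignore_attr = TRUE)
})

test_that("varimax criterion matches the reference rotation implementation", {
  set.seed(25)
  crit <- function(M) sum(apply(M^2, 2, function(cc) sum(cc^2) - sum(cc)^2 / length(cc)))
  L <- fit_ml_factors(stats::cov2cor(tcrossprod(matrix(stats::rnorm(18, 0, .6), 9, 2)) + diag(0.4, 9)),
                      2, 2000)$loadings
  mine <- crit(rotate_varimax(L, kaiser_normalize = FALSE))
  ref <- crit(stats::varimax(L, normalize = FALSE, eps = 1e-12)$loadings)
  expect_equal(mine, ref, tolerance = 1e-8)
})

test_that("factor scores invert the loading map exactly in the noiseless case", {
  set.seed(26)
  L <- matrix(stats::rnorm(12, 0, 0.7), 6, 2)
  Fa <- matrix(stats::rnorm(100 * 2), 100, 2)
  Y <- Fa %*% t(L)
  fs <- factor_scores(Y, L)
  Fc <- sweep(Fa, 2, colMeans(Fa))
  expect_equal(fs$scores, Fc, ignore_attr = TRUE, tolerance = 1e-12)
  expect_lt(max(abs(colMeans(fs$scores))), 1e-8)

  # orthonormal columns: scores reduce to L'(Y - Ybar)
  Lo <- qr.Q(qr(matrix(stats::rnorm(12), 6, 2)))
  Yo <- matrix(stats::rnorm(50 * 6), 50, 6)
  fso <- factor_scores(Yo, Lo)
  expect_equal(fso$scores, sweep(Yo, 2, colMeans(Yo)) %*% Lo,
               ignore_attr = TRUE, tolerance = 1e-12)

  Ym <- Y; Ym[1, 1] <- NA
  expect_error(factor_scores(Ym, L), "summary-statistics")
})

test_that("factor scores track the true factors in a simulated factor model", {
  set.seed(27)
  n <- 10000; P <- 20; K <- 4
  L <- matrix(0, P, K)
  for (i in 1:P) L[i, ((i - 1) %% K) + 1] <- sqrt(0.7)
  Fa <- matrix(stats::rnorm(n * K), n, K)
  Y <- Fa %*% t(L) + matrix(stats::rnorm(n * P), n, P) %*% diag(sqrt(1 - rowSums(L^2)))
  fs <- factor_scores(Y, L)
  expect_true(all(diag(stats::cor(fs$scores, Fa)) > 0.9))
  # scores of an orthogonal-factor model are near-uncorrelated
  off <- stats::cor(fs$scores); diag(off) <- 0
  expect_lt(max(abs(off)), 0.05)
})

test_that("factor contributions are row-normalised squared loadings", {
  C <- factor_contributions(matrix(c(0.6, 0.3), 1, 2))
  expect_equal(unname(C$contributions[1, ]), c(0.8, 0.2))
  C1 <- factor_contributions(matrix(c(0, 0.5, 0), 1, 3))
  expect_equal(unname(C1$contributions[1, ]), c(0, 1, 0))

  set.seed(28)
  Lr <- matrix(stats::rnorm(40), 10, 4)
  Cr <- factor_contributions(Lr)
  expect_lt(max(abs(rowSums(Cr$contributions) - 1)), 1e-12)
  expect_equal(Cr$signs, sign(Lr), ignore_attr = TRUE)

  Lz <- rbind(Lr, 0)
  expect_warning(Cz <- factor_contributions(Lz), "all-zero")
  expect_equal(unname(Cz$contributions[11, ]), rep(0, 4))
})

test_that("loadings and scree data round-trip through TSV", {
  set.seed(29)
  fit <- fit_ml_factors(stats::cov2cor(diag(5) + 0.3), 1, 1000)
  d <- withr::local_tempdir()
  write_loadings(fit, file.path(d, "l.tsv"))
  M <- read_loadings(file.path(d, "l.tsv"))
  expect_equal(M, fit$loadings, tolerance = 1e-6, ignore_attr = TRUE)
  pa <- parallel_analysis(diag(5), 500, seed = 1)
  write_scree(pa, file.path(d, "scree.tsv"))
  sc <- utils::read.table(file.path(d, "scree.tsv"), header = TRUE)
  expect_equal(sc$observed, attr(pa, "observed"))
})
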