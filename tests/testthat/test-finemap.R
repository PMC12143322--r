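toy_region <- function(z, R, n = 10000, bp = NULL) {
  p <- length(z)
  se <- rep(1 / sqrt(n), p)
  ss <- latentfm:::new_sumstats(data.frame(
    id = sprintf("v%d", seq_len(p)), chr = 1L,
    bp = if (is.null(bp)) seq_len(p) * 1000L else bp,
    effect_allele = "A", other_allele = "G", eaf = 0.3,
    beta = z * se, se = se, p = 2 * stats::pnorm(-abs(z)), info = 1,
    n = n, stringsAsFactors = FALSE), "toy")
  dimnames(R) <- list(ss$id, ss$id)
  region_data(ss, R, n = n)
}

ar1_corr <- function(p, r) r^abs(outer(seq_len(p), seq_len(p), `-`))

test_that("region data validates LD geometry", {
  R <- ar1_corr(3, 0.5)
  rd <- toy_region(c(0, 1, 2), R)
  expect_s3_class(rd, "region_data")
  bad <- R; bad[1, 2] <- 0.9
  expect_error(toy_region(c(0, 1, 2), bad), "symmetric")
  bad2 <- R; diag(bad2) <- c(1, 1, 2)
  expect_error(toy_region(c(0, 1, 2), bad2), "unit diagonal")
  npd <- matrix(c(1, 0.9, -0.9, 0.9, 1, 0.9, -0.9, 0.9, 1), 3)
  expect_error(toy_region(c(0, 1, 2), npd), "positive semi-definite")
})

test_that("model logBF matches its closed form and a quadrature oracle", {
  rd <- toy_region(c(0, 3, -2), ar1_corr(3, 0.4), n = 5000)
  expect_equal(model_logbf(rd, integer(0)), 0)

  # single SNP at z = 0: pure shrinkage, 0.5 log(V / (V + W)) with V = 1/n
  W <- 0.04^2; V <- 1 / 5000
  lb0 <- model_logbf(rd, 1)
  expect_lt(lb0, 0)
  expect_equal(as.numeric(lb0), 0.5 * log(V / (V + W)), tolerance = 1e-12)

  # numeric integration of the normal likelihood against the N(0, W) prior
  for (z in c(-2.5, 0.7, 4)) {
    rdz <- toy_region(c(z, 0), ar1_corr(2, 0), n = 5000)
    num <- stats::integrate(function(b)
      stats::dnorm(z, b / sqrt(V), 1) * stats::dnorm(b, 0, sqrt(W)),
      -Inf, Inf, rel.tol = 1e-12)$value
    oracle <- log(num / stats::dnorm(z))
    expect_equal(as.numeric(model_logbf(rdz, 1)), oracle, tolerance = 1e-6)
  }
})

test_that("vectorised size-2/3 scoring agrees with the generic matrix form", {
  set.seed(50)
  R <- ar1_corr(7, 0.7)
  z <- stats::rnorm(7, 0, 3)
  rd <- toy_region(z, R)
  mp <- enumerate_models(rd, 3)
  per_model <- vapply(seq_len(nrow(mp$models)), function(i) {
    ids <- if (mp$models$model[i] == "NULL") character(0)
    else strsplit(mp$models$model[i], ",")[[1]]
    as.numeric(model_logbf(rd, ids))
  }, numeric(1))
  expect_lt(max(abs(per_model - mp$models$logbf)), 1e-10)
})

test_that("enumeration equals an independent naive implementation", {
  for (s in 1:5) {
    set.seed(s)
    p <- sample(5:8, 1)
    R <- ar1_corr(p, stats::runif(1, 0.2, 0.8))
    z <- stats::rnorm(p, 0, 2.5)
    rd <- toy_region(z, R)
    mp <- enumerate_models(rd, 3)
    ref <- naive_enumerate(rd, 3)
    expect_lt(max(abs(mp$models$pp - ref$pp)), 1e-12)
    expect_lt(max(abs(unname(mp$mpp) - ref$mpp)), 1e-12)
  }
})

test_that("posterior probabilities normalise and MPPs are consistent with model PPs", {
  set.seed(51)
  rd <- toy_region(stats::rnorm(6, 0, 2), ar1_corr(6, 0.5))
  mp <- enumerate_models(rd, 2)
  expect_lt(abs(sum(mp$models$pp) - 1), 1e-10)
  mpp2 <- numeric(6); names(mpp2) <- mp$variant_ids
  for (i in seq_len(nrow(mp$models))) {
    if (mp$models$model[i] == "NULL") next
    ids <- strsplit(mp$models$model[i], ",")[[1]]
    mpp2[ids] <- mpp2[ids] + mp$models$pp[i]
  }
  expect_equal(mp$mpp, mpp2, tolerance = 1e-12)
  expect_true(all(mp$mpp >= 0 & mp$mpp <= 1))

  # null data: the null model dominates
  mp0 <- enumerate_models(toy_region(rep(0, 6), ar1_corr(6, 0.5)), 2)
  expect_equal(which.max(mp0$models$pp), which(mp0$models$model == "NULL"))

  expect_error(enumerate_models(toy_region(rep(0, 40), diag(40)), 10), "guard")
})

test_that("perfectly correlated variants are collapsed and re-expanded", {
  R3 <- ar1_corr(3, 0.3)
  R <- R3[c(1, 1, 2, 3), c(1, 1, 2, 3)]   # v1, v2 perfect proxies
  rd <- toy_region(c(5, 5, 1, 0), R)
  mp <- enumerate_models(rd, 2)
  expect_equal(mp$duplicate_of, c(NA, "v1", NA, NA))
  expect_equal(unname(mp$mpp["v2"]), unname(mp$mpp["v1"]))
  cs <- credible_set(mp)
  expect_true(all(c("v1", "v2") %in% cs$ids))
})

test_that("dynamic model-size selection identifies planted configurations", {
  # single strong causal among weakly linked variants
  set.seed(52)
  p <- 20
  R <- ar1_corr(p, 0.3)
  z <- as.vector(t(chol(R)) %*% stats::rnorm(p)) + 12 * R[, 10]
  mp <- dynamic_cmax(toy_region(z, R))
  expect_gt(mp$mpp["v10"], 0.95)
  top <- mp$models$model[which.max(mp$models$pp)]
  expect_equal(top, "v10")

  # two independent causals: the causal pair is the top model
  R2 <- diag(16)
  z2 <- stats::rnorm(16, 0, 0.5); z2[4] <- 10; z2[12] <- 10
  mp2 <- dynamic_cmax(toy_region(z2, R2))
  expect_gte(mp2$cmax_used, 2)
  expect_equal(mp2$models$model[which.max(mp2$models$pp)], "v4,v12")

  # null region: the null model stays modal
  set.seed(53)
  R3 <- ar1_corr(30, 0.6)
  z3 <- as.vector(t(chol(R3)) %*% stats::rnorm(30))
  mp3 <- dynamic_cmax(toy_region(z3, R3))
  expect_equal(mp3$models$model[which.max(mp3$models$pp)], "NULL")
})

test_that("the enumeration budget guards model-space growth", {
  set.seed(54)
  p <- 40
  R <- ar1_corr(p, 0.9)
  z <- as.vector(t(chol(R)) %*% stats::rnorm(p)) + 8 * R[, 20]
  mp <- dynamic_cmax(toy_region(z, R), max_models = 2000)
  expect_lte(sum(choose(sum(is.na(mp$duplicate_of)), 0:mp$cmax_used)), 2000)
  expect_true(mp$growth_guarded)
})

test_that("larger prior effect variance does not weaken a strong single-SNP model", {
  # monotone in W while the signal dominates the shrinkage penalty, i.e.
  # z^2 >= 1 + nW; checked at z = 8 across the plausible prior scale
  rd8 <- function(W) model_logbf(toy_region(c(8, 0), ar1_corr(2, 0.1)), 1,
                                 prior_var = W)
  vals <- vapply(c(1e-4, 4e-4, 1.6e-3, 3.6e-3), rd8, numeric(1))
  expect_true(all(diff(vals) >= 0))
})

test_that("credible sets are the smallest MPP-ranked prefix at the level", {
  ids <- sprintf("v%d", 1:3)
  mp1 <- make_mp(ids, list(character(0), "v2"), c(0, 1), bp = 1:3)
  cs1 <- credible_set(mp1)
  expect_equal(cs1$ids, "v2")

  ids100 <- sprintf("v%d", 1:100)
  mp100 <- make_mp(ids100, as.list(ids100), rep(0.01, 100), bp = 1:100)
  expect_equal(length(credible_set(mp100)$ids), 99L)

  # sort-oracle: smallest prefix of the mpp-sorted vector reaching the level
  for (s in 1:5) {
    set.seed(s)
    pp <- stats::runif(20); pp <- pp / sum(pp)
    mp <- make_mp(sprintf("v%d", 1:20), as.list(sprintf("v%d", 1:20)), pp)
    cs <- credible_set(mp, 0.9)
    srt <- sort(pp, decreasing = TRUE)
    expect_equal(length(cs$ids), which(cumsum(srt) >= 0.9)[1])
  }

  # unattainable level returns everything with a warning
  mp_low <- make_mp(ids, list(character(0), "v1"), c(0.5, 0.5), bp = 1:3)
  expect_warning(cs_low <- credible_set(mp_low), "below")
  expect_false(cs_low$attained)
})

test_that("variant groups follow single-linkage clustering of credible variants", {
  ids <- sprintf("v%d", 1:5)
  mp <- make_mp(ids, as.list(ids), c(0.4, 0.3, 0.2, 0.095, 0.005))
  # two LD blocks: {v1,v2} and {v3,v4}; v5 isolated and sub-threshold
  R <- diag(5)
  R[1, 2] <- R[2, 1] <- 0.95
  R[3, 4] <- R[4, 3] <- 0.92
  dimnames(R) <- list(ids, ids)
  vg <- group_variants(mp, R, mpp_min = 0.01, r2_min = 0.8)
  expect_equal(unname(vg$group[1:2]), c("1", "1"))
  expect_equal(unname(vg$group[3:4]), c("2", "2"))
  expect_equal(unname(vg$group[5]), "0")

  # all in perfect LD: one group
  R1 <- matrix(1, 3, 3); dimnames(R1) <- list(ids[1:3], ids[1:3])
  mp3 <- make_mp(ids[1:3], as.list(ids[1:3]), c(0.5, 0.3, 0.2))
  expect_equal(group_variants(mp3, R1)$n_groups, 1L)

  # all below the MPP floor: everything in group "0"
  mp0 <- make_mp(ids[1:3], list(character(0)), 1)
  expect_true(all(group_variants(mp0, R1)$group == "0"))
})

test_that("best-guess genotypes follow the certainty threshold and missingness rule", {
  G <- simulate_genotypes(10, 3, mafs = rep(0.3, 3), rho = 0, seed = 55)
  G$dosages[] <- 1
  G$dosages[1:2, 1] <- c(0.9, 1.15)   # within 0.2 of 1 -> hard call 1
  G$dosages[3:6, 2] <- 0.5            # unresolvable -> missing
  ld <- best_guess_ld(G, certainty = 0.2, min_nonmissing = 0.8)
  expect_equal(attr(ld, "excluded"), "rs1_2")  # 60% non-missing, excluded

  # integer dosages with no missingness equal plain Pearson correlation
  Gi <- simulate_genotypes(300, 4, mafs = rep(0.4, 4), rho = 0.5, seed = 56)
  ldi <- best_guess_ld(Gi)
  expect_equal(unclass(ldi), stats::cor(Gi$dosages), ignore_attr = TRUE)
})

test_that("credible sets cover the causal variant in simulated regions", {
  hits <- vapply(1:30, function(s) {
    cohort <- sim_region_cohort(7000 + s, n = 10000, p = 50, K = 1)
    mp <- dynamic_cmax(cohort$regions[[1]])
    cs <- suppressWarnings(credible_set(mp))
    cohort$causal_ids[1] %in% cs$ids
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})
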