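# Independent oracles and small fixture builders shared across tests.
# Everything here is written as straightforwardly as possible and kept
# independent of the package's computational paths.

# Multivariate normal log-density by direct determinant/solve evaluation.
mvn_logdens <- function(x, Sigma) {
  k <- length(x)
  -0.5 * (k * log(2 * pi) + as.numeric(determinant(Sigma)$modulus) +
            drop(crossprod(x, solve(Sigma, x))))
}

# Naive model enumeration: direct density-ratio Bayes factors and explicit
# normalisation, no shared code with the package's scoring internals.
naive_enumerate <- function(region, cmax, snp_prior = NULL,
                            prior_var = 0.04^2) {
  z <- region$ss$beta / region$ss$se
  R <- region$ld
  p <- length(z)
  if (is.null(snp_prior)) snp_prior <- 1 / p
  phi <- region$n * prior_var / region$trait_var
  models <- list(integer(0))
  for (s in seq_len(cmax))
    models <- c(models, lapply(asplit(utils::combn(p, s), 2), as.integer))
  logbf <- vapply(models, function(g) {
    if (!length(g)) return(0)
    Rg <- R[g, g, drop = FALSE]
    mvn_logdens(z[g], Rg + phi * Rg %*% Rg) - mvn_logdens(z[g], Rg)
  }, numeric(1))
  sizes <- lengths(models)
  logprior <- sizes * log(snp_prior) + (p - sizes) * log1p(-snp_prior)
  w <- exp(logprior + logbf - max(logprior + logbf))
  pp <- w / sum(w)
  mpp <- numeric(p)
  for (i in seq_along(models)) mpp[models[[i]]] <- mpp[models[[i]]] + pp[i]
  list(models = models, logbf = logbf, pp = pp, mpp = mpp)
}

# Hand-constructed model_posteriors (for credible-set / sharing tests that
# need exact posteriors independent of any data).
make_mp <- function(ids, models, pp, bp = seq_along(ids)) {
  stopifnot(length(models) == length(pp), abs(sum(pp) - 1) < 1e-12)
  model_str <- vapply(models, function(m)
    if (!length(m)) "NULL" else paste(sort(m), collapse = ","), character(1))
  mpp <- numeric(length(ids))
  names(mpp) <- ids
  for (i in seq_along(models))
    if (length(models[[i]]))
      mpp[models[[i]]] <- mpp[models[[i]]] + pp[i]
  structure(list(
    models = data.frame(model = model_str, size = lengths(models),
                        logbf = NA_real_, prior = NA_real_, pp = pp,
                        stringsAsFactors = FALSE),
    mpp = mpp, cmax_used = max(lengths(models)), variant_ids = ids,
    duplicate_of = rep(NA_character_, length(ids)),
    snp_prior = NA_real_, prior_var = NA_real_, bp = bp
  ), class = "model_posteriors")
}

# Brute-force trait-adjusted posteriors for the focal trait, enumerating all
# partner model combinations with pairwise sharing factors against the focal
# model (M = 2 or 3 partners lists).
joint_adjust_oracle <- function(focal, partners, p, kappa) {
  get_ids <- function(mp) lapply(strsplit(mp$models$model, ",", fixed = TRUE),
                                 function(v) setdiff(v, "NULL"))
  fi <- get_ids(focal)
  pair_factor <- function(a, b) {
    kappa^(length(intersect(a, b)) > 0) *
      compute_tau(p, kappa, length(a), length(b))
  }
  adj <- numeric(length(fi))
  for (i in seq_along(fi)) {
    contrib <- focal$models$pp[i]
    for (u in partners) {
      ui <- get_ids(u)
      s <- 0
      for (j in seq_along(ui))
        s <- s + u$models$pp[j] * pair_factor(fi[[i]], ui[[j]])
      contrib <- contrib * s
    }
    adj[i] <- contrib
  }
  adj / sum(adj)
}

# Exhaustive size-marginal consistency error of the (kappa, tau) prior:
# sum over all model pairs of p_i p_j kappa^overlap tau, relative to the
# product of the marginal sums (uniform prior within each size).
tau_consistency_relerr <- function(p, kappa, s1, s2) {
  m1 <- if (s1 == 0) list(integer(0)) else asplit(utils::combn(p, s1), 2)
  m2 <- if (s2 == 0) list(integer(0)) else asplit(utils::combn(p, s2), 2)
  tau <- compute_tau(p, kappa, s1, s2)
  tot <- 0
  for (a in m1) for (b in m2)
    tot <- tot + kappa^(length(intersect(a, b)) > 0) * tau
  abs(tot - length(m1) * length(m2)) / (length(m1) * length(m2))
}

# Simulated single-region cohort: K factors sharing (or not) planted causal
# variants, factor scores standardised, per-factor GWAS plus in-sample LD.
sim_region_cohort <- function(seed, n = 10000, p = 50, K = 3, rho = 0.9,
                              effect = 0.10, causal_idx = max(1, round(p / 2)),
                              shared = TRUE) {
  G <- simulate_genotypes(n, p, mafs = stats::runif(p, 0.1, 0.5), rho = rho,
                          seed = seed)
  if (shared) {
    causal <- rep(causal_idx[1], K)
  } else {
    causal <- rep_len(causal_idx, K)
  }
  cm <- lapply(seq_len(K), function(k)
    stats::setNames(effect, G$variants$id[causal[k]]))
  sim <- simulate_factor_traits(G, diag(K), cm, factor_noise_sd = 1,
                                trait_noise_sd = 0, seed = seed + 500000L)
  ld <- stats::cor(G$dosages)
  regions <- lapply(seq_len(K), function(k) {
    ss <- gwas_ols(G, scale(sim$truth$factor_scores[, k]), sprintf("F%d", k))
    region_data(ss, ld)
  })
  names(regions) <- sprintf("F%d", seq_len(K))
  list(regions = regions, causal_ids = G$variants$id[causal], G = G, ld = ld)
}

# Factor cohort with correlated traits for the latent-GWAS identity tests.
sim_factor_cohort <- function(seed, n = 2000, P = 12, K = 3, p = 300,
                              effects = c(0.3, 0.25, 0)) {
  set.seed(seed)
  L <- matrix(0, P, K)
  for (i in seq_len(P)) L[i, ((i - 1) %% K) + 1] <- stats::runif(1, 0.6, 0.9)
  L <- L + matrix(stats::rnorm(P * K, 0, 0.05), P, K)
  G <- simulate_genotypes(n, p, mafs = stats::runif(p, 0.05, 0.5), rho = 0.5,
                          seed = seed + 1L)
  cm <- lapply(seq_len(K), function(k) {
    if (effects[k] == 0) numeric(0)
    else stats::setNames(effects[k], G$variants$id[round(p * k / (K + 1))])
  })
  sim <- simulate_factor_traits(G, L, cm, factor_noise_sd = 1,
                                trait_noise_sd = 0.5, seed = seed + 2L)
  Ys <- scale(sim$traits$values)
  tables <- lapply(seq_len(P), function(j) gwas_ols(G, Ys[, j], sprintf("t%d", j)))
  list(G = G, L = L, Ys = Ys, tables = tables, truth = sim$truth)
}
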