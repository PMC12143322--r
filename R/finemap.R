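#' Bundle summary statistics and LD for one region
#'
#' Validates that the LD matrix is symmetric with unit diagonal and matches
#' the variant order of the summary statistics, and records the sample size
#' used by the Bayes-factor computation.
#'
#' @param ss A `sumstats` table restricted to the region.
#' @param ld Square variant correlation matrix over the same variants, in the
#'   same order (row/col names, if present, must match `ss$id`).
#' @param n GWAS sample size (defaults to the median of `ss$n`).
#' @param trait_var Trait variance (1 for standardised traits).
#' @return A `region_data` object.
#' @export
region_data <- function(ss, ld, n = NULL, trait_var = 1) {
  stopifnot(inherits(ss, "data.frame"))
  ld <- as.matrix(ld)
  p <- nrow(ss)
  if (!all(dim(ld) == p)) stop("LD matrix dimension must match the number of variants")
  if (!is.null(rownames(ld)) && !identical(rownames(ld), ss$id))
    stop("LD matrix variant order differs from the summary statistics")
  if (max(abs(ld - t(ld))) > 1e-8) stop("LD matrix must be symmetric")
  if (max(abs(diag(ld) - 1)) > 1e-8) stop("LD matrix must have unit diagonal")
  ev_min <- min(eigen((ld + t(ld)) / 2, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min < -1e-8)
    stop(sprintf("LD matrix is not positive semi-definite (min eigenvalue %.3g)", ev_min))
  if (is.null(n)) n <- stats::median(ss$n)
  dimnames(ld) <- list(ss$id, ss$id)
  structure(list(ss = ss, ld = ld, n = n, trait_var = trait_var),
            class = "region_data")
}

#' @export
print.region_data <- function(x, ...) {
  cat(sprintf("region_data: %d variants (chr %s), n = %d, min p = %.3g\n",
              nrow(x$ss), paste(unique(x$ss$chr), collapse = ","),
              as.integer(x$n), suppressWarnings(min(x$ss$p))))
  invisible(x)
}

# Collapse variants in perfect LD (|r| = 1 up to 1e-10) to one representative
# before model enumeration; returns index of representatives and, for each
# variant, its representative.
.collapse_duplicates <- function(ld) {
  p <- nrow(ld)
  rep_of <- seq_len(p)
  for (j in seq_len(p)) {
    if (rep_of[j] != j) next
    dup <- which(abs(abs(ld[j, ]) - 1) < 1e-10)
    dup <- dup[dup > j]
    rep_of[dup[rep_of[dup] == dup]] <- j
  }
  list(reps = which(rep_of == seq_len(p)), rep_of = rep_of)
}

#' Log Bayes factor of a multi-SNP model against the null
#'
#' Conjugate multivariate-normal Bayes factor computed from z-scores and LD:
#' under the null the model's z-vector is N(0, R); under the alternative the
#' standardised effects have independent N(0, W) priors, giving marginal
#' z ~ N(0, R + n W R R). Hence
#' `logBF = 0.5 * (logdet R - logdet A) + 0.5 * (z' R^-1 z - z' A^-1 z)` with
#' `A = R + nW R R`. A single SNP reduces to the familiar shrinkage form
#' `0.5 * log(V / (V + W)) + 0.5 * z^2 W / (V + W)` with `V = 1/n` (the
#' squared standard error of a standardised effect). Near-singular `R`
#' (perfect proxies) receives a ridge of 1e-6, flagged in the `ridged`
#' attribute.
#'
#' @param region A `region_data`.
#' @param model Integer indices or variant ids forming the model (empty =
#'   null model, logBF 0).
#' @param prior_var Per-SNP prior effect variance `W` on standardised
#'   effects (default 0.04^2).
#' @return The log Bayes factor (numeric scalar).
#' @export
model_logbf <- function(region, model, prior_var = 0.04^2) {
  stopifnot(inherits(region, "region_data"))
  if (is.character(model)) model <- match(model, region$ss$id)
  if (anyNA(model)) stop("model contains unknown variant ids")
  m <- length(model)
  if (m == 0) return(0)
  z <- region$ss$beta[model] / region$ss$se[model]
  R <- region$ld[model, model, drop = FALSE]
  phi <- region$n * prior_var / region$trait_var
  .logbf_core(z, R, phi)
}

.logbf_core <- function(z, R, phi) {
  m <- length(z)
  ridged <- FALSE
  if (m == 1) {
    return(structure(-0.5 * log1p(phi) + 0.5 * z^2 * phi / (1 + phi),
                     ridged = FALSE))
  }
  if (rcond(R) < 1e-10) {
    R <- R + diag(1e-6, m)
    ridged <- TRUE
  }
  A <- R + phi * (R %*% R)
  q1 <- drop(crossprod(z, solve(R, z)))
  q2 <- drop(crossprod(z, solve(A, z)))
  ld_r <- as.numeric(determinant(R)$modulus)
  ld_a <- as.numeric(determinant(A)$modulus)
  structure(0.5 * (ld_r - ld_a) + 0.5 * (q1 - q2), ridged = ridged)
}

# Vectorised logBF over all size-2 models given index pairs (i, j).
.logbf_pairs <- function(z, R, phi, i, j) {
  r <- R[cbind(i, j)]
  r2 <- r * r
  z1 <- z[i]; z2 <- z[j]
  det_r <- pmax(1 - r2, 1e-12)
  a <- 1 + phi * (1 + r2)
  b <- r * (1 + 2 * phi)
  det_a <- a * a - b * b
  q1 <- (z1 * z1 + z2 * z2 - 2 * r * z1 * z2) / det_r
  q2 <- (a * (z1 * z1 + z2 * z2) - 2 * b * z1 * z2) / det_a
  0.5 * (log(det_r) - log(det_a)) + 0.5 * (q1 - q2)
}

# Vectorised logBF over size-3 models via closed-form 3x3 determinants and
# adjugates: A = R(I + phi R), logdet A = logdet R + logdet(I + phi R) with
# det(I + phi R) = 1 + 3 phi + phi^2 e2 + phi^3 det R (elementary symmetric
# functions of R's eigenvalues), and q1 - q2 = z'R^-1 z - z'(I+phi R)^-1 R^-1 z.
.logbf_triples <- function(z, R, phi, i, j, k) {
  r12 <- R[cbind(i, j)]; r13 <- R[cbind(i, k)]; r23 <- R[cbind(j, k)]
  z1 <- z[i]; z2 <- z[j]; z3 <- z[k]
  det_r <- 1 + 2 * r12 * r13 * r23 - r12^2 - r13^2 - r23^2
  det_r <- pmax(det_r, 1e-12)
  e2 <- 3 - (r12^2 + r13^2 + r23^2)
  det_b <- 1 + 3 * phi + phi^2 * e2 + phi^3 * det_r
  # y = R^-1 z via the adjugate of R
  a11 <- 1 - r23^2; a22 <- 1 - r13^2; a33 <- 1 - r12^2
  a12 <- r13 * r23 - r12; a13 <- r12 * r23 - r13; a23 <- r12 * r13 - r23
  y1 <- (a11 * z1 + a12 * z2 + a13 * z3) / det_r
  y2 <- (a12 * z1 + a22 * z2 + a23 * z3) / det_r
  y3 <- (a13 * z1 + a23 * z2 + a33 * z3) / det_r
  q1 <- z1 * y1 + z2 * y2 + z3 * y3
  # w = (I + phi R)^-1 y via the adjugate of B = I + phi R
  b <- 1 + phi; c12 <- phi * r12; c13 <- phi * r13; c23 <- phi * r23
  B11 <- b * b - c23^2; B22 <- b * b - c13^2; B33 <- b * b - c12^2
  B12 <- c13 * c23 - c12 * b; B13 <- c12 * c23 - c13 * b
  B23 <- c12 * c13 - c23 * b
  w1 <- (B11 * y1 + B12 * y2 + B13 * y3) / det_b
  w2 <- (B12 * y1 + B22 * y2 + B23 * y3) / det_b
  w3 <- (B13 * y1 + B23 * y2 + B33 * y3) / det_b
  q2 <- z1 * w1 + z2 * w2 + z3 * w3
  -0.5 * log(det_b) + 0.5 * (q1 - q2)
}

# Eigen-decomposition logBF for arbitrary model size (used for sizes >= 4):
# with R = Q diag(lam) Q' and u = Q'z, logdet(I + phi R) = sum log(1 + phi lam)
# and q1 - q2 = sum u^2 phi / (1 + phi lam).
.logbf_eigen <- function(z, R, phi) {
  e <- eigen(R, symmetric = TRUE)
  lam <- e$values
  if (min(lam) < 1e-8) lam <- lam + 1e-6
  u <- drop(crossprod(e$vectors, z))
  -0.5 * sum(log1p(phi * lam)) + 0.5 * sum(u^2 * phi / (1 + phi * lam))
}

# Score every model of sizes 0..cmax on the collapsed representative set.
.score_models <- function(z, R, phi, cmax, snp_prior) {
  p <- length(z)
  models <- list(integer(0))
  logbf <- 0
  sizes <- 0L
  for (s in seq_len(cmax)) {
    if (s > p) break
    idx <- utils::combn(p, s)
    if (s == 1) {
      bf <- -0.5 * log1p(phi) + 0.5 * z^2 * phi / (1 + phi)
    } else if (s == 2) {
      bf <- .logbf_pairs(z, R, phi, idx[1, ], idx[2, ])
    } else if (s == 3) {
      bf <- .logbf_triples(z, R, phi, idx[1, ], idx[2, ], idx[3, ])
    } else {
      bf <- apply(idx, 2, function(g) .logbf_eigen(z[g], R[g, g, drop = FALSE], phi))
    }
    models <- c(models, lapply(seq_len(ncol(idx)), function(c) idx[, c]))
    logbf <- c(logbf, bf)
    sizes <- c(sizes, rep(s, ncol(idx)))
  }
  logprior <- sizes * log(snp_prior) + (p - sizes) * log1p(-snp_prior)
  lp <- logprior + logbf
  pp <- exp(lp - max(lp))
  pp <- pp / sum(pp)
  list(models = models, logbf = logbf, sizes = sizes,
       prior = exp(logprior), pp = pp)
}

#' Enumerate and score all causal-variant models up to a maximum size
#'
#' Scores every model of size 0..`cmax` with [model_logbf()], an independent
#' Bernoulli model-space prior `snp_prior^|m| (1-snp_prior)^(p-|m|)`, and
#' normalises posterior probabilities over the enumeration. Variants in
#' perfect LD are collapsed to a representative before enumeration and
#' expanded back afterwards (duplicates share their representative's
#' marginal posterior probability, flagged in `duplicate_of`).
#'
#' @param region A `region_data`.
#' @param cmax Maximum model size; the total number of models must not
#'   exceed 5e6.
#' @param snp_prior Per-SNP Bernoulli prior inclusion probability (default
#'   `1/p`, one expected causal variant per region).
#' @param prior_var Per-SNP prior effect variance (see [model_logbf()]).
#' @return A `model_posteriors` object: list with `models` (data.frame:
#'   `model` comma-separated ids, `size`, `logbf`, `prior`, `pp`), `mpp`
#'   (named per-variant marginal posterior probabilities), `cmax_used`,
#'   `variant_ids`, `duplicate_of`, `snp_prior`, `prior_var`.
#' @export
enumerate_models <- function(region, cmax, snp_prior = NULL,
                             prior_var = 0.04^2) {
  stopifnot(inherits(region, "region_data"))
  ids <- region$ss$id
  coll <- .collapse_duplicates(region$ld)
  reps <- coll$reps
  p <- length(reps)
  if (is.null(snp_prior)) snp_prior <- 1 / p
  n_models <- sum(choose(p, 0:min(cmax, p)))
  if (n_models > 5e6)
    stop(sprintf("enumeration of %.3g models exceeds the 5e6 guard; reduce cmax or thin the region",
                 n_models))
  z <- (region$ss$beta / region$ss$se)[reps]
  R <- region$ld[reps, reps, drop = FALSE]
  phi <- region$n * prior_var / region$trait_var
  sc <- .score_models(z, R, phi, cmax, snp_prior)

  mpp_rep <- numeric(p)
  for (i in seq_along(sc$models)) {
    g <- sc$models[[i]]
    if (length(g)) mpp_rep[g] <- mpp_rep[g] + sc$pp[i]
  }
  # expand to the full variant set: each duplicate inherits its
  # representative's MPP
  mpp <- mpp_rep[match(coll$rep_of, reps)]
  names(mpp) <- ids
  model_str <- vapply(sc$models, function(g)
    paste(ids[reps[g]], collapse = ","), character(1))
  model_str[model_str == ""] <- "NULL"
  structure(list(
    models = data.frame(model = model_str, size = sc$sizes,
                        logbf = sc$logbf, prior = sc$prior, pp = sc$pp,
                        stringsAsFactors = FALSE),
    mpp = mpp, cmax_used = as.integer(cmax), variant_ids = ids,
    duplicate_of = ifelse(coll$rep_of == seq_along(ids), NA_character_,
                          ids[coll$rep_of]),
    snp_prior = snp_prior, prior_var = prior_var,
    bp = region$ss$bp
  ), class = "model_posteriors")
}

#' @export
print.model_posteriors <- function(x, n = 5, ...) {
  cat(sprintf("model_posteriors: %d variants, %d models (cmax = %d)\n",
              length(x$mpp), nrow(x$models), x$cmax_used))
  top <- x$models[order(-x$models$pp), ][seq_len(min(n, nrow(x$models))), ]
  cat("  top models:\n")
  for (i in seq_len(nrow(top)))
    cat(sprintf("    %-30s PP = %.3f\n", top$model[i], top$pp[i]))
  invisible(x)
}

#' @export
summary.model_posteriors <- function(object, ...) {
  mpp <- sort(object$mpp, decreasing = TRUE)
  data.frame(id = names(mpp), mpp = unname(mpp), stringsAsFactors = FALSE)
}

#' Fine-map with data-driven maximum model size
#'
#' Starts at `cmax = 1` and increments the maximum model size while the
#' posterior mass on models of the current maximum size exceeds
#' `growth_threshold` (and `cmax < 10`), re-normalising over the grown
#' enumeration each time. The final enumeration is returned with
#' `cmax_used` recorded.
#'
#' @inheritParams enumerate_models
#' @param growth_threshold Posterior mass at the boundary size required to
#'   grow the model space (default 0.05).
#' @param max_models Enumeration budget guard: the model space stops growing
#'   once the next size would push the enumeration past this count (default
#'   1e5), so that wide regions in strong LD are fine-mapped at a bounded
#'   model size rather than by exhaustive search of very large spaces. The
#'   `growth_guarded` field records whether the budget (rather than the
#'   posterior-mass rule) stopped the growth.
#' @return A `model_posteriors` object (see [enumerate_models()]).
#' @export
dynamic_cmax <- function(region, snp_prior = NULL, prior_var = 0.04^2,
                         growth_threshold = 0.05, max_models = 1e5) {
  cmax <- 1L
  guarded <- FALSE
  repeat {
    mp <- enumerate_models(region, cmax, snp_prior, prior_var)
    boundary_mass <- sum(mp$models$pp[mp$models$size == cmax])
    if (boundary_mass <= growth_threshold || cmax >= 10L ||
        cmax >= length(mp$mpp)) break
    p_eff <- sum(is.na(mp$duplicate_of))
    if (sum(choose(p_eff, 0:(cmax + 1L))) > max_models) {
      guarded <- TRUE
      break
    }
    cmax <- cmax + 1L
  }
  mp$growth_guarded <- guarded
  mp
}

#' 99% credible set from marginal posterior probabilities
#'
#' Ranks variants by decreasing marginal posterior probability (ties broken
#' by ascending base-pair position) and accumulates until the cumulative MPP
#' reaches `level`. Variants in perfect LD with a selected representative
#' are appended alongside it (they are statistically indistinguishable).
#'
#' @param mp A `model_posteriors` object.
#' @param level Credible level (default 0.99).
#' @return A `credible_set`: list with `ids` (ordered), `cumulative_mpp`,
#'   `mpp`, `level`, `attained` (whether the level was reachable).
#' @export
credible_set <- function(mp, level = 0.99) {
  stopifnot(inherits(mp, "model_posteriors"))
  is_rep <- is.na(mp$duplicate_of)
  mpp <- mp$mpp[is_rep]
  bp <- mp$bp[is_rep]
  ord <- order(-mpp, bp)
  cum <- cumsum(mpp[ord])
  total <- cum[length(cum)]
  if (total < level) {
    warning(sprintf("total MPP %.3f is below the %.2f level; returning all variants", total, level))
    k <- length(ord)
  } else {
    k <- which(cum >= level)[1]
  }
  ids <- names(mpp)[ord[seq_len(k)]]
  # expand perfect-LD duplicates of selected representatives
  dup <- mp$variant_ids[!is.na(mp$duplicate_of) & mp$duplicate_of %in% ids]
  structure(list(ids = c(ids, dup), cumulative_mpp = cum[seq_len(k)],
                 mpp = unname(mpp[ord[seq_len(k)]]), level = level,
                 attained = total >= level),
            class = "credible_set")
}

#' @export
print.credible_set <- function(x, ...) {
  cat(sprintf("credible_set (level %.2f): %d variants, top MPP %.3f (%s)\n",
              x$level, length(x$ids), x$mpp[1], x$ids[1]))
  invisible(x)
}

#' Group credible variants by linkage disequilibrium
#'
#' Single-linkage clustering of variants with MPP above `mpp_min`, joining
#' variants with pairwise `r^2 > r2_min`; groups are labelled "1", "2", ...
#' by decreasing maximum-MPP member, and variants below `mpp_min` get group
#' "0".
#'
#' @param mp A `model_posteriors` object.
#' @param ld LD (correlation) matrix over `mp$variant_ids` in order.
#' @param mpp_min MPP threshold for group membership (default 0.01).
#' @param r2_min r^2 threshold for linkage (default 0.8).
#' @return A `variant_groups` object: list with `group` (character vector
#'   named by variant id) and `n_groups`.
#' @export
group_variants <- function(mp, ld, mpp_min = 0.01, r2_min = 0.8) {
  stopifnot(inherits(mp, "model_posteriors"))
  ld <- as.matrix(ld)
  p <- length(mp$mpp)
  grp <- rep("0", p)
  names(grp) <- mp$variant_ids
  cand <- which(mp$mpp > mpp_min)
  if (length(cand)) {
    # union-find over r2 > r2_min edges (single linkage = connected components)
    parent <- seq_along(cand)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    r2 <- ld[cand, cand, drop = FALSE]^2
    for (a in seq_along(cand)) for (b in seq_len(a - 1L)) {
      if (r2[a, b] > r2_min) {
        ra <- find(a); rb <- find(b)
        if (ra != rb) parent[ra] <- rb
      }
    }
    comp <- vapply(seq_along(cand), find, integer(1))
    comp_max <- tapply(mp$mpp[cand], comp, max)
    lab <- rank(-comp_max, ties.method = "first")
    grp[cand] <- as.character(lab[as.character(comp)])
  }
  structure(list(group = grp, n_groups = length(unique(grp[grp != "0"]))),
            class = "variant_groups")
}

#' LD from best-guess genotypes with a certainty threshold
#'
#' Maps each fractional dosage to the nearest hard genotype in {0, 1, 2}
#' when within `certainty` of it and to missing otherwise, drops variants
#' whose non-missing proportion falls below `min_nonmissing`, and computes
#' Pearson correlations on pairwise-complete individuals.
#'
#' @param G A `genotype_matrix` (dosages in `[0, 2]`, possibly fractional).
#' @param certainty Maximum distance from a hard call (default 0.2).
#' @param min_nonmissing Minimum per-variant non-missing proportion after
#'   thresholding (default 0.8).
#' @return Correlation matrix over the retained variants (ids as dimnames),
#'   with attribute `excluded` listing dropped variant ids.
#' @export
best_guess_ld <- function(G, certainty = 0.2, min_nonmissing = 0.8) {
  stopifnot(inherits(G, "genotype_matrix"))
  d <- G$dosages
  g <- round(d)
  g[abs(d - g) > certainty] <- NA_real_
  ok <- colMeans(!is.na(g)) >= min_nonmissing
  excluded <- G$variants$id[!ok]
  g <- g[, ok, drop = FALSE]
  ld <- suppressWarnings(stats::cor(g, use = "pairwise.complete.obs"))
  diag(ld) <- 1
  dimnames(ld) <- list(G$variants$id[ok], G$variants$id[ok])
  structure(ld, excluded = excluded)
}
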