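#' Rank inverse-normal transformation
#'
#' Maps values to normal quantiles of their Blom-type plotting positions,
#' `qnorm((r - 3/8) / (n + 1/4))`, with average ranks for ties. Missing
#' entries are preserved as missing; the transform is order preserving.
#'
#' @param values Numeric vector with at least 3 non-missing values.
#' @return Numeric vector of the same length.
#' @export
rank_inverse_normal <- function(values) {
  ok <- !is.na(values)
  x <- values[ok]
  if (length(x) < 3) stop("need at least 3 non-missing values")
  if (length(unique(x)) == 1L)
    stop("all values identical: ranks are degenerate")
  r <- rank(x, ties.method = "average")
  out <- values
  out[ok] <- stats::qnorm((r - 3 / 8) / (length(x) + 1 / 4))
  out
}

# Canonical summary statistics constructor (one trait or latent factor).
new_sumstats <- function(df, trait_name) {
  req <- c("id", "chr", "bp", "effect_allele", "other_allele",
           "eaf", "beta", "se", "p", "info", "n")
  stopifnot(all(req %in% names(df)))
  if (anyDuplicated(df$id)) stop("duplicate variant ids in summary statistics")
  structure(df[req], class = c("sumstats", "data.frame"),
            trait_name = trait_name)
}

#' @export
print.sumstats <- function(x, ...) {
  cat(sprintf("sumstats for %s: %d variants, min p = %.3g\n",
              attr(x, "trait_name"), nrow(x), suppressWarnings(min(x$p))))
  NextMethod()
}

#' Per-variant least-squares GWAS
#'
#' Simple linear regression of a quantitative trait on genotype dosage with
#' an intercept, run independently per variant on the pairwise-complete
#' individuals, with two-sided p-values from the t distribution on `n - 2`
#' degrees of freedom. Constant-dosage variants are skipped (recorded in the
#' `skipped` attribute).
#'
#' @param G A `genotype_matrix`.
#' @param y Numeric trait vector of length `nrow(G$dosages)` (may contain
#'   `NA`).
#' @param trait_name Label stored on the output.
#' @return A `sumstats` table (per-allele beta in trait units, `eaf` the
#'   sample effect-allele frequency, `n` the per-variant complete count).
#' @export
gwas_ols <- function(G, y, trait_name = "trait") {
  stopifnot(inherits(G, "genotype_matrix"))
  d <- G$dosages
  if (length(y) != nrow(d)) stop("length(y) must equal the number of individuals")
  p <- ncol(d)
  beta <- se <- pv <- eaf <- rep(NA_real_, p)
  nn <- integer(p)
  complete_y <- !is.na(y)
  for (j in seq_len(p)) {
    ok <- complete_y & !is.na(d[, j])
    m <- sum(ok)
    nn[j] <- m
    if (m < 3) next
    x <- d[ok, j]; yy <- y[ok]
    sxx <- sum((x - mean(x))^2)
    if (sxx == 0) next
    b <- sum((x - mean(x)) * yy) / sxx
    res <- yy - mean(yy) - b * (x - mean(x))
    s2 <- sum(res^2) / (m - 2)
    beta[j] <- b
    se[j] <- sqrt(s2 / sxx)
    pv[j] <- if (se[j] == 0) 0 else 2 * stats::pt(-abs(b / se[j]), m - 2)
    eaf[j] <- mean(x) / 2
  }
  keep <- !is.na(beta)
  out <- new_sumstats(data.frame(
    id = G$variants$id, chr = G$variants$chr, bp = G$variants$bp,
    effect_allele = G$variants$effect_allele,
    other_allele = G$variants$other_allele,
    eaf = eaf, beta = beta, se = se, p = pv, info = G$variants$info, n = nn,
    stringsAsFactors = FALSE
  )[keep, , drop = FALSE], trait_name)
  attr(out, "skipped") <- G$variants$id[!keep]
  out
}

#' Harmonise per-trait GWAS summary statistics to a common effect allele
#'
#' Restricts to variants present in every table, expresses all effects on the
#' first table's effect allele (negating beta and flipping the effect allele
#' frequency where a table's alleles are swapped), and applies MAF and INFO
#' filters in every table: variants are kept only when
#' `min(eaf, 1 - eaf) > min_maf` and `info > min_info` throughout. Allele
#' pairs that differ beyond a swap are dropped. Every removal rule's count is
#' recorded in `filter_log`.
#'
#' @param tables List of `sumstats` tables (one per observed trait).
#' @param min_maf Minimum minor allele frequency (exclusive; default 0.005).
#' @param min_info Minimum INFO score (exclusive; default 0.4).
#' @param drop_ambiguous Drop strand-ambiguous (A/T, C/G) variants; off by
#'   default, for single-cohort use.
#' @return A `harmonised_panel`: list with `variants` (reference metadata:
#'   id, chr, bp, alleles, eaf, min info, min n), `beta` and `se`
#'   (`V x P` matrices, columns named by trait), `trait_names`, `filter_log`.
#' @export
harmonise <- function(tables, min_maf = 0.005, min_info = 0.4,
                      drop_ambiguous = FALSE) {
  if (!length(tables)) stop("need at least one summary-statistics table")
  trait_names <- vapply(tables, function(t) attr(t, "trait_name"), character(1))
  names(tables) <- trait_names
  log <- list(input_union = length(unique(unlist(lapply(tables, `[[`, "id")))))

  ids <- Reduce(intersect, lapply(tables, `[[`, "id"))
  log$not_in_all_tables <- log$input_union - length(ids)
  ref <- tables[[1]]
  ref <- ref[match(ids, ref$id), , drop = FALSE]

  keep <- rep(TRUE, length(ids))
  mismatched <- 0L
  V <- length(ids); P <- length(tables)
  beta <- se <- eafm <- info <- nmat <- matrix(NA_real_, V, P,
                                               dimnames = list(ids, trait_names))
  for (j in seq_along(tables)) {
    t <- tables[[j]][match(ids, tables[[j]]$id), , drop = FALSE]
    same <- t$effect_allele == ref$effect_allele &
      t$other_allele == ref$other_allele
    swap <- t$effect_allele == ref$other_allele &
      t$other_allele == ref$effect_allele
    bad <- !(same | swap)
    mismatched <- mismatched + sum(bad & keep)
    keep <- keep & !bad
    b <- ifelse(swap, -t$beta, t$beta)
    f <- ifelse(swap, 1 - t$eaf, t$eaf)
    beta[, j] <- b; se[, j] <- t$se; eafm[, j] <- f
    info[, j] <- t$info; nmat[, j] <- t$n
  }
  log$allele_mismatch <- mismatched

  maf_ok <- apply(pmin(eafm, 1 - eafm), 1, min) > min_maf
  log$below_min_maf <- sum(keep & !maf_ok)
  keep <- keep & maf_ok
  info_ok <- apply(info, 1, min) > min_info
  log$below_min_info <- sum(keep & !info_ok)
  keep <- keep & info_ok
  if (drop_ambiguous) {
    comp <- c(A = "T", T = "A", C = "G", G = "C")
    amb <- comp[ref$effect_allele] == ref$other_allele & !is.na(comp[ref$effect_allele])
    log$strand_ambiguous <- sum(keep & amb)
    keep <- keep & !amb
  }
  if (!any(keep))
    stop("harmonisation left no variants; removal counts: ",
         paste(sprintf("%s=%s", names(log), unlist(log)), collapse = ", "))

  variants <- data.frame(
    id = ids, chr = ref$chr, bp = ref$bp,
    effect_allele = ref$effect_allele, other_allele = ref$other_allele,
    eaf = eafm[, 1], info = apply(info, 1, min), n = apply(nmat, 1, min),
    stringsAsFactors = FALSE
  )[keep, , drop = FALSE]
  structure(list(variants = variants,
                 beta = beta[keep, , drop = FALSE],
                 se = se[keep, , drop = FALSE],
                 trait_names = trait_names,
                 filter_log = log),
            class = "harmonised_panel")
}

#' @export
print.harmonised_panel <- function(x, ...) {
  cat(sprintf("harmonised_panel: %d variants x %d traits\n",
              nrow(x$variants), length(x$trait_names)))
  cat("  filters:", paste(sprintf("%s=%s", names(x$filter_log),
                                  unlist(x$filter_log)), collapse = ", "), "\n")
  invisible(x)
}

#' Extract one trait's harmonised summary statistics from a panel
#'
#' @param panel A `harmonised_panel`.
#' @param trait Trait name or column index.
#' @return A `sumstats` table on the panel's reference effect allele.
#' @export
panel_sumstats <- function(panel, trait) {
  stopifnot(inherits(panel, "harmonised_panel"))
  j <- if (is.character(trait)) match(trait, panel$trait_names) else trait
  z <- panel$beta[, j] / panel$se[, j]
  new_sumstats(data.frame(
    panel$variants[c("id", "chr", "bp", "effect_allele", "other_allele")],
    eaf = panel$variants$eaf, beta = panel$beta[, j], se = panel$se[, j],
    p = 2 * stats::pnorm(-abs(z)), info = panel$variants$info,
    n = panel$variants$n, stringsAsFactors = FALSE
  ), panel$trait_names[j])
}

#' Latent-factor GWAS summary statistics from observed-trait summary statistics
#'
#' The central summary-level identity: with loading matrix `L` the latent
#' factor scores are a fixed linear map of the traits, so per variant the
#' latent effect estimates are `beta* = (L'L)^-1 L' beta`, and their
#' covariance is `Var(beta*) = (L'L)^-1 L' Var(beta) L (L'L)^-1` with
#' `Var(beta)_ij = Cov(Y_i, Y_j) * se_i * se_j` built from the marginal trait
#' covariance. Association is assessed through `Z_k = beta*_k /
#' sqrt(diag(Var(beta*))_k)` with normal-approximation p-values (large-n
#' GWAS convention).
#'
#' On a complete cohort this reproduces, exactly in beta, the per-variant
#' least-squares GWAS of the factor scores themselves; standard errors agree
#' approximately because the marginal (not residual) trait covariance is
#' used.
#'
#' @param panel A `harmonised_panel` over the observed traits.
#' @param L A `loading_matrix` or `P x K` matrix, trait order matching the
#'   panel.
#' @param trait_cov `P x P` trait covariance (or correlation, for
#'   standardised traits) matrix in the same trait order. A non-unit-scale
#'   diagonal triggers a warning for nominally standardised traits.
#' @param store_cov Keep the full per-variant `K x K` covariance array
#'   (otherwise only its diagonal is used).
#' @return A `latent_sumstats` object: list of `sumstats` tables (one per
#'   factor, `trait_name` = factor name), plus `beta_star`/`se_star`
#'   matrices, the number of variants with clipped non-positive variances
#'   (`n_clipped`), and optionally `cov_star`.
#' @export
latent_sumstats <- function(panel, L, trait_cov, store_cov = FALSE) {
  stopifnot(inherits(panel, "harmonised_panel"))
  M <- if (inherits(L, "loading_matrix")) L$loadings else as.matrix(L)
  P <- nrow(M); K <- ncol(M)
  if (length(panel$trait_names) != P)
    stop("panel trait count must match nrow(L)")
  C <- as.matrix(trait_cov)
  if (!all(dim(C) == P)) stop("trait_cov must be P x P")
  if (max(abs(diag(C) - 1)) > 0.2)
    warning("trait_cov diagonal is far from 1; traits do not look standardised")
  G <- crossprod(M)
  if (rcond(G) < 1e-12) stop("L'L is singular")
  A <- solve(G, t(M))                               # K x P
  V <- nrow(panel$beta)
  beta_star <- panel$beta %*% t(A)                  # V x K
  var_star <- matrix(NA_real_, V, K)
  cov_star <- if (store_cov) array(NA_real_, c(K, K, V)) else NULL
  n_clipped <- 0L
  for (v in seq_len(V)) {
    u <- panel$se[v, ]
    Vb <- C * tcrossprod(u)
    Vs <- A %*% Vb %*% t(A)
    dg <- diag(Vs)
    if (any(dg <= 0)) {
      n_clipped <- n_clipped + 1L
      e <- eigen(Vs, symmetric = TRUE)
      e$values[e$values < 0] <- 0
      Vs <- e$vectors %*% (e$values * t(e$vectors))
      dg <- pmax(diag(Vs), .Machine$double.eps)
    }
    var_star[v, ] <- dg
    if (store_cov) cov_star[, , v] <- Vs
  }
  if (n_clipped > 0)
    warning(n_clipped, " variant(s) had non-positive latent effect variances; negative eigenvalues clipped to 0")
  se_star <- sqrt(var_star)
  z <- beta_star / se_star
  fn <- if (!is.null(colnames(M))) colnames(M) else sprintf("ML%d", seq_len(K))
  colnames(beta_star) <- colnames(se_star) <- fn
  tables <- lapply(seq_len(K), function(k) {
    new_sumstats(data.frame(
      panel$variants[c("id", "chr", "bp", "effect_allele", "other_allele")],
      eaf = panel$variants$eaf, beta = beta_star[, k], se = se_star[, k],
      p = 2 * stats::pnorm(-abs(z[, k])), info = panel$variants$info,
      n = panel$variants$n, stringsAsFactors = FALSE
    ), fn[k])
  })
  names(tables) <- fn
  structure(list(tables = tables, beta_star = beta_star, se_star = se_star,
                 factor_names = fn, n_clipped = n_clipped,
                 cov_star = cov_star),
            class = "latent_sumstats")
}

#' @export
print.latent_sumstats <- function(x, ...) {
  cat(sprintf("latent_sumstats: %d factors x %d variants\n",
              length(x$tables), nrow(x$beta_star)))
  minp <- vapply(x$tables, function(t) suppressWarnings(min(t$p)), numeric(1))
  cat("  min p per factor:",
      paste(sprintf("%s=%.2g", names(minp), minp), collapse = ", "), "\n")
  invisible(x)
}
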