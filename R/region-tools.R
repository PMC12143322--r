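#' Greedy LD clumping of significant variants
#'
#' PLINK-style greedy clumping: repeatedly take the smallest-p unassigned
#' genome-wide significant variant as a lead and assign every unassigned
#' variant with `r^2 > r2` to its clump (tags are absorbed in a single round
#' via the lead, not transitively), until no significant variant remains
#' unassigned.
#'
#' @param ss A `sumstats` table.
#' @param ld Correlation matrix over `ss$id` (in order, or with matching
#'   dimnames).
#' @param p_thresh Significance threshold for leads (default 5e-8).
#' @param r2 r^2 threshold for clump membership (default 0.6).
#' @return List of `clump` objects: each a list with `lead`, `members`
#'   (including the lead), `lead_p`.
#' @export
ld_clump <- function(ss, ld, p_thresh = 5e-8, r2 = 0.6) {
  ld <- as.matrix(ld)
  if (!is.null(rownames(ld))) {
    idx <- match(ss$id, rownames(ld))
    if (anyNA(idx)) stop("LD matrix must cover all variants in the summary statistics")
    ld <- ld[idx, idx, drop = FALSE]
  }
  sig <- which(ss$p < p_thresh)
  clumps <- list()
  assigned <- rep(FALSE, nrow(ss))
  while (any(!assigned[sig])) {
    open <- sig[!assigned[sig]]
    lead <- open[which.min(ss$p[open])]
    members <- which(!assigned & ld[lead, ]^2 > r2)
    members <- union(lead, members)
    assigned[members] <- TRUE
    clumps[[length(clumps) + 1L]] <- structure(
      list(lead = ss$id[lead], members = ss$id[members],
           lead_p = ss$p[lead]),
      class = "clump")
  }
  clumps
}

#' Build fine-mapping regions around lead variants
#'
#' Distance-clumps leads so that retained leads are at least
#' `min_separation` apart (within each window the smallest-p lead is kept,
#' sweeping leads in order of increasing p), flanks each retained lead by
#' `flank` on both sides, unions with any `extra_regions`, and merges
#' overlapping intervals per chromosome. Coordinates are 1-based inclusive.
#'
#' @param leads data.frame with columns `chr`, `bp` and optionally `p`
#'   (without `p`, leads are swept in position order).
#' @param min_separation Minimum distance between retained leads (default
#'   250kb).
#' @param flank Flank added on each side of a retained lead (default 250kb).
#' @param extra_regions Optional data.frame with `chr`, `start`, `end` to
#'   union in before merging.
#' @return data.frame with `chr`, `start`, `end` (merged, sorted).
#' @export
build_regions <- function(leads, min_separation = 250000, flank = 250000,
                          extra_regions = NULL) {
  stopifnot(all(c("chr", "bp") %in% names(leads)))
  kept <- leads[0, c("chr", "bp")]
  if (nrow(leads)) {
    ord <- if ("p" %in% names(leads)) order(leads$p, leads$chr, leads$bp)
    else order(leads$chr, leads$bp)
    pend <- leads[ord, , drop = FALSE]
    while (nrow(pend)) {
      top <- pend[1, , drop = FALSE]
      kept <- rbind(kept, top[c("chr", "bp")])
      near <- pend$chr == top$chr & abs(pend$bp - top$bp) < min_separation
      pend <- pend[!near, , drop = FALSE]
    }
  }
  regions <- if (nrow(kept))
    data.frame(chr = kept$chr, start = pmax(1, kept$bp - flank),
               end = kept$bp + flank)
  else data.frame(chr = integer(0), start = integer(0), end = integer(0))
  if (!is.null(extra_regions))
    regions <- rbind(regions, extra_regions[c("chr", "start", "end")])
  merge_regions(regions)
}

#' Merge overlapping 1-based inclusive intervals per chromosome
#'
#' @param regions data.frame with `chr`, `start`, `end`.
#' @return data.frame with the merged, sorted intervals.
#' @export
merge_regions <- function(regions) {
  if (!nrow(regions)) return(regions)
  regions <- regions[order(regions$chr, regions$start, regions$end), ]
  out <- regions[1, , drop = FALSE]
  if (nrow(regions) > 1) for (i in 2:nrow(regions)) {
    r <- regions[i, ]
    last <- nrow(out)
    if (r$chr == out$chr[last] && r$start <= out$end[last] + 1) {
      out$end[last] <- max(out$end[last], r$end)
    } else {
      out <- rbind(out, r)
    }
  }
  rownames(out) <- NULL
  out
}

#' Conditional association from summary statistics and LD
#'
#' Residualises each target variant's z-score on the z-scores of a set of
#' conditioning variants using the LD matrix:
#' `z_cond = (z_t - R_tC R_CC^-1 z_C) / sqrt(1 - R_tC R_CC^-1 R_Ct)`,
#' with beta and SE rescaled on the same denominator
#' (`beta_cond = se * num / (1 - h)`, `se_cond = se / sqrt(1 - h)`), the
#' summary-level analogue of adding the conditioning variants to the
#' regression. Conditioned variants are reported with `beta = 0`.
#'
#' @param ss A `sumstats` table.
#' @param ld Correlation matrix over `ss$id` (in order).
#' @param condition_ids Variant ids to condition on.
#' @param ridge Ridge added to `R_CC` when near-singular.
#' @return A `sumstats` table of conditional statistics (normal-approximation
#'   p-values).
#' @export
conditional_sumstats <- function(ss, ld, condition_ids, ridge = 1e-6) {
  ld <- as.matrix(ld)
  if (!length(condition_ids)) return(ss)
  ci <- match(condition_ids, ss$id)
  if (anyNA(ci)) stop("conditioning variant(s) not found in the summary statistics")
  z <- ss$beta / ss$se
  Rcc <- ld[ci, ci, drop = FALSE]
  if (rcond(Rcc) < 1e-10) {
    Rcc <- Rcc + diag(ridge, length(ci))
    warning("near-singular conditioning LD block; ridge added")
  }
  zc <- z[ci]
  out <- ss
  Rinv <- solve(Rcc)
  wz <- drop(Rinv %*% zc)          # R_CC^-1 z_C
  for (t in seq_len(nrow(ss))) {
    if (t %in% ci) {
      out$beta[t] <- 0
      out$p[t] <- 1
      next
    }
    rtc <- ld[t, ci]
    num <- z[t] - sum(rtc * wz)
    h <- drop(rtc %*% Rinv %*% rtc)
    h <- min(h, 1 - 1e-12)
    out$beta[t] <- ss$se[t] * num / (1 - h)
    out$se[t] <- ss$se[t] / sqrt(1 - h)
    out$p[t] <- 2 * stats::pnorm(-abs(num / sqrt(1 - h)))
  }
  out
}

#' Cross-tabulate trait clumps against latent-factor signals
#'
#' For each trait clump, counts how many traits are significantly associated
#' within it and whether any member variant is genome-wide significant for a
#' latent factor ("shared"), producing the stacked-bar source table and a
#' Cochran-Armitage trend test (equally spaced scores, via
#' [stats::prop.trend.test()]) of the proportion shared against the trait
#' count.
#'
#' @param trait_clumps List of `clump` objects, each with an additional
#'   `traits` field (character vector of traits significant in the clump).
#' @param latent_clumps List of `clump` objects from the latent-factor GWAS
#'   (their members are the latent GWS variants).
#' @return List with `table` (data.frame: `n_traits`, `shared`,
#'   `not_shared`), `statistic`, `p` (trend test; `NA` when fewer than 2
#'   trait-count categories; statistic 0 / p 1 for flat all-or-none sharing).
#' @export
clump_trait_crosstab <- function(trait_clumps, latent_clumps) {
  latent_members <- unique(unlist(lapply(latent_clumps, `[[`, "members")))
  n_traits <- vapply(trait_clumps, function(cl) length(unique(cl$traits)),
                     integer(1))
  shared <- vapply(trait_clumps, function(cl)
    any(cl$members %in% latent_members), logical(1))
  lev <- sort(unique(n_traits))
  tab <- data.frame(
    n_traits = lev,
    shared = vapply(lev, function(k) sum(shared[n_traits == k]), integer(1)),
    not_shared = vapply(lev, function(k) sum(!shared[n_traits == k]), integer(1))
  )
  if (nrow(tab) < 2) {
    stat <- NA_real_; pval <- NA_real_
  } else if (all(shared) || all(!shared)) {
    stat <- 0; pval <- 1
  } else {
    # prop.trend.test emits an incidental anova warning on perfectly linear
    # proportion profiles; the chi-square statistic itself is well defined
    tt <- suppressWarnings(
      stats::prop.trend.test(tab$shared, tab$shared + tab$not_shared,
                             score = seq_len(nrow(tab))))
    stat <- unname(tt$statistic)
    pval <- tt$p.value
  }
  list(table = tab, statistic = stat, p = pval)
}

#' Export regions as BED (0-based half-open)
#'
#' @param regions data.frame with `chr`, `start`, `end` (1-based inclusive).
#' @param path Output path.
#' @export
write_regions_bed <- function(regions, path) {
  bed <- data.frame(chrom = paste0("chr", regions$chr),
                    chromStart = regions$start - 1L,
                    chromEnd = regions$end)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(NULL)
}
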