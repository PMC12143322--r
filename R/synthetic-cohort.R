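#' Simulate genotype dosages with autoregressive linkage disequilibrium
#'
#' Generates an `n x p` matrix of unphased genotype dosages by drawing, for
#' each individual, two latent standard-normal haplotype processes with AR(1)
#' correlation `rho` along the variant axis, thresholding each at the
#' allele-frequency quantile, and summing the two allele indicators.
#' Independent haplotype draws imply Hardy-Weinberg proportions at every
#' variant; `rho` tunes the decay of between-variant r2 without an external
#' reference panel.
#'
#' @param n Number of individuals (positive integer).
#' @param p Number of variants (positive integer).
#' @param mafs Vector of length `p` of minor allele frequencies in (0, 0.5].
#' @param rho AR(1) haplotype correlation between adjacent variants, in
#'   `[0, 1)`.
#' @param seed Integer seed; output is fully deterministic given `seed`.
#' @param chr Chromosome label for the simulated variants.
#' @param bp_start,bp_step Base-pair position of the first variant and spacing
#'   between adjacent variants (1-based coordinates).
#' @return An object of class `genotype_matrix`: a list with `dosages`
#'   (`n x p` numeric matrix, values in `[0, 2]`, columns named by variant id)
#'   and `variants` (data.frame with `id`, `chr`, `bp`, `effect_allele`,
#'   `other_allele`, `maf`, `info`). INFO is 1 for directly simulated
#'   dosages; see [add_dosage_jitter()] for imputation-quality emulation.
#' @seealso [simulate_factor_traits()], [best_guess_ld()]
#' @export
simulate_genotypes <- function(n, p, mafs, rho, seed, chr = 1L,
                               bp_start = 1e6, bp_step = 1000) {
  if (length(n) != 1L || n < 1 || n != round(n)) stop("'n' must be a positive integer")
  if (length(p) != 1L || p < 1 || p != round(p)) stop("'p' must be a positive integer")
  if (length(mafs) == 1L) mafs <- rep(mafs, p)
  if (length(mafs) != p) stop("length(mafs) must equal p")
  if (any(mafs <= 0 | mafs > 0.5)) stop("all mafs must lie in (0, 0.5]")
  if (length(rho) != 1L || rho < 0 || rho >= 1) stop("'rho' must lie in [0, 1)")

  set.seed(as.integer(seed))
  thr <- stats::qnorm(mafs)
  dos <- matrix(0, n, p)
  sq <- sqrt(1 - rho^2)
  for (hap in 1:2) {
    h <- matrix(stats::rnorm(n * p), n, p)
    if (rho > 0 && p > 1) {
      for (j in 2:p) h[, j] <- rho * h[, j - 1] + sq * h[, j]
    }
    dos <- dos + (h < matrix(thr, n, p, byrow = TRUE))
  }
  ids <- sprintf("rs%d_%d", chr, seq_len(p))
  variants <- data.frame(
    id = ids, chr = as.integer(chr),
    bp = as.integer(bp_start + bp_step * (seq_len(p) - 1L)),
    effect_allele = "A", other_allele = "G",
    maf = mafs, info = 1, stringsAsFactors = FALSE
  )
  colnames(dos) <- ids
  structure(list(dosages = dos, variants = variants), class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d individuals x %d variants (chr %s, %s-%s bp)\n",
              nrow(x$dosages), ncol(x$dosages),
              paste(unique(x$variants$chr), collapse = ","),
              format(min(x$variants$bp), big.mark = ","),
              format(max(x$variants$bp), big.mark = ",")))
  invisible(x)
}

#' Add uniform dosage jitter and recompute INFO
#'
#' Perturbs hard-call dosages with Uniform(-amount, amount) noise (clipped to
#' `[0, 2]`) to emulate imputation uncertainty, and recomputes each variant's
#' INFO score as `var(dosage) / (2 * maf * (1 - maf))` (capped at 1), with
#' `maf` the sample allele frequency of the jittered dosages.
#'
#' @param G A `genotype_matrix`.
#' @param amount Half-width of the uniform jitter.
#' @param seed Integer seed.
#' @return A `genotype_matrix` with fractional dosages and updated `info`.
#' @export
add_dosage_jitter <- function(G, amount = 0.3, seed = 1L) {
  stopifnot(inherits(G, "genotype_matrix"))
  set.seed(as.integer(seed))
  d <- G$dosages + stats::runif(length(G$dosages), -amount, amount)
  d[d < 0] <- 0
  d[d > 2] <- 2
  af <- colMeans(d) / 2
  maf <- pmin(af, 1 - af)
  info <- pmin(1, apply(d, 2, stats::var) / (2 * maf * (1 - maf)))
  G$dosages <- d
  G$variants$maf <- maf
  G$variants$info <- info
  G
}

#' Simulate correlated traits from a genotype-driven factor model
#'
#' Builds `K` latent factor scores as sums of planted per-variant effects plus
#' Gaussian noise, then maps them through a `P x K` loading matrix and adds
#' independent per-trait noise: `F_k = sum(effect * dosage) + N(0, sd_k)` and
#' `Y = F t(L) + E`, individuals independent.
#'
#' @param G A `genotype_matrix`.
#' @param L `P x K` numeric loading matrix (rows = traits, columns = factors).
#' @param causal_map List of length `K`; element k is a named numeric vector
#'   of per-allele effects, names being variant ids in `G` (may be empty).
#' @param factor_noise_sd Length-`K` vector (or scalar) of factor noise SDs.
#' @param trait_noise_sd Length-`P` vector (or scalar) of trait noise SDs.
#' @param seed Integer seed.
#' @return A list with `traits` (a `trait_matrix`: `values` `n x P` matrix,
#'   `trait_names`) and `truth` (a `truth_record`: the causal map, true
#'   loading matrix, realised factor scores, noise SDs).
#' @export
simulate_factor_traits <- function(G, L, causal_map, factor_noise_sd,
                                   trait_noise_sd, seed) {
  stopifnot(inherits(G, "genotype_matrix"))
  L <- as.matrix(L)
  K <- ncol(L); P <- nrow(L)
  if (length(causal_map) != K)
    stop("causal_map must have one element per factor (ncol(L))")
  factor_noise_sd <- rep_len(factor_noise_sd, K)
  trait_noise_sd <- rep_len(trait_noise_sd, P)
  if (any(factor_noise_sd < 0) || any(trait_noise_sd < 0))
    stop("noise SDs must be non-negative")
  unknown <- setdiff(unlist(lapply(causal_map, names)), G$variants$id)
  if (length(unknown))
    stop("causal variant id(s) not in genotype matrix: ",
         paste(unknown, collapse = ", "))

  set.seed(as.integer(seed))
  n <- nrow(G$dosages)
  Fs <- matrix(0, n, K)
  for (k in seq_len(K)) {
    eff <- causal_map[[k]]
    if (length(eff))
      Fs[, k] <- G$dosages[, names(eff), drop = FALSE] %*% eff
    if (factor_noise_sd[k] > 0)
      Fs[, k] <- Fs[, k] + stats::rnorm(n, 0, factor_noise_sd[k])
  }
  Y <- Fs %*% t(L)
  if (any(trait_noise_sd > 0))
    Y <- Y + matrix(stats::rnorm(n * P), n, P) %*% diag(trait_noise_sd, P)
  trait_names <- if (!is.null(rownames(L))) rownames(L) else sprintf("trait%d", seq_len(P))
  factor_names <- if (!is.null(colnames(L))) colnames(L) else sprintf("F%d", seq_len(K))
  colnames(Y) <- trait_names
  colnames(Fs) <- factor_names
  traits <- structure(list(values = Y, trait_names = trait_names),
                      class = "trait_matrix")
  truth <- structure(list(causal_map = causal_map, loadings = L,
                          factor_scores = Fs,
                          factor_noise_sd = factor_noise_sd,
                          trait_noise_sd = trait_noise_sd),
                     class = "truth_record")
  list(traits = traits, truth = truth)
}

#' @export
print.trait_matrix <- function(x, ...) {
  cat(sprintf("trait_matrix: %d individuals x %d traits; %d missing values\n",
              nrow(x$values), ncol(x$values), sum(is.na(x$values))))
  invisible(x)
}

#' Inject missingness into a trait matrix
#'
#' Applies an independent Bernoulli missingness mask per trait, for exercising
#' pairwise-complete correlation paths.
#'
#' @param traits A `trait_matrix`.
#' @param rates Per-trait missingness probabilities (recycled).
#' @param seed Integer seed.
#' @return The `trait_matrix` with `NA` entries.
#' @export
add_missingness <- function(traits, rates, seed) {
  stopifnot(inherits(traits, "trait_matrix"))
  P <- ncol(traits$values)
  rates <- rep_len(rates, P)
  set.seed(as.integer(seed))
  for (j in seq_len(P)) {
    miss <- stats::runif(nrow(traits$values)) < rates[j]
    traits$values[miss, j] <- NA_real_
  }
  traits
}

#' Write / read a genotype matrix as plain TSV
#'
#' The dosage file has one row per variant (header line = individual ids,
#' first column `id`); variant metadata go to a companion TSV.
#'
#' @param G A `genotype_matrix`.
#' @param dosage_file,variant_file Output paths.
#' @export
write_genotypes <- function(G, dosage_file, variant_file) {
  stopifnot(inherits(G, "genotype_matrix"))
  d <- data.frame(id = G$variants$id, t(G$dosages), check.names = FALSE)
  colnames(d) <- c("id", sprintf("ind%d", seq_len(nrow(G$dosages))))
  utils::write.table(d, dosage_file, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(G$variants, variant_file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(NULL)
}

#' @rdname write_genotypes
#' @return `read_genotypes()` returns the round-tripped `genotype_matrix`.
#' @export
read_genotypes <- function(dosage_file, variant_file) {
  d <- utils::read.table(dosage_file, header = TRUE, sep = "\t",
                         check.names = FALSE, stringsAsFactors = FALSE)
  v <- utils::read.table(variant_file, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  dos <- t(as.matrix(d[, -1, drop = FALSE]))
  colnames(dos) <- d$id
  rownames(dos) <- NULL
  structure(list(dosages = dos, variants = v), class = "genotype_matrix")
}

#' Write a trait matrix as TSV
#' @param traits A `trait_matrix`.
#' @param path Output path.
#' @export
write_traits <- function(traits, path) {
  stopifnot(inherits(traits, "trait_matrix"))
  utils::write.table(as.data.frame(traits$values), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(NULL)
}
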