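# Canonical summary-statistics TSV dialect:
#   SNPID CHR BP EA OA EAF BETA SE P INFO N
# tab-separated, one header line; the reader tolerates extra columns and a
# set of common header aliases.

.ss_aliases <- list(
  id = c("SNPID", "SNP", "ID", "VARIANT", "RSID", "MARKERNAME"),
  chr = c("CHR", "CHROM", "CHROMOSOME"),
  bp = c("BP", "POS", "POSITION", "BASE_PAIR_LOCATION"),
  effect_allele = c("EA", "A1", "EFFECT_ALLELE", "ALLELE1"),
  other_allele = c("OA", "A2", "OTHER_ALLELE", "ALLELE0", "ALLELE2"),
  eaf = c("EAF", "AF", "A1FREQ", "FREQ", "EFFECT_ALLELE_FREQUENCY"),
  beta = c("BETA", "B", "EFFECT"),
  se = c("SE", "STDERR", "STANDARD_ERROR"),
  p = c("P", "PVAL", "PVALUE", "P_VALUE"),
  info = c("INFO", "IMPINFO", "R2"),
  n = c("N", "NSAMPLES", "SAMPLESIZE")
)

#' Read GWAS summary statistics from TSV
#'
#' Expects the canonical `SNPID CHR BP EA OA EAF BETA SE P INFO N` header,
#' resolving common aliases (e.g. CHROM/POS) and ignoring extra columns.
#' Rows with missing or non-positive SE, non-numeric beta, or p outside
#' (0, 1] are rejected with their line numbers recorded in the `rejected`
#' attribute.
#'
#' @param path Input TSV path.
#' @param trait_name Trait label (default: file name without extension).
#' @return A `sumstats` table.
#' @export
read_sumstats <- function(path, trait_name = NULL) {
  if (is.null(trait_name))
    trait_name <- sub("\\.[^.]*$", "", basename(path))
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, check.names = FALSE)
  up <- toupper(names(d))
  cols <- lapply(.ss_aliases, function(al) {
    hit <- match(al, up)
    hit <- hit[!is.na(hit)]
    if (length(hit)) hit[1] else NA_integer_
  })
  missing <- names(cols)[is.na(unlist(cols))]
  if (length(missing))
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  out <- data.frame(lapply(cols, function(j) d[[j]]),
                    stringsAsFactors = FALSE)
  num <- c("eaf", "beta", "se", "p", "info")
  for (cn in num) out[[cn]] <- suppressWarnings(as.numeric(out[[cn]]))
  bad <- is.na(out$beta) | is.na(out$se) | out$se <= 0 |
    is.na(out$p) | out$p <= 0 | out$p > 1
  if (any(bad))
    warning(sum(bad), " malformed row(s) rejected (lines ",
            paste(utils::head(which(bad) + 1L, 5), collapse = ", "),
            if (sum(bad) > 5) ", ..." else "", ")")
  res <- new_sumstats(out[!bad, , drop = FALSE], trait_name)
  attr(res, "rejected") <- which(bad) + 1L
  res
}

#' @rdname read_sumstats
#' @param ss A `sumstats` table.
#' @export
write_sumstats <- function(ss, path) {
  d <- data.frame(SNPID = ss$id, CHR = ss$chr, BP = ss$bp,
                  EA = ss$effect_allele, OA = ss$other_allele,
                  EAF = ss$eaf, BETA = ss$beta, SE = ss$se, P = ss$p,
                  INFO = ss$info, N = ss$n)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}

#' Read / write a square LD matrix
#'
#' Whitespace-delimited square matrix with a variant-id header row.
#'
#' @param path File path.
#' @export
read_ld_matrix <- function(path) {
  d <- utils::read.table(path, header = TRUE, check.names = FALSE)
  m <- as.matrix(d)
  rownames(m) <- colnames(m)
  m
}

#' @rdname read_ld_matrix
#' @param ld Square correlation matrix with variant-id dimnames.
#' @export
write_ld_matrix <- function(ld, path) {
  utils::write.table(as.data.frame(ld), path, sep = " ", quote = FALSE,
                     row.names = FALSE)
  invisible(NULL)
}

#' Parse a region specification string
#'
#' @param spec String `"chr:start-end"`, 1-based inclusive.
#' @return List with `chr`, `start`, `end`.
#' @export
parse_region <- function(spec) {
  m <- regmatches(spec, regexec("^([0-9XY]+):([0-9]+)-([0-9]+)$", spec))[[1]]
  if (length(m) != 4) stop("region must be of the form chr:start-end")
  list(chr = m[2], start = as.integer(m[3]), end = as.integer(m[4]))
}

#' Default pipeline configuration
#'
#' Threshold defaults follow standard GWAS fine-mapping practice: minimum
#' MAF 0.005 and INFO 0.4 for harmonisation, genome-wide significance
#' 5e-8, LD clumping r^2 0.6, a 20% factor-contribution link between traits
#' and factors, 99% credible sets, and MPP 0.90 for high-confidence calls.
#'
#' @param ... Named overrides of any default entry.
#' @return A `run_config` list.
#' @export
default_config <- function(...) {
  cfg <- list(
    sumstats_files = character(0),
    ld_file = NULL,
    trait_cov_file = NULL,
    loadings_file = NULL,
    output_dir = ".",
    n_factors = NULL,
    min_maf = 0.005, min_info = 0.4,
    gws_p = 5e-8, suggestive_p = 1e-6,
    clump_r2 = 0.6, contribution_min = 0.20,
    cs_level = 0.99, mpp_high = 0.90,
    kappa = 4, prior_var = 0.04^2, snp_prior = NULL,
    growth_threshold = 0.05,
    seed = 1L
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown config entries: ",
                            paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  # YAML round-trips vectors as lists and character(0) as NULL: normalise
  cfg$sumstats_files <- as.character(unlist(cfg$sumstats_files))
  cfg$seed <- as.integer(cfg$seed)
  validate_config(structure(cfg, class = "run_config"))
}

validate_config <- function(cfg) {
  in01 <- c("min_maf", "min_info", "gws_p", "suggestive_p", "clump_r2",
            "contribution_min", "cs_level", "mpp_high", "growth_threshold")
  for (nm in in01) {
    v <- cfg[[nm]]
    if (!is.numeric(v) || v <= 0 || v >= 1)
      stop(sprintf("config entry '%s' must lie in (0, 1)", nm))
  }
  if (cfg$kappa < 1) stop("config entry 'kappa' must be >= 1")
  cfg
}

#' Read / write a pipeline configuration (YAML)
#'
#' Configurations round-trip losslessly through serialisation.
#'
#' @param path YAML file path.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(default_config, cfg)
}

#' @rdname read_config
#' @param cfg A `run_config`.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(NULL)
}
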