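#' Quality-control and analysis thresholds
#'
#' Returns the full set of filtering and analysis thresholds used throughout
#' the pipeline. The defaults are the published study settings: genotypes are
#' dropped at depth < 8x, genotype quality < 20 or a minor-read ratio < 20%
#' (heterozygotes only); sites are dropped when masked, multiallelic with
#' more than four ALT alleles, missing in > 10% of genotypes, or spanning
#' > 15 nucleotides; candidate variants require population MAF < 1e-4 and a
#' CADD score above the gene-specific mutation significance cutoff; ancestry
#' PCA uses common well-called sites (MAF > 0.01, call rate > 0.99);
#' relatedness is cut at third degree (kinship 0.0442); runs of homozygosity
#' use a 1,000-kb / 50-SNV window over SNVs with MAF > 0.05, and samples with
#' more than 1% of the autosomal genome in such runs are flagged as born to
#' consanguineous parents.
#'
#' @param ... named overrides for any default listed above.
#' @return a named list of thresholds (class `filter_config`).
#' @export
#' @examples
#' filter_config(min_depth = 10)$min_depth
filter_config <- function(...) {
  cfg <- list(
    min_depth            = 8,
    min_gq               = 20,
    min_minor_read_ratio = 0.20,
    max_alt_alleles      = 4,
    max_site_missingness = 0.10,
    max_span_nt          = 15,
    candidate_max_maf    = 1e-4,
    msc_strict           = TRUE,   # CADD strictly > MSC; FALSE switches to >=
    pca_min_maf          = 0.01,
    pca_min_call_rate    = 0.99,
    kinship_threshold    = 0.0442,
    roh_window_kb        = 1000,
    roh_window_snps      = 50,
    roh_window_max_het   = 1,
    roh_window_max_miss  = 5,
    roh_overlap_fraction = 0.05,
    roh_min_segment_snps = 100,
    roh_min_segment_kb   = 1000,
    roh_snp_min_maf      = 0.05,
    consanguinity_threshold = 0.01
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(cfg))
  if (length(unknown) > 0) {
    abort(paste0("unknown filter_config field(s): ",
                 paste(unknown, collapse = ", ")))
  }
  cfg <- modifyList(cfg, overrides)
  numeric_fields <- setdiff(names(cfg), "msc_strict")
  bad <- numeric_fields[vapply(cfg[numeric_fields],
                               function(x) !is.numeric(x) || x <= 0, logical(1))]
  if (length(bad) > 0) {
    abort(paste0("filter_config thresholds must be strictly positive: ",
                 paste(bad, collapse = ", ")))
  }
  structure(cfg, class = c("filter_config", "list"))
}
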