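#' Genotype-level quality filtering
#'
#' Sets individual genotype calls to missing when they fail the study's
#' genotype QC rules: coverage below 8x, genotype quality below 20, or -- for
#' heterozygous calls only -- a minor-read ratio
#' `min(ref_reads, alt_reads) / (ref_reads + alt_reads)` below 20%.
#' Homozygous calls are exempt from the ratio rule (the least-covered-allele
#' ratio would reject essentially all good homozygous calls). Heterozygous
#' calls with no allele-depth information are set missing with their own log
#' reason. All thresholds are strict (`<`), so DP 8 / GQ 20 / ratio exactly
#' 0.20 are retained. Hemizygous calls (male chromosome X, flagged in the
#' optional `hemi` column) are single-allele calls and are exempt from the
#' heterozygote ratio rule, like homozygotes.
#'
#' @param calls genotype-call tibble with columns `sample_id`, `variant_id`,
#'   `dosage`, `dp`, `gq`, `ad_ref`, `ad_alt`, and optionally `hemi`.
#' @param config a [filter_config()].
#' @return a list with `calls` (failing dosages set to `NA`) and `qc_log`
#'   (tibble of per-reason failure counts).
#' @export
#' @examples
#' calls <- tibble::tibble(sample_id = "s1", variant_id = "1:1:A:G",
#'                         dosage = 1L, dp = 7L, gq = 60L,
#'                         ad_ref = 4L, ad_alt = 3L)
#' apply_genotype_filters(calls, filter_config())$qc_log
apply_genotype_filters <- function(calls, config = filter_config()) {
  assert_columns(calls, c("sample_id", "variant_id", "dosage", "dp", "gq",
                          "ad_ref", "ad_alt"), "calls")
  hemi <- if ("hemi" %in% names(calls)) calls$hemi %in% TRUE else
    rep(FALSE, nrow(calls))
  present <- !is.na(calls$dosage)
  low_dp <- present & !is.na(calls$dp) & calls$dp < config$min_depth
  low_gq <- present & !is.na(calls$gq) & calls$gq < config$min_gq
  het <- present & calls$dosage == 1L & !hemi
  ad_total <- calls$ad_ref + calls$ad_alt
  mrr <- pmin(calls$ad_ref, calls$ad_alt) / ad_total
  no_ad <- het & (is.na(ad_total) | ad_total == 0)
  low_mrr <- het & !no_ad & mrr < config$min_minor_read_ratio
  fail <- low_dp | low_gq | low_mrr | no_ad
  out <- calls
  out$dosage[fail] <- NA_integer_
  qc_log <- tibble::tibble(
    reason = c("low_depth", "low_genotype_quality", "low_minor_read_ratio",
               "het_missing_allele_depths"),
    n = c(sum(low_dp), sum(low_gq), sum(low_mrr), sum(no_ad))
  )
  list(calls = out, qc_log = qc_log)
}

#' Site-level quality filtering
#'
#' Drops variant sites that fall in a masked (low-complexity/decoy) region,
#' are multiallelic with more than four ALT alleles at the locus, have more
#' than 10% missing genotypes after genotype-level filtering, or span more
#' than 15 nucleotides. Boundaries are strict: exactly 4 alleles, 10%
#' missingness or 15 nt are retained. Site missingness is recomputed from
#' `calls` before filtering.
#'
#' @param variants variant tibble (see [simulate_cohort()]).
#' @param calls genotype calls after [apply_genotype_filters()].
#' @param config a [filter_config()].
#' @return a list with `variants` (retained sites, `site_missingness`
#'   updated) and `exclusion_log` (tibble: `variant_id`, `reason`).
#' @export
apply_site_filters <- function(variants, calls, config = filter_config()) {
  assert_columns(variants, c("variant_id", "n_alt_alleles_at_locus",
                             "span_nt", "in_masked_region"), "variants")
  miss <- calls |>
    dplyr::group_by(.data$variant_id) |>
    dplyr::summarise(site_missingness = mean(is.na(.data$dosage)))
  variants <- variants |>
    dplyr::select(-dplyr::any_of("site_missingness")) |>
    dplyr::left_join(miss, by = "variant_id") |>
    dplyr::mutate(site_missingness = dplyr::coalesce(.data$site_missingness, 0))
  reasons <- dplyr::bind_rows(
    tibble::tibble(variant_id = variants$variant_id[variants$in_masked_region],
                   reason = "masked_region"),
    tibble::tibble(variant_id = variants$variant_id[
      variants$n_alt_alleles_at_locus > config$max_alt_alleles],
      reason = "multiallelic_gt4"),
    tibble::tibble(variant_id = variants$variant_id[
      variants$site_missingness > config$max_site_missingness],
      reason = "high_missingness"),
    tibble::tibble(variant_id = variants$variant_id[
      variants$span_nt > config$max_span_nt],
      reason = "long_span")
  )
  list(
    variants = variants[!variants$variant_id %in% reasons$variant_id, ],
    exclusion_log = reasons
  )
}

#' Candidate variant class sets
#'
#' Partitions QC-passing panel variants into the analysis sets: the
#' `primary` set (nonsynonymous -- missense or pLOF -- and essential splice
#' variants with population MAF < 1e-4 and CADD above the gene-specific
#' mutation significance cutoff), the `plof` subset (primary-set variants
#' that are pLOF), the `plof_any_maf` set (pLOF with no MAF or CADD
#' restriction), and the `synonymous_control` set (synonymous, MAF < 1e-4,
#' no CADD rule) used for burden-test calibration.
#'
#' @param variants variant tibble (post site filters); every `gene` must be
#'   present in `panel`.
#' @param panel gene panel with `gene` and `msc` columns.
#' @param config a [filter_config()]; `msc_strict = FALSE` switches the CADD
#'   rule from strictly greater to greater-or-equal.
#' @return a named list of character vectors of variant ids (class
#'   `variant_class_sets`).
#' @export
select_candidate_variants <- function(variants, panel,
                                      config = filter_config()) {
  assert_columns(variants, c("variant_id", "gene", "consequence", "maf",
                             "cadd"), "variants")
  unknown <- setdiff(unique(variants$gene), panel$gene)
  if (length(unknown) > 0) {
    abort(paste0("variant(s) in gene(s) not in the panel: ",
                 paste(unknown, collapse = ", ")))
  }
  v <- dplyr::left_join(variants, panel[, c("gene", "msc")], by = "gene")
  above_msc <- if (isTRUE(config$msc_strict)) v$cadd > v$msc else v$cadd >= v$msc
  rare <- v$maf < config$candidate_max_maf
  nonsyn <- v$consequence %in% c("missense", "pLOF", "essential_splice")
  primary <- v$variant_id[nonsyn & rare & above_msc]
  structure(list(
    primary = primary,
    plof = intersect(v$variant_id[v$consequence == "pLOF"], primary),
    plof_any_maf = v$variant_id[v$consequence == "pLOF"],
    synonymous_control = v$variant_id[v$consequence == "synonymous" & rare]
  ), class = c("variant_class_sets", "list"))
}
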