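#' Run the full recessive enrichment analysis
#'
#' Orchestrates the analysis stages in order: genotype QC, site QC,
#' candidate-variant selection, recessive collapsing per variant set,
#' ancestry PCA, pairwise kinship, runs-of-homozygosity consanguinity,
#' covariate-adjusted burden tests (per variant set and gene subset) and
#' the cohort summary. Any stage failure aborts with a stage-named error.
#' Identical input and configuration yield byte-identical report tables.
#'
#' @param cohort an `rv_cohort` from [read_cohort()], [simulate_cohort()] or
#'   [pediatric_cohort_fixture()].
#' @param config a [filter_config()].
#' @param covariates covariate columns for the burden test (default sex and
#'   PC1..PC5; `character()` runs the unadjusted test).
#' @param variant_sets which variant class sets to analyse.
#' @param gene_subsets named list of gene subsets (`NULL` entry = all panel
#'   genes); by default the full panel and the autosomal genes.
#' @param out_dir optional output directory; when given, [write_report()]
#'   is called on the result.
#' @param precomputed optional named list of already-computed stage results
#'   to reuse (any of `qc`, `sites`, `sets`, `recessive_calls`, `pca`,
#'   `kinship`, `roh`), so a run can resume from a later stage with
#'   identical downstream numbers.
#' @return an `rv_report` list: `qc_log`, `site_exclusions`, `variant_sets`,
#'   `recessive_calls`, `pca`, `kinship`, `roh`, `burden`, `summary`,
#'   `config`, `seed`.
#' @export
run_pipeline <- function(cohort,
                         config = filter_config(),
                         covariates = c("sex", paste0("PC", 1:5)),
                         variant_sets = c("primary", "plof", "plof_any_maf",
                                          "synonymous_control"),
                         gene_subsets = NULL,
                         out_dir = NULL,
                         precomputed = list()) {
  stopifnot(inherits(cohort, "rv_cohort"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("stage %s: %s", name, conditionMessage(e)))
    })
  }
  panel <- cohort$panel
  if (is.null(gene_subsets)) {
    gene_subsets <- list(all_loci = NULL,
                         autosomal = panel$gene[!panel$is_x_linked])
  }

  qc <- precomputed$qc %||%
    stage("genotype_qc", apply_genotype_filters(cohort$calls, config))
  sites <- precomputed$sites %||%
    stage("site_qc", apply_site_filters(cohort$variants, qc$calls, config))
  sets <- precomputed$sets %||%
    stage("select_candidates",
          select_candidate_variants(sites$variants, panel, config))

  recessive_calls <- precomputed$recessive_calls %||%
    stage("collapse", {
      dplyr::bind_rows(lapply(variant_sets, function(lbl) {
        collapse_recessive(qc$calls, sets[[lbl]], sites$variants, panel,
                           cohort$samples, pedigree = cohort$pedigree,
                           deletions = cohort$deletions, set_label = lbl)
      }))
    })

  pca <- precomputed$pca %||%
    stage("pca", compute_pca(cohort$background, config))
  kinship <- precomputed$kinship %||%
    stage("kinship", king_kinship(cohort$background))
  roh <- precomputed$roh %||%
    stage("roh", homozygosity_rate(cohort$background, cohort$background_map,
                                   config))

  samples2 <- cohort$samples |>
    dplyr::left_join(roh$rates, by = "sample_id")

  burden <- stage("burden", {
    grid <- tidyr::expand_grid(set = variant_sets,
                               subset = names(gene_subsets))
    dplyr::bind_rows(purrr::pmap(grid, function(set, subset) {
      rc <- recessive_calls[recessive_calls$variant_set_label == set, ]
      res <- suppressWarnings(
        burden_test(samples2, rc, pca_scores = pca$scores,
                    covariates = covariates, genes = gene_subsets[[subset]],
                    set_label = set))
      dplyr::mutate(res, gene_subset = subset, .after = 1)
    })) |>
      dplyr::arrange(.data$gene_subset, .data$variant_set_label)
  })

  summary_tbl <- stage("summary", {
    cohort_summary(samples2,
                   recessive_calls[recessive_calls$variant_set_label ==
                                     "primary", ],
                   panel, kinship = kinship, config = config)
  })

  report <- structure(list(
    qc_log = qc$qc_log,
    site_exclusions = sites$exclusion_log,
    variant_sets = sets,
    recessive_calls = recessive_calls,
    pca = pca,
    kinship = kinship,
    roh = roh,
    burden = burden,
    summary = summary_tbl,
    config = unclass(config),
    seed = cohort$config$seed %||% NA_integer_
  ), class = "rv_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.rv_report <- function(x, ...) {
  cat("<rv_report>\n")
  cat(sprintf("  recessive calls: %d; burden rows: %d\n",
              nrow(x$recessive_calls), nrow(x$burden)))
  print(x$burden[, c("gene_subset", "variant_set_label", "carriers_cases",
                     "n_cases", "carriers_controls", "n_controls",
                     "odds_ratio", "p_value")])
  invisible(x)
}
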