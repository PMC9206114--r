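#' Recessive burden test
#'
#' Compares the proportion of cases and controls carrying at least one
#' qualifying recessive genotype, with a Firth penalized logistic regression
#' of case status on the carrier indicator, optionally adjusted for sex and
#' the first five ancestry principal components. The p-value is a penalized
#' likelihood-ratio test and the 95% confidence interval comes from the
#' profile penalized likelihood. Gene subsets (e.g. the 14 autosomal loci)
#' are supported through `genes`.
#'
#' @param samples sample tibble with `sample_id`, `group` (`"case"` /
#'   `"control"`) and, when used as covariates, `sex` and PC columns.
#' @param recessive_calls output of [collapse_recessive()].
#' @param pca_scores optional tibble from [compute_pca()]`$scores`, joined
#'   by `sample_id`.
#' @param covariates character vector of covariate column names (default
#'   `sex` and `PC1`..`PC5`; use `character()` for the unadjusted test).
#' @param genes optional gene subset; carriers are counted only for calls in
#'   these genes.
#' @param set_label label copied into the result row.
#' @return one-row tibble (class `burden_result`): carrier counts and sizes
#'   per group, `odds_ratio`, `ci_low`, `ci_high`, `p_value`,
#'   `covariates_used`.
#' @export
burden_test <- function(samples, recessive_calls, pca_scores = NULL,
                        covariates = c("sex", paste0("PC", 1:5)),
                        genes = NULL, set_label = NULL) {
  d <- samples[!is.na(samples$group), ]
  calls <- recessive_calls
  if (!is.null(genes)) calls <- calls[calls$gene %in% genes, ]
  d$carrier <- d$sample_id %in% calls$sample_id
  if (!is.null(pca_scores)) {
    d <- dplyr::left_join(d, pca_scores, by = "sample_id")
  }
  missing_cov <- setdiff(covariates, names(d))
  if (length(missing_cov) > 0) {
    abort(paste0("covariate column(s) not found: ",
                 paste(missing_cov, collapse = ", ")))
  }
  y <- as.numeric(d$group == "case")
  a <- sum(d$carrier & y == 1); b <- sum(!d$carrier & y == 1)
  c_ <- sum(d$carrier & y == 0); dd <- sum(!d$carrier & y == 0)
  label <- set_label %||% (unique(calls$variant_set_label)[1] %||% NA_character_)
  base <- tibble::tibble(
    variant_set_label = label,
    carriers_cases = a, n_cases = a + b,
    carriers_controls = c_, n_controls = c_ + dd,
    covariates_used = paste(covariates, collapse = ","))
  if (length(unique(d$carrier)) < 2) {
    warn("carrier indicator is constant; burden test is uninformative")
    return(structure(dplyr::mutate(base, odds_ratio = NA_real_,
                                   ci_low = NA_real_, ci_high = NA_real_,
                                   p_value = 1),
                     class = c("burden_result", class(base))))
  }
  rhs <- paste(c("carrier", covariates), collapse = " + ")
  fit <- firth_glm(stats::as.formula(paste("y ~", rhs)),
                   data = cbind(d, y = y))
  row <- tidy(fit, exponentiate = TRUE)
  row <- row[row$term == "carrierTRUE" | row$term == "carrier", ]
  out <- dplyr::mutate(base,
                       odds_ratio = row$estimate,
                       ci_low = row$conf.low,
                       ci_high = row$conf.high,
                       p_value = row$p.value)
  structure(out, class = c("burden_result", class(out)))
}

#' Cohort summary statistics
#'
#' Computes the descriptive statistics reported alongside the burden test:
#' carrier percentage in cases and controls (overall and in the unrelated
#' subset), prevalence of autosomal-recessive mechanisms among unrelated
#' patients (overall and in the critical stratum), X-linked carrier
#' percentage among male cases, consanguinity percentage per group with the
#' consanguinity-by-status Fisher exact test, an AR-carrier-by-consanguinity
#' Fisher test among unrelated cases, and the male:female case ratio.
#' Percentages are rounded half-up to one decimal (two decimals for the
#' control carrier percentage, whose magnitude is below 1).
#'
#' @param samples sample tibble; must contain `is_consanguineous` (e.g.
#'   joined from [homozygosity_rate()]`$rates`) for the consanguinity rows.
#' @param recessive_calls output of [collapse_recessive()] (primary set).
#' @param panel gene panel (separates AR from XR mechanisms).
#' @param kinship optional [king_kinship()] output for the unrelated-subset
#'   rows.
#' @param config a [filter_config()].
#' @return tibble with columns `metric`, `numerator`, `denominator`,
#'   `value` (unrounded) and `value_rounded`.
#' @export
cohort_summary <- function(samples, recessive_calls, panel, kinship = NULL,
                           config = filter_config()) {
  panel <- validate_panel(panel)
  d <- samples[!is.na(samples$group), ]
  ar_genes <- panel$gene[!panel$is_x_linked]
  xr_genes <- panel$gene[panel$is_x_linked]
  carriers <- unique(recessive_calls$sample_id)
  ar_mech <- c("homozygous", "compound_het_potential",
               "compound_het_confirmed", "homozygous_deletion")
  ar_carriers <- unique(recessive_calls$sample_id[
    recessive_calls$gene %in% ar_genes &
      recessive_calls$mechanism %in% ar_mech])
  xr_carriers <- unique(recessive_calls$sample_id[
    recessive_calls$gene %in% xr_genes &
      recessive_calls$mechanism == "hemizygous"])
  cases <- d$sample_id[d$group == "case"]
  ctrls <- d$sample_id[d$group == "control"]
  boys <- d$sample_id[d$group == "case" & d$sex == "male"]
  girls <- d$sample_id[d$group == "case" & d$sex == "female"]

  pct <- function(metric, num, den, digits = 1) {
    tibble::tibble(metric = metric, numerator = num, denominator = den,
                   value = 100 * num / den,
                   value_rounded = round_half_up(100 * num / den, digits))
  }
  rows <- list(
    pct("carrier_pct_cases", sum(cases %in% carriers), length(cases)),
    pct("carrier_pct_controls", sum(ctrls %in% carriers), length(ctrls),
        digits = 2),
    pct("xr_carrier_pct_male_cases", sum(boys %in% xr_carriers),
        length(boys))
  )
  if (!is.null(kinship)) {
    d_cases <- dplyr::mutate(d[d$group == "case", ],
                             carrier = .data$sample_id %in% carriers)
    unrel <- unrelated_subset(d_cases, kinship,
                              threshold = config$kinship_threshold)
    crit <- intersect(unrel, d$sample_id[d$severity %in% "critical"])
    rows <- c(rows, list(
      pct("carrier_pct_unrelated_cases", sum(unrel %in% carriers),
          length(unrel)),
      pct("ar_carrier_pct_unrelated_cases", sum(unrel %in% ar_carriers),
          length(unrel)),
      pct("ar_carrier_pct_unrelated_critical_cases",
          sum(crit %in% ar_carriers), length(crit))
    ))
    if ("is_consanguineous" %in% names(d)) {
      cons <- d$sample_id[d$is_consanguineous %in% TRUE]
      u_cons <- intersect(unrel, cons)
      u_noncons <- setdiff(unrel, cons)
      a <- sum(u_cons %in% ar_carriers); b <- length(u_cons) - a
      cc <- sum(u_noncons %in% ar_carriers); dd2 <- length(u_noncons) - cc
      rows <- c(rows, list(
        pct("ar_carrier_pct_unrelated_consanguineous_cases", a,
            length(u_cons)),
        pct("ar_carrier_pct_unrelated_nonconsanguineous_cases", cc,
            length(u_noncons)),
        tibble::tibble(metric = "fisher_ar_by_consanguinity_p",
                       numerator = a, denominator = cc,
                       value = fisher_exact_2x2(a, b, cc, dd2),
                       value_rounded = NA_real_)
      ))
    }
  }
  if ("is_consanguineous" %in% names(d)) {
    cons <- d$sample_id[d$is_consanguineous %in% TRUE]
    a <- sum(cases %in% cons); b <- length(cases) - a
    cc <- sum(ctrls %in% cons); dd2 <- length(ctrls) - cc
    rows <- c(rows, list(
      pct("consanguineous_pct_cases", a, length(cases)),
      pct("consanguineous_pct_controls", cc, length(ctrls)),
      tibble::tibble(metric = "fisher_consanguinity_by_status_p",
                     numerator = a, denominator = cc,
                     value = fisher_exact_2x2(a, b, cc, dd2),
                     value_rounded = NA_real_)
    ))
  }
  ratio <- length(boys) / length(girls)
  rows <- c(rows, list(
    tibble::tibble(metric = "male_female_ratio_cases",
                   numerator = length(boys), denominator = length(girls),
                   value = ratio, value_rounded = round_half_up(ratio, 1))
  ))
  dplyr::bind_rows(rows)
}
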