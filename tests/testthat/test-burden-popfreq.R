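test_that("burden test reports counts, OR and penalized-LRT p", {
  co <- planted_test_cohort(seed = 41)
  qc <- apply_genotype_filters(co$calls)
  st <- apply_site_filters(co$variants, qc$calls)
  sets <- select_candidate_variants(st$variants, co$panel)
  rc <- collapse_recessive(qc$calls, sets$primary, st$variants, co$panel,
                           co$samples, pedigree = co$pedigree)
  res <- burden_test(co$samples, rc, covariates = character())
  expect_s3_class(res, "burden_result")
  expect_equal(res$n_cases, 50)
  expect_equal(res$n_controls, 80)
  expect_equal(res$carriers_cases, 10)    # 4 hom + 3 chet + 3 hemi planted
  expect_equal(res$carriers_controls, 2)
  expect_true(res$ci_low <= res$odds_ratio & res$odds_ratio <= res$ci_high)
  expect_lt(res$p_value, 0.05)
  # gene subsetting: X-linked gene only
  res_x <- burden_test(co$samples, rc, covariates = character(),
                       genes = "TLR7")
  expect_equal(res_x$carriers_cases, 3)
})

test_that("a constant carrier indicator yields p = 1 with a warning", {
  co <- planted_test_cohort(seed = 42)
  empty <- co$truth[0, ]
  empty$variant_set_label <- character()
  expect_warning(
    res <- burden_test(co$samples,
                       tibble::tibble(sample_id = character(),
                                      gene = character(),
                                      mechanism = character(),
                                      variant_keys = character(),
                                      variant_set_label = character()),
                       covariates = character()),
    "constant")
  expect_equal(res$p_value, 1)
})

test_that("a null burden shows no association", {
  planted <- tibble::tibble(gene = "TYK2", mechanism = "homozygous",
                            n = 12, group = "any")
  co <- simulate_cohort(sim_config(n_cases = 80, n_controls = 160,
                                   n_background_snps = 200,
                                   planted_carriers = planted, seed = 43))
  qc <- apply_genotype_filters(co$calls)
  st <- apply_site_filters(co$variants, qc$calls)
  sets <- select_candidate_variants(st$variants, co$panel)
  rc <- collapse_recessive(qc$calls, sets$primary, st$variants, co$panel,
                           co$samples)
  res <- burden_test(co$samples, rc, covariates = character())
  expect_gt(res$p_value, 0.01)
})

test_that("ancestry adjustment absorbs confounded carrier imbalance", {
  # carriers concentrated in population 1; cases also drawn mostly from
  # population 1 -> unadjusted test confounded, PC-adjusted test less so
  planted <- tibble::tibble(gene = c("TYK2", "TYK2"),
                            mechanism = "homozygous",
                            n = c(28, 4), group = "any",
                            population = c(1L, 2L))
  co <- simulate_cohort(sim_config(
    n_cases = 100, n_controls = 200, n_populations = 2, fst = 0.1,
    n_background_snps = 600,
    pop_weights_cases = c(0.75, 0.25), pop_weights_controls = c(0.25, 0.75),
    planted_carriers = planted, seed = 44))
  qc <- apply_genotype_filters(co$calls)
  st <- apply_site_filters(co$variants, qc$calls)
  sets <- select_candidate_variants(st$variants, co$panel)
  rc <- collapse_recessive(qc$calls, sets$primary, st$variants, co$panel,
                           co$samples)
  pca <- compute_pca(co$background)
  p_unadj <- burden_test(co$samples, rc, covariates = character())$p_value
  p_adj <- burden_test(co$samples, rc, pca_scores = pca$scores,
                       covariates = paste0("PC", 1:5))$p_value
  expect_gt(p_adj, p_unadj)
})

test_that("recessive genotype frequencies follow Hardy-Weinberg arithmetic", {
  r <- recessive_genotype_frequency(c(0.001, 0.001), "autosomal")
  expect_equal(r$cumulative_maf, 0.002)
  expect_equal(r$genotype_frequency, 4e-6)
  x <- recessive_genotype_frequency(c(4e-5, 4e-5), "x_linked",
                                    male_fraction = 0.5)
  expect_equal(x$cumulative_maf, 8e-5)
  expect_equal(x$genotype_frequency, 0.5 * 8e-5 + 0.5 * (8e-5)^2)
  empty <- recessive_genotype_frequency(numeric(0), "autosomal")
  expect_equal(empty$cumulative_maf, 0)
  expect_equal(empty$genotype_frequency, 0)
  expect_error(recessive_genotype_frequency(c(0.6), "autosomal"), "0.5")
  # genotype frequency never exceeds cumulative MAF; (sum q)^2 >= sum q^2
  set.seed(45)
  for (i in 1:20) {
    q <- runif(sample(1:6, 1), 0, 0.05)
    rr <- recessive_genotype_frequency(q, "autosomal")
    expect_lte(rr$genotype_frequency, rr$cumulative_maf)
    expect_gte(rr$genotype_frequency, sum(q^2) - 1e-15)
  }
})

test_that("panel aggregation is additive and order-insensitive in Q", {
  g1 <- recessive_genotype_frequency(c(0.001), "autosomal", gene = "A")
  g2 <- recessive_genotype_frequency(c(0.001), "autosomal", gene = "B")
  agg <- panel_cumulative_frequency(dplyr::bind_rows(g1, g2))
  expect_equal(agg$cumulative_maf, 0.002)
  expect_equal(agg$genotype_frequency, 2e-6)
  # single gene: identity
  one <- panel_cumulative_frequency(g1)
  expect_equal(one$genotype_frequency, g1$genotype_frequency)
  expect_error(panel_cumulative_frequency(dplyr::bind_rows(g1, g1)),
               "duplicated")
  # Q is linear under allele partitioning; the genotype frequency is not
  split_gene <- dplyr::bind_rows(
    recessive_genotype_frequency(c(0.001), "autosomal", gene = "A1"),
    recessive_genotype_frequency(c(0.001), "autosomal", gene = "A2"))
  joint <- recessive_genotype_frequency(c(0.001, 0.001), "autosomal",
                                        gene = "A")
  agg_split <- panel_cumulative_frequency(split_gene)
  expect_equal(agg_split$cumulative_maf, joint$cumulative_maf)
  expect_lt(agg_split$genotype_frequency, joint$genotype_frequency)
})
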