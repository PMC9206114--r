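test_that("genotype filters implement the depth/GQ/allele-balance rules", {
  calls <- dplyr::bind_rows(
    toy_call("a", dp = 7, gq = 60),                       # depth < 8
    toy_call("b", dp = 30, gq = 19),                      # GQ < 20
    toy_call("c", ad_ref = 10, ad_alt = 3, dp = 13),      # 3/13 = 0.231 kept
    toy_call("d", ad_ref = 10, ad_alt = 2, dp = 12),      # 2/12 = 0.167 out
    toy_call("e", dp = 8, gq = 20, ad_ref = 4, ad_alt = 4),  # boundary kept
    toy_call("f", dosage = 2, ad_ref = 0, ad_alt = 30),   # hom exempt
    toy_call("g", ad_ref = NA, ad_alt = NA),              # het without AD
    toy_call("h", dosage = 1, hemi = TRUE, ad_ref = 0, ad_alt = 30)
  )
  out <- apply_genotype_filters(calls, filter_config())
  missing_now <- out$calls$sample_id[is.na(out$calls$dosage)]
  expect_setequal(missing_now, c("a", "b", "d", "g"))
  log <- tibble::deframe(out$qc_log)
  expect_equal(unname(log["low_depth"]), 1)
  expect_equal(unname(log["low_genotype_quality"]), 1)
  expect_equal(unname(log["low_minor_read_ratio"]), 1)
  expect_equal(unname(log["het_missing_allele_depths"]), 1)
})

test_that("site filters drop masked, hypermultiallelic, missing-rich and long sites", {
  variants <- dplyr::bind_rows(
    toy_variant("v_ok"),
    toy_variant("v_mask", masked = TRUE),
    toy_variant("v_alt5", n_alt = 5L),
    toy_variant("v_alt4", n_alt = 4L),
    toy_variant("v_span15", span = 15L),
    toy_variant("v_span16", span = 16L),
    toy_variant("v_miss")
  )
  samples <- sprintf("s%02d", 1:50)
  calls <- tidyr::expand_grid(sample_id = samples,
                              variant_id = variants$variant_id) |>
    dplyr::mutate(dosage = 0L, hemi = FALSE, dp = 30L, gq = 99L,
                  ad_ref = 30L, ad_alt = 0L)
  # 12% missing at v_miss only
  calls$dosage[calls$variant_id == "v_miss"][1:6] <- NA_integer_
  out <- apply_site_filters(variants, calls, filter_config())
  expect_setequal(out$variants$variant_id,
                  c("v_ok", "v_alt4", "v_span15"))
  expect_setequal(out$exclusion_log$variant_id,
                  c("v_mask", "v_alt5", "v_span16", "v_miss"))
  expect_equal(
    out$exclusion_log$reason[out$exclusion_log$variant_id == "v_miss"],
    "high_missingness")
})

test_that("filtering is idempotent", {
  co <- planted_test_cohort(seed = 5, qc_noise = list(missing_rate = 0.05,
                                                      mean_depth = 20,
                                                      gq_mean = 60,
                                                      gq_sd = 30))
  once <- apply_genotype_filters(co$calls)
  twice <- apply_genotype_filters(once$calls)
  expect_identical(once$calls$dosage, twice$calls$dosage)
  s_once <- apply_site_filters(co$variants, once$calls)
  s_twice <- apply_site_filters(s_once$variants, once$calls)
  expect_identical(s_once$variants$variant_id, s_twice$variants$variant_id)
})

test_that("tightening thresholds never enlarges the retained set", {
  co <- planted_test_cohort(seed = 6, qc_noise = list(missing_rate = 0.03,
                                                      mean_depth = 15,
                                                      gq_mean = 50,
                                                      gq_sd = 30))
  loose <- apply_genotype_filters(co$calls, filter_config())
  tight <- apply_genotype_filters(co$calls, filter_config(min_depth = 15,
                                                          min_gq = 40))
  kept_loose <- !is.na(loose$calls$dosage)
  kept_tight <- !is.na(tight$calls$dosage)
  expect_true(all(kept_loose | !kept_tight))  # tight subset of loose
  s_loose <- apply_site_filters(co$variants, loose$calls, filter_config())
  s_tight <- apply_site_filters(co$variants, loose$calls,
                                filter_config(max_site_missingness = 0.02,
                                              max_span_nt = 5))
  expect_true(all(s_tight$variants$variant_id %in%
                    s_loose$variants$variant_id))
})

test_that("candidate selection builds the four variant class sets", {
  panel <- default_gene_panel(msc = 20)
  variants <- dplyr::bind_rows(
    toy_variant("qual_mis", consequence = "missense", maf = 5e-5, cadd = 25),
    toy_variant("common_mis", consequence = "missense", maf = 2e-4, cadd = 25),
    toy_variant("weak_mis", consequence = "missense", maf = 5e-5, cadd = 18),
    toy_variant("msc_tie", consequence = "missense", maf = 5e-5, cadd = 20),
    toy_variant("qual_lof", consequence = "pLOF", maf = 5e-5, cadd = 35),
    toy_variant("common_lof", consequence = "pLOF", maf = 2e-3, cadd = 35),
    toy_variant("splice", consequence = "essential_splice", maf = 5e-5,
                cadd = 28),
    toy_variant("syn", consequence = "synonymous", maf = 5e-5, cadd = 2),
    toy_variant("syn_common", consequence = "synonymous", maf = 1e-3,
                cadd = 2)
  )
  sets <- select_candidate_variants(variants, panel)
  expect_setequal(sets$primary, c("qual_mis", "qual_lof", "splice"))
  expect_setequal(sets$plof, "qual_lof")
  expect_setequal(sets$plof_any_maf, c("qual_lof", "common_lof"))
  expect_setequal(sets$synonymous_control, "syn")
  # invariants: plof within primary; synonymous disjoint from primary
  expect_true(all(sets$plof %in% sets$primary))
  expect_length(intersect(sets$synonymous_control, sets$primary), 0)
  # strict ">" by default; ">=" by flag
  expect_false("msc_tie" %in% sets$primary)
  sets_ge <- select_candidate_variants(variants, panel,
                                       filter_config(msc_strict = FALSE))
  expect_true("msc_tie" %in% sets_ge$primary)
  expect_error(
    select_candidate_variants(toy_variant(gene = "NOTAGENE"), panel),
    "NOTAGENE")
})
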