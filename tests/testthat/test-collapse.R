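panel20 <- default_gene_panel(msc = 20)

test_that("recessive mechanisms are assigned per the model", {
  variants <- dplyr::bind_rows(
    toy_variant("t1", gene = "TYK2"),
    toy_variant("t2", gene = "TYK2"),
    toy_variant("x1", gene = "TLR7", chromosome = "X")
  )
  samples <- dplyr::bind_rows(
    toy_samples("hom_f", sex = "female"),
    toy_samples("het_f", sex = "female"),
    toy_samples("chet_f", sex = "female"),
    toy_samples("hemi_m", sex = "male"),
    toy_samples("x_het_f", sex = "female")
  )
  calls <- dplyr::bind_rows(
    toy_call("hom_f", "t1", dosage = 2, ad_ref = 0, ad_alt = 30),
    toy_call("het_f", "t1", dosage = 1),
    toy_call("chet_f", "t1", dosage = 1),
    toy_call("chet_f", "t2", dosage = 1),
    toy_call("hemi_m", "x1", dosage = 1, hemi = TRUE, ad_ref = 0,
             ad_alt = 30),
    toy_call("x_het_f", "x1", dosage = 1)
  )
  rc <- collapse_recessive(calls, variants$variant_id, variants, panel20,
                           samples)
  mech <- setNames(rc$mechanism, rc$sample_id)
  expect_equal(unname(mech["hom_f"]), "homozygous")
  expect_equal(unname(mech["chet_f"]), "compound_het_potential")
  expect_equal(unname(mech["hemi_m"]), "hemizygous")
  # single heterozygous sites are not recessive genotypes
  expect_false("het_f" %in% rc$sample_id)
  expect_false("x_het_f" %in% rc$sample_id)
})

test_that("trio genotypes separate trans from cis compound heterozygotes", {
  variants <- dplyr::bind_rows(toy_variant("a", gene = "STAT2",
                                           chromosome = "12"),
                               toy_variant("b", gene = "STAT2",
                                           chromosome = "12"))
  variants$variant_id <- c("a", "b")
  ped <- tibble::tibble(family_id = "f1", sample_id = "kid",
                        father_id = "dad", mother_id = "mum",
                        sex = "male", affected = TRUE)
  samples <- toy_samples(c("kid", "dad", "mum"))
  base <- dplyr::bind_rows(
    toy_call("kid", "a", dosage = 1), toy_call("kid", "b", dosage = 1))
  trans <- dplyr::bind_rows(
    base,
    toy_call("dad", "a", dosage = 1), toy_call("dad", "b", dosage = 0),
    toy_call("mum", "a", dosage = 0), toy_call("mum", "b", dosage = 1))
  rc <- collapse_recessive(trans, c("a", "b"), variants, panel20, samples,
                           pedigree = ped)
  expect_equal(rc$mechanism, "compound_het_confirmed")

  cis <- dplyr::bind_rows(
    base,
    toy_call("dad", "a", dosage = 1), toy_call("dad", "b", dosage = 1),
    toy_call("mum", "a", dosage = 0), toy_call("mum", "b", dosage = 0))
  rc_cis <- collapse_recessive(cis, c("a", "b"), variants, panel20, samples,
                               pedigree = ped)
  expect_false("kid" %in% rc_cis$sample_id)

  # no parental genotypes -> potential, still a carrier
  rc_nop <- collapse_recessive(base, c("a", "b"), variants, panel20,
                               samples)
  expect_equal(rc_nop$mechanism, "compound_het_potential")
})

test_that("homozygous deletions are carriers; malformed inputs error", {
  variants <- toy_variant("t1", gene = "TYK2")
  samples <- toy_samples("s1", sex = "female")
  del <- tibble::tibble(sample_id = "s1", gene = "IFNAR1",
                        chromosome = "21", start = 10L, end = 20L,
                        copy_number = 0L)
  rc <- collapse_recessive(toy_call("s1", "t1", dosage = 0), "t1", variants,
                           panel20, samples, deletions = del)
  expect_equal(rc$mechanism, "homozygous_deletion")
  expect_equal(rc$gene, "IFNAR1")
  # deletions do not contribute synonymous-set carriers
  rc_syn <- collapse_recessive(toy_call("s1", "t1", dosage = 0), "t1",
                               variants, panel20, samples, deletions = del,
                               set_label = "synonymous_control")
  expect_equal(nrow(rc_syn), 0)
  expect_error(
    collapse_recessive(toy_call("s1", "t1"), "t1", variants, panel20,
                       samples,
                       deletions = dplyr::mutate(del, copy_number = 1L)),
    "copy_number")
  ped_bad <- tibble::tibble(family_id = "f", sample_id = "ghost",
                            father_id = NA, mother_id = NA, sex = "male",
                            affected = TRUE)
  expect_error(
    collapse_recessive(toy_call("s1", "t1"), "t1", variants, panel20,
                       samples, pedigree = ped_bad),
    "unknown sample")
})

test_that("one call per gene with the strongest mechanism", {
  variants <- dplyr::bind_rows(toy_variant("a", gene = "TYK2"),
                               toy_variant("b", gene = "TYK2"),
                               toy_variant("c", gene = "TYK2"))
  variants$variant_id <- c("a", "b", "c")
  samples <- toy_samples("s1", sex = "female")
  calls <- dplyr::bind_rows(
    toy_call("s1", "a", dosage = 2, ad_ref = 0, ad_alt = 30),
    toy_call("s1", "b", dosage = 1),
    toy_call("s1", "c", dosage = 1))
  rc <- collapse_recessive(calls, c("a", "b", "c"), variants, panel20,
                           samples)
  expect_equal(nrow(rc), 1)
  expect_equal(rc$mechanism, "homozygous")
})

test_that("carrier status is order/batch invariant and anti-monotone", {
  co <- planted_test_cohort(seed = 31)
  qc <- apply_genotype_filters(co$calls)
  st <- apply_site_filters(co$variants, qc$calls)
  sets <- select_candidate_variants(st$variants, co$panel)
  rc <- collapse_recessive(qc$calls, sets$primary, st$variants, co$panel,
                           co$samples, pedigree = co$pedigree)
  # permuted call order
  set.seed(1)
  rc_perm <- collapse_recessive(qc$calls[sample(nrow(qc$calls)), ],
                                sets$primary, st$variants, co$panel,
                                co$samples, pedigree = co$pedigree)
  expect_identical(rc, rc_perm)
  # batch split by variant: union of per-batch qualifying sets
  half <- seq_len(floor(length(sets$primary) / 2))
  rc_a <- collapse_recessive(qc$calls, sets$primary[half], st$variants,
                             co$panel, co$samples, pedigree = co$pedigree)
  rc_b <- collapse_recessive(qc$calls, sets$primary[-half], st$variants,
                             co$panel, co$samples, pedigree = co$pedigree)
  carriers_split <- union(rc_a$sample_id, rc_b$sample_id)
  # removing variants never creates carriers (anti-monotone), and every
  # full-set carrier whose variants fall wholly in one batch reappears
  expect_true(all(carriers_split %in% rc$sample_id))
  for (drop_one in sample(sets$primary, 5)) {
    rc_drop <- collapse_recessive(qc$calls, setdiff(sets$primary, drop_one),
                                  st$variants, co$panel, co$samples,
                                  pedigree = co$pedigree)
    expect_true(all(rc_drop$sample_id %in% rc$sample_id))
  }
})

test_that("planted carriers and mechanisms are recovered exactly", {
  co <- planted_test_cohort(seed = 32)
  qc <- apply_genotype_filters(co$calls)
  st <- apply_site_filters(co$variants, qc$calls)
  sets <- select_candidate_variants(st$variants, co$panel)
  rc <- collapse_recessive(qc$calls, sets$primary, st$variants, co$panel,
                           co$samples, pedigree = co$pedigree)
  rc <- rc[rc$sample_id %in%
             co$samples$sample_id[!is.na(co$samples$group)], ]
  truth_key <- paste(co$truth$sample_id, co$truth$gene)
  found_key <- paste(rc$sample_id, rc$gene)
  expect_setequal(found_key, truth_key)
  # mechanism labels match (compound hets may be upgraded to confirmed by
  # their trio)
  merged <- dplyr::inner_join(co$truth, rc, by = c("sample_id", "gene"))
  expect_true(all(
    merged$mechanism.y == merged$mechanism.x |
      (merged$mechanism.x == "compound_het" &
         merged$mechanism.y %in% c("compound_het_potential",
                                   "compound_het_confirmed"))))
})

test_that("segregation reports distinguish penetrance from Mendel errors", {
  variants <- toy_variant("a", gene = "TYK2")
  ped <- tibble::tibble(
    family_id = "f1",
    sample_id = c("kid", "dad", "mum", "sib"),
    father_id = c("dad", NA, NA, "dad"),
    mother_id = c("mum", NA, NA, "mum"),
    sex = c("male", "male", "female", "male"),
    affected = c(TRUE, FALSE, FALSE, FALSE))
  textbook <- dplyr::bind_rows(
    toy_call("kid", "a", dosage = 2, ad_ref = 0, ad_alt = 30),
    toy_call("dad", "a", dosage = 1),
    toy_call("mum", "a", dosage = 1),
    toy_call("sib", "a", dosage = 1))
  rep1 <- check_segregation(ped, textbook, variants, panel20, "TYK2")
  expect_true(rep1$consistent)
  expect_equal(rep1$genotype_positive_unaffected, "")

  # unaffected sib with the full genotype: penetrance note, not an error
  shared <- textbook
  shared$dosage[shared$sample_id == "sib"] <- 2L
  rep2 <- check_segregation(ped, shared, variants, panel20, "TYK2")
  expect_true(rep2$consistent)
  expect_equal(rep2$genotype_positive_unaffected, "sib")

  # genotyped parent without the allele: Mendelian inconsistency
  mendel <- textbook
  mendel$dosage[mendel$sample_id == "dad"] <- 0L
  rep3 <- check_segregation(ped, mendel, variants, panel20, "TYK2")
  expect_false(rep3$consistent)
  expect_gt(rep3$n_inconsistencies, 0)

  # hemizygote with an asymptomatic carrier sibling
  xv <- toy_variant("x1", gene = "TLR7", chromosome = "X")
  xcalls <- dplyr::bind_rows(
    toy_call("kid", "x1", dosage = 1, hemi = TRUE, ad_ref = 0, ad_alt = 30),
    toy_call("mum", "x1", dosage = 1),
    toy_call("sib", "x1", dosage = 1, hemi = TRUE, ad_ref = 0, ad_alt = 30))
  rep4 <- check_segregation(ped, xcalls, xv, panel20, "TLR7")
  expect_true(rep4$consistent)
  expect_equal(rep4$genotype_positive_unaffected, "sib")
})
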