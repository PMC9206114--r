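#' Built-in pediatric COVID-19 pneumonia cohort fixture
#'
#' Constructs, fully in code, a cohort reproducing the published structure of
#' an international study of recessive inborn errors of type I IFN immunity
#' in children hospitalized for COVID-19 pneumonia: 112 patients (78 boys,
#' 34 girls; 25 moderate, 15 severe, 72 critical) and 1,224 asymptomatic or
#' mildly infected controls (306 male, 918 female). Twelve patients carry a
#' qualifying recessive genotype at the 15-gene candidate panel -- one STAT2
#' compound heterozygote (critical), three TYK2 homozygotes (moderate,
#' critical, critical), seven TLR7 hemizygotes and one IFNAR1 homozygous
#' deletion (critical) -- and three controls carry qualifying but
#' biochemically neutral genotypes (TLR7 hemizygous, IFIH1 homozygous, IRF7
#' homozygous). Twenty-six patients and 75 controls are simulated as
#' offspring of consanguineous unions (inbreeding coefficient 0.0625). Four
#' related patient pairs are planted as full siblings: the two TLR7 carrier
#' pairs sharing a variant, plus two non-carrier pairs placed among critical
#' patients so that the unrelated subset contains 108 patients, 70 of them
#' critical.
#'
#' All genotypes are noise-free (depth 30, GQ 99), so quality filters pass
#' everything through and the printed cohort proportions are recovered
#' deterministically.
#'
#' @param seed integer seed controlling the background genome, ancestry
#'   assignment and autozygous block placement (the carrier layout above is
#'   fixed and independent of the seed).
#' @param n_background_snps number of common autosomal SNPs in the
#'   background map used for PCA, kinship and runs of homozygosity.
#' @return an `rv_cohort` object (see [simulate_cohort()]); `truth` carries
#'   an `is_deleterious` flag separating the 12 patient genotypes from the 3
#'   neutral control genotypes.
#' @export
#' @examples
#' \donttest{
#' cohort <- pediatric_cohort_fixture(seed = 1, n_background_snps = 2000)
#' dplyr::count(cohort$samples, group, sex)
#' }
pediatric_cohort_fixture <- function(seed = 1, n_background_snps = 16000) {
  config <- sim_config(
    n_cases = 112, n_controls = 1224,
    n_populations = 3, fst = 0.1,
    pop_weights_cases = c(0.5, 0.3, 0.2),
    pop_weights_controls = c(0.2, 0.65, 0.15),
    n_background_snps = n_background_snps,
    consanguineous_fraction_cases = 0,
    consanguineous_fraction_controls = 0,
    seed = seed
  )
  case_ids <- sprintf("P%03d", 1:112)
  ctrl_ids <- sprintf("C%04d", 1:1224)

  # --- carrier layout (fixed) --------------------------------------------
  carrier_sex <- c(P001 = "male", P002 = "female", P003 = "male",
                   P004 = "male", P005 = "male", P006 = "male",
                   P007 = "male", P008 = "male", P009 = "male",
                   P010 = "male", P011 = "male", P012 = "female")
  carrier_sev <- c(P001 = "critical", P002 = "moderate", P003 = "critical",
                   P004 = "critical", P005 = "severe", P006 = "severe",
                   P007 = "severe", P008 = "critical", P009 = "moderate",
                   P010 = "critical", P011 = "critical", P012 = "critical")
  sibling_pairs <- list(c("P006", "P007"), c("P008", "P009"),
                        c("P013", "P014"), c("P015", "P016"))

  set.seed(derive_seed(seed, "fixture-samples"))
  # severity for non-carrier patients: totals 25 moderate / 15 severe /
  # 72 critical; carriers contribute 2/3/7 and P013-P016 are critical.
  rest_ids <- sprintf("P%03d", 17:112)                # 96 samples
  rest_sev <- sample(rep(c("moderate", "severe", "critical"),
                         c(23, 12, 61)))
  severity_cases <- c(carrier_sev,
                      setNames(rep("critical", 4), sprintf("P%03d", 13:16)),
                      setNames(rest_sev, rest_ids))[case_ids]
  # sex: 78 boys in total, 10 of them carriers
  noncarrier_ids <- sprintf("P%03d", 13:112)
  sex_rest <- sample(rep(c("male", "female"), c(68, 32)))
  sex_cases <- c(carrier_sex, setNames(sex_rest, noncarrier_ids))[case_ids]

  ctrl_sex <- setNames(rep(NA_character_, 1224), ctrl_ids)
  ctrl_sex[c("C0001", "C0002", "C0003")] <- c("male", "female", "male")
  ctrl_sex[is.na(ctrl_sex)] <- sample(rep(c("male", "female"), c(304, 917)))
  ctrl_sev <- setNames(sample(c("asymptomatic", "mild"), 1224, TRUE,
                              prob = c(0.4, 0.6)), ctrl_ids)
  ctrl_sev[c("C0001", "C0002", "C0003")] <- "asymptomatic"

  samples <- tibble::tibble(
    sample_id = c(case_ids, ctrl_ids),
    group = rep(c("case", "control"), c(112, 1224)),
    sex = c(sex_cases, unname(ctrl_sex)),
    severity = c(severity_cases, unname(ctrl_sev)),
    family_id = NA_character_
  )
  for (k in seq_along(sibling_pairs)) {
    samples$family_id[samples$sample_id %in% sibling_pairs[[k]]] <-
      sprintf("fam_%02d", k)
  }
  # ancestry: carriers predominantly population 1 (P005 population 2)
  samples$population <- NA_integer_
  is_case <- samples$group == "case"
  samples$population[is_case] <-
    sample.int(3, 112, TRUE, prob = config$pop_weights_cases)
  samples$population[!is_case] <-
    sample.int(3, 1224, TRUE, prob = config$pop_weights_controls)
  samples$population[samples$sample_id %in% names(carrier_sex)] <- 1L
  samples$population[samples$sample_id == "P005"] <- 2L
  for (pair in sibling_pairs) {
    idx <- match(pair, samples$sample_id)
    samples$population[idx[2]] <- samples$population[idx[1]]
  }

  # consanguineous subsets: 26 patients (incl. the TYK2 homozygotes, P011
  # and P012) and 75 controls; sibling-pair members stay outbred
  cons_cases <- c("P002", "P003", "P004", "P011", "P012",
                  sample(sprintf("P%03d", 17:112), 21))
  cons_ctrls <- sample(sprintf("C%04d", 4:1224), 75)
  samples$consanguineous_truth <-
    samples$sample_id %in% c(cons_cases, cons_ctrls)

  # --- background genome --------------------------------------------------
  set.seed(derive_seed(seed, "fixture-background"))
  bg <- sim_background_map(config)
  G <- sim_background_genotypes(samples$population, bg$pop_freq)
  rownames(G) <- samples$sample_id
  colnames(G) <- bg$map$variant_id

  set.seed(derive_seed(seed, "fixture-siblings"))
  for (pair in sibling_pairs) {
    idx <- match(pair, samples$sample_id)
    G <- sim_sibling_rows(G, idx, bg$pop_freq[samples$population[idx[1]], ])
  }

  set.seed(derive_seed(seed, "fixture-autozygosity"))
  autoz <- list()
  for (i in which(samples$consanguineous_truth)) {
    res <- simulate_autozygosity(G[i, ], bg$map,
                                 bg$pop_freq[samples$population[i], ],
                                 config$inbreeding_f,
                                 config$autozygous_block_kb)
    G[i, ] <- res$dosages
    autoz[[length(autoz) + 1]] <-
      dplyr::mutate(res$segments, sample_id = samples$sample_id[i],
                    .before = 1)
  }

  # --- panel variants -----------------------------------------------------
  set.seed(derive_seed(seed, "fixture-panel"))
  variants <- sim_panel_variants(config)
  # bespoke carrier variants (qualifying: rare, nonsynonymous, CADD > MSC)
  fx <- function(gene, offset, consequence, cadd, maf = 2e-5) {
    prow <- panel_gene_positions(config$panel, config$chrom_length)
    prow <- prow[prow$gene == gene, ]
    tibble::tibble(
      chromosome = prow$chromosome, position = prow$gene_pos + 60000 + offset,
      ref = "C", alt = "T", gene = gene, consequence = consequence,
      maf = maf, cadd = cadd, n_alt_alleles_at_locus = 1L, span_nt = 1L,
      in_masked_region = FALSE)
  }
  bespoke <- dplyr::bind_rows(
    fx("STAT2", 10, "missense", 26),  # P1, allele 1
    fx("STAT2", 20, "pLOF", 41),      # P1, allele 2
    fx("TYK2", 10, "pLOF", 38),       # P2-P4
    fx("TLR7", 10, "missense", 24),   # P5
    fx("TLR7", 20, "missense", 27),   # P6, P7
    fx("TLR7", 30, "missense", 25),   # P8, P9
    fx("TLR7", 40, "missense", 28),   # P10
    fx("TLR7", 50, "missense", 23),   # P11
    fx("TLR7", 60, "missense", 22),   # C1 (neutral)
    fx("IFIH1", 10, "missense", 24),  # C2 (neutral)
    fx("IRF7", 10, "missense", 21)    # C3 (neutral)
  )
  bespoke$variant_id <- variant_id(bespoke$chromosome, bespoke$position,
                                   bespoke$ref, bespoke$alt)
  variants <- dplyr::bind_rows(variants, bespoke)

  D <- sim_panel_background(variants[!variants$variant_id %in%
                                       bespoke$variant_id, ],
                            samples, config$panel)
  Db <- matrix(0L, nrow(samples), nrow(bespoke),
               dimnames = list(samples$sample_id, bespoke$variant_id))
  D <- cbind(D, Db)[, variants$variant_id]

  bv <- bespoke$variant_id
  plant <- list(
    list("P001", bv[1:2], c(1L, 1L), "STAT2", "compound_het", TRUE),
    list("P002", bv[3], 2L, "TYK2", "homozygous", TRUE),
    list("P003", bv[3], 2L, "TYK2", "homozygous", TRUE),
    list("P004", bv[3], 2L, "TYK2", "homozygous", TRUE),
    list("P005", bv[4], 1L, "TLR7", "hemizygous", TRUE),
    list("P006", bv[5], 1L, "TLR7", "hemizygous", TRUE),
    list("P007", bv[5], 1L, "TLR7", "hemizygous", TRUE),
    list("P008", bv[6], 1L, "TLR7", "hemizygous", TRUE),
    list("P009", bv[6], 1L, "TLR7", "hemizygous", TRUE),
    list("P010", bv[7], 1L, "TLR7", "hemizygous", TRUE),
    list("P011", bv[8], 1L, "TLR7", "hemizygous", TRUE),
    list("C0001", bv[9], 1L, "TLR7", "hemizygous", FALSE),
    list("C0002", bv[10], 2L, "IFIH1", "homozygous", FALSE),
    list("C0003", bv[11], 2L, "IRF7", "homozygous", FALSE)
  )
  truth <- list()
  for (p in plant) {
    D[p[[1]], p[[2]]] <- p[[3]]
    truth[[length(truth) + 1]] <- tibble::tibble(
      sample_id = p[[1]], gene = p[[4]], mechanism = p[[5]],
      variant_keys = paste(sort(p[[2]]), collapse = ","),
      is_deleterious = p[[6]])
  }
  deletions <- tibble::tibble(
    sample_id = "P012", gene = "IFNAR1", chromosome = "21",
    start = 8500001L, end = 8504394L, copy_number = 0L)
  truth[[length(truth) + 1]] <- tibble::tibble(
    sample_id = "P012", gene = "IFNAR1", mechanism = "homozygous_deletion",
    variant_keys = "IFNAR1:del", is_deleterious = TRUE)
  truth <- dplyr::bind_rows(truth)

  # a few rare synonymous homozygotes so the synonymous control analysis is
  # exercised (not carriers of the primary set)
  syn <- variants$variant_id[variants$consequence == "synonymous" &
                               variants$maf < 1e-4 &
                               !(variants$gene %in% "TLR7")]
  syn_carriers <- c(sample(sprintf("P%03d", 17:112), 2),
                    sample(sprintf("C%04d", 4:1224), 18))
  for (s in syn_carriers) D[s, sample(syn, 1)] <- 2L

  set.seed(derive_seed(seed, "fixture-calls"))
  calls <- sim_calls_from_dosage(D, variants, samples, config$panel,
                                 qc_noise = NULL)
  variants$site_missingness <- 0

  structure(list(
    samples = samples,
    panel = config$panel,
    variants = variants,
    calls = calls,
    background = G,
    background_map = bg$map,
    pedigree = NULL,
    deletions = deletions,
    truth = truth,
    autozygous_truth = dplyr::bind_rows(autoz),
    sibling_pairs = sibling_pairs,
    config = config
  ), class = "rv_cohort")
}
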