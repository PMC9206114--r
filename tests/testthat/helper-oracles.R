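# Independent oracles and small builders shared across test files.

# Brute-force maximizer of the Firth-penalized log-likelihood for a
# two-parameter (intercept + one covariate) design, by iterative 2-D grid
# refinement. Written directly from the definition of the penalized
# likelihood; shares no code with the package's Newton fitter.
oracle_pll <- function(X, y, beta) {
  eta <- drop(X %*% beta)
  pi <- plogis(eta)
  w <- pi * (1 - pi)
  info <- t(X) %*% (X * w)
  lse <- ifelse(eta > 0, eta + log1p(exp(-eta)), log1p(exp(eta)))
  ld <- determinant(info, logarithm = TRUE)
  sum(y * eta - lse) + 0.5 * as.numeric(ld$modulus)
}

oracle_grid_max <- function(X, y, centre = c(0, 0), width = 8, rounds = 8) {
  for (r in seq_len(rounds)) {
    b0 <- seq(centre[1] - width, centre[1] + width, length.out = 31)
    b1 <- seq(centre[2] - width, centre[2] + width, length.out = 31)
    vals <- outer(seq_along(b0), seq_along(b1), Vectorize(function(i, j)
      oracle_pll(X, y, c(b0[i], b1[j]))))
    best <- arrayInd(which.max(vals), dim(vals))
    centre <- c(b0[best[1]], b1[best[2]])
    width <- width * 2 / 30 * 1.5
  }
  centre
}

# Per-base interval-overlap oracle for BED masking: is 1-based position p on
# chromosome ch covered by any 0-based half-open [start, end) interval?
oracle_bed_covers <- function(bed, ch, p) {
  covered <- FALSE
  for (i in seq_len(nrow(bed))) {
    if (bed$chrom[i] != ch) next
    for (base0 in seq(bed$start[i], bed$end[i] - 1)) {
      if (base0 + 1 == p) covered <- TRUE   # 0-based base -> 1-based position
    }
  }
  covered
}

# Minimal genotype-call tibble builder.
toy_call <- function(sample_id = "s1", variant_id = "1:100:A:G",
                     dosage = 1L, dp = 30L, gq = 99L,
                     ad_ref = 15L, ad_alt = 15L, hemi = FALSE) {
  tibble::tibble(sample_id = sample_id, variant_id = variant_id,
                 dosage = as.integer(dosage), hemi = hemi,
                 dp = as.integer(dp), gq = as.integer(gq),
                 ad_ref = as.integer(ad_ref), ad_alt = as.integer(ad_alt))
}

# Minimal variant row joined to the default panel.
toy_variant <- function(variant_id = "1:100:A:G", gene = "TYK2",
                        chromosome = "19", position = 100L,
                        consequence = "missense", maf = 1e-5, cadd = 25,
                        n_alt = 1L, span = 1L, masked = FALSE) {
  tibble::tibble(variant_id = variant_id, chromosome = chromosome,
                 position = position, ref = "A", alt = "G", gene = gene,
                 consequence = consequence, maf = maf, cadd = cadd,
                 n_alt_alleles_at_locus = n_alt, span_nt = span,
                 in_masked_region = masked, site_missingness = 0)
}

toy_samples <- function(ids, sex = "male", group = "case") {
  tibble::tibble(sample_id = ids,
                 sex = rep_len(sex, length(ids)),
                 group = rep_len(group, length(ids)),
                 severity = ifelse(rep_len(group, length(ids)) == "case",
                                   "critical", "asymptomatic"),
                 family_id = NA_character_)
}

# One small planted cohort reused by collapsing/recovery tests.
planted_test_cohort <- function(seed = 21, qc_noise = NULL) {
  planted <- tibble::tibble(
    gene = c("TYK2", "STAT2", "TLR7", "IFIH1"),
    mechanism = c("homozygous", "compound_het", "hemizygous", "homozygous"),
    n = c(4, 3, 3, 2),
    group = c("case", "case", "case", "control"))
  simulate_cohort(sim_config(
    n_cases = 50, n_controls = 80, n_background_snps = 300,
    planted_carriers = planted, n_trios = 2, qc_noise = qc_noise,
    seed = seed))
}
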