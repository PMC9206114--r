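#' Configuration for the synthetic cohort generator
#'
#' Builds the parameter list consumed by [simulate_cohort()]. The defaults
#' describe the cohort structure the pipeline was designed for: 112 cases and
#' 1,224 controls with a male fraction of 78/112 among cases and 306/1,224
#' among controls, several ancestral populations diverged at a given
#' \eqn{F_{ST}}, a panel of 15 candidate genes carrying rare variants with
#' log-uniform allele frequencies, an optional consanguineous subset with a
#' per-sample inbreeding coefficient, optional trios, and optional
#' quality-control noise on depth, genotype quality, allele balance and
#' missingness.
#'
#' The synthetic genome is a scaled-down map: `n_autosomes` chromosomes of
#' `chrom_length` bp each (plus an X of the same length), over which
#' `n_background_snps` common SNPs are placed. The default 22 x 13 Mb map
#' keeps the published runs-of-homozygosity window (1,000 kb and 50 SNVs)
#' satisfiable at simulation-sized SNP counts while preserving the genome
#' fraction arithmetic of consanguinity estimation.
#'
#' @param n_cases,n_controls cohort sizes.
#' @param male_fraction_cases,male_fraction_controls male fractions per group.
#' @param n_populations number of ancestral populations `K`.
#' @param fst Balding-Nichols divergence parameter in (0, 1).
#' @param pop_weights_cases,pop_weights_controls population sampling weights
#'   per group (default uniform); unequal weights between groups create
#'   ancestry-outcome confounding.
#' @param n_background_snps number of common autosomal SNPs used for PCA,
#'   kinship and runs of homozygosity.
#' @param n_autosomes,chrom_length synthetic genome dimensions (bp).
#' @param panel gene-panel tibble, see [default_gene_panel()].
#' @param variants_per_gene number of panel variants simulated per gene (at
#'   least 6: the generator always plants two qualifying pLOF, two qualifying
#'   missense, one benign common missense and one rare synonymous variant per
#'   gene, plus extras).
#' @param panel_maf_range range of the log-uniform population MAF law for
#'   extra panel variants.
#' @param planted_carriers `NULL` or a tibble with columns `gene`,
#'   `mechanism` (`"homozygous"`, `"compound_het"`, `"hemizygous"`),
#'   `n`, `group` (`"case"`, `"control"` or `"any"`) and optionally
#'   `population` (integer, `NA` = any) and `variant_class` (`"primary"` or
#'   `"synonymous"`).
#' @param consanguineous_fraction_cases,consanguineous_fraction_controls
#'   fraction of each group simulated as offspring of consanguineous unions.
#' @param inbreeding_f inbreeding coefficient F applied to consanguineous
#'   samples (0.0625 = first-cousin offspring).
#' @param autozygous_block_kb target autozygous block length (kb).
#' @param n_case_sibling_pairs number of case pairs regenerated as full
#'   siblings (kinship 0.25).
#' @param n_trios number of planted-carrier cases for which both parents are
#'   added as extra genotyped samples (with a pedigree), enabling
#'   trans-configuration confirmation of compound heterozygotes.
#' @param qc_noise `NULL` for noise-free genotypes, or a list with elements
#'   `mean_depth`, `depth_dispersion`, `gq_mean`, `gq_sd`, `missing_rate`.
#' @param seed integer run seed; identical seeds give identical cohorts.
#' @return a named list of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(n_cases = 20, n_controls = 40, n_background_snps = 200)
sim_config <- function(n_cases = 112,
                       n_controls = 1224,
                       male_fraction_cases = 78 / 112,
                       male_fraction_controls = 306 / 1224,
                       n_populations = 3,
                       fst = 0.1,
                       pop_weights_cases = NULL,
                       pop_weights_controls = NULL,
                       n_background_snps = 4000,
                       n_autosomes = 22,
                       chrom_length = 13e6,
                       panel = default_gene_panel(),
                       variants_per_gene = 6,
                       panel_maf_range = c(1e-6, 1e-2),
                       planted_carriers = NULL,
                       consanguineous_fraction_cases = 0,
                       consanguineous_fraction_controls = 0,
                       inbreeding_f = 0.0625,
                       autozygous_block_kb = 2500,
                       n_case_sibling_pairs = 0,
                       n_trios = 0,
                       qc_noise = NULL,
                       seed = 1) {
  stopifnot(n_cases >= 1, n_controls >= 1,
            fst > 0, fst < 1, n_populations >= 1,
            variants_per_gene >= 6,
            inbreeding_f >= 0, inbreeding_f < 1)
  panel <- validate_panel(panel)
  if (!is.null(planted_carriers)) {
    planted_carriers <- tibble::as_tibble(planted_carriers)
    assert_columns(planted_carriers, c("gene", "mechanism", "n", "group"),
                   "planted_carriers")
    if (!"population" %in% names(planted_carriers)) {
      planted_carriers$population <- NA_integer_
    }
    if (!"variant_class" %in% names(planted_carriers)) {
      planted_carriers$variant_class <- "primary"
    }
    bad_mech <- setdiff(planted_carriers$mechanism,
                        c("homozygous", "compound_het", "hemizygous"))
    if (length(bad_mech) > 0) {
      abort(paste0("unknown planted mechanism(s): ",
                   paste(bad_mech, collapse = ", ")))
    }
    x_genes <- panel$gene[panel$is_x_linked]
    hemi_bad <- planted_carriers$mechanism == "hemizygous" &
      !(planted_carriers$gene %in% x_genes)
    if (any(hemi_bad)) {
      abort("hemizygous carriers can only be planted on X-linked genes")
    }
  }
  pw <- function(w) {
    if (is.null(w)) w <- rep(1, n_populations)
    if (length(w) != n_populations) abort("population weights must have length K")
    w / sum(w)
  }
  structure(list(
    n_cases = n_cases, n_controls = n_controls,
    male_fraction_cases = male_fraction_cases,
    male_fraction_controls = male_fraction_controls,
    n_populations = n_populations, fst = fst,
    pop_weights_cases = pw(pop_weights_cases),
    pop_weights_controls = pw(pop_weights_controls),
    n_background_snps = n_background_snps,
    n_autosomes = n_autosomes, chrom_length = chrom_length,
    panel = panel, variants_per_gene = variants_per_gene,
    panel_maf_range = panel_maf_range,
    planted_carriers = planted_carriers,
    consanguineous_fraction_cases = consanguineous_fraction_cases,
    consanguineous_fraction_controls = consanguineous_fraction_controls,
    inbreeding_f = inbreeding_f,
    autozygous_block_kb = autozygous_block_kb,
    n_case_sibling_pairs = n_case_sibling_pairs,
    n_trios = n_trios,
    qc_noise = qc_noise,
    seed = seed
  ), class = c("sim_config", "list"))
}

# ---- internal building blocks -------------------------------------------

# Common-SNP map over the synthetic autosomes: sorted positions, ancestral
# frequency p ~ U(0.05, 0.5), per-population frequencies Balding-Nichols.
sim_background_map <- function(config) {
  m <- config$n_background_snps
  chrom <- sort(sample.int(config$n_autosomes, m, replace = TRUE))
  pos <- integer(m)
  for (cc in unique(chrom)) {
    idx <- chrom == cc
    pos[idx] <- sort(sample.int(config$chrom_length, sum(idx)))
  }
  p_anc <- runif(m, 0.05, 0.5)
  fst <- config$fst
  pop_freq <- matrix(
    rbeta(config$n_populations * m,
          shape1 = rep(p_anc, each = config$n_populations) * (1 - fst) / fst,
          shape2 = rep(1 - p_anc, each = config$n_populations) * (1 - fst) / fst),
    nrow = config$n_populations
  )
  pop_freq[] <- pmin(pmax(pop_freq, 1e-6), 1 - 1e-6)
  list(
    map = tibble::tibble(
      variant_id = variant_id(as.character(chrom), pos, "A", "G"),
      chromosome = as.character(chrom),
      position = pos,
      ancestral_freq = p_anc
    ),
    pop_freq = pop_freq
  )
}

# Hardy-Weinberg genotypes within each subpopulation.
sim_background_genotypes <- function(population, pop_freq) {
  n <- length(population)
  m <- ncol(pop_freq)
  p <- pop_freq[population, , drop = FALSE]
  G <- matrix(rbinom(n * m, 2L, p), nrow = n, ncol = m)
  storage.mode(G) <- "integer"
  G
}

# Regenerate rows `idx` (same population) as children of one simulated
# couple; per-SNP independent transmission gives the expected kinship for
# the KING estimator without requiring linkage.
sim_sibling_rows <- function(G, idx, freqs) {
  m <- length(freqs)
  mo <- cbind(rbinom(m, 1L, freqs), rbinom(m, 1L, freqs))
  fa <- cbind(rbinom(m, 1L, freqs), rbinom(m, 1L, freqs))
  for (i in idx) {
    pick_m <- sample.int(2L, m, replace = TRUE)
    pick_f <- sample.int(2L, m, replace = TRUE)
    G[i, ] <- mo[cbind(seq_len(m), pick_m)] + fa[cbind(seq_len(m), pick_f)]
  }
  G
}

# Parent genotypes consistent with an existing child row: the child's two
# alleles are split at random between the parents; each parent's second
# allele is drawn from the population frequency.
sim_parent_rows <- function(child, freqs) {
  m <- length(child)
  a1 <- integer(m); a2 <- integer(m)
  a1[child == 2L] <- 1L; a2[child == 2L] <- 1L
  het <- which(child == 1L)
  to_a1 <- rbinom(length(het), 1L, 0.5) == 1L
  a1[het[to_a1]] <- 1L
  a2[het[!to_a1]] <- 1L
  father <- a1 + rbinom(m, 1L, freqs)
  mother <- a2 + rbinom(m, 1L, freqs)
  rbind(as.integer(father), as.integer(mother))
}

#' Overlay autozygous blocks on one sample's genotypes
#'
#' Models the genomic signature of consanguinity: a fraction `f` of the
#' mapped autosomal genome is forced autozygous in blocks, within which every
#' SNP is set homozygous for a single allele drawn from its population
#' frequency. The total autozygous length is made equal to
#' `f x` (mapped genome extent) by placing `round(f * extent / block)`
#' equal-length blocks at random non-overlapping positions, so the planted
#' fraction equals `f` exactly rather than only in expectation; this gives
#' the downstream consanguinity flag a deterministic truth value.
#'
#' @param dosages integer vector of genotypes (0/1/2) along `map`.
#' @param map tibble with `chromosome` and `position` for each genotype.
#' @param freqs per-SNP alternate-allele frequencies in the sample's
#'   population (used to draw the autozygous allele).
#' @param f inbreeding coefficient in `[0, 1)`; `f = 0` returns the input
#'   unchanged.
#' @param block_kb target autozygous block length in kb.
#' @return a list with `dosages` (modified genotypes) and `segments`
#'   (tibble of true autozygous intervals: `chromosome`, `start`, `end`).
#' @export
#' @examples
#' map <- tibble::tibble(chromosome = "1", position = seq(1e4, 2e6, by = 1e4))
#' g <- rbinom(nrow(map), 2, 0.3)
#' out <- simulate_autozygosity(g, map, rep(0.3, nrow(map)), f = 0.25,
#'                              block_kb = 300)
#' sum(out$segments$end - out$segments$start + 1)
simulate_autozygosity <- function(dosages, map, freqs, f, block_kb = 2500) {
  if (f >= 1) abort("inbreeding coefficient f must be < 1")
  if (f < 0) abort("inbreeding coefficient f must be >= 0")
  empty <- tibble::tibble(chromosome = character(), start = integer(),
                          end = integer())
  if (f == 0) return(list(dosages = dosages, segments = empty))
  chroms <- unique(map$chromosome)
  starts_map <- vapply(chroms, function(cc)
    min(map$position[map$chromosome == cc]), numeric(1))
  extents <- vapply(chroms, function(cc) {
    pp <- map$position[map$chromosome == cc]
    diff(range(pp)) + 1
  }, numeric(1))
  total <- sum(extents)
  target <- f * total
  block_len <- block_kb * 1000
  segments <- list()
  if (f >= 0.4) {
    # high inbreeding: one long block of f * extent per chromosome
    for (ci in seq_along(chroms)) {
      len <- f * extents[ci]
      off <- floor(runif(1, 0, extents[ci] - len))
      segments[[ci]] <- tibble::tibble(
        chromosome = chroms[ci],
        start = as.integer(starts_map[ci] + off),
        end = as.integer(starts_map[ci] + off + len - 1))
    }
  } else {
    # equal-length blocks; chromosomes get blocks in proportion to extent
    # (capped at half-fill) and each block is placed uniformly inside its
    # own slot, so blocks never overlap
    n_blocks <- max(1L, round(target / block_len))
    len <- target / n_blocks
    cap <- pmax(0L, floor(extents / (2 * len)))
    if (sum(cap) == 0) {
      # map smaller than two blocks: single truncated block
      ci <- which.max(extents)
      cap[ci] <- 1L
      len <- min(len, extents[ci] / 2)
    }
    k <- integer(length(chroms))
    draw <- sample(chroms, min(n_blocks, sum(cap)), replace = TRUE,
                   prob = extents / total)
    for (cc in draw) {
      ci <- match(cc, chroms)
      if (k[ci] < cap[ci]) k[ci] <- k[ci] + 1L
    }
    # top up if probability-weighted draws hit chromosome caps
    short <- max(0L, min(n_blocks, sum(cap)) - sum(k))
    if (short > 0) {
      for (ci in order(cap - k, decreasing = TRUE)) {
        add <- min(short, cap[ci] - k[ci])
        k[ci] <- k[ci] + add
        short <- short - add
        if (short == 0) break
      }
    }
    for (ci in seq_along(chroms)) {
      if (k[ci] == 0) next
      slot <- extents[ci] / k[ci]
      for (b in seq_len(k[ci])) {
        off <- (b - 1) * slot + floor(runif(1, 0, slot - len))
        segments[[length(segments) + 1]] <- tibble::tibble(
          chromosome = chroms[ci],
          start = as.integer(starts_map[ci] + off),
          end = as.integer(starts_map[ci] + off + len - 1))
      }
    }
  }
  segments <- dplyr::bind_rows(segments)
  for (b in seq_len(nrow(segments))) {
    idx <- which(map$chromosome == segments$chromosome[b] &
                   map$position >= segments$start[b] &
                   map$position <= segments$end[b])
    if (length(idx) > 0) {
      dosages[idx] <- 2L * rbinom(length(idx), 1L, freqs[idx])
    }
  }
  list(dosages = dosages, segments = dplyr::arrange(segments,
                                                    .data$chromosome,
                                                    .data$start))
}

# Panel variant table: per gene two qualifying pLOF, two qualifying
# missense, one common benign missense, one rare synonymous, plus random
# extras. CADD is drawn class-conditionally so qualifying classes sit above
# the gene MSC and synonymous variants below it.
sim_panel_variants <- function(config) {
  panel <- panel_gene_positions(config$panel, config$chrom_length)
  rows <- purrr::pmap(panel, function(gene, chromosome, is_x_linked,
                                      inheritance, msc, gene_pos) {
    k <- config$variants_per_gene
    consequence <- c("pLOF", "pLOF", "missense", "missense", "missense",
                     "synonymous")
    maf <- c(10^runif(2, -6, -4.3),       # rare pLOF
             10^runif(2, -6, -4.3),       # rare missense
             10^runif(1, -3, -2),         # common benign missense
             10^runif(1, -6, -4.3))       # rare synonymous
    cadd <- c(msc + runif(2, 8, 20), msc + runif(2, 3, 12),
              msc - runif(1, 5, 10), pmax(0.1, msc - runif(1, 8, 14)))
    if (k > 6) {
      extra_cons <- sample(c("missense", "synonymous", "essential_splice",
                             "other"), k - 6, replace = TRUE,
                           prob = c(0.45, 0.3, 0.15, 0.1))
      extra_maf <- 10^runif(k - 6, log10(config$panel_maf_range[1]),
                            log10(config$panel_maf_range[2]))
      extra_cadd <- ifelse(extra_cons %in% c("essential_splice"),
                           msc + runif(k - 6, 5, 15),
                           ifelse(extra_cons == "missense",
                                  runif(k - 6, 0.5, msc + 10),
                                  pmax(0.1, msc - runif(k - 6, 5, 12))))
      consequence <- c(consequence, extra_cons)
      maf <- c(maf, extra_maf)
      cadd <- c(cadd, extra_cadd)
    }
    pos <- gene_pos + sort(sample.int(5e4, k))
    ref <- sample(c("A", "C", "G", "T"), k, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1),
                  character(1))
    tibble::tibble(
      chromosome = chromosome, position = pos, ref = ref, alt = alt,
      gene = gene, consequence = consequence,
      maf = maf, cadd = round(cadd, 2),
      n_alt_alleles_at_locus = 1L,
      span_nt = 1L, in_masked_region = FALSE
    )
  })
  out <- dplyr::bind_rows(rows)
  out$variant_id <- variant_id(out$chromosome, out$position, out$ref, out$alt)
  dplyr::relocate(out, "variant_id")
}

# Background (non-planted) alternate alleles at panel variants. To keep the
# generator's truth table exhaustive, spontaneous recessive genotypes are
# never created: background carriers are heterozygous only, at most one
# qualifying variant per gene per sample, and on X-linked genes background
# alternate alleles are given to females only (a male X alternate allele
# would be a hemizygous carrier).
sim_panel_background <- function(variants, samples, panel) {
  n <- nrow(samples)
  v <- nrow(variants)
  D <- matrix(0L, nrow = n, ncol = v,
              dimnames = list(samples$sample_id, variants$variant_id))
  x_genes <- panel$gene[panel$is_x_linked]
  male <- samples$sex == "male"
  qualifying <- variants$consequence %in%
    c("missense", "pLOF", "essential_splice")
  for (j in seq_len(v)) {
    q <- variants$maf[j]
    eligible <- if (variants$gene[j] %in% x_genes) !male else rep(TRUE, n)
    het <- rbinom(n, 1L, 2 * q * (1 - q)) == 1L & eligible
    D[het, j] <- 1L
  }
  # at most one qualifying heterozygote per gene per sample
  for (g in unique(variants$gene)) {
    cols <- which(variants$gene == g & qualifying)
    if (length(cols) < 2) next
    extra <- rowSums(D[, cols, drop = FALSE] > 0) > 1
    for (i in which(extra)) {
      keep <- which(D[i, cols] > 0)[1]
      D[i, cols[-keep]] <- 0L
    }
  }
  D
}

# Sample planted carriers and write their genotypes into the panel dosage
# matrix. Returns the updated matrix plus the truth table.
sim_apply_plants <- function(D, variants, samples, panel, planted) {
  truth <- list()
  if (is.null(planted) || nrow(planted) == 0) {
    return(list(D = D, truth = tibble::tibble(
      sample_id = character(), gene = character(), mechanism = character(),
      variant_keys = character())))
  }
  x_genes <- panel$gene[panel$is_x_linked]
  taken <- character()
  for (r in seq_len(nrow(planted))) {
    row <- planted[r, ]
    qual <- variants$consequence %in% c("missense", "pLOF", "essential_splice") &
      variants$maf < 1e-4
    if (row$variant_class == "synonymous") {
      qual <- variants$consequence == "synonymous" & variants$maf < 1e-4
    }
    vg <- variants[variants$gene == row$gene & qual, ]
    if (nrow(vg) == 0) abort(sprintf("no plantable variant in gene %s", row$gene))
    eligible <- samples$sample_id
    if (row$group != "any") eligible <- eligible[samples$group %in% row$group]
    if (!is.na(row$population)) {
      eligible <- intersect(eligible,
                            samples$sample_id[samples$population == row$population])
    }
    if (row$mechanism == "hemizygous") {
      eligible <- intersect(eligible, samples$sample_id[samples$sex == "male"])
    }
    eligible <- setdiff(eligible, taken)
    if (length(eligible) < row$n) {
      abort(sprintf("planted carrier count (%d) exceeds eligible %s samples for %s",
                    row$n, row$group, row$gene))
    }
    chosen <- sample(eligible, row$n)
    taken <- c(taken, chosen)
    for (s in chosen) {
      i <- match(s, samples$sample_id)
      if (row$mechanism == "compound_het") {
        if (nrow(vg) < 2) abort("compound-het plant needs >= 2 qualifying sites")
        keys <- sample(vg$variant_id, 2)
        D[i, keys] <- 1L
      } else if (row$mechanism == "homozygous") {
        keys <- sample(vg$variant_id, 1)
        if (row$gene %in% x_genes && samples$sex[i] == "male") {
          abort("homozygous plant on X for a male sample; use hemizygous")
        }
        D[i, keys] <- 2L
      } else { # hemizygous
        keys <- sample(vg$variant_id, 1)
        D[i, keys] <- 1L
      }
      truth[[length(truth) + 1]] <- tibble::tibble(
        sample_id = s, gene = row$gene,
        mechanism = ifelse(row$mechanism == "compound_het",
                           "compound_het", row$mechanism),
        variant_keys = paste(sort(keys), collapse = ","))
    }
  }
  list(D = D, truth = dplyr::bind_rows(truth))
}

# Long genotype-call tibble from a panel dosage matrix, with QC fields.
# Noise-free calls get DP 30, GQ 99 and perfectly balanced allele depths.
sim_calls_from_dosage <- function(D, variants, samples, panel, qc_noise) {
  n <- nrow(D); v <- ncol(D)
  x_genes <- panel$gene[panel$is_x_linked]
  on_x <- variants$gene %in% x_genes
  male <- samples$sex == "male"
  calls <- tidyr::expand_grid(sample_id = samples$sample_id,
                              variant_id = variants$variant_id)
  dosage <- as.integer(t(D))
  if (is.null(qc_noise)) {
    dp <- rep(30L, length(dosage))
    gq <- rep(99L, length(dosage))
    miss <- rep(FALSE, length(dosage))
  } else {
    dp <- stats::rnbinom(length(dosage), mu = qc_noise$mean_depth %||% 30,
                         size = qc_noise$depth_dispersion %||% 8)
    gq <- pmin(99L, pmax(0L, as.integer(round(
      rnorm(length(dosage), qc_noise$gq_mean %||% 80, qc_noise$gq_sd %||% 20)))))
    miss <- runif(length(dosage)) < (qc_noise$missing_rate %||% 0)
  }
  hemi <- rep(on_x, times = n) & rep(male, each = v)
  het <- dosage == 1L & !hemi
  hom_alt <- dosage == 2L | (dosage == 1L & hemi)
  ad_alt <- integer(length(dosage))
  if (is.null(qc_noise)) {
    ad_alt[het] <- as.integer(ceiling(dp[het] / 2))
  } else {
    ad_alt[het] <- rbinom(sum(het), dp[het], 0.5)
  }
  ad_alt[hom_alt] <- dp[hom_alt]
  ad_ref <- dp - ad_alt
  dosage[miss] <- NA_integer_
  calls$dosage <- dosage
  calls$hemi <- hemi
  calls$dp <- as.integer(dp)
  calls$gq <- gq
  calls$ad_ref <- as.integer(ad_ref)
  calls$ad_alt <- as.integer(ad_alt)
  calls
}

#' Generate a synthetic case-control exome cohort
#'
#' Draws a full cohort with the statistical structure the downstream
#' analysis assumes: subpopulation allele frequencies follow a
#' Balding-Nichols law around ancestral frequencies, genotypes are
#' Hardy-Weinberg within subpopulation (except in consanguineous samples,
#' which receive autozygous blocks via [simulate_autozygosity()]), rare
#' panel variants are simulated per gene with class-conditional CADD scores,
#' recessive carriers are planted per the configuration, and a truth table
#' records every carrier with its mechanism. Identical seeds give identical
#' cohorts.
#'
#' @param config a [sim_config()] object.
#' @return an object of class `rv_cohort`: a list with tibbles `samples`,
#'   `variants`, `calls`, `background_map`, `truth`, optional `pedigree` and
#'   `deletions`, the `panel`, and an integer `background` genotype matrix
#'   (samples x SNPs).
#' @export
#' @examples
#' cohort <- simulate_cohort(sim_config(n_cases = 15, n_controls = 30,
#'                                      n_background_snps = 300, seed = 7))
#' dplyr::count(cohort$samples, group)
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, "samples"))
  n <- config$n_cases + config$n_controls
  n_male_cases <- round(config$n_cases * config$male_fraction_cases)
  n_male_controls <- round(config$n_controls * config$male_fraction_controls)
  case_ids <- sprintf("case_%03d", seq_len(config$n_cases))
  ctrl_ids <- sprintf("ctrl_%04d", seq_len(config$n_controls))
  samples <- tibble::tibble(
    sample_id = c(case_ids, ctrl_ids),
    group = rep(c("case", "control"), c(config$n_cases, config$n_controls)),
    sex = c(sample(rep(c("male", "female"),
                       c(n_male_cases, config$n_cases - n_male_cases))),
            sample(rep(c("male", "female"),
                       c(n_male_controls, config$n_controls - n_male_controls)))),
    family_id = NA_character_
  )
  samples$severity <- ifelse(
    samples$group == "case",
    sample(c("moderate", "severe", "critical"), n, replace = TRUE,
           prob = c(0.22, 0.13, 0.65)),
    sample(c("asymptomatic", "mild"), n, replace = TRUE, prob = c(0.4, 0.6)))
  samples$population <- NA_integer_
  is_case <- samples$group == "case"
  samples$population[is_case] <- sample.int(
    config$n_populations, sum(is_case), replace = TRUE,
    prob = config$pop_weights_cases)
  samples$population[!is_case] <- sample.int(
    config$n_populations, sum(!is_case), replace = TRUE,
    prob = config$pop_weights_controls)
  n_cons_cases <- round(config$n_cases * config$consanguineous_fraction_cases)
  n_cons_ctrls <- round(config$n_controls * config$consanguineous_fraction_controls)
  samples$consanguineous_truth <- FALSE
  samples$consanguineous_truth[sample(which(is_case), n_cons_cases)] <- TRUE
  samples$consanguineous_truth[sample(which(!is_case), n_cons_ctrls)] <- TRUE

  set.seed(derive_seed(config$seed, "background"))
  bg <- sim_background_map(config)
  G <- sim_background_genotypes(samples$population, bg$pop_freq)
  rownames(G) <- samples$sample_id
  colnames(G) <- bg$map$variant_id

  set.seed(derive_seed(config$seed, "siblings"))
  sib_pairs <- list()
  if (config$n_case_sibling_pairs > 0) {
    avail <- which(is_case & !samples$consanguineous_truth)
    for (k in seq_len(config$n_case_sibling_pairs)) {
      pair <- avail[(2 * k - 1):(2 * k)]
      samples$population[pair[2]] <- samples$population[pair[1]]
      G <- sim_sibling_rows(G, pair, bg$pop_freq[samples$population[pair[1]], ])
      fam <- sprintf("fam_sib_%02d", k)
      samples$family_id[pair] <- fam
      sib_pairs[[k]] <- samples$sample_id[pair]
    }
  }

  set.seed(derive_seed(config$seed, "autozygosity"))
  autoz <- list()
  for (i in which(samples$consanguineous_truth)) {
    res <- simulate_autozygosity(G[i, ], bg$map,
                                 bg$pop_freq[samples$population[i], ],
                                 config$inbreeding_f,
                                 config$autozygous_block_kb)
    G[i, ] <- res$dosages
    if (nrow(res$segments) > 0) {
      autoz[[length(autoz) + 1]] <-
        dplyr::mutate(res$segments, sample_id = samples$sample_id[i],
                      .before = 1)
    }
  }
  autozygous_truth <- dplyr::bind_rows(autoz)

  set.seed(derive_seed(config$seed, "panel"))
  variants <- sim_panel_variants(config)
  D <- sim_panel_background(variants, samples, config$panel)
  planted <- sim_apply_plants(D, variants, samples, config$panel,
                              config$planted_carriers)
  D <- planted$D

  # trios: add genotyped parents for planted compound-het cases first
  set.seed(derive_seed(config$seed, "trios"))
  pedigree <- NULL
  if (config$n_trios > 0) {
    chet_cases <- planted$truth$sample_id[
      planted$truth$mechanism == "compound_het" &
        planted$truth$sample_id %in% case_ids]
    probands <- head(unique(c(chet_cases, case_ids)), config$n_trios)
    ped_rows <- list()
    for (k in seq_along(probands)) {
      child <- probands[k]
      i <- match(child, samples$sample_id)
      fam <- sprintf("fam_trio_%02d", k)
      fa_id <- paste0(child, "_fa"); mo_id <- paste0(child, "_mo")
      parents <- sim_parent_rows(G[i, ],
                                 bg$pop_freq[samples$population[i], ])
      G <- rbind(G, parents)
      rownames(G)[nrow(G) - 1:0] <- c(fa_id, mo_id)
      # panel: split the child's alternate alleles between the parents, in
      # trans for compound heterozygotes
      dpar <- matrix(0L, 2, ncol(D), dimnames = list(c(fa_id, mo_id),
                                                     colnames(D)))
      alt_sites <- which(D[i, ] > 0)
      if (length(alt_sites) > 0) {
        to_fa <- seq_along(alt_sites) %% 2 == 1
        dpar[1, alt_sites[to_fa]] <- 1L
        dpar[2, alt_sites[!to_fa]] <- 1L
        dpar[1, D[i, ] == 2L] <- 1L
        dpar[2, D[i, ] == 2L] <- 1L
      }
      D <- rbind(D, dpar)
      samples <- dplyr::bind_rows(samples, tibble::tibble(
        sample_id = c(fa_id, mo_id), group = NA_character_,
        sex = c("male", "female"), family_id = fam,
        severity = NA_character_, population = samples$population[i],
        consanguineous_truth = FALSE))
      samples$family_id[i] <- fam
      ped_rows[[k]] <- tibble::tibble(
        family_id = fam,
        sample_id = c(child, fa_id, mo_id),
        father_id = c(fa_id, NA, NA),
        mother_id = c(mo_id, NA, NA),
        sex = c(samples$sex[i], "male", "female"),
        affected = c(TRUE, FALSE, FALSE))
    }
    pedigree <- dplyr::bind_rows(ped_rows)
  }

  set.seed(derive_seed(config$seed, "qc"))
  calls <- sim_calls_from_dosage(D, variants, samples, config$panel,
                                 config$qc_noise)
  if (!is.null(config$qc_noise) && (config$qc_noise$missing_rate %||% 0) > 0) {
    G[runif(length(G)) < config$qc_noise$missing_rate] <- NA_integer_
  }
  variants$site_missingness <- calls |>
    dplyr::group_by(.data$variant_id) |>
    dplyr::summarise(miss = mean(is.na(.data$dosage))) |>
    dplyr::pull(.data$miss, name = .data$variant_id) |>
    (\(x) unname(x[variants$variant_id]))()

  structure(list(
    samples = samples,
    panel = config$panel,
    variants = variants,
    calls = calls,
    background = G,
    background_map = bg$map,
    pedigree = pedigree,
    deletions = NULL,
    truth = planted$truth,
    autozygous_truth = autozygous_truth,
    sibling_pairs = sib_pairs,
    config = config
  ), class = "rv_cohort")
}

#' @export
print.rv_cohort <- function(x, ...) {
  n_case <- sum(x$samples$group == "case", na.rm = TRUE)
  n_ctrl <- sum(x$samples$group == "control", na.rm = TRUE)
  cat(sprintf(paste0("<rv_cohort> %d cases / %d controls; %d panel variants",
                     " in %d genes; %d background SNPs\n"),
              n_case, n_ctrl, nrow(x$variants),
              dplyr::n_distinct(x$variants$gene), ncol(x$background)))
  invisible(x)
}

#' Simulate a genotype pair with a known relationship
#'
#' Draws two genotype vectors at independent biallelic SNPs with the given
#' pedigree relationship, for calibrating kinship classification:
#' `"duplicate"` (monozygotic, kinship 0.5), `"parent_offspring"` (0.25),
#' `"full_sibling"` (0.25), `"half_sibling"` (second degree, 0.125),
#' `"unrelated"` (0).
#'
#' @param freqs vector of alternate-allele frequencies.
#' @param relationship one of the relationships above.
#' @return an integer matrix with 2 rows (the pair) and one column per SNP.
#' @export
#' @examples
#' pair <- simulate_relative_pair(runif(2000, 0.05, 0.5), "parent_offspring")
simulate_relative_pair <- function(freqs,
                                   relationship = c("duplicate",
                                                    "parent_offspring",
                                                    "full_sibling",
                                                    "half_sibling",
                                                    "unrelated")) {
  relationship <- match.arg(relationship)
  m <- length(freqs)
  draw <- function() rbinom(m, 1L, freqs)
  g <- switch(
    relationship,
    duplicate = {
      a <- draw() + draw()
      rbind(a, a)
    },
    parent_offspring = {
      p1 <- draw(); p2 <- draw()
      parent <- p1 + p2
      transmitted <- ifelse(rbinom(m, 1L, 0.5) == 1L, p1, p2)
      rbind(parent, transmitted + draw())
    },
    full_sibling = {
      mo <- cbind(draw(), draw()); fa <- cbind(draw(), draw())
      child <- function() {
        mo[cbind(seq_len(m), sample.int(2, m, TRUE))] +
          fa[cbind(seq_len(m), sample.int(2, m, TRUE))]
      }
      rbind(child(), child())
    },
    half_sibling = {
      shared <- cbind(draw(), draw())
      child <- function() {
        shared[cbind(seq_len(m), sample.int(2, m, TRUE))] + draw()
      }
      rbind(child(), child())
    },
    unrelated = rbind(draw() + draw(), draw() + draw())
  )
  storage.mode(g) <- "integer"
  rownames(g) <- c("s1", "s2")
  g
}
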