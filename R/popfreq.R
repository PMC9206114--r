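#' Population recessive genotype frequency for one gene
#'
#' Under random mating, the population frequency of a biallelic (recessive)
#' genotype at an autosomal gene with qualifying allele frequencies
#' \eqn{q_1, ..., q_k} is \eqn{Q^2} with cumulative MAF \eqn{Q = \sum q_i}
#' (capturing homozygotes and compound heterozygotes alike); for an X-linked
#' gene the frequency adds male hemizygosity:
#' \eqn{m Q + (1 - m) Q^2} for male fraction \eqn{m}. The sum
#' \eqn{\sum q_i} is used for the cumulative MAF rather than
#' \eqn{1 - \prod(1 - q_i)}: at the allele frequencies relevant here
#' (q at most 1e-2) the difference is negligible and the sum is the
#' conventional reporting scale.
#'
#' @param allele_freqs numeric vector of qualifying allele frequencies,
#'   each in `[0, 0.5]`.
#' @param mode `"autosomal"` or `"x_linked"`.
#' @param male_fraction male population fraction used for X-linked genes.
#' @param gene optional gene symbol carried into the result.
#' @return one-row tibble: `gene`, `mode`, `cumulative_maf`,
#'   `genotype_frequency`, `male_fraction`.
#' @export
#' @examples
#' recessive_genotype_frequency(c(0.001, 0.001), "autosomal")
recessive_genotype_frequency <- function(allele_freqs,
                                         mode = c("autosomal", "x_linked"),
                                         male_fraction = 0.5,
                                         gene = NA_character_) {
  mode <- match.arg(mode)
  if (length(allele_freqs) > 0 &&
      (any(allele_freqs < 0) || any(allele_freqs > 0.5))) {
    abort("allele frequencies must lie in [0, 0.5]")
  }
  q_total <- sum(allele_freqs)
  freq <- if (mode == "autosomal") {
    q_total^2
  } else {
    male_fraction * q_total + (1 - male_fraction) * q_total^2
  }
  tibble::tibble(gene = gene, mode = mode, cumulative_maf = q_total,
                 genotype_frequency = freq, male_fraction = male_fraction)
}

#' Aggregate recessive genotype frequency over a gene panel
#'
#' Sums per-gene cumulative MAFs and recessive genotype frequencies across
#' a panel (rare-event additivity: with per-gene genotype frequencies this
#' small, the union probability is the sum to excellent approximation).
#' Both aggregates are monotone in every input.
#'
#' @param per_gene tibble of per-gene results from
#'   [recessive_genotype_frequency()] (one row per gene).
#' @return one-row tibble: `n_genes`, `cumulative_maf`,
#'   `genotype_frequency`.
#' @export
panel_cumulative_frequency <- function(per_gene) {
  assert_columns(per_gene, c("gene", "cumulative_maf", "genotype_frequency"),
                 "per_gene")
  if (anyDuplicated(per_gene$gene)) {
    abort("per_gene has duplicated gene rows")
  }
  tibble::tibble(
    n_genes = nrow(per_gene),
    cumulative_maf = sum(per_gene$cumulative_maf),
    genotype_frequency = sum(per_gene$genotype_frequency)
  )
}
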