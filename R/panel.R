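#' Candidate gene panel for recessive type I IFN deficiencies
#'
#' The 15 loci at which recessive, biochemically complete inborn errors of
#' type I interferon immunity have been reported: TLR3, TICAM1, UNC93B1,
#' TLR7, IRAK4, MYD88, IFIH1, TBK1, IRF7, IFNAR1, IFNAR2, TYK2, STAT1,
#' STAT2 and IRF9. TLR7 is the only X-linked gene (XR inheritance); the 14
#' others are autosomal (AR). The per-gene mutation significance cutoff
#' (MSC) is a CADD-scale threshold below which variants in that gene are
#' treated as likely benign; MSC values are not part of the published cohort
#' tables and are configurable here (default 15 for every gene, a
#' conventional mid-range CADD cutoff).
#'
#' Chromosome labels follow the human assignment of each gene; positions
#' used by the simulator are scaled to the synthetic genome (see
#' [sim_config()]).
#'
#' @param msc either a single CADD-scale cutoff applied to all genes or a
#'   named numeric vector of per-gene cutoffs.
#' @return a tibble with columns `gene`, `chromosome`, `is_x_linked`,
#'   `inheritance` (`"AR"` or `"XR"`), and `msc`.
#' @export
#' @examples
#' default_gene_panel()
default_gene_panel <- function(msc = 15) {
  genes <- c("TLR3", "TICAM1", "UNC93B1", "TLR7", "IRAK4", "MYD88", "IFIH1",
             "TBK1", "IRF7", "IFNAR1", "IFNAR2", "TYK2", "STAT1", "STAT2",
             "IRF9")
  chrom <- c("4", "19", "11", "X", "12", "3", "2",
             "12", "11", "21", "21", "19", "2", "12", "14")
  if (length(msc) == 1L && is.null(names(msc))) {
    msc <- setNames(rep(msc, length(genes)), genes)
  }
  panel <- tibble::tibble(
    gene = genes,
    chromosome = chrom,
    is_x_linked = chrom == "X",
    inheritance = ifelse(chrom == "X", "XR", "AR"),
    msc = unname(msc[genes])
  )
  validate_panel(panel)
}

#' Validate a gene-panel table
#'
#' Checks the structural invariants of a panel table: X-linkage must agree
#' with the chromosome label, inheritance must be XR exactly for X-linked
#' genes, MSC must be positive, and gene symbols must be unique.
#'
#' @param panel a data frame with columns `gene`, `chromosome`,
#'   `is_x_linked`, `inheritance`, `msc`.
#' @return the validated panel as a tibble (invisibly usable in pipes).
#' @export
validate_panel <- function(panel) {
  assert_columns(panel, c("gene", "chromosome", "is_x_linked",
                          "inheritance", "msc"), "panel")
  panel <- tibble::as_tibble(panel)
  if (anyDuplicated(panel$gene)) abort("panel has duplicated gene symbols")
  if (!all(panel$is_x_linked == (panel$chromosome == "X"))) {
    abort("panel: is_x_linked must equal (chromosome == \"X\")")
  }
  if (!all(panel$inheritance == ifelse(panel$is_x_linked, "XR", "AR"))) {
    abort("panel: inheritance must be XR exactly for X-linked genes")
  }
  if (!all(is.finite(panel$msc)) || any(panel$msc <= 0)) {
    abort("panel: msc must be a positive CADD-scale score")
  }
  panel
}

# Scaled gene anchor positions (bp) on the synthetic genome, used by the
# simulator to place panel variants; spread out so genes on a shared
# chromosome do not collide.
panel_gene_positions <- function(panel, chrom_length = 13e6) {
  panel |>
    dplyr::group_by(.data$chromosome) |>
    dplyr::mutate(gene_pos = round(chrom_length *
                                     seq_len(dplyr::n()) / (dplyr::n() + 1))) |>
    dplyr::ungroup()
}
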