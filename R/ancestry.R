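#' Genotype principal component analysis
#'
#' Computes per-sample ancestry principal components from a matrix of common
#' biallelic genotypes (dosage 0/1/2). Sites are restricted to MAF above
#' `pca_min_maf` and call rate above `pca_min_call_rate`; missing genotypes
#' are mean-imputed; genotypes are centred by `2 * p_hat` and scaled by
#' `sqrt(2 * p_hat * (1 - p_hat))`; scores are the projections onto the top
#' right-singular directions (computed through the sample-by-sample
#' cross-product, which is exact and fast when SNPs outnumber samples).
#'
#' @param genotypes integer matrix, samples x SNPs, rownames = sample ids.
#' @param config a [filter_config()].
#' @param n_pcs number of components to return (default 5, the number used
#'   as burden-test covariates).
#' @return a list of class `rv_pca`: `scores` (tibble `sample_id`,
#'   `PC1`..`PCn`), `explained_variance` (proportion per component), and
#'   `n_snps_used`.
#' @export
compute_pca <- function(genotypes, config = filter_config(), n_pcs = 5) {
  stopifnot(is.matrix(genotypes))
  call_rate <- colMeans(!is.na(genotypes))
  p_hat <- colMeans(genotypes, na.rm = TRUE) / 2
  maf <- pmin(p_hat, 1 - p_hat)
  keep <- call_rate > config$pca_min_call_rate & maf > config$pca_min_maf
  X <- genotypes[, keep, drop = FALSE]
  p <- colMeans(X, na.rm = TRUE) / 2
  sd_col <- sqrt(2 * p * (1 - p))
  nonzero <- sd_col > 0
  X <- X[, nonzero, drop = FALSE]
  p <- p[nonzero]; sd_col <- sd_col[nonzero]
  if (ncol(X) == 0) abort("degenerate genotype matrix: no usable SNPs")
  # mean-impute, centre, scale
  X <- sweep(X, 2, 2 * p)
  X[is.na(X)] <- 0
  X <- sweep(X, 2, sd_col, "/")
  K <- tcrossprod(X) / ncol(X)
  if (sum(diag(K)) < 1e-12) {
    abort("degenerate genotype matrix: all samples identical")
  }
  eig <- eigen(K, symmetric = TRUE)
  ev <- pmax(eig$values, 0)
  if (ev[1] < 1e-12) abort("degenerate genotype matrix")
  n_pcs <- min(n_pcs, sum(ev > 1e-12))
  scores <- eig$vectors[, seq_len(n_pcs), drop = FALSE] %*%
    diag(sqrt(ev[seq_len(n_pcs)]), n_pcs)
  colnames(scores) <- paste0("PC", seq_len(n_pcs))
  out <- list(
    scores = tibble::tibble(sample_id = rownames(genotypes),
                            tibble::as_tibble(scores)),
    explained_variance = ev[seq_len(n_pcs)] / sum(ev),
    n_snps_used = ncol(X)
  )
  class(out) <- "rv_pca"
  out
}

#' @export
print.rv_pca <- function(x, ...) {
  cat(sprintf("<rv_pca> %d samples, %d SNPs; var explained: %s\n",
              nrow(x$scores), x$n_snps_used,
              paste(sprintf("%.1f%%", 100 * x$explained_variance),
                    collapse = " ")))
  invisible(x)
}

king_degree <- function(phi) {
  dplyr::case_when(
    is.na(phi) ~ "unevaluable",
    phi > 0.354 ~ "duplicate_MZ",
    phi > 0.177 ~ "first",
    phi > 0.0884 ~ "second",
    phi >= 0.0442 ~ "third",
    TRUE ~ "unrelated"
  )
}

#' KING-robust pairwise kinship
#'
#' Estimates the kinship coefficient for every sample pair with the
#' between-family robust estimator
#' \deqn{\hat\phi = \frac{N_{both het} - 2 N_{opp hom}}{N_{het,i} + N_{het,j}}}
#' where counts are taken over sites non-missing in both samples:
#' `N_both_het` sites heterozygous in both, `N_opp_hom` sites with opposite
#' homozygotes, and `N_het_i`/`N_het_j` the per-sample heterozygote counts.
#' This estimator is robust to population structure (unrelated pairs drawn
#' from different subpopulations stay near zero). Degrees follow the
#' standard thresholds: > 0.354 duplicate/monozygotic, (0.177, 0.354] first,
#' (0.0884, 0.177] second, [0.0442, 0.0884] third degree, < 0.0442
#' unrelated. Pairs in which neither sample has a heterozygous call are
#' flagged `unevaluable` (`phi = NA`).
#'
#' @param genotypes integer matrix, samples x SNPs (0/1/2, `NA` missing).
#' @return tibble with `sample_i`, `sample_j` (i < j by row order), `phi`,
#'   `degree`.
#' @export
king_kinship <- function(genotypes) {
  stopifnot(is.matrix(genotypes), nrow(genotypes) >= 2)
  ids <- rownames(genotypes) %||% as.character(seq_len(nrow(genotypes)))
  NM <- (!is.na(genotypes)) * 1
  G0 <- genotypes; G0[is.na(G0)] <- -1L
  H <- (G0 == 1L) * 1
  A0 <- (G0 == 0L) * 1
  A2 <- (G0 == 2L) * 1
  n_both_het <- tcrossprod(H)
  n_opp <- tcrossprod(A0, A2)
  n_opp <- n_opp + t(n_opp)
  het_i <- tcrossprod(H, NM)   # het in i, non-missing in j
  denom <- het_i + t(het_i)
  phi <- (n_both_het - 2 * n_opp) / denom
  phi[denom == 0] <- NA_real_
  ut <- which(upper.tri(phi), arr.ind = TRUE)
  phi_vec <- phi[ut]
  tibble::tibble(
    sample_i = ids[ut[, 1]],
    sample_j = ids[ut[, 2]],
    phi = phi_vec,
    degree = king_degree(phi_vec)
  )
}

#' Select a maximal unrelated sample subset
#'
#' Removes one sample per related pair (kinship at or above `threshold`)
#' using greedy maximum-degree elimination: while related pairs remain, the
#' sample related to the most others is removed; ties prefer removing
#' controls over cases, then non-carriers over carriers, then the
#' lexicographically larger sample id, so the retained set is deterministic
#' and favours analysis power.
#'
#' @param samples sample tibble with `sample_id` and optionally `group` and
#'   `carrier` columns (used for tie-breaking).
#' @param kinship output of [king_kinship()] (may include samples outside
#'   `samples`; those pairs are ignored).
#' @param threshold kinship threshold (default third degree, 0.0442).
#' @return character vector of retained sample ids.
#' @export
unrelated_subset <- function(samples, kinship, threshold = 0.0442) {
  ids <- samples$sample_id
  rel <- kinship[!is.na(kinship$phi) & kinship$phi >= threshold &
                   kinship$sample_i %in% ids & kinship$sample_j %in% ids, ]
  if (nrow(rel) == 0) return(ids)
  group <- setNames(samples$group %||% rep(NA_character_, length(ids)), ids)
  carrier <- setNames(
    if ("carrier" %in% names(samples)) samples$carrier else
      rep(FALSE, length(ids)), ids)
  edges <- rel[, c("sample_i", "sample_j")]
  removed <- character()
  repeat {
    live <- edges[!(edges$sample_i %in% removed) &
                    !(edges$sample_j %in% removed), ]
    if (nrow(live) == 0) break
    deg <- table(c(live$sample_i, live$sample_j))
    cand <- names(deg)[deg == max(deg)]
    # among ties: remove controls before cases, non-carriers before
    # carriers, then the lexicographically larger id
    is_case <- !is.na(group[cand]) & group[cand] == "case"
    is_carrier <- carrier[cand] %in% TRUE
    cand <- cand[order(is_case, is_carrier, -xtfrm(cand))]
    removed <- c(removed, cand[1])
  }
  setdiff(ids, removed)
}
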