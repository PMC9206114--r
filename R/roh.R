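#' Runs of homozygosity and exome homozygosity rate
#'
#' Detects runs of homozygosity (ROH) per sample with a PLINK-style sliding
#' window scan over common autosomal SNVs (MAF above `roh_snp_min_maf`),
#' then summarises each sample's homozygosity rate -- the proportion of the
#' mapped autosomal genome falling in ROH -- and flags samples above the
#' consanguinity threshold (1% by default) as born to consanguineous
#' parents.
#'
#' The scan slides a window of `roh_window_snps` consecutive SNVs (50) whose
#' physical span must not exceed `roh_window_kb` (1,000 kb); a window is
#' called homozygous when it contains at most `roh_window_max_het`
#' heterozygotes (1) and `roh_window_max_miss` missing calls (5). A SNV is
#' in a run when at least `roh_overlap_fraction` (5%) of the valid windows
#' covering it are homozygous; maximal runs of such SNVs are emitted if they
#' contain at least `roh_min_segment_snps` SNVs (100) and span at least
#' `roh_min_segment_kb` (1,000 kb). The rate denominator is the mapped
#' autosomal extent: the sum over chromosomes of (max - min SNV position).
#'
#' @param genotypes integer matrix, samples x SNVs (0/1/2, `NA` missing),
#'   columns ordered consistently with `map`.
#' @param map tibble with `chromosome` and `position` per SNV (autosomal).
#' @param config a [filter_config()].
#' @return a list of class `rv_roh`: `segments` (tibble `sample_id`,
#'   `chromosome`, `start`, `end`, `n_snps`, `length_bp`) and `rates`
#'   (tibble `sample_id`, `homozygosity_rate`, `is_consanguineous`). With
#'   fewer than `roh_window_snps` mapped SNVs the rate is `NA` and samples
#'   are flagged unevaluable.
#' @export
homozygosity_rate <- function(genotypes, map, config = filter_config()) {
  stopifnot(is.matrix(genotypes), nrow(map) == ncol(genotypes))
  ids <- rownames(genotypes) %||% as.character(seq_len(nrow(genotypes)))
  w <- config$roh_window_snps
  chroms <- unique(map$chromosome)
  extents <- vapply(chroms, function(cc) {
    pp <- map$position[map$chromosome == cc]
    diff(range(pp)) + 1
  }, numeric(1))
  denom <- sum(extents)
  if (nrow(map) < w) {
    return(structure(list(
      segments = tibble::tibble(sample_id = character(),
                                chromosome = character(), start = integer(),
                                end = integer(), n_snps = integer(),
                                length_bp = integer()),
      rates = tibble::tibble(sample_id = ids, homozygosity_rate = NA_real_,
                             is_consanguineous = NA)
    ), class = "rv_roh"))
  }
  chr_index <- split(seq_len(nrow(map)), map$chromosome)
  # precompute window validity (span <= roh_window_kb) per chromosome
  win_ok <- lapply(chr_index, function(idx) {
    m <- length(idx)
    if (m < w) return(logical(0))
    starts <- seq_len(m - w + 1)
    span <- map$position[idx[starts + w - 1]] - map$position[idx[starts]]
    span <= config$roh_window_kb * 1000
  })
  roll <- function(x, w) {
    cs <- c(0, cumsum(x))
    cs[(w + 1):length(cs)] - cs[seq_len(length(cs) - w)]
  }
  seg_list <- vector("list", length(ids))
  rates <- numeric(length(ids))
  for (i in seq_along(ids)) {
    total_len <- 0
    segs <- list()
    for (cc in names(chr_index)) {
      idx <- chr_index[[cc]]
      m <- length(idx)
      if (m < w) next
      g <- genotypes[i, idx]
      het <- !is.na(g) & g == 1L
      mis <- is.na(g)
      hom_win <- roll(het, w) <= config$roh_window_max_het &
        roll(mis, w) <= config$roh_window_max_miss & win_ok[[cc]]
      valid <- win_ok[[cc]]
      # per-SNP: fraction of valid windows covering it that are homozygous
      n_win <- length(hom_win)
      cum_hom <- c(0, cumsum(hom_win))
      cum_val <- c(0, cumsum(valid))
      lo <- pmax(1L, seq_len(m) - w + 1L)
      hi <- pmin(n_win, seq_len(m))
      covering_hom <- cum_hom[hi + 1L] - cum_hom[lo]
      covering_val <- cum_val[hi + 1L] - cum_val[lo]
      in_roh <- covering_val > 0 &
        covering_hom / pmax(covering_val, 1) >= config$roh_overlap_fraction
      r <- rle(in_roh)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1
      runs <- which(r$values)
      for (k in runs) {
        s <- starts[k]; e <- ends[k]
        n_snps <- e - s + 1
        len <- map$position[idx[e]] - map$position[idx[s]] + 1
        if (n_snps >= config$roh_min_segment_snps &&
            len >= config$roh_min_segment_kb * 1000) {
          total_len <- total_len + len
          segs[[length(segs) + 1]] <- tibble::tibble(
            sample_id = ids[i], chromosome = cc,
            start = map$position[idx[s]], end = map$position[idx[e]],
            n_snps = as.integer(n_snps), length_bp = as.integer(len))
        }
      }
    }
    seg_list[[i]] <- if (length(segs) > 0) dplyr::bind_rows(segs) else NULL
    rates[i] <- total_len / denom
  }
  structure(list(
    segments = dplyr::bind_rows(seg_list),
    rates = tibble::tibble(
      sample_id = ids,
      homozygosity_rate = rates,
      is_consanguineous = rates > config$consanguinity_threshold)
  ), class = "rv_roh")
}

#' @export
print.rv_roh <- function(x, ...) {
  cat(sprintf("<rv_roh> %d samples, %d segments, %d flagged consanguineous\n",
              nrow(x$rates), nrow(x$segments),
              sum(x$rates$is_consanguineous, na.rm = TRUE)))
  invisible(x)
}
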