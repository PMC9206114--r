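# Left-align/trim a variant representation: drop shared trailing bases,
# then shared leading bases (keeping at least one), adjusting the position.
normalize_variant <- function(position, ref, alt) {
  while (nchar(ref) > 1 && nchar(alt) > 1 &&
         substr(ref, nchar(ref), nchar(ref)) ==
         substr(alt, nchar(alt), nchar(alt))) {
    ref <- substr(ref, 1, nchar(ref) - 1)
    alt <- substr(alt, 1, nchar(alt) - 1)
  }
  while (nchar(ref) > 1 && nchar(alt) > 1 &&
         substr(ref, 1, 1) == substr(alt, 1, 1)) {
    ref <- substr(ref, 2, nchar(ref))
    alt <- substr(alt, 2, nchar(alt))
    position <- position + 1
  }
  list(position = position, ref = ref, alt = alt)
}

# Does a 0-based half-open BED interval set cover a 1-based position?
# [s, e) masks 1-based positions s+1 .. e.
bed_mask_positions <- function(bed, chromosome, position) {
  if (is.null(bed) || nrow(bed) == 0) return(rep(FALSE, length(position)))
  vapply(seq_along(position), function(i) {
    any(bed$chrom == chromosome[i] &
          bed$start + 1 <= position[i] &
          position[i] <= bed$end)
  }, logical(1))
}

parse_gt_dosage <- function(gt, allele = 1L) {
  # counts of `allele` in a GT string; "." or "./." -> NA
  if (is.na(gt) || gt == "." || gt == "./." || gt == ".|.") return(NA_integer_)
  alleles <- strsplit(gt, "[/|]")[[1]]
  if (any(alleles == ".")) return(NA_integer_)
  sum(alleles == as.character(allele))
}

#' Load a cohort from standard files
#'
#' Reads a multi-sample VCF 4.2 (GT/DP/GQ/AD), the per-variant annotation
#' TSV, the gene panel TSV and the sample metadata TSV, plus optional
#' PED pedigree, BED mask of low-complexity/decoy regions and
#' homozygous-deletion TSV, and assembles the `rv_cohort` container used by
#' the pipeline. Multiallelic VCF rows are split into biallelic records
#' (the pre-split ALT allele count is kept as `n_alt_alleles_at_locus`),
#' indel representations are trimmed/left-aligned before keying on
#' (chrom, pos, ref, alt), male chromosome-X genotypes are normalized to
#' hemizygous dosage 0/1 (a heterozygous male X call is set missing and
#' counted as a QC anomaly), and BED intervals (0-based half-open) are
#' converted to the 1-based inclusive convention when flagging masked
#' sites. VCF records with no matching annotation row are treated as
#' background SNVs (used for PCA, kinship and runs of homozygosity);
#' annotation rows matching no VCF record are an error.
#'
#' @param vcf_path,annotation_path,panel_path,samples_path required input
#'   files.
#' @param pedigree_path,mask_path,deletions_path optional inputs.
#' @return an `rv_cohort`; the `qc_anomalies` element counts normalization
#'   anomalies (e.g. heterozygous male X calls set missing).
#' @export
read_cohort <- function(vcf_path, annotation_path, panel_path, samples_path,
                        pedigree_path = NULL, mask_path = NULL,
                        deletions_path = NULL) {
  for (f in c(vcf_path, annotation_path, panel_path, samples_path,
              pedigree_path, mask_path, deletions_path)) {
    if (!is.null(f) && !file.exists(f)) {
      abort(paste0("load_cohort: file not found: ", f))
    }
  }
  samples <- readr::read_tsv(samples_path, show_col_types = FALSE,
                             col_types = readr::cols(.default = "c"))
  assert_columns(samples, c("sample_id", "sex", "group"), "samples table")
  if (anyDuplicated(samples$sample_id)) {
    abort(paste0("duplicated sample id(s): ",
                 paste(unique(samples$sample_id[
                   duplicated(samples$sample_id)]), collapse = ", ")))
  }
  if (!"severity" %in% names(samples)) samples$severity <- NA_character_
  if (!"family_id" %in% names(samples)) samples$family_id <- NA_character_

  panel <- readr::read_tsv(panel_path, show_col_types = FALSE)
  panel$is_x_linked <- panel$chromosome == "X"
  panel <- validate_panel(panel)

  anno <- readr::read_tsv(annotation_path, show_col_types = FALSE,
                          col_types = readr::cols(chrom = "c", ref = "c",
                                                  alt = "c",
                                                  .default = readr::col_guess()))
  assert_columns(anno, c("chrom", "pos", "ref", "alt", "gene", "consequence",
                         "gnomad_maf", "cadd"), "annotation")

  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  vcf_samples <- colnames(vcf@gt)[-1]
  unknown <- setdiff(vcf_samples, samples$sample_id)
  if (length(unknown) > 0) {
    abort(paste0("VCF sample id(s) missing from the metadata table: ",
                 paste(head(unknown, 5), collapse = ", ")))
  }
  fix_m <- vcfR::getFIX(vcf)
  if (is.null(dim(fix_m))) fix_m <- t(fix_m)   # single-record VCF
  fix <- tibble::as_tibble(fix_m)
  fix$POS <- as.integer(fix$POS)
  as_row_matrix <- function(x) {
    if (is.null(dim(x))) matrix(x, nrow = 1, dimnames = list(NULL, names(x)))
    else x
  }
  gt_raw <- as_row_matrix(vcfR::extract.gt(vcf, "GT"))
  dp_raw <- as_row_matrix(
    suppressWarnings(vcfR::extract.gt(vcf, "DP", as.numeric = TRUE)))
  gq_raw <- as_row_matrix(
    suppressWarnings(vcfR::extract.gt(vcf, "GQ", as.numeric = TRUE)))
  ad_raw <- as_row_matrix(vcfR::extract.gt(vcf, "AD"))

  male <- setNames(samples$sex == "male", samples$sample_id)[vcf_samples]
  female_hemi <- 0L
  male_x_het <- 0L

  records <- list()
  for (r in seq_len(nrow(fix))) {
    alts <- strsplit(fix$ALT[r], ",", fixed = TRUE)[[1]]
    n_alt <- length(alts)
    on_x <- fix$CHROM[r] == "X"
    for (k in seq_len(n_alt)) {
      norm <- normalize_variant(fix$POS[r], fix$REF[r], alts[k])
      gt <- gt_raw[r, ]
      dos <- vapply(gt, parse_gt_dosage, integer(1), allele = k)
      ploidy <- vapply(gt, function(g) {
        if (is.na(g)) return(NA_integer_)
        length(strsplit(g, "[/|]")[[1]])
      }, integer(1))
      if (on_x) {
        if (any(!male & !is.na(ploidy) & ploidy == 1L)) {
          abort("female sample with hemizygous (haploid) X encoding")
        }
        # male X: diploid "1/1" -> hemizygous dosage 1; "0/1" inconsistent
        het_male <- male & !is.na(dos) & dos == 1L & ploidy == 2L
        male_x_het <- male_x_het + sum(het_male, na.rm = TRUE)
        dos[het_male] <- NA_integer_
        dos[male & !is.na(dos) & dos == 2L] <- 1L
      }
      ad <- ad_raw[r, ]
      ad_split <- strsplit(ifelse(is.na(ad), "", ad), ",", fixed = TRUE)
      ad_ref <- vapply(ad_split, function(x)
        if (length(x) >= 1) suppressWarnings(as.integer(x[1])) else NA_integer_,
        integer(1))
      ad_alt <- vapply(ad_split, function(x)
        if (length(x) >= k + 1) suppressWarnings(as.integer(x[k + 1])) else
          NA_integer_, integer(1))
      records[[length(records) + 1]] <- list(
        chromosome = fix$CHROM[r], position = norm$position,
        ref = norm$ref, alt = norm$alt, n_alt = n_alt,
        dosage = dos, dp = dp_raw[r, ], gq = gq_raw[r, ],
        ad_ref = ad_ref, ad_alt = ad_alt)
    }
  }
  rec_key <- vapply(records, function(x)
    variant_id(x$chromosome, x$position, x$ref, x$alt), character(1))
  anno_norm <- purrr::pmap(anno[, c("pos", "ref", "alt")],
                           function(pos, ref, alt)
                             normalize_variant(pos, ref, alt))
  anno_key <- vapply(seq_len(nrow(anno)), function(i)
    variant_id(anno$chrom[i], anno_norm[[i]]$position, anno_norm[[i]]$ref,
               anno_norm[[i]]$alt), character(1))
  orphans <- setdiff(anno_key, rec_key)
  if (length(orphans) > 0) {
    abort(paste0("annotation key(s) matching no VCF record: ",
                 paste(head(orphans, 10), collapse = ", ")))
  }

  mask <- NULL
  if (!is.null(mask_path)) {
    mask <- readr::read_tsv(mask_path, col_names = c("chrom", "start", "end"),
                            show_col_types = FALSE,
                            col_types = readr::cols(chrom = "c", start = "i",
                                                    end = "i"))
  }

  is_panel <- rec_key %in% anno_key
  panel_records <- records[is_panel]
  panel_keys <- rec_key[is_panel]
  av <- anno[match(panel_keys, anno_key), ]
  variants <- tibble::tibble(
    variant_id = panel_keys,
    chromosome = vapply(panel_records, `[[`, character(1), "chromosome"),
    position = vapply(panel_records, `[[`, numeric(1), "position"),
    ref = vapply(panel_records, `[[`, character(1), "ref"),
    alt = vapply(panel_records, `[[`, character(1), "alt"),
    gene = av$gene, consequence = av$consequence,
    maf = av$gnomad_maf, cadd = av$cadd,
    n_alt_alleles_at_locus = vapply(panel_records, `[[`, numeric(1), "n_alt")
  )
  variants$span_nt <- pmax(nchar(variants$ref), nchar(variants$alt))
  variants$in_masked_region <- bed_mask_positions(mask, variants$chromosome,
                                                  variants$position)
  calls <- purrr::map2(panel_records, panel_keys, function(rec, key) {
    tibble::tibble(sample_id = vcf_samples, variant_id = key,
                   dosage = unname(rec$dosage),
                   hemi = rec$chromosome == "X" & unname(male),
                   dp = as.integer(unname(rec$dp)),
                   gq = as.integer(unname(rec$gq)),
                   ad_ref = unname(rec$ad_ref), ad_alt = unname(rec$ad_alt))
  }) |> dplyr::bind_rows()
  variants$site_missingness <- calls |>
    dplyr::group_by(.data$variant_id) |>
    dplyr::summarise(m = mean(is.na(.data$dosage))) |>
    (\(x) x$m[match(variants$variant_id, x$variant_id)])()

  bg_records <- records[!is_panel]
  bg_keys <- rec_key[!is_panel]
  background <- NULL
  background_map <- tibble::tibble(variant_id = character(),
                                   chromosome = character(),
                                   position = integer())
  if (length(bg_records) > 0) {
    background <- do.call(cbind, lapply(bg_records, function(x)
      as.integer(x$dosage)))
    rownames(background) <- vcf_samples
    colnames(background) <- bg_keys
    background_map <- tibble::tibble(
      variant_id = bg_keys,
      chromosome = vapply(bg_records, `[[`, character(1), "chromosome"),
      position = as.integer(vapply(bg_records, `[[`, numeric(1), "position")))
  }

  pedigree <- NULL
  if (!is.null(pedigree_path)) {
    ped <- readr::read_tsv(pedigree_path,
                           col_names = c("family_id", "sample_id",
                                         "father_id", "mother_id", "sex",
                                         "phenotype"),
                           show_col_types = FALSE,
                           col_types = "ccccii")
    pedigree <- tibble::tibble(
      family_id = ped$family_id, sample_id = ped$sample_id,
      father_id = ifelse(ped$father_id == "0", NA_character_, ped$father_id),
      mother_id = ifelse(ped$mother_id == "0", NA_character_, ped$mother_id),
      sex = ifelse(ped$sex == 1, "male", "female"),
      affected = ped$phenotype == 2)
  }
  deletions <- NULL
  if (!is.null(deletions_path)) {
    deletions <- readr::read_tsv(deletions_path, show_col_types = FALSE)
    if ("chrom" %in% names(deletions)) {
      names(deletions)[names(deletions) == "chrom"] <- "chromosome"
    }
    deletions$chromosome <- as.character(deletions$chromosome)
  }

  structure(list(
    samples = tibble::as_tibble(samples),
    panel = panel,
    variants = variants,
    calls = calls,
    background = background,
    background_map = background_map,
    pedigree = pedigree,
    deletions = deletions,
    truth = NULL,
    qc_anomalies = tibble::tibble(reason = "male_x_heterozygous_set_missing",
                                  n = male_x_het),
    config = NULL
  ), class = "rv_cohort")
}
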