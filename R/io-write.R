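format_gt <- function(dosage, hemi) {
  out <- rep("./.", length(dosage))
  out[!is.na(dosage) & dosage == 0L & !hemi] <- "0/0"
  out[!is.na(dosage) & dosage == 1L & !hemi] <- "0/1"
  out[!is.na(dosage) & dosage == 2L & !hemi] <- "1/1"
  out[!is.na(dosage) & dosage == 0L & hemi] <- "0"
  out[!is.na(dosage) & dosage == 1L & hemi] <- "1"
  out[is.na(dosage) & hemi] <- "."
  out
}

#' Write a cohort to disk in standard formats
#'
#' Emits a VCF 4.2 (GT:DP:GQ:AD genotypes; male X genotypes haploid), a
#' variant annotation TSV (`chrom`, `pos`, `ref`, `alt`, `gene`,
#' `consequence`, `gnomad_maf`, `cadd`), a sample metadata TSV, the gene
#' panel TSV, and -- when present -- a 6-column PED pedigree, a deletions
#' TSV and the simulation truth table. Output is deterministic: writing the
#' same cohort twice produces byte-identical files.
#'
#' @param cohort an `rv_cohort`.
#' @param dir output directory (created if needed).
#' @return invisibly, a named list of the file paths written.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    vcf = file.path(dir, "cohort.vcf"),
    annotation = file.path(dir, "annotation.tsv"),
    samples = file.path(dir, "samples.tsv"),
    panel = file.path(dir, "panel.tsv")
  )
  samples <- cohort$samples
  male <- samples$sex == "male"

  # --- VCF ----------------------------------------------------------------
  pv <- cohort$variants
  panel_rows <- tibble::tibble(
    chromosome = pv$chromosome, position = pv$position,
    ref = pv$ref, alt = pv$alt, variant_id = pv$variant_id, panel = TRUE)
  bg_rows <- tibble::tibble(
    chromosome = cohort$background_map$chromosome,
    position = cohort$background_map$position,
    ref = "A", alt = "G",
    variant_id = cohort$background_map$variant_id, panel = FALSE)
  allv <- dplyr::bind_rows(panel_rows, bg_rows)
  chrom_rank <- function(ch) {
    r <- suppressWarnings(as.integer(ch))
    r[ch == "X"] <- 23L
    r
  }
  allv <- allv[order(chrom_rank(allv$chromosome), allv$position,
                     allv$ref, allv$alt), ]

  # genotype string block: panel calls from the long tibble, background from
  # the matrix (constant DP 30 / GQ 99)
  gt_cols <- function(vid, on_x) {
    if (vid %in% panel_rows$variant_id) {
      cc <- cohort$calls[cohort$calls$variant_id == vid, ]
      cc <- cc[match(samples$sample_id, cc$sample_id), ]
      hemi <- on_x & male
      gt <- format_gt(cc$dosage, hemi)
      sprintf("%s:%d:%d:%d,%d", gt, cc$dp, cc$gq, cc$ad_ref, cc$ad_alt)
    } else {
      g <- cohort$background[samples$sample_id,
                             match(vid, colnames(cohort$background))]
      hemi <- rep(FALSE, length(g))
      gt <- format_gt(g, hemi)
      ad_alt <- ifelse(is.na(g), 0L, as.integer(g / 2 * 30))
      ad_alt[!is.na(g) & g == 1L] <- 15L
      sprintf("%s:30:99:%d,%d", gt, 30L - ad_alt, ad_alt)
    }
  }
  body <- vapply(seq_len(nrow(allv)), function(k) {
    on_x <- allv$chromosome[k] == "X"
    paste(c(allv$chromosome[k], allv$position[k], allv$variant_id[k],
            allv$ref[k], allv$alt[k], ".", "PASS", ".", "GT:DP:GQ:AD",
            gt_cols(allv$variant_id[k], on_x)), collapse = "\t")
  }, character(1))
  contigs <- unique(allv$chromosome[order(chrom_rank(allv$chromosome))])
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=recburden",
    paste0("##contig=<ID=", contigs, ">"),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples$sample_id), collapse = "\t"))
  writeLines(c(header, body), paths$vcf)

  # --- annotation (panel variants only) ------------------------------------
  readr::write_tsv(tibble::tibble(
    chrom = pv$chromosome, pos = pv$position, ref = pv$ref, alt = pv$alt,
    gene = pv$gene, consequence = pv$consequence, gnomad_maf = pv$maf,
    cadd = pv$cadd), paths$annotation)

  readr::write_tsv(samples[, c("sample_id", "sex", "group", "severity",
                               "family_id")], paths$samples)
  readr::write_tsv(cohort$panel[, c("gene", "chromosome", "msc",
                                    "inheritance")], paths$panel)

  if (!is.null(cohort$pedigree)) {
    paths$pedigree <- file.path(dir, "cohort.ped")
    ped <- cohort$pedigree
    readr::write_tsv(tibble::tibble(
      family_id = ped$family_id, sample_id = ped$sample_id,
      father_id = dplyr::coalesce(ped$father_id, "0"),
      mother_id = dplyr::coalesce(ped$mother_id, "0"),
      sex = ifelse(ped$sex == "male", 1L, 2L),
      phenotype = ifelse(ped$affected, 2L, 1L)),
      paths$pedigree, col_names = FALSE)
  }
  if (!is.null(cohort$deletions)) {
    paths$deletions <- file.path(dir, "deletions.tsv")
    readr::write_tsv(cohort$deletions, paths$deletions)
  }
  if (!is.null(cohort$truth)) {
    paths$truth <- file.path(dir, "truth.tsv")
    readr::write_tsv(cohort$truth, paths$truth)
  }
  invisible(paths)
}

#' Write an analysis report bundle
#'
#' Writes every result table of a pipeline run as TSV plus a JSON metadata
#' file (configuration, seed, package version). Re-running on identical
#' input reproduces byte-identical TSVs. An empty result set yields a
#' header-only TSV.
#'
#' @param report an `rv_report` from [run_pipeline()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_report <- function(report, out_dir) {
  ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) abort(paste0("cannot create ", out_dir))
  tables <- list(
    burden_results = report$burden,
    cohort_summary = report$summary,
    recessive_calls = report$recessive_calls,
    qc_genotype_log = report$qc_log,
    site_exclusions = report$site_exclusions,
    pca_scores = report$pca$scores,
    kinship = report$kinship,
    roh_rates = report$roh$rates,
    roh_segments = report$roh$segments
  )
  paths <- list()
  for (nm in names(tables)) {
    if (is.null(tables[[nm]])) next
    paths[[nm]] <- file.path(out_dir, paste0(nm, ".tsv"))
    readr::write_tsv(tables[[nm]], paths[[nm]])
  }
  paths$metadata <- file.path(out_dir, "run_metadata.json")
  meta <- list(
    package = "recburden",
    version = as.character(utils::packageVersion("recburden")),
    seed = report$seed,
    config = report$config[!vapply(report$config, is.function, logical(1))]
  )
  jsonlite::write_json(meta, paths$metadata, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(paths)
}
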