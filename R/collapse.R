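#' Collapse qualifying variants into recessive genotype calls
#'
#' Emits one call per sample per gene under a recessive model: `homozygous`
#' if any qualifying site has dosage 2; `hemizygous` if the sample is male,
#' the gene X-linked and a qualifying site has dosage 1; compound
#' heterozygous if the sample carries two or more distinct qualifying
#' heterozygous sites in the same gene -- `compound_het_confirmed` when
#' genotyped parents establish a trans configuration,
#' `compound_het_potential` otherwise (a pair established as cis by the
#' parents yields no call); and `homozygous_deletion` from precomputed
#' homozygous deletion calls overlapping a panel gene (treated as a pLOF
#' homozygous mechanism). When several mechanisms apply in one gene, the
#' strongest is reported (homozygous > homozygous deletion > hemizygous >
#' confirmed > potential compound heterozygote).
#'
#' A sample's panel-level carrier status is having at least one call in the
#' given variant set; without parental data, potential compound
#' heterozygotes count as carriers.
#'
#' @param calls genotype calls (post QC), long tibble.
#' @param variant_set character vector of qualifying variant ids (one
#'   element of [select_candidate_variants()]).
#' @param variants variant tibble (maps variant id to gene).
#' @param panel gene panel.
#' @param samples sample tibble with `sample_id` and `sex`.
#' @param pedigree optional pedigree tibble (`family_id`, `sample_id`,
#'   `father_id`, `mother_id`) enabling trans confirmation.
#' @param deletions optional homozygous-deletion tibble (`sample_id`,
#'   `gene`, `copy_number` 0). Ignored for the synonymous control set.
#' @param set_label label stored in the output (`"primary"`, `"plof"`,
#'   `"plof_any_maf"`, `"synonymous_control"`).
#' @return tibble of recessive calls: `sample_id`, `gene`, `mechanism`,
#'   `variant_keys` (comma-separated), `variant_set_label`.
#' @export
collapse_recessive <- function(calls, variant_set, variants, panel, samples,
                               pedigree = NULL, deletions = NULL,
                               set_label = "primary") {
  panel <- validate_panel(panel)
  if (!is.null(pedigree)) {
    refs <- setdiff(stats::na.omit(c(pedigree$sample_id, pedigree$father_id,
                                     pedigree$mother_id)),
                    c(samples$sample_id, "0"))
    if (length(refs) > 0) {
      abort(paste0("pedigree references unknown sample(s): ",
                   paste(refs, collapse = ", ")))
    }
  }
  if (!is.null(deletions) && nrow(deletions) > 0) {
    if (any(deletions$copy_number != 0)) {
      abort("deletion calls must have copy_number 0 (homozygous deletions)")
    }
    deletions <- deletions[deletions$gene %in% panel$gene, ]
  }
  x_genes <- panel$gene[panel$is_x_linked]
  qual <- calls |>
    dplyr::filter(.data$variant_id %in% variant_set,
                  !is.na(.data$dosage), .data$dosage > 0) |>
    dplyr::inner_join(variants[, c("variant_id", "gene")], by = "variant_id") |>
    dplyr::inner_join(samples[, c("sample_id", "sex")], by = "sample_id")

  parent_alt <- function(parent_id, vids) {
    # dosage > 0 at each variant id; NA dosage treated as unknown -> FALSE
    if (is.na(parent_id) || parent_id == "0") return(NULL)
    pc <- calls[calls$sample_id == parent_id & calls$variant_id %in% vids, ]
    if (nrow(pc) == 0) return(NULL)
    setNames(!is.na(pc$dosage) & pc$dosage > 0, pc$variant_id)[vids]
  }

  per_group <- qual |>
    dplyr::group_by(.data$sample_id, .data$gene, .data$sex) |>
    dplyr::summarise(
      hom_keys = list(.data$variant_id[.data$dosage == 2L]),
      het_keys = list(.data$variant_id[.data$dosage == 1L]),
      .groups = "drop")

  rows <- purrr::pmap(per_group, function(sample_id, gene, sex, hom_keys,
                                          het_keys) {
    on_x <- gene %in% x_genes
    male <- identical(sex, "male")
    if (length(hom_keys) > 0 && !(on_x && male)) {
      return(tibble::tibble(sample_id = sample_id, gene = gene,
                            mechanism = "homozygous",
                            variant_keys = paste(sort(hom_keys),
                                                 collapse = ",")))
    }
    if (on_x && male) {
      keys <- sort(unique(c(hom_keys, het_keys)))
      if (length(keys) > 0) {
        return(tibble::tibble(sample_id = sample_id, gene = gene,
                              mechanism = "hemizygous",
                              variant_keys = paste(keys, collapse = ",")))
      }
      return(NULL)
    }
    if (length(het_keys) >= 2) {
      mech <- "compound_het_potential"
      if (!is.null(pedigree)) {
        ped <- pedigree[pedigree$sample_id == sample_id, ]
        if (nrow(ped) == 1) {
          fa <- parent_alt(ped$father_id[1], het_keys)
          mo <- parent_alt(ped$mother_id[1], het_keys)
          if (!is.null(fa) && !is.null(mo)) {
            pairs <- utils::combn(seq_along(het_keys), 2)
            trans <- cis <- FALSE
            for (k in seq_len(ncol(pairs))) {
              a <- pairs[1, k]; b <- pairs[2, k]
              t1 <- isTRUE(fa[a]) && !isTRUE(fa[b]) &&
                isTRUE(mo[b]) && !isTRUE(mo[a])
              t2 <- isTRUE(fa[b]) && !isTRUE(fa[a]) &&
                isTRUE(mo[a]) && !isTRUE(mo[b])
              c1 <- isTRUE(fa[a]) && isTRUE(fa[b]) &&
                !isTRUE(mo[a]) && !isTRUE(mo[b])
              c2 <- isTRUE(mo[a]) && isTRUE(mo[b]) &&
                !isTRUE(fa[a]) && !isTRUE(fa[b])
              if (t1 || t2) trans <- TRUE
              if (c1 || c2) cis <- TRUE
            }
            if (trans) mech <- "compound_het_confirmed"
            else if (cis) return(NULL)  # all alleles on one haplotype
          }
        }
      }
      return(tibble::tibble(sample_id = sample_id, gene = gene,
                            mechanism = mech,
                            variant_keys = paste(sort(het_keys),
                                                 collapse = ",")))
    }
    NULL
  })
  out <- dplyr::bind_rows(rows)

  if (!is.null(deletions) && nrow(deletions) > 0 &&
      set_label != "synonymous_control") {
    del <- tibble::tibble(sample_id = deletions$sample_id,
                          gene = deletions$gene,
                          mechanism = "homozygous_deletion",
                          variant_keys = paste0(deletions$gene, ":del"))
    out <- dplyr::bind_rows(out, del)
  }
  if (nrow(out) == 0) {
    return(tibble::tibble(sample_id = character(), gene = character(),
                          mechanism = character(), variant_keys = character(),
                          variant_set_label = character()))
  }
  # one call per sample-gene, strongest mechanism
  strength <- c(homozygous = 1, homozygous_deletion = 2, hemizygous = 3,
                compound_het_confirmed = 4, compound_het_potential = 5)
  out |>
    dplyr::mutate(.rank = strength[.data$mechanism]) |>
    dplyr::group_by(.data$sample_id, .data$gene) |>
    dplyr::slice_min(.data$.rank, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::select(-".rank") |>
    dplyr::mutate(variant_set_label = set_label) |>
    dplyr::arrange(.data$gene, .data$sample_id)
}

#' Per-sample carrier status
#'
#' @param recessive_calls output of [collapse_recessive()].
#' @param samples sample tibble.
#' @return `samples` with a logical `carrier` column and a `carrier_gene`
#'   column (first carrier gene, `NA` for non-carriers).
#' @export
carrier_status <- function(recessive_calls, samples) {
  first_gene <- recessive_calls |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(carrier_gene = .data$gene[1])
  samples |>
    dplyr::left_join(first_gene, by = "sample_id") |>
    dplyr::mutate(carrier = !is.na(.data$carrier_gene))
}

#' Familial segregation check for a recessive genotype
#'
#' For each family in the pedigree containing an affected member with a
#' recessive genotype at `gene`, checks consistency with recessive
#' inheritance: each genotyped parent of an autosomal homozygote must carry
#' at least one alternate allele, and the mother of a hemizygote must carry
#' the allele; a genotyped parent carrying zero alleles is a Mendelian
#' inconsistency. Unaffected relatives who share the full recessive genotype
#' are reported as incomplete-penetrance observations, not inconsistencies.
#'
#' @param pedigree tibble with `family_id`, `sample_id`, `father_id`,
#'   `mother_id`, `affected` (logical).
#' @param calls genotype calls for all family members.
#' @param variants variant tibble.
#' @param panel gene panel.
#' @param gene gene symbol to check.
#' @param variant_set optional restriction of qualifying variant ids
#'   (default: all variants in the gene).
#' @return tibble with one row per family: `family_id`, `consistent`,
#'   `n_inconsistencies`, `genotype_positive_unaffected` (comma-separated
#'   sample ids).
#' @export
check_segregation <- function(pedigree, calls, variants, panel, gene,
                              variant_set = NULL) {
  panel <- validate_panel(panel)
  if (is.null(variant_set)) {
    variant_set <- variants$variant_id[variants$gene == gene]
  }
  fam_samples <- unique(pedigree$sample_id)
  samples <- tibble::tibble(
    sample_id = fam_samples,
    sex = pedigree$sex[match(fam_samples, pedigree$sample_id)])
  rc <- collapse_recessive(calls, variant_set, variants, panel, samples,
                           pedigree = NULL, deletions = NULL)
  rc <- rc[rc$gene == gene, ]
  dosage_of <- function(sid, vid) {
    d <- calls$dosage[calls$sample_id == sid & calls$variant_id == vid]
    if (length(d) == 0) NA_integer_ else d[1]
  }
  out <- list()
  for (fam in unique(pedigree$family_id)) {
    ped <- pedigree[pedigree$family_id == fam, ]
    affected <- ped$sample_id[ped$affected]
    probands <- intersect(affected, rc$sample_id)
    if (length(probands) == 0) next
    inconsistencies <- character()
    gp_unaffected <- character()
    for (pr in probands) {
      call <- rc[rc$sample_id == pr, ]
      keys <- strsplit(call$variant_keys, ",")[[1]]
      prow <- ped[ped$sample_id == pr, ]
      check_parent <- function(pid, required_keys) {
        if (is.na(pid) || pid == "0") return(invisible(NULL))
        if (!pid %in% calls$sample_id) return(invisible(NULL))
        carries <- vapply(required_keys, function(v) {
          d <- dosage_of(pid, v)
          !is.na(d) && d > 0
        }, logical(1))
        if (!any(carries)) {
          inconsistencies <<- c(
            inconsistencies,
            sprintf("parent %s of %s carries no qualifying allele", pid, pr))
        }
      }
      if (call$mechanism %in% c("homozygous", "compound_het_potential",
                                "compound_het_confirmed")) {
        check_parent(prow$father_id[1], keys)
        check_parent(prow$mother_id[1], keys)
      } else if (call$mechanism == "hemizygous") {
        check_parent(prow$mother_id[1], keys)
      }
    }
    # unaffected members sharing a full recessive genotype at this gene
    unaff <- setdiff(ped$sample_id, affected)
    gp_unaffected <- intersect(unaff, rc$sample_id)
    out[[length(out) + 1]] <- tibble::tibble(
      family_id = fam,
      consistent = length(inconsistencies) == 0,
      n_inconsistencies = length(inconsistencies),
      inconsistencies = paste(inconsistencies, collapse = "; "),
      genotype_positive_unaffected = paste(gp_unaffected, collapse = ","))
  }
  dplyr::bind_rows(out)
}
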