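# MD/LD/UD driver category assignment, the deleterious UD subset used for
# functional analysis, and the expression-above-background rule for
# hematopoietic tissues.

#' Assign a driver category to gene symbols
#'
#' `MD` if the gene is in the myeloid driver catalog, else `LD` if in the
#' lymphoid catalog, else `UD` (unknown driver). A gene present in both
#' catalogs is MD — the clinically primary category with the more permissive
#' quality gate; affected genes are reported with a message so the
#' precedence is auditable.
#'
#' @param gene Character vector of HGNC symbols (case-insensitive).
#' @param catalog A `ch_gene_catalog`.
#' @return Character vector of `"MD"` / `"LD"` / `"UD"`.
#' @examples
#' cat <- gene_catalog(myeloid = c("TET2", "DNMT3A"), lymphoid = "KMT2D")
#' categorize_gene(c("TET2", "KMT2D", "HBP1"), cat) # MD LD UD
#' @export
categorize_gene <- function(gene, catalog) {
  g <- toupper(gene)
  both <- intersect(unique(g), intersect(catalog$myeloid, catalog$lymphoid))
  if (length(both) > 0) {
    inform(sprintf(
      "gene(s) in both catalogs categorized MD: %s",
      paste(both, collapse = ", ")
    ))
  }
  case_when(
    g %in% catalog$myeloid ~ "MD",
    g %in% catalog$lymphoid ~ "LD",
    TRUE ~ "UD"
  )
}

#' Deleterious subset of unknown-driver calls
#'
#' For functional analysis of UD variants, keeps protein-truncating variants
#' (frameshift indels and nonsense) plus missense variants with M-CAP
#' strictly greater than `mcap_min`; other missense variants, and missense
#' variants without an M-CAP score, are excluded (the latter with a
#' message).
#'
#' @param calls A CH-call tibble (rows with `category == "UD"` are
#'   considered; others are dropped).
#' @param mcap_min M-CAP cutoff, strict inequality. Default 0.025.
#' @return The deleterious UD subset of `calls`.
#' @export
select_deleterious_ud <- function(calls, mcap_min = 0.025) {
  ud <- calls %>% filter(.data$category == "UD")
  missing_mcap <- ud %>%
    filter(
      !.data$protein_truncating, .data$consequence == "missense",
      is.na(.data$mcap)
    )
  if (nrow(missing_mcap) > 0) {
    inform(sprintf(
      "%d missense UD variant(s) without an M-CAP score excluded",
      nrow(missing_mcap)
    ))
  }
  ud %>%
    filter(
      .data$protein_truncating |
        (.data$consequence == "missense" & !is.na(.data$mcap) &
           .data$mcap > mcap_min)
    )
}

#' Expression-above-background rule for hematopoietic tissues
#'
#' A gene counts as expressed above background if any supplied record
#' satisfies its assay's rule: `sqrt(100 * FPKM) > 1` for bulk RNA-seq,
#' `intensity^(2/3) > 1` for microarray data, or `log10(ppm) > -1` for
#' protein abundance. The rule is monotone in each record's value.
#'
#' @param records Tibble with columns `gene`, `assay` (one of
#'   `rnaseq_fpkm`, `microarray_intensity`, `protein_ppm`) and non-negative
#'   `value`; typically restricted to immune/blood tissues upstream.
#' @return A tibble `gene`, `expressed` (logical), one row per gene.
#' @export
expression_above_background <- function(records) {
  bad <- setdiff(
    unique(records$assay),
    c("rnaseq_fpkm", "microarray_intensity", "protein_ppm")
  )
  if (length(bad) > 0) {
    abort(sprintf("unknown assay type(s): %s", paste(bad, collapse = ", ")))
  }
  if (any(records$value < 0)) abort("expression values must be non-negative")
  records %>%
    mutate(hit = case_when(
      .data$assay == "rnaseq_fpkm" ~ sqrt(100 * .data$value) > 1,
      .data$assay == "microarray_intensity" ~ .data$value^(2 / 3) > 1,
      .data$assay == "protein_ppm" ~ .data$value > 0 & log10(.data$value) > -1
    )) %>%
    group_by(.data$gene) %>%
    summarise(expressed = any(.data$hit), .groups = "drop")
}

#' Export per-group ranked gene lists
#'
#' Produces one ranked gene list per (disease, LOY-status) stratum for
#' consumption by an external gene-set enrichment tool. The rank score is an
#' explicit, documented function: carrier frequency within the stratum,
#' weighted by impact class (protein-truncating 2, deleterious missense 1.5
#' when M-CAP > 0.025, otherwise 1) and by category weight (MD 3, LD 2,
#' UD 1). No equivalence with any published ranking is claimed.
#'
#' @param calls CH-call tibble.
#' @param subjects_classified Output of [classify_subjects()].
#' @return Tibble `group` (e.g. `"AD-LOY"`), `gene`, `score`, sorted by
#'   descending score within group.
#' @export
rank_genes_for_gsea <- function(calls, subjects_classified) {
  strata <- subjects_classified %>%
    mutate(stratum = paste(.data$group, .data$loy_status, sep = "-"))
  n_per <- strata %>% dplyr::count(.data$stratum, name = "n_subjects")
  calls %>%
    inner_join(
      strata %>% select("subject_id", "stratum"),
      by = "subject_id"
    ) %>%
    mutate(
      impact_w = case_when(
        .data$protein_truncating ~ 2,
        .data$consequence == "missense" & !is.na(.data$mcap) &
          .data$mcap > 0.025 ~ 1.5,
        TRUE ~ 1
      ),
      category_w = case_when(
        .data$category == "MD" ~ 3,
        .data$category == "LD" ~ 2,
        TRUE ~ 1
      )
    ) %>%
    group_by(.data$stratum, .data$gene) %>%
    summarise(
      n_carriers = n_distinct(.data$subject_id),
      weight = max(.data$impact_w * .data$category_w),
      .groups = "drop"
    ) %>%
    left_join(n_per, by = "stratum") %>%
    transmute(
      group = .data$stratum, .data$gene,
      score = .data$weight * .data$n_carriers / .data$n_subjects
    ) %>%
    arrange(.data$group, dplyr::desc(.data$score), .data$gene)
}
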