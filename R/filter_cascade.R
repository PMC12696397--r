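# The staged variant filter cascade: caller prefilter, caller-flag filter,
# gnomAD popmax filter, consequence filter, zygosity designation, driver
# category assignment, category-specific quality filters, and the cohort
# singleton rule. Every input variant is attributed to the first stage that
# dropped it, so drops + survivors always reconcile with the input count.

#' Filter cascade configuration
#'
#' All thresholds behave exactly as printed in the defaults' source rules:
#' inclusive at `>=`/`<=` boundaries. Myeloid-driver (MD) variants face a
#' more permissive quality gate (depth >= 20, >= 3 alternate reads, VAF >=
#' 0.01) than lymphoid/unknown-driver (LD/UD) variants (depth >= 20, >= 5
#' alternate reads, VAF >= 0.02); both require strand-balanced alternate
#' support. "Balanced" defaults to the weakest reading — at least
#' `min_per_strand = 1` alternate read on each strand.
#'
#' @param prefilter_mq_min Minimum read mapping quality; reads below exclude
#'   the variant. Default 30.
#' @param prefilter_hq_alt_min Minimum number of alternate reads with base
#'   quality >= 30 supporting the call. Default 5.
#' @param flags_kept Caller FILTER values admitted. Default
#'   `c("PASS", "alleleBias")`.
#' @param popmax_max Maximum gnomAD popmax MAF; unlisted variants are kept.
#'   Default 0.01.
#' @param md_dp_min,md_alt_min,md_vaf_min Quality gate for MD variants
#'   (20, 3, 0.01).
#' @param ldud_dp_min,ldud_alt_min,ldud_vaf_min Quality gate for LD/UD
#'   variants (20, 5, 0.02).
#' @param min_per_strand Minimum alternate reads per strand for balance.
#' @param singleton Apply the cohort singleton rule. Default TRUE.
#' @param oncogenic_md_exempt Exempt highly oncogenic MD variants from the
#'   singleton rule. Default TRUE.
#' @param auto_reclass_early_clonal Automatically reclassify germline-
#'   designated variants carrying the early-clonal VAF profile as
#'   post-zygotic. Default FALSE: candidates are flagged in the audit and
#'   reclassified only through the explicit `overrides` argument of
#'   [run_cascade()].
#' @param early_clonal_min_low,early_clonal_ratio_min Parameters of
#'   [early_clonal_flag()].
#' @param rescue A [rescue_config()].
#' @return A `filter_config` list.
#' @export
filter_config <- function(prefilter_mq_min = 30,
                          prefilter_hq_alt_min = 5,
                          flags_kept = c("PASS", "alleleBias"),
                          popmax_max = 0.01,
                          md_dp_min = 20, md_alt_min = 3, md_vaf_min = 0.01,
                          ldud_dp_min = 20, ldud_alt_min = 5,
                          ldud_vaf_min = 0.02,
                          min_per_strand = 1,
                          singleton = TRUE,
                          oncogenic_md_exempt = TRUE,
                          auto_reclass_early_clonal = FALSE,
                          early_clonal_min_low = 0.05,
                          early_clonal_ratio_min = 2.0,
                          rescue = rescue_config()) {
  cfg <- as.list(environment())
  stopifnot(
    md_vaf_min >= 0, md_vaf_min <= 1, ldud_vaf_min >= 0, ldud_vaf_min <= 1,
    popmax_max >= 0, min_per_strand >= 0
  )
  structure(cfg, class = "filter_config")
}

KEY_COLS <- c("subject_id", "chrom", "pos", "ref", "alt")

#' Caller-level read-quality prefilter
#'
#' Drops calls whose supporting reads have poor mapping quality
#' (`min_read_mq` below 30) or fewer than five alternate reads of base
#' quality >= 30. Rows with missing metrics are dropped with reason
#' `"missing-evidence"`.
#'
#' @param variants Variant tibble (per-fraction rows).
#' @param config A [filter_config()].
#' @return The input with logical `keep` and character `reason` columns.
#' @export
caller_prefilter <- function(variants, config = filter_config()) {
  variants %>%
    mutate(
      reason = case_when(
        is.na(.data$min_read_mq) | is.na(.data$n_hq_alt) ~ "missing-evidence",
        .data$min_read_mq < config$prefilter_mq_min ~ "low-mapping-quality",
        .data$n_hq_alt < config$prefilter_hq_alt_min ~ "few-hq-alt-reads",
        TRUE ~ NA_character_
      ),
      keep = is.na(.data$reason)
    )
}

#' Caller flag filter
#'
#' Keeps calls whose caller FILTER value is in the admitted set
#' (PASS and alleleBias by default; alleleBias is retained deliberately,
#' since genuine post-zygotic variants sit far from the 0.5 heterozygous
#' expectation).
#'
#' @inheritParams caller_prefilter
#' @return Input with a logical `keep` column.
#' @export
flag_filter <- function(variants, config = filter_config()) {
  variants %>% mutate(keep = .data$caller_flag %in% config$flags_kept)
}

#' Population-frequency filter
#'
#' Keeps variants whose gnomAD popmax minor allele frequency is at most
#' `popmax_max` (inclusive) or absent ("not listed in gnomAD").
#'
#' @inheritParams caller_prefilter
#' @return Input with a logical `keep` column.
#' @export
population_filter <- function(variants, config = filter_config()) {
  variants %>%
    mutate(keep = is.na(.data$popmax_maf) | .data$popmax_maf <= config$popmax_max)
}

#' Consequence filter
#'
#' Keeps exonic frameshift indels, nonsense and missense variants;
#' everything else (the `"other"` class) is dropped. Frameshift indels and
#' nonsense variants are the protein-truncating classes.
#'
#' @param variants Variant tibble.
#' @return Input with a logical `keep` column.
#' @export
consequence_filter <- function(variants) {
  variants %>%
    mutate(keep = .data$consequence %in% c("frameshift_indel", "nonsense", "missense"))
}

#' Category-specific quality filter
#'
#' MD variants: depth >= 20, >= 3 alternate reads, VAF >= 0.01.
#' LD/UD variants: depth >= 20, >= 5 alternate reads, VAF >= 0.02.
#' Both require at least `min_per_strand` alternate reads on each strand.
#'
#' @param variants Variant rows carrying a `category` column (`MD`, `LD`,
#'   `UD`).
#' @param config A [filter_config()].
#' @return Input with logical `keep` and character `reason` columns.
#' @export
quality_filter <- function(variants, config = filter_config()) {
  variants %>%
    mutate(
      alt_total = .data$alt_fwd + .data$alt_rev,
      dp_min = if_else(.data$category == "MD", config$md_dp_min, config$ldud_dp_min),
      alt_min = if_else(.data$category == "MD", config$md_alt_min, config$ldud_alt_min),
      vaf_min = if_else(.data$category == "MD", config$md_vaf_min, config$ldud_vaf_min),
      reason = case_when(
        .data$depth < .data$dp_min ~ "low-depth",
        .data$alt_total < .data$alt_min ~ "few-alt-reads",
        .data$alt_fwd < config$min_per_strand |
          .data$alt_rev < config$min_per_strand ~ "strand-imbalance",
        .data$vaf < .data$vaf_min ~ "low-vaf",
        TRUE ~ NA_character_
      ),
      keep = is.na(.data$reason)
    ) %>%
    select(-"dp_min", -"alt_min", -"vaf_min", -"alt_total")
}

#' Cohort singleton filter
#'
#' Keeps variants observed in exactly one subject of the cohort. Recurrence
#' is counted at the subject level on the variant key (chrom, pos, ref,
#' alt): a variant in two fractions of one subject is still a singleton.
#' Highly oncogenic myeloid-driver variants are exempt and kept even when
#' recurrent.
#'
#' @param calls Per-(subject, variant) tibble with `category` and
#'   `oncogenic` columns.
#' @param config A [filter_config()].
#' @return Input with a logical `keep` column.
#' @export
singleton_filter <- function(calls, config = filter_config()) {
  counts <- calls %>%
    group_by(.data$chrom, .data$pos, .data$ref, .data$alt) %>%
    summarise(n_subjects = n_distinct(.data$subject_id), .groups = "drop")
  calls %>%
    left_join(counts, by = c("chrom", "pos", "ref", "alt")) %>%
    mutate(
      keep = !config$singleton |
        .data$n_subjects == 1L |
        (config$oncogenic_md_exempt & .data$category == "MD" & .data$oncogenic)
    ) %>%
    select(-"n_subjects")
}

#' Run the full variant filter cascade
#'
#' Applies, in order: caller prefilter, flag filter, popmax filter,
#' consequence filter, cross-fraction presence resolution and zygosity
#' designation (germline variants dropped, subject to the early-clonal
#' override), driver category assignment, category-specific quality gates,
#' and the singleton rule. The unit of accounting is the
#' (subject, variant key) pair; per-fraction stages keep a variant when at
#' least one of its fraction rows passes.
#'
#' Rescued fractions (uncalled, but meeting the pileup evidence thresholds)
#' count towards presence, zygosity and the sharing pattern; the quality
#' gate is evaluated on caller-reported rows, which carry strand counts.
#'
#' @param variants Per-fraction variant tibble from [read_variant_table()].
#' @param subjects Long subject tibble from [read_subject_table()], used for
#'   the assayed-fraction sets.
#' @param catalog A `ch_gene_catalog`.
#' @param config A [filter_config()].
#' @param evidence Optional pileup-evidence tibble for uncalled fractions
#'   (columns `subject_id`, `chrom`, `pos`, `ref`, `alt`, `cell_type`,
#'   `depth`, `n_hq_alt`, `site_mq`, `vaf`).
#' @param overrides Optional tibble of zygosity overrides (columns `chrom`,
#'   `pos`, `ref`, `alt`, `forced_zygosity`, optional `subject_id`,
#'   `justification`), echoed into the audit table.
#' @return A `ch_callset`: list with `calls` (one row per surviving
#'   post-zygotic variant per subject), `fractions` (long per-fraction VAFs
#'   of surviving variants), `audit` (first drop stage per input variant)
#'   and `stage_counts`.
#' @export
run_cascade <- function(variants, subjects, catalog,
                        config = filter_config(),
                        evidence = NULL, overrides = NULL) {
  fractions <- assayed_fractions(subjects)
  if (!"vaf" %in% names(variants)) {
    variants <- validate_variants(variants)
  }
  units <- variants %>%
    group_by(across(dplyr::all_of(KEY_COLS))) %>%
    summarise(
      gene = first(.data$gene),
      consequence = first(.data$consequence),
      popmax_maf = first(.data$popmax_maf),
      mcap = first(.data$mcap),
      oncogenic = any(.data$oncogenic),
      .groups = "drop"
    )
  audit <- units %>% mutate(stage = NA_character_, detail = NA_character_)

  mark <- function(audit, dropped_keys, stage_label, detail_label = NA_character_) {
    hit <- vctrs_in(audit, dropped_keys, KEY_COLS) & is.na(audit$stage)
    audit$detail[hit & !is.na(detail_label)] <- detail_label
    audit$stage[hit] <- stage_label
    audit
  }

  # --- per-fraction row stages -------------------------------------------
  rows <- caller_prefilter(variants, config)
  dropped <- unit_dropped(rows)
  audit <- mark(audit, dropped, "prefilter")
  rows <- rows %>% filter(.data$keep) %>% select(-"keep", -"reason")

  rows <- flag_filter(rows, config)
  dropped <- unit_dropped(rows)
  audit <- mark(audit, dropped, "flag")
  rows <- rows %>% filter(.data$keep) %>% select(-"keep")

  # --- per-variant annotation stages -------------------------------------
  rows <- population_filter(rows, config)
  dropped <- unit_dropped(rows)
  audit <- mark(audit, dropped, "popmax")
  rows <- rows %>% filter(.data$keep) %>% select(-"keep")

  rows <- consequence_filter(rows)
  dropped <- unit_dropped(rows)
  audit <- mark(audit, dropped, "consequence")
  rows <- rows %>% filter(.data$keep) %>% select(-"keep")

  # --- presence resolution and zygosity ----------------------------------
  presence <- resolve_presence(rows, evidence, fractions, config$rescue)
  pres_units <- presence %>%
    group_by(across(dplyr::all_of(KEY_COLS))) %>%
    summarise(
      n_fractions = n(),
      n_with_evidence = sum(.data$has_evidence),
      n_present = sum(.data$present),
      .groups = "drop"
    )
  # The designation rule needs evidence (a call or a pileup row) in every
  # assayed fraction; otherwise absence elsewhere cannot be established.
  no_rule <- pres_units %>%
    filter(.data$n_with_evidence < .data$n_fractions | .data$n_fractions < 2)
  audit <- mark(audit, no_rule, "missing_evidence")
  pres_units <- pres_units %>% anti_join(no_rule, by = KEY_COLS)

  zyg <- pres_units %>%
    mutate(zygosity = if_else(
      .data$n_present == .data$n_fractions, "germline", "post_zygotic"
    ))

  # Per-fraction VAFs of presence fractions (called VAF, else pileup VAF)
  vaf_map <- presence %>%
    semi_join(zyg, by = KEY_COLS) %>%
    left_join(
      rows %>% select(dplyr::all_of(KEY_COLS), "cell_type", call_vaf = "vaf"),
      by = c(KEY_COLS, "cell_type")
    ) %>%
    mutate(frac_vaf = dplyr::coalesce(.data$call_vaf, .data$ev_vaf, 0))

  # Early-clonal candidates among germline designations
  germ_keys <- zyg %>% filter(.data$zygosity == "germline")
  flagged <- vaf_map %>%
    semi_join(germ_keys, by = KEY_COLS) %>%
    group_by(across(dplyr::all_of(KEY_COLS))) %>%
    summarise(
      early_clonal = early_clonal_flag(
        .data$frac_vaf,
        min_low = config$early_clonal_min_low,
        ratio_min = config$early_clonal_ratio_min
      ),
      .groups = "drop"
    ) %>%
    filter(.data$early_clonal)

  forced_pz <- override_keys(overrides, "post_zygotic", units)
  forced_germ <- override_keys(overrides, "germline", units)
  reclass <- if (config$auto_reclass_early_clonal) {
    bind_rows(flagged %>% select(dplyr::all_of(KEY_COLS)), forced_pz) %>%
      distinct()
  } else {
    forced_pz
  }
  zyg <- zyg %>%
    mutate(
      zygosity = if_else(
        vctrs_in(., reclass, KEY_COLS), "post_zygotic", .data$zygosity
      ),
      zygosity = if_else(
        vctrs_in(., forced_germ, KEY_COLS), "germline", .data$zygosity
      )
    )

  germ_final <- zyg %>% filter(.data$zygosity == "germline")
  audit <- mark(
    audit, germ_final %>% semi_join(flagged, by = KEY_COLS),
    "germline", "early-clonal-candidate"
  )
  audit <- mark(audit, germ_final, "germline")
  pz <- zyg %>% filter(.data$zygosity == "post_zygotic")

  # --- category assignment and quality -----------------------------------
  pz_rows <- rows %>%
    semi_join(pz, by = KEY_COLS) %>%
    mutate(category = categorize_gene(.data$gene, catalog))
  pz_rows <- quality_filter(pz_rows, config)
  q_ok <- pz_rows %>%
    group_by(across(dplyr::all_of(KEY_COLS))) %>%
    summarise(keep = any(.data$keep), .groups = "drop")
  audit <- mark(audit, q_ok %>% filter(!.data$keep), "quality")
  pz <- pz %>% semi_join(q_ok %>% filter(.data$keep), by = KEY_COLS)

  # --- singleton rule ----------------------------------------------------
  calls <- pz %>%
    left_join(units, by = KEY_COLS) %>%
    mutate(
      category = categorize_gene(.data$gene, catalog),
      protein_truncating = .data$consequence %in% c("frameshift_indel", "nonsense")
    )
  calls <- singleton_filter(calls, config)
  audit <- mark(audit, calls %>% filter(!.data$keep), "singleton")
  calls <- calls %>% filter(.data$keep) %>% select(-"keep")

  # --- assemble output ---------------------------------------------------
  present_frac <- vaf_map %>%
    filter(.data$present) %>%
    semi_join(calls, by = KEY_COLS) %>%
    transmute(
      .data$subject_id, .data$chrom, .data$pos, .data$ref, .data$alt,
      .data$gene, .data$cell_type,
      vaf = .data$frac_vaf,
      source = if_else(.data$called_by_caller, "called", "rescued")
    ) %>%
    left_join(
      calls %>% select(dplyr::all_of(KEY_COLS), "category"),
      by = KEY_COLS
    )

  call_summ <- if (nrow(present_frac) == 0) {
    tibble(
      subject_id = character(), chrom = character(), pos = integer(),
      ref = character(), alt = character(), present_in = character(),
      pattern = character(), n_fractions_present = integer(),
      max_vaf = numeric()
    )
  } else {
    present_frac %>%
      group_by(across(dplyr::all_of(KEY_COLS))) %>%
      summarise(
        present_in = paste(
          CELL_TYPES[sort(match(unique(.data$cell_type), CELL_TYPES))],
          collapse = "+"
        ),
        pattern = sharing_pattern(.data$cell_type),
        n_fractions_present = n_distinct(.data$cell_type),
        max_vaf = max(.data$vaf),
        .groups = "drop"
      )
  }
  calls <- calls %>%
    left_join(call_summ, by = KEY_COLS) %>%
    mutate(
      zygosity = "post_zygotic",
      early_clonal = vctrs_in(., flagged, KEY_COLS)
    ) %>%
    select(
      "subject_id", "chrom", "pos", "ref", "alt", "gene", "category",
      "consequence", "protein_truncating", "oncogenic", "mcap",
      "present_in", "pattern", "n_fractions_present", "max_vaf",
      "zygosity", "early_clonal"
    ) %>%
    arrange(.data$subject_id, .data$chrom, .data$pos, .data$ref, .data$alt)

  audit <- audit %>%
    mutate(stage = if_else(is.na(.data$stage), "survivor", .data$stage))
  if (!is.null(overrides) && nrow(overrides) > 0) {
    ov <- overrides
    if (!"subject_id" %in% names(ov)) ov$subject_id <- NA_character_
    if (!"justification" %in% names(ov)) ov$justification <- NA_character_
    attr(audit, "overrides") <- as_tibble(ov)
  }
  stage_order <- c(
    "prefilter", "flag", "popmax", "consequence", "missing_evidence",
    "germline", "quality", "singleton", "survivor"
  )
  stage_counts <- audit %>%
    dplyr::count(stage = factor(.data$stage, levels = stage_order),
                 .drop = FALSE, name = "n") %>%
    mutate(stage = as.character(.data$stage))

  structure(
    list(
      calls = calls,
      fractions = present_frac,
      audit = audit,
      stage_counts = stage_counts,
      config = config
    ),
    class = "ch_callset"
  )
}

#' @export
print.ch_callset <- function(x, ...) {
  cat(sprintf(
    "<ch_callset> %d post-zygotic CH calls in %d subjects (%d input variants)\n",
    nrow(x$calls), n_distinct(x$calls$subject_id), nrow(x$audit)
  ))
  print(x$stage_counts)
  invisible(x)
}

# Units whose rows ALL failed the row-level `keep` flag.
unit_dropped <- function(rows) {
  rows %>%
    group_by(across(dplyr::all_of(KEY_COLS))) %>%
    summarise(keep = any(.data$keep), .groups = "drop") %>%
    filter(!.data$keep)
}

# Row membership of `tbl` keys in `keys`, by the columns in `by`.
vctrs_in <- function(tbl, keys, by) {
  if (is.null(keys) || nrow(keys) == 0) {
    return(rep(FALSE, nrow(tbl)))
  }
  a <- do.call(paste, c(tbl[by], sep = "\r"))
  b <- do.call(paste, c(keys[by], sep = "\r"))
  a %in% b
}

override_keys <- function(overrides, zygosity, units) {
  if (is.null(overrides) || nrow(overrides) == 0) {
    return(tibble(
      subject_id = character(), chrom = character(), pos = integer(),
      ref = character(), alt = character()
    ))
  }
  ov <- overrides %>% filter(.data$forced_zygosity == zygosity)
  if (!"subject_id" %in% names(ov) || all(is.na(ov$subject_id))) {
    units %>%
      semi_join(ov, by = c("chrom", "pos", "ref", "alt")) %>%
      select(dplyr::all_of(KEY_COLS))
  } else {
    units %>%
      semi_join(ov, by = KEY_COLS) %>%
      select(dplyr::all_of(KEY_COLS))
  }
}
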