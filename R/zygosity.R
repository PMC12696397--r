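# Germline vs post-zygotic designation by cross-fraction presence within a
# subject, with a programmatic rescue check standing in for manual pileup
# review, and an explicit override path for early-clonal variants present in
# all lineages at strongly imbalanced VAFs.

#' Rescue configuration for presence resolution
#'
#' When a variant is called in one fraction but not another, the uncalled
#' fraction's pileup evidence can still establish presence: at least
#' `alt_min` alternate reads of base quality >= `bq_min`, total depth >=
#' `dp_min`, and site mapping quality >= `mq_min`. The base-quality cutoff of
#' 60 exceeds the usual per-base Phred range and is best understood as a
#' summed/recalibrated score; it is configurable for that reason.
#'
#' @param alt_min,dp_min,mq_min,bq_min Rescue thresholds (defaults 5, 20,
#'   60, 60).
#' @return A `rescue_config` list.
#' @export
rescue_config <- function(alt_min = 5, dp_min = 20, mq_min = 60, bq_min = 60) {
  structure(
    list(alt_min = alt_min, dp_min = dp_min, mq_min = mq_min, bq_min = bq_min),
    class = "rescue_config"
  )
}

#' Presence of a variant in a fraction, with rescue
#'
#' A variant is present in a fraction if the caller reported it there, or if
#' the pileup evidence meets all rescue thresholds. Vectorised.
#'
#' @param called_by_caller Logical: did the caller report the variant here?
#' @param n_hq_alt Alternate reads at or above the rescue base-quality cutoff.
#' @param depth Total read depth at the site.
#' @param site_mq Mapping quality at the site.
#' @param config A [rescue_config()].
#' @return Logical vector of presence.
#' @export
rescue_presence <- function(called_by_caller, n_hq_alt, depth, site_mq,
                            config = rescue_config()) {
  called_by_caller |
    (n_hq_alt >= config$alt_min &
       depth >= config$dp_min &
       site_mq >= config$mq_min)
}

#' Designate a variant germline or post-zygotic from its presence set
#'
#' Within one subject, a variant present in every assayed fraction is
#' germline; present in at least one but not all, post-zygotic. Presence in
#' zero fractions is an error (the variant should never have been called).
#'
#' @param present Logical vector over the subject's assayed fractions.
#' @return `"germline"` or `"post_zygotic"`.
#' @export
designate_zygosity <- function(present) {
  if (length(present) < 2) {
    abort("zygosity designation needs evidence in at least two fractions")
  }
  n_present <- sum(present)
  if (n_present == 0) {
    abort("variant present in zero fractions: should not have been called")
  }
  if (n_present == length(present)) "germline" else "post_zygotic"
}

#' Flag germline-designated variants with an early-clonal VAF profile
#'
#' A somatic variant acquired in a hematopoietic stem or progenitor cell can
#' appear in all three lineages yet at strongly imbalanced VAFs (e.g. barely
#' detectable in CD4+ T cells but at 0.1-0.2 in NK and myeloid cells). Such
#' variants would be designated germline by the presence rule alone. This
#' flags candidates whose minimum VAF is at most `min_low` and whose max/min
#' VAF ratio is at least `ratio_min`; flagged variants are only reclassified
#' post-zygotic when `auto_reclass` is enabled in [run_cascade()] or listed
#' in an explicit override.
#'
#' @param vafs Numeric vector of per-fraction VAFs (all assayed fractions).
#' @param min_low Maximum of the lowest per-fraction VAF. Default 0.05.
#' @param ratio_min Minimum max/min VAF ratio. Default 2.
#' @return Logical scalar.
#' @export
early_clonal_flag <- function(vafs, min_low = 0.05, ratio_min = 2.0) {
  lo <- min(vafs)
  hi <- max(vafs)
  ratio <- if (lo == 0) Inf else hi / lo
  lo <= min_low && ratio >= ratio_min
}

#' Lineage sharing pattern of a presence set
#'
#' Maps a post-zygotic variant's set of carrying fractions to one of the
#' seven sharing-pattern labels (`all_three`, `NK_MYEL`, `CD4_NK`,
#' `CD4_MYEL`, `CD4_only`, `NK_only`, `MYEL_only`).
#'
#' @param present_in Character vector of fraction labels (subset of
#'   `CD4`, `NK`, `MYEL`).
#' @return A pattern label.
#' @export
sharing_pattern <- function(present_in) {
  s <- sort(match(unique(present_in), CELL_TYPES))
  if (anyNA(s) || length(s) == 0) {
    abort("present_in must be a non-empty subset of CD4/NK/MYEL")
  }
  key <- paste(CELL_TYPES[s], collapse = "_")
  switch(key,
    "CD4_NK_MYEL" = "all_three",
    "NK_MYEL" = "NK_MYEL",
    "CD4_NK" = "CD4_NK",
    "CD4_MYEL" = "CD4_MYEL",
    "CD4" = "CD4_only",
    "NK" = "NK_only",
    "MYEL" = "MYEL_only"
  )
}

# Resolve presence of every (subject, variant key) across the subject's
# assayed fractions. `calls` are caller rows surviving the per-row filters;
# `evidence` optionally supplies pileup metrics for uncalled fractions.
# Returns one row per (subject, key, fraction) with a `present` flag, or
# drops the variant with reason "missing-evidence" when fractions without a
# call also lack evidence rows (the designation rule cannot be applied).
resolve_presence <- function(calls, evidence, fractions,
                             config = rescue_config()) {
  keys <- calls %>%
    distinct(
      .data$subject_id, .data$chrom, .data$pos, .data$ref, .data$alt,
      .data$gene
    )
  grid <- keys %>%
    inner_join(fractions, by = "subject_id", relationship = "many-to-many")
  called <- calls %>%
    distinct(
      .data$subject_id, .data$chrom, .data$pos, .data$ref, .data$alt,
      .data$cell_type
    ) %>%
    mutate(called_by_caller = TRUE)
  grid <- grid %>%
    left_join(
      called,
      by = c("subject_id", "chrom", "pos", "ref", "alt", "cell_type")
    ) %>%
    mutate(called_by_caller = !is.na(.data$called_by_caller))
  if (!is.null(evidence)) {
    grid <- grid %>%
      left_join(
        evidence %>%
          select(
            "subject_id", "chrom", "pos", "ref", "alt", "cell_type",
            ev_depth = "depth", ev_n_hq_alt = "n_hq_alt",
            ev_site_mq = "site_mq", ev_vaf = "vaf"
          ),
        by = c("subject_id", "chrom", "pos", "ref", "alt", "cell_type")
      )
  } else {
    grid <- grid %>%
      mutate(
        ev_depth = NA_real_, ev_n_hq_alt = NA_real_,
        ev_site_mq = NA_real_, ev_vaf = NA_real_
      )
  }
  grid %>%
    mutate(
      has_evidence = .data$called_by_caller | !is.na(.data$ev_n_hq_alt),
      present = rescue_presence(
        .data$called_by_caller,
        dplyr::coalesce(.data$ev_n_hq_alt, 0),
        dplyr::coalesce(.data$ev_depth, 0),
        dplyr::coalesce(.data$ev_site_mq, 0),
        config
      )
    )
}
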