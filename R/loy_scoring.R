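# Conversion of raw LOY measurements (mLRR-Y, ddPCR) to %LOY, resolution of
# the two assays, and LOY/ROY classification of fractions and subjects.

#' LOY scoring configuration
#'
#' @param threshold_pct Percentage of Y-lacking cells at or above which a
#'   fraction is classified LOY. Default 15.
#' @param mlrry_k Exponent multiplier in the mLRR-Y conversion
#'   `100 * (1 - 2^(k * mLRRY))`. Default 1 (single-copy Y intensity model);
#'   exposed so alternative published calibrations can be matched.
#' @param prefer Which assay wins when a fraction was measured by both;
#'   ddPCR by default.
#' @return A `loy_config` list.
#' @export
loy_config <- function(threshold_pct = 15,
                       mlrry_k = 1,
                       prefer = c("ddPCR", "mLRRY")) {
  prefer <- match.arg(prefer)
  if (threshold_pct <= 0 || threshold_pct >= 100) {
    abort("threshold_pct must lie in (0, 100)")
  }
  if (mlrry_k <= 0) abort("mlrry_k must be positive")
  structure(
    list(threshold_pct = threshold_pct, mlrry_k = mlrry_k, prefer = prefer),
    class = "loy_config"
  )
}

#' Percent LOY from an mLRR-Y value
#'
#' mLRR-Y is the median log2 R ratio over Y-chromosome SNP-array probes; it
#' falls as the Y-bearing cell fraction shrinks. Under a single-copy intensity
#' model the Y-bearing fraction is `2^(k * mLRRY)`, so
#' `%LOY = 100 * (1 - 2^(k * mLRRY))`, clamped to `[0, 100]` (positive
#' mLRR-Y noise would otherwise yield negative percentages).
#'
#' @param mlrry Numeric vector of mLRR-Y log2 ratios.
#' @param config A [loy_config()].
#' @return Percentages in `[0, 100]`.
#' @examples
#' pct_loy_from_mlrry(c(0, -1, log2(0.9))) # 0, 50, 10
#' @export
pct_loy_from_mlrry <- function(mlrry, config = loy_config()) {
  if (any(!is.finite(mlrry))) abort("mlrry values must be finite")
  pmin(100, pmax(0, 100 * (1 - 2^(config$mlrry_k * mlrry))))
}

#' Percent LOY from ddPCR AMELY/AMELX concentrations
#'
#' The autosomal-normalised Y copy number is the ratio of AMELY to AMELX
#' droplet-derived concentrations; `%LOY = 100 * (1 - AMELY/AMELX)`, clamped
#' to `[0, 100]`.
#'
#' @param amely,amelx Droplet-derived copy concentrations; `amelx` must be
#'   positive (it is the reference signal).
#' @param ... Unused.
#' @return Percentages in `[0, 100]`.
#' @export
pct_loy_from_ddpcr <- function(amely, amelx, ...) {
  if (any(amelx <= 0)) abort("amelx must be positive (no reference signal)")
  if (any(amely < 0)) abort("amely must be non-negative")
  pct_loy_from_ratio(amely / amelx)
}

# ddPCR raw values in the subject table are stored as the AMELY/AMELX ratio.
pct_loy_from_ratio <- function(ratio) {
  pmin(100, pmax(0, 100 * (1 - ratio)))
}

#' Resolve per-fraction %LOY and classify fractions
#'
#' Converts every measurement to %LOY, then keeps one value per
#' (subject, fraction): the ddPCR-derived value when present, otherwise the
#' mLRR-Y-derived value (or the reverse under `prefer = "mLRRY"`). The
#' non-preferred value is retained in `pct_loy_other` for QC but never used
#' for classification.
#'
#' @param subjects Long measurement tibble from [read_subject_table()].
#' @param config A [loy_config()].
#' @return A tibble with one row per (subject, fraction): `subject_id`,
#'   `group`, `age`, `cell_type`, `method_used`, `pct_loy`, `pct_loy_other`,
#'   `fraction_status` (`"LOY"`/`"ROY"`).
#' @export
score_loy_fractions <- function(subjects, config = loy_config()) {
  scored <- subjects %>%
    mutate(pct = if_else(
      .data$method == "mLRRY",
      pct_loy_from_mlrry(.data$raw_value, config),
      pct_loy_from_ratio(.data$raw_value)
    ))
  preferred <- config$prefer
  scored %>%
    group_by(.data$subject_id, .data$group, .data$age, .data$cell_type) %>%
    summarise(
      method_used = if (any(.data$method == preferred)) {
        preferred
      } else {
        .data$method[1]
      },
      pct_loy = .data$pct[.data$method == .data$method_used[1]][1],
      pct_loy_other = if (n() > 1) {
        .data$pct[.data$method != .data$method_used[1]][1]
      } else {
        NA_real_
      },
      .groups = "drop"
    ) %>%
    mutate(fraction_status = classify_fraction(.data$pct_loy, config)) %>%
    arrange(.data$subject_id, match(.data$cell_type, CELL_TYPES))
}

#' Classify a fraction as LOY or ROY
#'
#' LOY if and only if the percentage of Y-lacking cells is at or above the
#' threshold (inclusive; the default 15 classifies 15.0 as LOY).
#'
#' @param pct_loy Percentages in `[0, 100]`.
#' @param config A [loy_config()].
#' @return Character vector of `"LOY"` / `"ROY"`.
#' @export
classify_fraction <- function(pct_loy, config = loy_config()) {
  if (any(pct_loy < 0 | pct_loy > 100, na.rm = TRUE)) {
    abort("pct_loy must lie in [0, 100]")
  }
  if_else(pct_loy >= config$threshold_pct, "LOY", "ROY")
}

#' Classify subjects as LOY or ROY
#'
#' A subject is LOY if any assayed fraction is LOY; otherwise ROY.
#'
#' @param fraction_scores Output of [score_loy_fractions()].
#' @param config A [loy_config()].
#' @return A tibble with one row per subject: `subject_id`, `group`, `age`,
#'   `loy_status`, `max_pct_loy`, and per-fraction `pct_loy_CD4` /
#'   `pct_loy_NK` / `pct_loy_MYEL` columns (NA when not assayed).
#' @export
classify_subjects <- function(fraction_scores, config = loy_config()) {
  if (nrow(fraction_scores) == 0) abort("no resolvable fractions")
  wide <- fraction_scores %>%
    select(
      "subject_id", "group", "age", "cell_type", "pct_loy"
    ) %>%
    pivot_wider(
      names_from = "cell_type", values_from = "pct_loy",
      names_prefix = "pct_loy_"
    )
  for (ct in CELL_TYPES) {
    col <- paste0("pct_loy_", ct)
    if (!col %in% names(wide)) wide[[col]] <- NA_real_
  }
  fraction_scores %>%
    group_by(.data$subject_id) %>%
    summarise(
      max_pct_loy = max(.data$pct_loy),
      loy_status = if_else(
        any(.data$fraction_status == "LOY"), "LOY", "ROY"
      ),
      .groups = "drop"
    ) %>%
    left_join(wide, by = "subject_id") %>%
    select(
      "subject_id", "group", "age", "loy_status", "max_pct_loy",
      "pct_loy_CD4", "pct_loy_NK", "pct_loy_MYEL"
    )
}
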