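# Derived per-subject quantities (max VAF, cell fractions, total burden),
# landscape summaries, and the orchestrated co-occurrence statistics:
# stratified logistic odds ratios, VAF comparisons, and burden-LOY
# correlations, each BH-adjusted within its declared family.

CH_TYPES <- c("MD", "LD", "UD", "Any")

#' Statistics configuration
#'
#' Benjamini-Hochberg family sizes are fixed by the analysis design, not
#' inferred from how many tests happened to be estimable: 8 for the
#' stratified carrier association family (4 CH types x 2 disease groups),
#' 5 for the VAF-distribution family, 3 for the burden-correlation family
#' (one per cell type). The Fisher tests accompany the logistic family and
#' share its size by default.
#'
#' @param logistic_family,vaf_family,burden_family,fisher_family BH family
#'   sizes.
#' @param firth Use Firth-penalized logistic fits.
#' @param conf_level Confidence level for odds-ratio intervals.
#' @return A `stats_config` list.
#' @export
stats_config <- function(logistic_family = 8, vaf_family = 5,
                         burden_family = 3, fisher_family = 8,
                         firth = FALSE, conf_level = 0.95) {
  structure(as.list(environment()), class = "stats_config")
}

#' Highest VAF per subject and CH type
#'
#' When a subject carries several variants of the same CH type, only the
#' one with the highest VAF enters the VAF-distribution comparisons. Ties
#' are broken by (chrom, pos, ref, alt) lexicographic order for
#' determinism.
#'
#' @param calls CH-call tibble.
#' @return Tibble `subject_id`, `category`, `max_vaf` (plus the variant key
#'   of the selected variant).
#' @export
max_vaf_per_subject_type <- function(calls) {
  calls %>%
    arrange(
      .data$subject_id, .data$category, dplyr::desc(.data$max_vaf),
      .data$chrom, .data$pos, .data$ref, .data$alt
    ) %>%
    group_by(.data$subject_id, .data$category) %>%
    dplyr::slice(1) %>%
    ungroup() %>%
    select("subject_id", "category", "chrom", "pos", "ref", "alt",
           max_vaf = "max_vaf")
}

#' Percentage of cells carrying a heterozygous variant
#'
#' For a heterozygous autosomal variant the carrying cell fraction is twice
#' the VAF; values above 100% (VAF > 0.5, e.g. at hemizygous or
#' LOH-affected sites) are capped at 100.
#'
#' @param vaf VAFs in `[0, 1]`.
#' @return Percentages in `[0, 100]`.
#' @export
cells_fraction <- function(vaf) {
  if (any(vaf < 0 | vaf > 1, na.rm = TRUE)) abort("vaf must lie in [0, 1]")
  pmin(100, 200 * vaf)
}

#' Total CH burden per sample
#'
#' The total CH burden of a (subject, cell fraction) sample is the sum of
#' the VAFs of all its post-zygotic variants; samples with no variants have
#' burden 0. Per-category components are returned alongside.
#'
#' @param fractions Long per-fraction VAF tibble (the `fractions` element
#'   of a `ch_callset`).
#' @param samples Tibble `subject_id`, `cell_type` enumerating all assayed
#'   samples ([assayed_fractions()]); samples without variants get burden 0.
#' @return Tibble `subject_id`, `cell_type`, `total_burden`, `md_burden`,
#'   `ld_burden`, `ud_burden`.
#' @export
total_burden <- function(fractions, samples) {
  burdens <- fractions %>%
    group_by(.data$subject_id, .data$cell_type) %>%
    summarise(
      total_burden = sum(.data$vaf),
      md_burden = sum(.data$vaf[.data$category == "MD"]),
      ld_burden = sum(.data$vaf[.data$category == "LD"]),
      ud_burden = sum(.data$vaf[.data$category == "UD"]),
      .groups = "drop"
    )
  samples %>%
    left_join(burdens, by = c("subject_id", "cell_type")) %>%
    mutate(across(
      c("total_burden", "md_burden", "ld_burden", "ud_burden"),
      ~ dplyr::coalesce(.x, 0)
    ))
}

#' Per-subject carrier status by CH type
#'
#' @param calls CH-call tibble.
#' @param subjects_classified Output of [classify_subjects()].
#' @return Tibble with one row per subject: `subject_id`, `group`, `age`,
#'   `loy_status`, logical `MD`, `LD`, `UD`, `Any`.
#' @export
carrier_matrix <- function(calls, subjects_classified) {
  pres <- calls %>%
    distinct(.data$subject_id, .data$category) %>%
    mutate(present = TRUE) %>%
    pivot_wider(names_from = "category", values_from = "present")
  out <- subjects_classified %>%
    select("subject_id", "group", "age", "loy_status") %>%
    left_join(pres, by = "subject_id")
  for (ct in c("MD", "LD", "UD")) {
    if (!ct %in% names(out)) out[[ct]] <- NA
    out[[ct]] <- !is.na(out[[ct]]) & out[[ct]]
  }
  out %>% mutate(Any = .data$MD | .data$LD | .data$UD)
}

#' Cohort landscape and stratified counts
#'
#' Summarises the CH call set against the classified subjects: the
#' per-subject presence matrix of MD/LD/UD/Any (the landscape), carrier
#' counts and proportions per (disease group x LOY status x CH type),
#' the recurrently affected gene table, and the lineage sharing-pattern
#' table (subjects per pattern, split by LOY status).
#'
#' @param calls CH-call tibble.
#' @param subjects_classified Output of [classify_subjects()].
#' @return A `ch_cohort_summary` list with elements `landscape`,
#'   `carrier_counts`, `recurrent_genes`, `sharing`.
#' @export
cohort_summary <- function(calls, subjects_classified) {
  landscape <- carrier_matrix(calls, subjects_classified)
  carrier_counts <- landscape %>%
    pivot_longer(
      dplyr::all_of(CH_TYPES),
      names_to = "ch_type", values_to = "carrier"
    ) %>%
    group_by(.data$group, .data$loy_status, .data$ch_type) %>%
    summarise(
      n = n(), carriers = sum(.data$carrier),
      proportion = mean(.data$carrier),
      .groups = "drop"
    ) %>%
    mutate(ch_type = factor(.data$ch_type, levels = CH_TYPES)) %>%
    arrange(.data$ch_type, .data$group, dplyr::desc(.data$loy_status)) %>%
    mutate(ch_type = as.character(.data$ch_type))
  recurrent_genes <- calls %>%
    left_join(
      subjects_classified %>% select("subject_id", "loy_status"),
      by = "subject_id"
    ) %>%
    group_by(.data$category, .data$gene) %>%
    summarise(
      n_subjects = n_distinct(.data$subject_id),
      loy = n_distinct(.data$subject_id[.data$loy_status == "LOY"]),
      roy = n_distinct(.data$subject_id[.data$loy_status == "ROY"]),
      .groups = "drop"
    ) %>%
    filter(.data$n_subjects >= 2) %>%
    arrange(.data$category, dplyr::desc(.data$n_subjects))
  sharing <- calls %>%
    distinct(.data$subject_id, .data$pattern) %>%
    left_join(
      subjects_classified %>% select("subject_id", "loy_status"),
      by = "subject_id"
    ) %>%
    group_by(.data$pattern) %>%
    summarise(
      n_subjects = n_distinct(.data$subject_id),
      loy = n_distinct(.data$subject_id[.data$loy_status == "LOY"]),
      roy = n_distinct(.data$subject_id[.data$loy_status == "ROY"]),
      .groups = "drop"
    )
  structure(
    list(
      landscape = landscape, carrier_counts = carrier_counts,
      recurrent_genes = recurrent_genes, sharing = sharing
    ),
    class = "ch_cohort_summary"
  )
}

#' @export
print.ch_cohort_summary <- function(x, ...) {
  cat(sprintf("<ch_cohort_summary> %d subjects\n", nrow(x$landscape)))
  print(x$carrier_counts)
  invisible(x)
}

#' Run the full co-occurrence analysis
#'
#' Computes three BH-adjusted test families over a CH call set and the
#' classified subjects:
#'
#' * carrier association: for each CH type (MD, LD, UD, Any) within each
#'   disease group (AD, CTRL), the LOY odds ratio from logistic regression
#'   adjusted for age and age squared, with a companion Fisher's exact
#'   test on the 2x2 carrier table; BH family of 8;
#' * VAF distributions: Mann-Whitney comparisons of the per-subject
#'   highest VAF between LOY and ROY subjects, for MD, LD and UD in the
#'   combined cohort plus UD within AD and within CTRL; BH family of 5;
#' * burden correlation: per cell fraction, the Spearman correlation of
#'   total CH burden with %LOY; BH family of 3.
#'
#' Strata without both carriers and non-carriers (or with an empty sample)
#' are reported as not estimable with `NA` statistics; their slot in the
#' BH family is retained.
#'
#' @param callset A `ch_callset` from [run_cascade()].
#' @param subjects_classified Output of [classify_subjects()].
#' @param fraction_scores Output of [score_loy_fractions()] (per-fraction
#'   %LOY, needed for the burden correlation).
#' @param config A [stats_config()].
#' @return A `ch_cohort_result` list with tibbles `association`,
#'   `vaf_tests`, `burden_correlation`, the [cohort_summary()] and the
#'   configuration.
#' @export
run_full_stats <- function(callset, subjects_classified, fraction_scores,
                           config = stats_config()) {
  calls <- callset$calls
  carriers <- carrier_matrix(calls, subjects_classified)
  summary <- cohort_summary(calls, subjects_classified)

  # --- carrier association family (logistic + Fisher) --------------------
  assoc_grid <- tidyr::expand_grid(
    group = c("AD", "CTRL"), ch_type = CH_TYPES
  )
  association <- purrr::pmap(assoc_grid, function(group, ch_type) {
    dat <- carriers %>%
      filter(.data$group == .env$group) %>%
      transmute(
        carrier = .data[[ch_type]],
        loy = .data$loy_status == "LOY",
        age = .data$age
      )
    a <- sum(dat$carrier & dat$loy)
    b <- sum(!dat$carrier & dat$loy)
    cc <- sum(dat$carrier & !dat$loy)
    d <- sum(!dat$carrier & !dat$loy)
    fisher_p <- if (nrow(dat) == 0) NA_real_ else fisher_exact_2x2(a, b, cc, d)
    estimable <- any(dat$carrier) && any(!dat$carrier) &&
      any(dat$loy) && any(!dat$loy)
    if (estimable) {
      fit <- logistic_or(dat, conf_level = config$conf_level,
                         firth = config$firth)
      tibble(
        group = group, ch_type = ch_type,
        n_loy = a + b, n_roy = cc + d,
        carriers_loy = a, carriers_roy = cc,
        or = fit$or, ci_lo = fit$ci_lo, ci_hi = fit$ci_hi,
        p_logistic = fit$p, ci_unbounded = fit$ci_unbounded,
        p_fisher = fisher_p, estimable = TRUE
      )
    } else {
      tibble(
        group = group, ch_type = ch_type,
        n_loy = a + b, n_roy = cc + d,
        carriers_loy = a, carriers_roy = cc,
        or = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_,
        p_logistic = NA_real_, ci_unbounded = NA,
        p_fisher = fisher_p, estimable = FALSE
      )
    }
  }) %>% list_rbind()
  association <- association %>%
    mutate(
      p_logistic_adj = bh_na(.data$p_logistic, config$logistic_family),
      p_fisher_adj = bh_na(.data$p_fisher, config$fisher_family)
    )

  # --- VAF-distribution family -------------------------------------------
  maxv <- max_vaf_per_subject_type(calls) %>%
    left_join(
      subjects_classified %>% select("subject_id", "group", "loy_status"),
      by = "subject_id"
    )
  vaf_specs <- tibble(
    ch_type = c("MD", "LD", "UD", "UD", "UD"),
    stratum = c("combined", "combined", "combined", "AD", "CTRL")
  )
  vaf_tests <- purrr::pmap(vaf_specs, function(ch_type, stratum) {
    dat <- maxv %>% filter(.data$category == .env$ch_type)
    if (stratum != "combined") dat <- dat %>% filter(.data$group == .env$stratum)
    x <- dat$max_vaf[dat$loy_status == "LOY"]
    y <- dat$max_vaf[dat$loy_status == "ROY"]
    if (length(x) == 0 || length(y) == 0) {
      return(tibble(
        ch_type = ch_type, stratum = stratum,
        n_loy = length(x), n_roy = length(y),
        median_loy = if (length(x)) median(x) else NA_real_,
        median_roy = if (length(y)) median(y) else NA_real_,
        u = NA_real_, p = NA_real_, method = NA_character_,
        estimable = FALSE
      ))
    }
    mw <- mann_whitney_u(x, y)
    tibble(
      ch_type = ch_type, stratum = stratum,
      n_loy = length(x), n_roy = length(y),
      median_loy = median(x), median_roy = median(y),
      u = mw$statistic, p = mw$p_value, method = mw$method,
      estimable = TRUE
    )
  }) %>% list_rbind()
  vaf_tests <- vaf_tests %>%
    mutate(p_adj = bh_na(.data$p, config$vaf_family))

  # --- burden correlation family -----------------------------------------
  samples <- fraction_scores %>% select("subject_id", "cell_type", "pct_loy")
  burdens <- total_burden(
    callset$fractions, samples %>% select("subject_id", "cell_type")
  ) %>%
    left_join(samples, by = c("subject_id", "cell_type"))
  burden_correlation <- purrr::map(CELL_TYPES, function(ct) {
    dat <- burdens %>% filter(.data$cell_type == ct)
    if (nrow(dat) < 3) {
      return(tibble(
        cell_type = ct, n = nrow(dat), rho = NA_real_, p = NA_real_,
        estimable = FALSE
      ))
    }
    sp <- spearman_rho(dat$total_burden, dat$pct_loy)
    tibble(
      cell_type = ct, n = sp$n, rho = sp$rho, p = sp$p_value,
      estimable = !is.na(sp$rho)
    )
  }) %>% list_rbind()
  burden_correlation <- burden_correlation %>%
    mutate(p_adj = bh_na(.data$p, config$burden_family))

  structure(
    list(
      association = association,
      vaf_tests = vaf_tests,
      burden_correlation = burden_correlation,
      summary = summary,
      carriers = carriers,
      burdens = burdens,
      config = config
    ),
    class = "ch_cohort_result"
  )
}

# BH over the estimable members of a family whose declared size may exceed
# the number of estimable tests.
bh_na <- function(p, m) {
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  if (any(ok)) out[ok] <- bh_adjust(p[ok], m = max(m, sum(ok)))
  out
}

#' @export
print.ch_cohort_result <- function(x, ...) {
  cat("<ch_cohort_result>\n\nCarrier association (logistic, age-adjusted):\n")
  print(
    x$association %>%
      select("group", "ch_type", "or", "ci_lo", "ci_hi", "p_logistic",
             "p_logistic_adj")
  )
  cat("\nVAF distributions (Mann-Whitney):\n")
  print(x$vaf_tests %>% select("ch_type", "stratum", "p", "p_adj"))
  cat("\nBurden-LOY correlation (Spearman):\n")
  print(x$burden_correlation)
  invisible(x)
}

#' @rdname run_full_stats
#' @param x A `ch_cohort_result`.
#' @param ... Unused.
#' @method tidy ch_cohort_result
#' @export
tidy.ch_cohort_result <- function(x, ...) {
  bind_rows(
    x$association %>%
      transmute(
        family = "association",
        term = paste(.data$group, .data$ch_type, sep = "-"),
        estimate = .data$or, conf.low = .data$ci_lo, conf.high = .data$ci_hi,
        p.value = .data$p_logistic, p.adjusted = .data$p_logistic_adj
      ),
    x$vaf_tests %>%
      transmute(
        family = "vaf",
        term = paste(.data$ch_type, .data$stratum, sep = "-"),
        estimate = .data$median_loy - .data$median_roy,
        conf.low = NA_real_, conf.high = NA_real_,
        p.value = .data$p, p.adjusted = .data$p_adj
      ),
    x$burden_correlation %>%
      transmute(
        family = "burden",
        term = .data$cell_type,
        estimate = .data$rho,
        conf.low = NA_real_, conf.high = NA_real_,
        p.value = .data$p, p.adjusted = .data$p_adj
      )
  )
}

#' @rdname run_full_stats
#' @method glance ch_cohort_result
#' @export
glance.ch_cohort_result <- function(x, ...) {
  cc <- x$summary$carrier_counts
  prop <- function(type) {
    sub <- cc %>% filter(.data$ch_type == type)
    sum(sub$carriers) / sum(sub$n)
  }
  tibble(
    n_subjects = nrow(x$summary$landscape),
    n_carriers = sum(x$carriers$Any),
    md_carrier_prop = prop("MD"),
    ld_carrier_prop = prop("LD"),
    ud_carrier_prop = prop("UD"),
    any_carrier_prop = prop("Any"),
    n_significant = sum(
      c(x$association$p_logistic_adj, x$vaf_tests$p_adj,
        x$burden_correlation$p_adj) < 0.05,
      na.rm = TRUE
    )
  )
}
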