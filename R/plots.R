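# ggplot2 views of the analysis results: the per-subject CH landscape, the
# odds-ratio forest of the carrier association family, and the ranked
# burden-LOY scatter.

#' Landscape plot of CH carriage across the cohort
#'
#' One column per subject, stratified by disease group and LOY status; one
#' row per CH category, tiles marking carriage.
#'
#' @param summary A `ch_cohort_summary` (or a `ch_cohort_result`).
#' @return A ggplot object.
#' @export
plot_landscape <- function(summary) {
  if (inherits(summary, "ch_cohort_result")) summary <- summary$summary
  long <- summary$landscape %>%
    pivot_longer(
      dplyr::all_of(c("MD", "LD", "UD")),
      names_to = "ch_type", values_to = "carrier"
    ) %>%
    mutate(
      ch_type = factor(.data$ch_type, levels = c("MD", "LD", "UD")),
      stratum = paste(.data$group, .data$loy_status, sep = "-")
    )
  ggplot2::ggplot(
    long,
    ggplot2::aes(
      x = .data$subject_id, y = .data$ch_type,
      fill = if_else(.data$carrier, as.character(.data$ch_type), NA_character_)
    )
  ) +
    ggplot2::geom_tile(color = "grey85") +
    ggplot2::facet_grid(. ~ stratum, scales = "free_x", space = "free_x") +
    ggplot2::scale_fill_manual(
      values = c(MD = "#2c7fb8", LD = "#31a354", UD = "#de2d26"),
      na.value = "white", guide = "none"
    ) +
    ggplot2::labs(x = NULL, y = NULL, title = "Clonal hematopoiesis landscape") +
    ggplot2::theme_minimal() +
    ggplot2::theme(
      axis.text.x = ggplot2::element_blank(),
      panel.grid = ggplot2::element_blank()
    )
}

#' Odds-ratio forest of the carrier association family
#'
#' @param object A `ch_cohort_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ch_cohort_result
#' @export
autoplot.ch_cohort_result <- function(object, ...) {
  dat <- object$association %>%
    filter(.data$estimable) %>%
    mutate(label = paste(.data$group, .data$ch_type, sep = " "))
  ggplot2::ggplot(
    dat,
    ggplot2::aes(x = .data$or, y = .data$label)
  ) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$ci_lo, xmax = .data$ci_hi), height = 0.2
    ) +
    ggplot2::geom_point(
      ggplot2::aes(shape = .data$p_logistic_adj < 0.05), size = 2.5
    ) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_shape_manual(
      values = c(`TRUE` = 16, `FALSE` = 1), name = "adj. P < 0.05"
    ) +
    ggplot2::labs(
      x = "LOY odds ratio (age-adjusted, log scale)", y = NULL,
      title = "CH carriage vs LOY status"
    ) +
    ggplot2::theme_minimal()
}

#' Ranked burden-LOY scatter per cell fraction
#'
#' Total CH burden and %LOY are converted to ranks within each cell
#' fraction; a least-squares line on the ranks visualises the Spearman
#' correlation.
#'
#' @param result A `ch_cohort_result`.
#' @return A ggplot object.
#' @export
plot_burden_ranks <- function(result) {
  dat <- result$burdens %>%
    group_by(.data$cell_type) %>%
    mutate(
      burden_rank = rank(.data$total_burden),
      loy_rank = rank(.data$pct_loy)
    ) %>%
    ungroup()
  ggplot2::ggplot(
    dat, ggplot2::aes(x = .data$burden_rank, y = .data$loy_rank)
  ) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_smooth(
      method = "lm", formula = y ~ x, se = FALSE,
      linetype = 2, colour = "black"
    ) +
    ggplot2::facet_wrap(~cell_type, scales = "free") +
    ggplot2::labs(
      x = "total CH burden (rank)", y = "%LOY (rank)",
      title = "Total CH burden vs LOY level"
    ) +
    ggplot2::theme_minimal()
}
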