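# Staged variant filters: boundary semantics, singleton rule, cascade
# orchestration and accounting.

test_that("caller prefilter enforces MQ >= 30 and >= 5 high-quality alt reads", {
  rows <- dplyr::bind_rows(
    variant_row(pos = 1L, min_read_mq = 29),
    variant_row(pos = 2L, n_hq_alt = 4L),
    variant_row(pos = 3L, min_read_mq = 30, n_hq_alt = 5L),
    variant_row(pos = 4L, min_read_mq = NA)
  )
  out <- caller_prefilter(rows)
  expect_equal(out$keep, c(FALSE, FALSE, TRUE, FALSE))
  expect_equal(
    out$reason,
    c("low-mapping-quality", "few-hq-alt-reads", NA, "missing-evidence")
  )
})

test_that("flag filter admits PASS and alleleBias only", {
  rows <- dplyr::bind_rows(
    variant_row(pos = 1L, caller_flag = "PASS"),
    variant_row(pos = 2L, caller_flag = "alleleBias"),
    variant_row(pos = 3L, caller_flag = "strandBias"),
    variant_row(pos = 4L, caller_flag = "badReads")
  )
  expect_equal(flag_filter(rows)$keep, c(TRUE, TRUE, FALSE, FALSE))
})

test_that("population filter keeps popmax <= 0.01 or unlisted", {
  rows <- dplyr::bind_rows(
    variant_row(pos = 1L, popmax_maf = 0.01),
    variant_row(pos = 2L, popmax_maf = 0.011),
    variant_row(pos = 3L, popmax_maf = NA)
  )
  expect_equal(population_filter(rows)$keep, c(TRUE, FALSE, TRUE))
})

test_that("consequence filter keeps the three exonic coding classes", {
  rows <- dplyr::bind_rows(
    variant_row(pos = 1L, consequence = "nonsense"),
    variant_row(pos = 2L, consequence = "other"),
    variant_row(pos = 3L, consequence = "frameshift_indel", ref = "AT", alt = "A"),
    variant_row(pos = 4L, consequence = "missense")
  )
  expect_equal(consequence_filter(rows)$keep, c(TRUE, FALSE, TRUE, TRUE))
})

test_that("quality gates differ by category and check strand balance", {
  md_boundary <- variant_row(
    pos = 1L, depth = 300L, alt_fwd = 2L, alt_rev = 1L
  ) %>%
    dplyr::mutate(vaf = 0.01, category = "MD")
  expect_true(quality_filter(md_boundary)$keep)

  md_low_depth <- md_boundary %>% dplyr::mutate(depth = 19L)
  expect_false(quality_filter(md_low_depth)$keep)

  # the same evidence fails the stricter LD/UD gate (3 < 5 alt reads)
  ud_same <- md_boundary %>% dplyr::mutate(category = "UD")
  expect_false(quality_filter(ud_same)$keep)

  ud_unbalanced <- variant_row(
    pos = 2L, depth = 100L, alt_fwd = 5L, alt_rev = 0L
  ) %>%
    dplyr::mutate(vaf = 0.05, category = "UD")
  out <- quality_filter(ud_unbalanced)
  expect_false(out$keep)
  expect_equal(out$reason, "strand-imbalance")

  ud_low_vaf <- variant_row(
    pos = 3L, depth = 300L, alt_fwd = 3L, alt_rev = 3L
  ) %>%
    dplyr::mutate(vaf = 0.019, category = "UD")
  expect_false(quality_filter(ud_low_vaf)$keep)

  ud_ok <- ud_low_vaf %>% dplyr::mutate(vaf = 0.02)
  expect_true(quality_filter(ud_ok)$keep)
})

test_that("singleton rule counts subjects, with the oncogenic-MD exemption", {
  calls <- dplyr::bind_rows(
    # UD variant in two subjects: both dropped
    tibble::tibble(subject_id = c("S1", "S2"), chrom = "chr1", pos = 10L,
                   ref = "A", alt = "G", category = "UD", oncogenic = FALSE),
    # oncogenic MD variant in two subjects: both kept
    tibble::tibble(subject_id = c("S1", "S3"), chrom = "chr2", pos = 20L,
                   ref = "C", alt = "T", category = "MD", oncogenic = TRUE),
    # non-oncogenic MD variant in two subjects: dropped
    tibble::tibble(subject_id = c("S2", "S3"), chrom = "chr3", pos = 30L,
                   ref = "G", alt = "A", category = "MD", oncogenic = FALSE),
    # singleton in one subject, two fractions collapse to one row upstream
    tibble::tibble(subject_id = "S4", chrom = "chr4", pos = 40L,
                   ref = "T", alt = "C", category = "UD", oncogenic = FALSE)
  )
  out <- singleton_filter(calls)
  expect_equal(out$keep, c(FALSE, FALSE, TRUE, TRUE, FALSE, FALSE, TRUE))
  # disabling the exemption drops the recurrent oncogenic MD variant too
  out2 <- singleton_filter(calls, filter_config(oncogenic_md_exempt = FALSE))
  expect_equal(out2$keep[3:4], c(FALSE, FALSE))
})

test_that("pure per-variant filters are order-insensitive", {
  withr::with_seed(13, {
    rows <- purrr::map(1:40, function(i) {
      variant_row(
        pos = i * 7L,
        caller_flag = sample(c("PASS", "alleleBias", "strandBias"), 1),
        popmax_maf = if (runif(1) < 0.4) NA else runif(1, 0, 0.05),
        consequence = sample(
          c("missense", "nonsense", "frameshift_indel", "other"), 1
        )
      ) %>%
        dplyr::mutate(
          ref = ifelse(consequence == "frameshift_indel", "AT", ref)
        )
    }) %>% dplyr::bind_rows()
    kept_keys <- function(tbl) {
      tbl %>%
        flag_filter() %>% dplyr::filter(keep) %>% dplyr::select(-keep) %>%
        population_filter() %>% dplyr::filter(keep) %>% dplyr::select(-keep) %>%
        consequence_filter() %>% dplyr::filter(keep) %>%
        dplyr::pull(pos) %>% sort()
    }
    shuffled <- rows[sample(nrow(rows)), ]
    expect_equal(kept_keys(rows), kept_keys(shuffled))
    # permuting the filter order leaves the survivor set unchanged
    alt_order <- rows %>%
      consequence_filter() %>% dplyr::filter(keep) %>% dplyr::select(-keep) %>%
      population_filter() %>% dplyr::filter(keep) %>% dplyr::select(-keep) %>%
      flag_filter() %>% dplyr::filter(keep) %>%
      dplyr::pull(pos) %>% sort()
    expect_equal(kept_keys(rows), alt_order)
  })
})

test_that("tightening thresholds never enlarges the survivor set", {
  withr::with_seed(17, {
    rows <- purrr::map(1:60, function(i) {
      dp <- sample(15:60, 1)
      alt <- sample(1:12, 1)
      alt <- min(alt, dp)
      fwd <- sample(0:alt, 1)
      variant_row(
        pos = i * 3L, depth = dp, alt_fwd = fwd, alt_rev = alt - fwd,
        n_hq_alt = alt
      ) %>%
        dplyr::mutate(vaf = (alt_fwd + alt_rev) / depth,
                      category = sample(c("MD", "UD"), 1))
    }) %>% dplyr::bind_rows()
    base <- quality_filter(rows)$keep
    for (cfg in list(
      filter_config(md_alt_min = 4, ldud_alt_min = 6),
      filter_config(md_dp_min = 30, ldud_dp_min = 30),
      filter_config(md_vaf_min = 0.05, ldud_vaf_min = 0.08),
      filter_config(min_per_strand = 2)
    )) {
      tight <- quality_filter(rows, cfg)$keep
      expect_true(all(base | !tight))
    }
  })
})

cascade_fixture <- function() {
  subjects <- dplyr::bind_rows(
    subject_rows("S1", pct = c(CD4 = 1, NK = 20, MYEL = 40)),
    subject_rows("S2", group = "CTRL", pct = c(CD4 = 1, NK = 2, MYEL = 3))
  )
  clone <- dplyr::bind_rows(
    variant_row("S1", "NK", pos = 501L, gene = "UDGX", depth = 136L,
                alt_fwd = 14L, alt_rev = 13L, n_hq_alt = 27L),
    variant_row("S1", "MYEL", pos = 501L, gene = "UDGX", depth = 136L,
                alt_fwd = 13L, alt_rev = 14L, n_hq_alt = 27L)
  )
  germline <- purrr::map(c("CD4", "NK", "MYEL"), function(ct) {
    variant_row("S1", ct, pos = 900L, gene = "GERM1", depth = 100L,
                alt_fwd = 25L, alt_rev = 25L, n_hq_alt = 50L)
  }) %>% dplyr::bind_rows()
  evidence <- tibble::tibble(
    subject_id = "S1", chrom = "chr1", pos = 501L, ref = "A", alt = "G",
    cell_type = "CD4", depth = 140L, n_hq_alt = 0L, site_mq = 60, vaf = 0
  )
  list(
    subjects = subjects,
    variants = dplyr::bind_rows(clone, germline),
    evidence = evidence
  )
}

test_that("the cascade recovers a planted NK+myeloid clone exactly once", {
  fx <- cascade_fixture()
  cs <- run_cascade(fx$variants, fx$subjects, test_catalog(),
                    evidence = fx$evidence)
  expect_equal(nrow(cs$calls), 1)
  expect_equal(cs$calls$present_in, "NK+MYEL")
  expect_equal(cs$calls$pattern, "NK_MYEL")
  expect_equal(cs$calls$category, "UD")
  expect_equal(cs$calls$max_vaf, 27 / 136)
  expect_equal(cs$calls$zygosity, "post_zygotic")
  # the germline variant was designated germline, not quality-dropped
  germ_audit <- cs$audit %>% dplyr::filter(pos == 900L)
  expect_equal(germ_audit$stage, "germline")
})

test_that("a germline-only cohort yields zero CH calls with full accounting", {
  fx <- cascade_fixture()
  germ_only <- fx$variants %>% dplyr::filter(pos == 900L)
  cs <- run_cascade(germ_only, fx$subjects, test_catalog())
  expect_equal(nrow(cs$calls), 0)
  expect_equal(sum(cs$stage_counts$n), nrow(cs$audit))
  expect_equal(
    sum(cs$stage_counts$n[cs$stage_counts$stage != "survivor"]) +
      sum(cs$stage_counts$n[cs$stage_counts$stage == "survivor"]),
    dplyr::n_distinct(germ_only$pos)
  )
})

test_that("fractions without evidence rows exclude the variant, with a reason", {
  fx <- cascade_fixture()
  cs <- run_cascade(fx$variants, fx$subjects, test_catalog(), evidence = NULL)
  audit <- cs$audit %>% dplyr::filter(pos == 501L)
  expect_equal(audit$stage, "missing_evidence")
})

test_that("zygosity overrides reclassify through the documented mechanism", {
  fx <- cascade_fixture()
  # an early-clonal profile: present everywhere, CD4 VAF far below NK/MYEL
  early <- dplyr::bind_rows(
    variant_row("S1", "CD4", pos = 700L, gene = "TET2", depth = 100L,
                alt_fwd = 3L, alt_rev = 2L, n_hq_alt = 5L,
                consequence = "nonsense", oncogenic = TRUE),
    variant_row("S1", "NK", pos = 700L, gene = "TET2", depth = 100L,
                alt_fwd = 8L, alt_rev = 9L, n_hq_alt = 17L,
                consequence = "nonsense", oncogenic = TRUE),
    variant_row("S1", "MYEL", pos = 700L, gene = "TET2", depth = 100L,
                alt_fwd = 7L, alt_rev = 8L, n_hq_alt = 15L,
                consequence = "nonsense", oncogenic = TRUE)
  )
  variants <- dplyr::bind_rows(fx$variants, early)
  # default: flagged as a candidate but still dropped as germline
  cs <- run_cascade(variants, fx$subjects, test_catalog(),
                    evidence = fx$evidence)
  audit <- cs$audit %>% dplyr::filter(pos == 700L)
  expect_equal(audit$stage, "germline")
  expect_equal(audit$detail, "early-clonal-candidate")
  # auto-reclassification recovers it as post-zygotic
  cs2 <- run_cascade(variants, fx$subjects, test_catalog(),
                     config = filter_config(auto_reclass_early_clonal = TRUE),
                     evidence = fx$evidence)
  expect_true(700L %in% cs2$calls$pos)
  tet2 <- cs2$calls %>% dplyr::filter(pos == 700L)
  expect_equal(tet2$pattern, "all_three")
  expect_true(tet2$early_clonal)
  # an explicit override file achieves the same without the global switch
  ov <- tibble::tibble(
    chrom = "chr1", pos = 700L, ref = "A", alt = "G",
    forced_zygosity = "post_zygotic", justification = "early clonal origin"
  )
  cs3 <- run_cascade(variants, fx$subjects, test_catalog(),
                     evidence = fx$evidence, overrides = ov)
  expect_true(700L %in% cs3$calls$pos)
  expect_equal(attr(cs3$audit, "overrides")$justification,
               "early clonal origin")
})
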