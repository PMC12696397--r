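# Seeded synthetic cohort generator. Emulates the statistical structure the
# pipeline assumes: four strata with Table-1-style sizes and ages, three
# sorted fractions per subject (occasionally two), germline variants at
# VAF ~ 0.5 in every fraction, post-zygotic clones with lineage-sharing
# structure, per-fraction %LOY with myeloid > NK >> CD4, binomial read
# sampling at exome-like depth, and full truth labels.

#' Synthetic cohort configuration
#'
#' Defaults encode the study conditions: stratum sizes 32/34/23/29
#' (AD-LOY/AD-ROY/CTRL-LOY/CTRL-ROY), ages drawn from scaled logistic
#' distributions matched to the per-stratum median and IQR, on-target
#' depth ~ Normal(136, 28) clamped to [62, 200], and sharing-pattern rates
#' that reproduce the observed predominance of NK+myeloid and NK-only
#' clones. The LOY-to-UD-carrier odds multiplier defaults to 1 (no planted
#' association); use [plant_association()] to set a target odds ratio.
#'
#' @param seed Integer seed; fixed seed implies byte-identical output.
#' @param n_ad_loy,n_ad_roy,n_ctrl_loy,n_ctrl_roy Stratum sizes.
#' @param age_medians,age_iqrs Named numeric vectors (`AD_LOY`, `AD_ROY`,
#'   `CTRL_LOY`, `CTRL_ROY`) of age medians and interquartile ranges.
#' @param depth_median,depth_sd,depth_range On-target coverage model.
#' @param germline_lambda Mean number of germline variants per subject
#'   (Poisson).
#' @param popmax_decoy_frac Fraction of germline variants given a gnomAD
#'   popmax above 0.01 (population-filter decoys); the remainder carry no
#'   popmax annotation.
#' @param ud_carrier_base_rate Probability that a ROY subject carries at
#'   least one UD clone.
#' @param loy_ud_or Odds multiplier for UD-clone carriage in LOY subjects.
#' @param ud_clones_extra Poisson mean of additional UD clones per carrier.
#' @param md_clone_rate,ld_clone_rate Per-subject probabilities of an MD /
#'   LD clone.
#' @param pattern_probs Named probabilities over proper-subset sharing
#'   patterns for each clone.
#' @param all_three_early_rate Per-subject probability of an early-clonal
#'   variant present in all three lineages with a depressed CD4 VAF (the
#'   configuration that the presence rule alone would call germline).
#' @param clone_vaf_range Uniform range of clone VAFs.
#' @param loy_coupled_frac Fraction of clones in LOY subjects whose cell
#'   fraction tracks the fraction's %LOY (VAF = %LOY/200).
#' @param md_oncogenic_rate,other_oncogenic_rate Probability of the
#'   high-oncogenic-potential annotation for MD / non-MD clones.
#' @param missing_fraction_rate Probability a subject lacks one fraction
#'   (never dropping below two).
#' @param caller_miss_rate Probability the caller misses a well-supported
#'   (five or more alternate reads) truly present variant in a fraction,
#'   exercising the pileup rescue path; marginally supported sites are
#'   missed at a fixed 10%.
#' @param noise_sd_pct Gaussian noise (percentage points) on planted %LOY
#'   before conversion to raw assay values.
#' @param artifact_lambda,lowmq_lambda Poisson means of per-subject decoy
#'   calls carrying a rejected caller flag / poor read mapping quality.
#' @param plant_recurrent_md Plant one oncogenic myeloid hotspot variant in
#'   two subjects (exempt from the singleton rule).
#' @param plant_recurrent_ud Plant one UD variant in two subjects (dropped
#'   by the singleton rule).
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_ad_loy = 32, n_ad_roy = 34,
                       n_ctrl_loy = 23, n_ctrl_roy = 29,
                       age_medians = c(AD_LOY = 83.5, AD_ROY = 81.0,
                                       CTRL_LOY = 72.0, CTRL_ROY = 72.0),
                       age_iqrs = c(AD_LOY = 9.5, AD_ROY = 7.0,
                                    CTRL_LOY = 8.0, CTRL_ROY = 5.0),
                       depth_median = 136, depth_sd = 28,
                       depth_range = c(62, 200),
                       germline_lambda = 20,
                       popmax_decoy_frac = 0.3,
                       ud_carrier_base_rate = 0.35,
                       loy_ud_or = 1,
                       ud_clones_extra = 1.5,
                       md_clone_rate = 0.10,
                       ld_clone_rate = 0.09,
                       pattern_probs = c(NK_MYEL = 0.37, NK_only = 0.30,
                                         MYEL_only = 0.15, CD4_only = 0.08,
                                         CD4_NK = 0.05, CD4_MYEL = 0.05),
                       all_three_early_rate = 0.017,
                       clone_vaf_range = c(0.01, 0.4),
                       loy_coupled_frac = 0.5,
                       md_oncogenic_rate = 0.9,
                       other_oncogenic_rate = 0.02,
                       missing_fraction_rate = 0.093,
                       caller_miss_rate = 0.01,
                       noise_sd_pct = 0.3,
                       artifact_lambda = 1,
                       lowmq_lambda = 0.5,
                       plant_recurrent_md = TRUE,
                       plant_recurrent_ud = TRUE) {
  cfg <- as.list(environment())
  rates <- c(
    popmax_decoy_frac, ud_carrier_base_rate, md_clone_rate, ld_clone_rate,
    all_three_early_rate, loy_coupled_frac, md_oncogenic_rate,
    other_oncogenic_rate, missing_fraction_rate, caller_miss_rate
  )
  if (any(rates < 0 | rates > 1)) abort("rates must lie in [0, 1]")
  if (loy_ud_or <= 0) abort("loy_ud_or must be positive")
  if (depth_range[1] > depth_range[2]) abort("depth_range must be ordered")
  if (abs(sum(pattern_probs) - 1) > 1e-8) {
    abort("pattern_probs must sum to 1")
  }
  structure(cfg, class = "sim_config")
}

#' Set the LOY-to-UD-carrier odds multiplier for a target odds ratio
#'
#' Given the configured base (ROY) carrier rate p0, sets the multiplier so
#' that the LOY-group carrier probability equals
#' `odds^-1(target_or * p0 / (1 - p0))`, making the population odds ratio
#' equal to `target_or`.
#'
#' @param cfg A [sim_config()].
#' @param target_or Target odds ratio (> 0).
#' @return The modified config.
#' @export
plant_association <- function(cfg, target_or) {
  if (target_or <= 0) abort("target_or must be positive")
  p0 <- cfg$ud_carrier_base_rate
  if (p0 <= 0 || p0 >= 1) abort("base carrier rate must lie in (0, 1)")
  cfg$loy_ud_or <- target_or
  cfg
}

# LOY-group carrier probability implied by the base rate and multiplier.
loy_carrier_prob <- function(p0, or) {
  odds <- or * p0 / (1 - p0)
  odds / (1 + odds)
}

# Scaled/shifted logistic draw matched to a median and IQR
# (IQR of a logistic = 2 log(3) * scale).
rage <- function(n, med, iqr) {
  rlogis(n, location = med, scale = iqr / (2 * log(3)))
}

rdepth <- function(n, cfg) {
  as.integer(pmin(
    cfg$depth_range[2],
    pmax(cfg$depth_range[1], round(rnorm(n, cfg$depth_median, cfg$depth_sd)))
  ))
}

clamp <- function(x, lo, hi) pmin(hi, pmax(lo, x))

# Built-in synthetic driver catalogs: recognisable recurrent symbols padded
# with synthetic placeholders to the catalog sizes used in the field.
synthetic_catalog <- function() {
  myeloid <- unique(c(
    "TET2", "DNMT3A", "SRSF2", "ASXL1", "TP53", "JAK2", "CBL", "IDH1",
    "IDH2", "SF3B1", "U2AF1", "PPM1D", "GNB1", "BCOR", "STAG2",
    sprintf("MDG%03d", 1:82)
  ))[1:97]
  lymphoid <- unique(c(
    "KMT2D", "ATM", "BRCA1", "NFE2", "MED12", "MGA", "NOTCH1", "CARD11",
    "B2M", "CREBBP", "EP300", "TNFAIP3",
    sprintf("LDG%03d", 1:323)
  ))[1:335]
  gene_catalog(myeloid = myeloid, lymphoid = lymphoid)
}

#' Generate a synthetic cohort with truth labels
#'
#' Returns subject/variant/evidence tables in exactly the dialects the
#' readers consume, plus per-variant truth labels recording zygosity,
#' sharing pattern, category, clone cell fraction and per-fraction true
#' VAFs. Identical configurations (including the seed) produce identical
#' outputs.
#'
#' @param cfg A [sim_config()].
#' @return A `ch_sim_cohort` list: `subjects` (long measurement tibble),
#'   `variants`, `evidence`, `truth`, `catalog`, `config`.
#' @export
generate_cohort <- function(cfg = sim_config()) {
  withr::with_seed(cfg$seed, generate_cohort_impl(cfg))
}

generate_cohort_impl <- function(cfg) {
  catalog <- synthetic_catalog()
  strata <- tibble(
    stratum = c("AD_LOY", "AD_ROY", "CTRL_LOY", "CTRL_ROY"),
    group = c("AD", "AD", "CTRL", "CTRL"),
    loy_true = c(TRUE, FALSE, TRUE, FALSE),
    n = c(cfg$n_ad_loy, cfg$n_ad_roy, cfg$n_ctrl_loy, cfg$n_ctrl_roy)
  )
  subj <- strata %>%
    purrr::pmap(function(stratum, group, loy_true, n) {
      tibble(
        stratum = stratum, group = group, loy_true = loy_true,
        age = round(rage(n, cfg$age_medians[[stratum]],
                         cfg$age_iqrs[[stratum]]), 1)
      )
    }) %>%
    list_rbind() %>%
    mutate(
      age = clamp(.data$age, 60, 105),
      subject_id = sprintf("S%03d", row_number())
    )
  n_subj <- nrow(subj)

  # Assayed fractions: drop one at random for a configurable minority.
  subj$fractions <- purrr::map(seq_len(n_subj), function(i) {
    if (runif(1) < cfg$missing_fraction_rate) {
      sort(sample(3, 2))
    } else {
      1:3
    }
  })

  # Planted per-fraction %LOY. The subject's highest-LOY assayed fraction
  # drives classification; LOY subjects get a myeloid-dominant profile kept
  # clear of the 15% threshold, ROY subjects stay well below it.
  loy_tbl <- purrr::map(seq_len(n_subj), function(i) {
    fr <- CELL_TYPES[subj$fractions[[i]]]
    if (subj$loy_true[i]) {
      pct <- c(
        CD4 = clamp(rlogis(1, 1.1, 1.5), 0, 10),
        NK = clamp(rlogis(1, 16.5, 6), 0, 60),
        MYEL = clamp(rlogis(1, 44, 18), 16.5, 97)
      )
      # guarantee the criterion fraction is assayed
      if (!"MYEL" %in% fr) pct[["NK"]] <- clamp(rlogis(1, 30, 8), 16.5, 60)
    } else {
      pct <- c(
        CD4 = clamp(abs(rnorm(1, 0.8, 1.5)), 0, 12),
        NK = clamp(abs(rnorm(1, 1.0, 2.0)), 0, 12),
        MYEL = clamp(abs(rnorm(1, 2.5, 3.0)), 0, 12)
      )
    }
    tibble(
      subject_id = subj$subject_id[i], cell_type = fr,
      pct_true = unname(pct[fr])
    )
  }) %>% list_rbind()

  # Measurement rows: mLRR-Y only, ddPCR only, or both.
  subjects <- loy_tbl %>%
    left_join(
      subj %>% select("subject_id", "group", "age"),
      by = "subject_id"
    ) %>%
    mutate(assay = sample(
      c("mLRRY", "ddPCR", "both"), n(),
      replace = TRUE, prob = c(0.52, 0.41, 0.07)
    )) %>%
    purrr::pmap(function(subject_id, cell_type, pct_true, group, age, assay) {
      methods <- if (assay == "both") c("mLRRY", "ddPCR") else assay
      purrr::map(methods, function(m) {
        noisy <- clamp(pct_true + rnorm(1, 0, cfg$noise_sd_pct), 0, 99.9)
        raw <- if (m == "mLRRY") log2(1 - noisy / 100) else 1 - noisy / 100
        tibble(
          subject_id = subject_id, group = group, age = age,
          cell_type = cell_type, method = m, raw_value = raw,
          smoker = NA
        )
      }) %>% list_rbind()
    }) %>%
    list_rbind()

  # ---- planted variants --------------------------------------------------
  plan <- plan_variants(subj, loy_tbl, cfg, catalog)
  reads <- sample_reads(plan, subj, cfg)

  structure(
    list(
      subjects = subjects,
      variants = reads$variants,
      evidence = reads$evidence,
      truth = plan$truth,
      catalog = catalog,
      config = cfg
    ),
    class = "ch_sim_cohort"
  )
}

# Decide, per subject, which variants exist and their true per-fraction VAFs.
plan_variants <- function(subj, loy_tbl, cfg, catalog) {
  n_subj <- nrow(subj)
  ud_genes <- sprintf("UDG%04d", 1:5000)
  consequences <- c("frameshift_indel", "nonsense", "missense", "other")
  germ_csq_p <- c(0.05, 0.05, 0.55, 0.35)
  # clones are exonic coding variants by construction: the CH definition
  # admits only frameshift/nonsense/missense, with ~21% protein-truncating
  clone_csq_p <- c(0.105, 0.105, 0.79, 0)

  next_pos <- local({
    counter <- 0L
    function(n) {
      counter <<- counter + n
      seq_len(n) + (counter - n)
    }
  })
  mk_key <- function(n, kind) {
    idx <- next_pos(n)
    tibble(
      chrom = paste0("chr", (idx %% 22L) + 1L),
      pos = 1000L + idx * 37L,
      ref = "A",
      alt = "G"
    )
  }
  adjust_alleles <- function(tbl) {
    tbl %>%
      mutate(
        ref = if_else(.data$consequence == "frameshift_indel", "AT", .data$ref),
        alt = if_else(.data$consequence == "frameshift_indel", "A", .data$alt)
      )
  }

  one_subject <- function(i) {
    sid <- subj$subject_id[i]
    fr <- CELL_TYPES[subj$fractions[[i]]]
    loy <- subj$loy_true[i]
    pct <- loy_tbl %>% filter(.data$subject_id == sid)
    pct_of <- setNames(pct$pct_true, pct$cell_type)

    out <- list()
    # germline variants: present in every fraction at VAF ~ 0.5
    n_germ <- rpois(1, cfg$germline_lambda)
    if (n_germ > 0) {
      keys <- mk_key(n_germ, "germ")
      csq <- sample(consequences, n_germ, replace = TRUE, prob = germ_csq_p)
      decoy <- runif(n_germ) < cfg$popmax_decoy_frac
      out$germ <- keys %>%
        mutate(
          subject_id = sid,
          gene = sample(ud_genes, n_germ, replace = TRUE),
          consequence = csq,
          popmax_maf = if_else(decoy, runif(n_germ, 0.02, 0.5), NA_real_),
          zygosity = "germline",
          pattern = "all_three",
          category_true = "UD",
          oncogenic = FALSE,
          clone_fraction = NA_real_,
          vaf_CD4 = rbeta(n_germ, 200, 200),
          vaf_NK = rbeta(n_germ, 200, 200),
          vaf_MYEL = rbeta(n_germ, 200, 200),
          is_decoy = decoy
        ) %>%
        adjust_alleles()
    }

    # post-zygotic clones
    p_carrier <- if (loy) {
      loy_carrier_prob(cfg$ud_carrier_base_rate, cfg$loy_ud_or)
    } else {
      cfg$ud_carrier_base_rate
    }
    n_ud <- if (runif(1) < p_carrier) 1L + rpois(1, cfg$ud_clones_extra) else 0L
    n_md <- rbinom(1, 1, cfg$md_clone_rate)
    n_ld <- rbinom(1, 1, cfg$ld_clone_rate)
    specs <- tibble(
      category_true = c(
        rep("UD", n_ud), rep("MD", n_md), rep("LD", n_ld)
      )
    )
    if (nrow(specs) > 0) {
      n_cl <- nrow(specs)
      keys <- mk_key(n_cl, "clone")
      patt <- sample(
        names(cfg$pattern_probs), n_cl, replace = TRUE,
        prob = cfg$pattern_probs
      )
      coupled <- loy & runif(n_cl) < cfg$loy_coupled_frac
      base_vaf <- runif(n_cl, cfg$clone_vaf_range[1], cfg$clone_vaf_range[2])
      csq <- sample(consequences, n_cl, replace = TRUE, prob = clone_csq_p)
      gene <- purrr::map_chr(specs$category_true, function(cat) {
        switch(cat,
          MD = sample(catalog$myeloid, 1),
          LD = sample(setdiff(catalog$lymphoid, catalog$myeloid), 1),
          UD = sample(ud_genes, 1)
        )
      })
      onc_rate <- if_else(
        specs$category_true == "MD", cfg$md_oncogenic_rate,
        cfg$other_oncogenic_rate
      )
      vafs <- purrr::map(seq_len(n_cl), function(j) {
        members <- pattern_members(patt[j])
        v <- setNames(rep(0, 3), CELL_TYPES)
        for (ct in members) {
          has_pct <- ct %in% names(pct_of) && pct_of[[ct]] > 0
          v[ct] <- if (coupled[j] && has_pct) {
            max(0.005, pct_of[[ct]] / 200)
          } else {
            base_vaf[j]
          }
        }
        v
      })
      out$clones <- keys %>%
        mutate(
          subject_id = sid,
          gene = gene,
          consequence = csq,
          popmax_maf = NA_real_,
          zygosity = "post_zygotic",
          pattern = patt,
          category_true = specs$category_true,
          oncogenic = runif(n_cl) < onc_rate,
          clone_fraction = 2 * base_vaf,
          vaf_CD4 = map_dbl(vafs, "CD4"),
          vaf_NK = map_dbl(vafs, "NK"),
          vaf_MYEL = map_dbl(vafs, "MYEL"),
          is_decoy = FALSE
        ) %>%
        adjust_alleles()
    }

    # early-clonal variant: all three lineages, CD4 VAF depressed
    if (length(fr) == 3 && runif(1) < cfg$all_three_early_rate) {
      keys <- mk_key(1, "early")
      hi <- runif(1, 0.10, 0.17)
      out$early <- keys %>%
        mutate(
          subject_id = sid,
          gene = sample(catalog$myeloid, 1),
          consequence = "nonsense",
          popmax_maf = NA_real_,
          zygosity = "post_zygotic",
          pattern = "all_three_early",
          category_true = "MD",
          oncogenic = TRUE,
          clone_fraction = 2 * hi,
          vaf_CD4 = runif(1, 0.01, 0.05),
          vaf_NK = hi,
          vaf_MYEL = runif(1, 0.10, 0.17),
          is_decoy = FALSE
        )
    }
    list_rbind(out)
  }

  truth <- purrr::map(seq_len(n_subj), one_subject) %>% list_rbind()

  # recurrent variants shared between two subjects
  eligible <- subj$subject_id[purrr::map_int(subj$fractions, length) == 3]
  recurrent <- list()
  if (cfg$plant_recurrent_md && length(eligible) >= 2) {
    pair <- sample(eligible, 2)
    key <- mk_key(1, "rec")
    recurrent$md <- purrr::map(pair, function(sid) {
      key %>%
        mutate(
          subject_id = sid, gene = "SRSF2", consequence = "missense",
          popmax_maf = NA_real_, zygosity = "post_zygotic",
          pattern = "NK_MYEL", category_true = "MD", oncogenic = TRUE,
          clone_fraction = NA_real_, vaf_CD4 = 0,
          vaf_NK = runif(1, 0.1, 0.3), vaf_MYEL = runif(1, 0.1, 0.3),
          is_decoy = FALSE
        )
    }) %>% list_rbind()
  }
  if (cfg$plant_recurrent_ud && length(eligible) >= 4) {
    pair <- sample(setdiff(eligible, recurrent$md$subject_id %||% character()), 2)
    key <- mk_key(1, "rec")
    recurrent$ud <- purrr::map(pair, function(sid) {
      key %>%
        mutate(
          subject_id = sid, gene = "UDGREC1", consequence = "missense",
          popmax_maf = NA_real_, zygosity = "post_zygotic",
          pattern = "NK_only", category_true = "UD", oncogenic = FALSE,
          clone_fraction = NA_real_, vaf_CD4 = 0,
          vaf_NK = runif(1, 0.1, 0.3), vaf_MYEL = 0,
          is_decoy = TRUE
        )
    }) %>% list_rbind()
  }
  truth <- bind_rows(truth, list_rbind(recurrent))
  list(truth = truth)
}

pattern_members <- function(pattern) {
  switch(pattern,
    all_three = ,
    all_three_early = CELL_TYPES,
    NK_MYEL = c("NK", "MYEL"),
    CD4_NK = c("CD4", "NK"),
    CD4_MYEL = c("CD4", "MYEL"),
    CD4_only = "CD4",
    NK_only = "NK",
    MYEL_only = "MYEL"
  )
}

# Sample reads for every (variant, assayed fraction), emitting caller rows
# for called fractions and evidence rows otherwise; append caller-artifact
# and low-mapping-quality decoy calls.
sample_reads <- function(plan, subj, cfg) {
  frac_tbl <- subj %>%
    transmute(
      .data$subject_id,
      cell_type = purrr::map(.data$fractions, ~ CELL_TYPES[.x])
    ) %>%
    unnest("cell_type")
  long <- plan$truth %>%
    pivot_longer(
      c("vaf_CD4", "vaf_NK", "vaf_MYEL"),
      names_to = "cell_type", values_to = "true_vaf",
      names_prefix = "vaf_"
    ) %>%
    semi_join(frac_tbl, by = c("subject_id", "cell_type"))
  n <- nrow(long)
  depth_n <- rdepth(n, cfg)
  alt_n <- rbinom(n, depth_n, long$true_vaf)
  fwd_n <- rbinom(n, alt_n, 0.5)
  # caller misses concentrate at low allelic support
  miss_p <- ifelse(alt_n >= 5, cfg$caller_miss_rate, 0.10)
  missed <- runif(n) < miss_p
  called_n <- alt_n >= 3 & alt_n / depth_n >= 0.005 & !missed
  obs_vaf_n <- ifelse(depth_n > 0, alt_n / depth_n, 0)
  flag_n <- ifelse(
    obs_vaf_n < 0.35 & runif(n) < 0.3, "alleleBias", "PASS"
  )
  mcap_n <- ifelse(
    long$consequence == "missense" & runif(n) < 0.9,
    round(rbeta(n, 0.5, 3), 4), NA_real_
  )
  # keep annotations constant across a variant's rows
  mcap_const <- tibble(
    subject_id = long$subject_id, chrom = long$chrom, pos = long$pos,
    ref = long$ref, alt_allele = long$alt, mcap = mcap_n
  ) %>%
    group_by(.data$subject_id, .data$chrom, .data$pos, .data$ref,
             .data$alt_allele) %>%
    mutate(mcap = first(.data$mcap)) %>%
    ungroup() %>%
    pull("mcap")

  base <- long %>%
    mutate(
      depth = .env$depth_n, alt_fwd = .env$fwd_n,
      alt_rev = .env$alt_n - .env$fwd_n,
      n_hq_alt = .env$alt_n, min_read_mq = 60, site_mq = 60,
      caller_flag = .env$flag_n, called = .env$called_n,
      obs_vaf = .env$obs_vaf_n,
      mcap = .env$mcap_const
    )
  variants <- base %>%
    filter(.data$called) %>%
    transmute(
      .data$subject_id, .data$cell_type, .data$chrom, .data$pos,
      .data$ref, .data$alt, .data$gene, .data$consequence,
      .data$caller_flag, .data$depth, .data$alt_fwd, .data$alt_rev,
      .data$n_hq_alt, .data$min_read_mq, .data$popmax_maf, .data$mcap,
      .data$oncogenic
    )
  evidence <- base %>%
    filter(!.data$called) %>%
    transmute(
      .data$subject_id, .data$chrom, .data$pos, .data$ref, .data$alt,
      .data$cell_type, .data$depth, .data$n_hq_alt, .data$site_mq,
      vaf = .data$obs_vaf
    )

  # decoy calls exercising the flag filter and the read-quality prefilter
  decoys <- purrr::map(seq_len(nrow(subj)), function(i) {
    sid <- subj$subject_id[i]
    fr <- CELL_TYPES[subj$fractions[[i]]]
    n_art <- rpois(1, cfg$artifact_lambda)
    n_mq <- rpois(1, cfg$lowmq_lambda)
    n_tot <- n_art + n_mq
    if (n_tot == 0) return(NULL)
    dp <- rdepth(n_tot, cfg)
    av <- rbinom(n_tot, dp, 0.1)
    av <- pmax(av, 5L)
    fw <- rbinom(n_tot, av, 0.5)
    tibble(
      subject_id = sid,
      cell_type = sample(fr, n_tot, replace = TRUE),
      chrom = "chrX",
      pos = as.integer(sample.int(1e7, n_tot) + 2e7),
      ref = "C", alt = "T",
      gene = sprintf("UDG%04d", sample.int(5000, n_tot, replace = TRUE)),
      consequence = "missense",
      caller_flag = c(rep("strandBias", n_art), rep("PASS", n_mq)),
      depth = dp, alt_fwd = fw, alt_rev = av - fw,
      n_hq_alt = av,
      min_read_mq = c(rep(60, n_art), rep(20, n_mq)),
      popmax_maf = NA_real_, mcap = NA_real_, oncogenic = FALSE
    )
  }) %>% list_rbind()
  variants <- bind_rows(variants, decoys) %>%
    arrange(.data$subject_id, .data$chrom, .data$pos, .data$cell_type)
  list(variants = variants, evidence = evidence)
}

#' Simulate subject-level carrier data from the logistic model family
#'
#' Lightweight companion to [generate_cohort()] for parameter-recovery and
#' type-I-error studies of the carrier association model: LOY status is
#' Bernoulli, age is logistic-distributed, and carrier status follows
#' `logit P(carrier) = logit(base_rate) + log(or) * loy` with no age
#' effect, so the true LOY log odds ratio is exactly `log(or)`.
#'
#' @param n Number of subjects.
#' @param or True LOY odds ratio.
#' @param base_rate Carrier probability in the ROY group.
#' @param loy_rate LOY prevalence.
#' @param age_median,age_iqr Age distribution parameters.
#' @return Tibble `carrier`, `loy`, `age`.
#' @export
simulate_association <- function(n, or = 1, base_rate = 0.3, loy_rate = 0.5,
                                 age_median = 78, age_iqr = 9) {
  loy <- runif(n) < loy_rate
  p <- stats::plogis(qlogis(base_rate) + log(or) * loy)
  tibble(
    carrier = runif(n) < p,
    loy = loy,
    age = rage(n, age_median, age_iqr)
  )
}

#' Write a synthetic cohort to the on-disk TSV dialects
#'
#' @param cohort A `ch_sim_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly; files `subjects.tsv`, `variants.tsv`,
#'   `evidence.tsv`, `myeloid_genes.txt`, `lymphoid_genes.txt`,
#'   `truth.tsv`.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(cohort$subjects, file.path(dir, "subjects.tsv"),
                   progress = FALSE)
  write_variant_table(cohort$variants, file.path(dir, "variants.tsv"))
  readr::write_tsv(cohort$evidence, file.path(dir, "evidence.tsv"),
                   progress = FALSE)
  readr::write_tsv(cohort$truth, file.path(dir, "truth.tsv"), progress = FALSE)
  writeLines(cohort$catalog$myeloid, file.path(dir, "myeloid_genes.txt"))
  writeLines(cohort$catalog$lymphoid, file.path(dir, "lymphoid_genes.txt"))
  invisible(dir)
}

#' Evaluate pipeline recovery against planted truth
#'
#' Compares a cascade call set with the truth labels of the cohort it was
#' run on. Clone sensitivity is measured over recoverable planted clones:
#' non-decoy post-zygotic variants whose realized presence set (pattern
#' intersected with the subject's assayed fractions) is a non-empty proper
#' subset of those fractions, with a true VAF of at least `vaf_min` in at
#' least one carrying fraction, excluding the all-lineage early-clonal
#' variants (which the presence rule alone must designate germline).
#' Germline contamination is the fraction of planted germline variants
#' that appear in the final calls.
#'
#' @param callset A `ch_callset` from [run_cascade()].
#' @param cohort The `ch_sim_cohort` the call set was computed from.
#' @param vaf_min Minimum true VAF for a clone to count as recoverable.
#' @return A one-row tibble: `n_eligible`, `n_recovered`, `sensitivity`,
#'   `n_germline`, `n_contaminating`, `contamination`.
#' @export
evaluate_recovery <- function(callset, cohort, vaf_min = 0.05) {
  key <- c("subject_id", "chrom", "pos", "ref", "alt")
  assayed <- cohort$subjects %>%
    distinct(.data$subject_id, .data$cell_type) %>%
    group_by(.data$subject_id) %>%
    summarise(fr = list(.data$cell_type), .groups = "drop")
  truth <- cohort$truth %>%
    left_join(assayed, by = "subject_id") %>%
    mutate(
      realized = purrr::map2(.data$pattern, .data$fr, function(p, fr) {
        intersect(pattern_members(p), fr)
      }),
      n_assayed = lengths(.data$fr),
      n_present = lengths(.data$realized),
      max_true_vaf = purrr::pmap_dbl(
        list(.data$realized, .data$vaf_CD4, .data$vaf_NK, .data$vaf_MYEL),
        function(r, v1, v2, v3) {
          v <- c(CD4 = v1, NK = v2, MYEL = v3)
          if (length(r) == 0) NA_real_ else max(v[r])
        }
      )
    )
  eligible <- truth %>%
    filter(
      .data$zygosity == "post_zygotic",
      .data$pattern != "all_three_early",
      !.data$is_decoy,
      .data$n_present >= 1,
      .data$n_present < .data$n_assayed,
      .data$max_true_vaf >= vaf_min
    )
  recovered <- eligible %>% semi_join(callset$calls, by = key)
  germ <- truth %>% filter(.data$zygosity == "germline")
  contam <- germ %>% semi_join(callset$calls, by = key)
  tibble(
    n_eligible = nrow(eligible),
    n_recovered = nrow(recovered),
    sensitivity = nrow(recovered) / nrow(eligible),
    n_germline = nrow(germ),
    n_contaminating = nrow(contam),
    contamination = nrow(contam) / nrow(germ)
  )
}

#' @export
print.ch_sim_cohort <- function(x, ...) {
  cat(sprintf(
    "<ch_sim_cohort> %d subjects, %d called variant rows, %d evidence rows (seed %d)\n",
    n_distinct(x$subjects$subject_id), nrow(x$variants), nrow(x$evidence),
    x$config$seed
  ))
  invisible(x)
}
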