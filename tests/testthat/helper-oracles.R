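# Independent brute-force oracles for the exact tests, plus tiny fixture
# builders. The oracles deliberately share no code with the implementation.

# Two-sided Fisher p by full enumeration of tables with the observed
# margins: sum of hypergeometric probabilities <= observed (relative tie
# tolerance 1e-7).
fisher_enum_oracle <- function(a, b, c, d) {
  m <- a + b       # row 1 total
  n <- c + d       # row 2 total
  k <- a + c       # column 1 total
  lo <- max(0L, k - n)
  hi <- min(k, m)
  xs <- lo:hi
  probs <- dhyper(xs, m, n, k)
  obs <- dhyper(a, m, n, k)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# Two-sided Mann-Whitney p by enumeration of all group labelings.
mw_enum_oracle <- function(x, y) {
  n <- length(x)
  pooled <- c(x, y)
  N <- length(pooled)
  r <- rank(pooled)
  u_of <- function(idx) sum(r[idx]) - n * (n + 1) / 2
  u_obs <- u_of(seq_len(n))
  combos <- utils::combn(N, n)
  us <- apply(combos, 2, u_of)
  mu <- n * length(y) / 2
  p <- mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
  min(1, p)
}

# Quadratic-time BH step-up reference with explicit family size m.
bh_quad_oracle <- function(p, m) {
  n <- length(p)
  ord <- order(p)
  ranks <- integer(n)
  ranks[ord] <- seq_len(n)
  vapply(seq_len(n), function(i) {
    candidates <- vapply(seq_len(n), function(j) {
      if (ranks[j] >= ranks[i]) m * p[j] / ranks[j] else Inf
    }, numeric(1))
    min(1, min(candidates))
  }, numeric(1))
}

# One variant-table row with overridable fields; defaults pass every filter.
variant_row <- function(subject_id = "S1", cell_type = "NK", chrom = "chr1",
                        pos = 100L, ref = "A", alt = "G", gene = "GENE1",
                        consequence = "missense", caller_flag = "PASS",
                        depth = 100L, alt_fwd = 10L, alt_rev = 10L,
                        n_hq_alt = 20L, min_read_mq = 60,
                        popmax_maf = NA_real_, mcap = NA_real_,
                        oncogenic = FALSE) {
  tibble::tibble(
    subject_id = subject_id, cell_type = cell_type, chrom = chrom,
    pos = pos, ref = ref, alt = alt, gene = gene,
    consequence = consequence, caller_flag = caller_flag, depth = depth,
    alt_fwd = alt_fwd, alt_rev = alt_rev, n_hq_alt = n_hq_alt,
    min_read_mq = min_read_mq, popmax_maf = popmax_maf, mcap = mcap,
    oncogenic = oncogenic
  )
}

# Long-form subject rows for one subject with given per-fraction %LOY,
# encoded as exact mLRR-Y values.
subject_rows <- function(subject_id = "S1", group = "AD", age = 80,
                         pct = c(CD4 = 1, NK = 2, MYEL = 3)) {
  tibble::tibble(
    subject_id = subject_id, group = group, age = age,
    cell_type = names(pct), method = "mLRRY",
    raw_value = log2(1 - unname(pct) / 100),
    smoker = NA
  )
}

test_catalog <- function() {
  gene_catalog(
    myeloid = c("TET2", "DNMT3A", "SRSF2"),
    lymphoid = c("KMT2D", "ATM", "NFE2")
  )
}

# stratum lookup by reconstructing from the deterministic subject order
subject_stratum <- function(co, ids) {
  cfg <- co$config
  sizes <- c(cfg$n_ad_loy, cfg$n_ad_roy, cfg$n_ctrl_loy, cfg$n_ctrl_roy)
  labels <- rep(c("AD_LOY", "AD_ROY", "CTRL_LOY", "CTRL_ROY"), sizes)
  labels[as.integer(sub("^S", "", ids))]
}
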