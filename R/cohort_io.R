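# Readers and writers for the tabular inputs of the pipeline: per-fraction
# variant calls, subject/LOY measurement tables, and driver-gene catalogs.

VARIANT_REQUIRED_COLS <- c(
  "subject_id", "cell_type", "chrom", "pos", "ref", "alt", "gene",
  "consequence", "caller_flag", "depth", "alt_fwd", "alt_rev",
  "n_hq_alt", "min_read_mq", "popmax_maf", "mcap", "oncogenic"
)

CONSEQUENCES <- c("frameshift_indel", "nonsense", "missense", "other")

#' Compute a variant allele frequency from strand-split read counts
#'
#' VAF is the fraction of reads supporting the alternate allele,
#' `(alt_fwd + alt_rev) / depth`. A zero-depth site returns 0 with a warning
#' rather than `NaN` so that downstream filters treat it as unsupported.
#'
#' @param alt_fwd,alt_rev Non-negative integer counts of alternate-supporting
#'   reads on the forward and reverse strand.
#' @param depth Total read depth (DP) at the site.
#' @return A numeric vector of allele fractions in `[0, 1]`.
#' @examples
#' compute_vaf(6, 4, 100) # 0.10
#' @export
compute_vaf <- function(alt_fwd, alt_rev, depth) {
  if (any(alt_fwd < 0 | alt_rev < 0 | depth < 0, na.rm = TRUE)) {
    abort("read counts must be non-negative")
  }
  alt <- alt_fwd + alt_rev
  bad <- which(alt > depth)
  if (length(bad) > 0) {
    abort(sprintf(
      "alternate reads exceed depth at position(s) %s",
      paste(utils::head(bad, 5), collapse = ", ")
    ))
  }
  zero <- depth == 0
  if (any(zero, na.rm = TRUE)) {
    warn("zero-depth site(s): VAF set to 0")
  }
  if_else(zero, 0, alt / depth)
}

#' Read a per-fraction variant call table
#'
#' Parses annotated variant calls, one row per variant per sorted cell
#' fraction. The TSV dialect uses a fixed header (see
#' `chloy:::VARIANT_REQUIRED_COLS`); the VCF dialect reads one file per
#' (subject, fraction) sample with the annotations carried as INFO keys
#' (`GENE`, `CSQ`, `DP`, `SAF`, `SAR`, `NHQ`, `MMQ`, `POPMAX`, `MCAP`, `ONC`)
#' and the caller flag taken from FILTER.
#'
#' Absent `popmax_maf` / `mcap` annotations (empty, `"."` or `NA`) are kept as
#' `NA`, never coerced to 0: the population filter treats "not listed in
#' gnomAD" as retained. Coordinates are 1-based.
#'
#' @param path Path to the variant table.
#' @param format `"tsv"` (default) or `"vcf"`.
#' @param subject_id,cell_type Required for `format = "vcf"`, where the file
#'   carries calls for a single sorted fraction of a single subject.
#' @return A tibble of validated variant calls with a computed `vaf` column.
#' @export
read_variant_table <- function(path, format = c("tsv", "vcf"),
                               subject_id = NULL, cell_type = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  raw <- switch(format,
    tsv = read_variant_tsv(path),
    vcf = read_variant_vcf(path, subject_id, cell_type)
  )
  validate_variants(raw, source = path)
}

read_variant_tsv <- function(path) {
  # column mismatches surface as structured errors below, not readr warnings
  tbl <- suppressWarnings(readr::read_tsv(
    path,
    col_types = readr::cols(
      subject_id = readr::col_character(),
      cell_type = readr::col_character(),
      chrom = readr::col_character(),
      pos = readr::col_integer(),
      ref = readr::col_character(),
      alt = readr::col_character(),
      gene = readr::col_character(),
      consequence = readr::col_character(),
      caller_flag = readr::col_character(),
      depth = readr::col_integer(),
      alt_fwd = readr::col_integer(),
      alt_rev = readr::col_integer(),
      n_hq_alt = readr::col_integer(),
      min_read_mq = readr::col_double(),
      popmax_maf = readr::col_character(),
      mcap = readr::col_character(),
      oncogenic = readr::col_logical()
    ),
    na = c("", "NA"),
    progress = FALSE, show_col_types = FALSE
  ))
  missing_cols <- setdiff(VARIANT_REQUIRED_COLS, names(tbl))
  if (length(missing_cols) > 0) {
    abort(sprintf(
      "variant table %s is missing required column(s): %s",
      path, paste(missing_cols, collapse = ", ")
    ))
  }
  probs <- readr::problems(tbl)
  if (nrow(probs) > 0) {
    abort(sprintf(
      "malformed variant row in %s at line %d: expected %s, got %s",
      path, probs$row[1] + 1L, probs$expected[1], probs$actual[1]
    ))
  }
  tbl %>%
    mutate(
      popmax_maf = parse_optional_numeric(.data$popmax_maf),
      mcap = parse_optional_numeric(.data$mcap)
    )
}

# "." and empty strings denote an absent annotation; anything else must parse
# as a number.
parse_optional_numeric <- function(x) {
  x <- as.character(x)
  absent <- is.na(x) | x == "." | x == ""
  out <- suppressWarnings(as.numeric(x))
  if (any(!absent & is.na(out))) {
    abort(sprintf(
      "non-numeric annotation value(s): %s",
      paste(unique(x[!absent & is.na(out)]), collapse = ", ")
    ))
  }
  out[absent] <- NA_real_
  out
}

read_variant_vcf <- function(path, subject_id, cell_type) {
  if (is.null(subject_id) || is.null(cell_type)) {
    abort("VCF input carries one fraction: supply subject_id and cell_type")
  }
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    abort("the VCF dialect requires the vcfR package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  info_num <- function(key) {
    suppressWarnings(as.numeric(vcfR::extract.info(v, element = key)))
  }
  info_chr <- function(key) vcfR::extract.info(v, element = key)
  tibble(
    subject_id = subject_id,
    cell_type = cell_type,
    chrom = fix$CHROM,
    pos = as.integer(fix$POS),
    ref = fix$REF,
    alt = fix$ALT,
    gene = info_chr("GENE"),
    consequence = info_chr("CSQ"),
    caller_flag = fix$FILTER,
    depth = as.integer(info_num("DP")),
    alt_fwd = as.integer(info_num("SAF")),
    alt_rev = as.integer(info_num("SAR")),
    n_hq_alt = as.integer(info_num("NHQ")),
    min_read_mq = info_num("MMQ"),
    popmax_maf = info_num("POPMAX"),
    mcap = info_num("MCAP"),
    oncogenic = !is.na(info_chr("ONC")) & info_chr("ONC") %in% c("1", "TRUE")
  )
}

validate_variants <- function(tbl, source = "variant table") {
  req_complete <- c(
    "subject_id", "cell_type", "chrom", "pos", "ref", "alt", "gene",
    "consequence", "caller_flag", "depth", "alt_fwd", "alt_rev"
  )
  for (col in req_complete) {
    bad <- which(is.na(tbl[[col]]))
    if (length(bad) > 0) {
      abort(sprintf("%s: missing %s at data row %d", source, col, bad[1]))
    }
  }
  bad_ct <- which(!tbl$cell_type %in% CELL_TYPES)
  if (length(bad_ct) > 0) {
    abort(sprintf(
      "%s: unknown cell_type '%s' at data row %d",
      source, tbl$cell_type[bad_ct[1]], bad_ct[1]
    ))
  }
  bad_csq <- which(!tbl$consequence %in% CONSEQUENCES)
  if (length(bad_csq) > 0) {
    abort(sprintf(
      "%s: unknown consequence '%s' at data row %d",
      source, tbl$consequence[bad_csq[1]], bad_csq[1]
    ))
  }
  if (any(tbl$pos < 1)) abort(sprintf("%s: positions must be 1-based", source))
  bad_fs <- which(
    tbl$consequence == "frameshift_indel" & nchar(tbl$ref) == nchar(tbl$alt)
  )
  if (length(bad_fs) > 0) {
    abort(sprintf(
      "%s: frameshift_indel with length-preserving alleles at data row %d",
      source, bad_fs[1]
    ))
  }
  bad_alt <- which(tbl$alt_fwd + tbl$alt_rev > tbl$depth)
  if (length(bad_alt) > 0) {
    abort(sprintf(
      "%s: alt reads exceed depth at data row %d", source, bad_alt[1]
    ))
  }
  tbl %>%
    mutate(vaf = compute_vaf(.data$alt_fwd, .data$alt_rev, .data$depth)) %>%
    as_tibble()
}

#' Write a variant call table to TSV
#'
#' Inverse of [read_variant_table()] for the TSV dialect; absent annotations
#' are written as `.` so a round trip preserves their absence.
#'
#' @param variants A variant tibble as returned by [read_variant_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(variants, path) {
  out <- variants %>%
    select(dplyr::all_of(VARIANT_REQUIRED_COLS)) %>%
    mutate(
      popmax_maf = if_else(
        is.na(.data$popmax_maf), ".", format_plain(.data$popmax_maf)
      ),
      mcap = if_else(is.na(.data$mcap), ".", format_plain(.data$mcap))
    )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

format_plain <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) "." else format(v, scientific = FALSE, trim = TRUE, digits = 15)
  }, character(1))
}

#' Read a subject and LOY-measurement table
#'
#' Long-form TSV with one row per (subject, cell fraction, assay) measurement:
#' columns `subject_id`, `group` (`AD`/`CTRL`), `age`, `cell_type`, `method`
#' (`mLRRY`/`ddPCR`), `raw_value`, and optionally `smoker`. `raw_value` is the
#' mLRR-Y log2 ratio or the AMELY/AMELX concentration ratio depending on
#' `method`. When a fraction was assayed by both methods, both rows are kept
#' for later resolution (ddPCR preferred).
#'
#' Each subject must contribute at least two distinct cell fractions.
#'
#' @param path Path to the TSV.
#' @return A validated long tibble of measurements.
#' @export
read_subject_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  tbl <- readr::read_tsv(
    path,
    col_types = readr::cols(
      subject_id = readr::col_character(),
      group = readr::col_character(),
      age = readr::col_double(),
      cell_type = readr::col_character(),
      method = readr::col_character(),
      raw_value = readr::col_double(),
      .default = readr::col_guess()
    ),
    progress = FALSE, show_col_types = FALSE
  )
  missing_cols <- setdiff(
    c("subject_id", "group", "age", "cell_type", "method", "raw_value"),
    names(tbl)
  )
  if (length(missing_cols) > 0) {
    abort(sprintf(
      "subject table is missing required column(s): %s",
      paste(missing_cols, collapse = ", ")
    ))
  }
  if (!"smoker" %in% names(tbl)) tbl$smoker <- NA
  validate_subjects(tbl)
}

validate_subjects <- function(tbl) {
  bad_grp <- setdiff(unique(tbl$group), c("AD", "CTRL"))
  if (length(bad_grp) > 0) {
    abort(sprintf("unknown group label(s): %s", paste(bad_grp, collapse = ", ")))
  }
  bad_ct <- setdiff(unique(tbl$cell_type), CELL_TYPES)
  if (length(bad_ct) > 0) {
    abort(sprintf("unknown cell_type label(s): %s", paste(bad_ct, collapse = ", ")))
  }
  bad_m <- setdiff(unique(tbl$method), c("mLRRY", "ddPCR"))
  if (length(bad_m) > 0) {
    abort(sprintf("unknown method label(s): %s", paste(bad_m, collapse = ", ")))
  }
  dup <- tbl %>%
    dplyr::count(.data$subject_id, .data$cell_type, .data$method) %>%
    filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(sprintf(
      "duplicate measurement for subject %s, fraction %s, method %s",
      dup$subject_id[1], dup$cell_type[1], dup$method[1]
    ))
  }
  frac_n <- tbl %>%
    group_by(.data$subject_id) %>%
    summarise(n_frac = n_distinct(.data$cell_type), .groups = "drop") %>%
    filter(.data$n_frac < 2)
  if (nrow(frac_n) > 0) {
    abort(sprintf(
      "subject %s contributed fewer than two cell fractions",
      frac_n$subject_id[1]
    ))
  }
  as_tibble(tbl)
}

#' Cell fractions assayed per subject
#'
#' @param subjects A long measurement tibble from [read_subject_table()].
#' @return A tibble `subject_id`, `cell_type`, one row per assayed fraction.
#' @export
assayed_fractions <- function(subjects) {
  subjects %>%
    distinct(.data$subject_id, .data$cell_type) %>%
    arrange(.data$subject_id, match(.data$cell_type, CELL_TYPES))
}

#' Read myeloid and lymphoid driver gene catalogs
#'
#' Each file lists one HGNC symbol per line. Symbols are upper-cased;
#' duplicates within a file are dropped with a warning. A gene present in
#' both catalogs is retained in both sets; category precedence (myeloid
#' first) is resolved by [categorize_gene()].
#'
#' @param md_path Path to the myeloid driver list.
#' @param ld_path Path to the lymphoid driver list.
#' @return A `ch_gene_catalog` list with character-vector elements
#'   `myeloid` and `lymphoid`.
#' @export
read_gene_catalog <- function(md_path, ld_path) {
  read_one <- function(path, label) {
    if (!file.exists(path)) abort(sprintf("file not found: %s", path))
    syms <- readr::read_lines(path)
    syms <- toupper(trimws(syms))
    syms <- syms[syms != ""]
    if (length(syms) == 0) abort(sprintf("empty gene catalog: %s", path))
    if (anyDuplicated(syms)) {
      warn(sprintf(
        "%s catalog %s: dropped %d duplicate symbol(s)",
        label, path, sum(duplicated(syms))
      ))
      syms <- unique(syms)
    }
    syms
  }
  gene_catalog(
    myeloid = read_one(md_path, "myeloid"),
    lymphoid = read_one(ld_path, "lymphoid")
  )
}

#' Construct a gene catalog from character vectors
#'
#' @param myeloid,lymphoid Character vectors of HGNC symbols.
#' @return A `ch_gene_catalog` object.
#' @export
gene_catalog <- function(myeloid, lymphoid) {
  if (length(myeloid) == 0 || length(lymphoid) == 0) {
    abort("gene catalogs must be non-empty")
  }
  structure(
    list(myeloid = toupper(unique(myeloid)), lymphoid = toupper(unique(lymphoid))),
    class = "ch_gene_catalog"
  )
}

#' @export
print.ch_gene_catalog <- function(x, ...) {
  cat(sprintf(
    "<ch_gene_catalog> %d myeloid, %d lymphoid driver genes (%d shared)\n",
    length(x$myeloid), length(x$lymphoid),
    length(intersect(x$myeloid, x$lymphoid))
  ))
  invisible(x)
}
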