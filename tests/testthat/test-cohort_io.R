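# Readers, writers and per-variant derived quantities.

test_that("compute_vaf matches alt/(depth) and handles edge cases", {
  expect_equal(compute_vaf(6, 4, 100), 0.10)
  expect_equal(compute_vaf(0, 0, 50), 0)
  expect_warning(v0 <- compute_vaf(0, 0, 0), "zero-depth")
  expect_equal(v0, 0)
  expect_error(compute_vaf(60, 50, 100), "exceed depth")
  expect_error(compute_vaf(-1, 0, 10), "non-negative")
})

test_that("compute_vaf is scale-free in the counts", {
  withr::with_seed(11, {
    for (i in 1:50) {
      dp <- sample(20:200, 1)
      alt <- sample.int(dp, 1)
      fwd <- sample(0:alt, 1)
      k <- sample(2:5, 1)
      expect_equal(
        compute_vaf(fwd, alt - fwd, dp),
        compute_vaf(k * fwd, k * (alt - fwd), k * dp)
      )
    }
  })
})

test_that("TSV variant tables round-trip bit-exactly, keeping absence absent", {
  tbl <- dplyr::bind_rows(
    variant_row(popmax_maf = 0.005, mcap = 0.3),
    variant_row(pos = 200L, popmax_maf = NA, mcap = NA),
    variant_row(
      pos = 300L, consequence = "frameshift_indel", ref = "AT", alt = "A"
    )
  )
  path <- withr::local_tempfile(fileext = ".tsv")
  write_variant_table(tbl, path)
  back <- read_variant_table(path)
  expect_equal(
    back %>% dplyr::select(dplyr::all_of(names(tbl))),
    tbl
  )
  expect_true(is.na(back$popmax_maf[2]))
  expect_true(is.na(back$mcap[2]))
  expect_equal(back$vaf, rep(0.2, 3))
  # "." in the file denotes absence and survives a second round trip
  raw <- readLines(path)
  expect_true(grepl("\\.\t\\.", raw[3]))
})

test_that("variant reader enforces required columns and valid rows", {
  path <- withr::local_tempfile(fileext = ".tsv")
  tbl <- variant_row()
  readr::write_tsv(tbl %>% dplyr::select(-"gene"), path)
  expect_error(read_variant_table(path), "gene")

  bad <- variant_row(alt_fwd = 80L, alt_rev = 30L, depth = 100L)
  path2 <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(bad, path2)
  expect_error(read_variant_table(path2), "exceed depth")

  fs_bad <- variant_row(consequence = "frameshift_indel") # ref/alt same length
  path3 <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(fs_bad, path3)
  expect_error(read_variant_table(path3), "frameshift")

  empty <- variant_row()[0, ]
  path4 <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(empty, path4)
  expect_equal(nrow(read_variant_table(path4)), 0)
})

test_that("parsing never coerces absent annotations to numbers", {
  withr::with_seed(5, {
    for (i in 1:20) {
      n <- 8
      absent <- runif(n) < 0.5
      vals <- round(runif(n, 0, 0.5), 4)
      tbl <- purrr::map(seq_len(n), function(j) {
        variant_row(pos = j * 10L, popmax_maf = if (absent[j]) NA else vals[j])
      }) %>% dplyr::bind_rows()
      path <- withr::local_tempfile(fileext = ".tsv")
      write_variant_table(tbl, path)
      back <- read_variant_table(path)
      expect_identical(is.na(back$popmax_maf), absent)
      expect_equal(back$popmax_maf[!absent], vals[!absent])
    }
  })
})

test_that("VCF dialect reads INFO-encoded annotations", {
  vcf <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
    "##INFO=<ID=SAF,Number=1,Type=Integer,Description=\"Alt fwd\">",
    "##INFO=<ID=SAR,Number=1,Type=Integer,Description=\"Alt rev\">",
    "##INFO=<ID=NHQ,Number=1,Type=Integer,Description=\"HQ alt reads\">",
    "##INFO=<ID=MMQ,Number=1,Type=Float,Description=\"Min read MQ\">",
    "##INFO=<ID=POPMAX,Number=1,Type=Float,Description=\"gnomAD popmax\">",
    "##INFO=<ID=MCAP,Number=1,Type=Float,Description=\"M-CAP\">",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene\">",
    "##INFO=<ID=CSQ,Number=1,Type=String,Description=\"Consequence\">",
    "##INFO=<ID=ONC,Number=1,Type=String,Description=\"Oncogenic\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    paste0("chr2\t500\t.\tC\tT\t.\tPASS\t",
           "DP=120;SAF=7;SAR=5;NHQ=12;MMQ=60;GENE=TET2;CSQ=missense;MCAP=0.1"),
    paste0("chr3\t900\t.\tG\tA\t.\talleleBias\t",
           "DP=80;SAF=3;SAR=2;NHQ=5;MMQ=55;GENE=HBP1;CSQ=nonsense;ONC=1;POPMAX=0.001")
  )
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(vcf, path)
  tbl <- read_variant_table(path, format = "vcf",
                            subject_id = "S9", cell_type = "MYEL")
  expect_equal(nrow(tbl), 2)
  expect_equal(tbl$vaf[1], 12 / 120)
  expect_true(is.na(tbl$popmax_maf[1]))
  expect_equal(tbl$popmax_maf[2], 0.001)
  expect_equal(tbl$caller_flag, c("PASS", "alleleBias"))
  expect_true(tbl$oncogenic[2])
  expect_error(read_variant_table(path, format = "vcf"), "subject_id")
})

test_that("subject table reader validates structure and the two-fraction rule", {
  good <- dplyr::bind_rows(
    subject_rows("S1", pct = c(CD4 = 1, NK = 20, MYEL = 40)),
    subject_rows("S2", pct = c(CD4 = 1, NK = 2))
  )
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(good, path)
  tbl <- read_subject_table(path)
  af <- assayed_fractions(tbl)
  expect_equal(sum(af$subject_id == "S1"), 3)
  expect_equal(sum(af$subject_id == "S2"), 2)

  single <- subject_rows("S3", pct = c(CD4 = 1))
  path2 <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(single, path2)
  expect_error(read_subject_table(path2), "fewer than two")

  dup <- dplyr::bind_rows(good, subject_rows("S1", pct = c(CD4 = 1, NK = 20, MYEL = 40)))
  path3 <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(dup, path3)
  expect_error(read_subject_table(path3), "duplicate")

  bad_grp <- good %>% dplyr::mutate(group = "PATIENT")
  path4 <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(bad_grp, path4)
  expect_error(read_subject_table(path4), "group")
})

test_that("dual-assay measurements are both retained for later resolution", {
  both <- tibble::tibble(
    subject_id = "S1", group = "AD", age = 80,
    cell_type = c("MYEL", "MYEL", "NK"),
    method = c("mLRRY", "ddPCR", "mLRRY"),
    raw_value = c(log2(0.75), 0.8, log2(0.99)),
    smoker = NA
  )
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(both, path)
  tbl <- read_subject_table(path)
  expect_equal(nrow(tbl %>% dplyr::filter(cell_type == "MYEL")), 2)
})

test_that("gene catalogs normalise case, deduplicate and reject empties", {
  md <- withr::local_tempfile(fileext = ".txt")
  ld <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("tet2", "DNMT3A", "SRSF2"), md)
  writeLines(c("KMT2D", "KMT2D", "ATM"), ld)
  expect_warning(cat <- read_gene_catalog(md, ld), "duplicate")
  expect_setequal(cat$myeloid, c("TET2", "DNMT3A", "SRSF2"))
  expect_setequal(cat$lymphoid, c("KMT2D", "ATM"))

  empty <- withr::local_tempfile(fileext = ".txt")
  writeLines(character(0), empty)
  expect_error(read_gene_catalog(empty, ld), "empty")
})
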