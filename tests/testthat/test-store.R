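test_that("writes are counted, atomic and read back byte-identically", {
  con <- example_store()
  on.exit(DBI::dbDisconnect(con))
  si <- DBI::dbReadTable(con, "snp_info")
  expect_equal(nrow(si), 7)
  expect_equal(si$snp_id, sprintf("s%d", 1:7))
  tf <- DBI::dbReadTable(con, "tfbs_results")
  expect_equal(tf$ref_mss[tf$snp_id == "s1"], 0.99)
  expect_true(is.na(tf$alt_mss[tf$snp_id == "s1"]))

  # integrity violation rolls the whole transaction back
  before <- DBI::dbGetQuery(con, "SELECT COUNT(*) n FROM tfbs_results")$n
  expect_error(
    write_results(con, tfbs_results = tibble::tibble(
      snp_id = "unknown", pwm_id = "V$X_01", strand = "+", start = 1L,
      allele_presence = "both", ref_mss = 1, ref_css = 1, alt_mss = 1,
      alt_css = 1, consequence = "no_effect")),
    "absent from snp_region")
  expect_error(
    write_results(con, snp_region = tibble::tibble(
      snp_id = "s1", gene_id = "no_such_gene", transcript_id = "t", dist_tss = 0L)),
    "unknown gene_id")
  after <- DBI::dbGetQuery(con, "SELECT COUNT(*) n FROM tfbs_results")$n
  expect_equal(before, after)
})

test_that("the four query modes return joined slices; unknown keys are empty", {
  con <- example_store()
  on.exit(DBI::dbDisconnect(con))

  by_rsid <- query_store(con, "rsid", "s3")
  expect_equal(by_rsid$snp_info$snp_id, "s3")
  expect_equal(by_rsid$gene_info$gene_id, "g1")
  expect_equal(by_rsid$snp_region$dist_tss, -115L)
  expect_equal(by_rsid$tfbs_results$consequence, "score_change")

  by_pos <- query_store(con, "position", "chr1:3000")
  expect_equal(by_pos$snp_info$snp_id, "s3")

  by_region <- query_store(con, "region", "chr1:1500-3500")
  expect_setequal(by_region$snp_info$snp_id, c("s2", "s3"))
  expect_error(query_store(con, "region", "chr1:15-"), "malformed")

  # gene mode accepts stable id or gene name, verified against a linear scan
  by_gene <- query_store(con, "gene", "alpha")
  sr <- DBI::dbReadTable(con, "snp_region")
  expect_setequal(by_gene$snp_region$snp_id, sr$snp_id[sr$gene_id == "g1"])
  expect_setequal(by_gene$tfbs_results$snp_id,
                  intersect(sr$snp_id[sr$gene_id == "g1"],
                            DBI::dbReadTable(con, "tfbs_results")$snp_id))
  expect_identical(query_store(con, "gene", "g1")$snp_region,
                   by_gene$snp_region)

  empty <- query_store(con, "rsid", "rs_not_there")
  expect_true(all(vapply(empty, nrow, integer(1)) == 0))
})

test_that("promoter narrowing filters snp_region and its dependents", {
  con <- example_store()
  on.exit(DBI::dbDisconnect(con))
  full <- query_store(con, "gene", "g1")
  narrowed <- query_store(con, "gene", "g1", upstream = 750, downstream = 250)
  expect_true(all(narrowed$snp_region$dist_tss >= -750 &
                    narrowed$snp_region$dist_tss <= 250))
  expect_true(all(narrowed$snp_region$snp_id %in% full$snp_region$snp_id))
  expect_setequal(narrowed$snp_region$snp_id, c("s3", "s4"))
  expect_setequal(narrowed$tfbs_results$snp_id, c("s3", "s4"))
})

test_that("CSV export and re-import reproduce the tables", {
  con <- example_store()
  on.exit(DBI::dbDisconnect(con), add = TRUE)
  dir <- tempfile("csv")
  store_export_csv(con, dir)
  con2 <- store_import_csv(dir)
  on.exit(DBI::dbDisconnect(con2), add = TRUE)
  for (nm in c("snp_info", "gene_info", "snp_region", "tfbs_results")) {
    a <- DBI::dbReadTable(con, nm)
    b <- DBI::dbReadTable(con2, nm)
    a <- a[do.call(order, a), ]
    b <- b[do.call(order, b), ]
    expect_equal(a, b, ignore_attr = TRUE)
  }
})

test_that("chromosome-wise export splits rows by the SNP's chromosome", {
  con <- example_store()
  on.exit(DBI::dbDisconnect(con))
  dir <- tempfile("csv_chrom")
  files <- store_export_csv(con, dir, by_chromosome = TRUE)
  expect_true(file.exists(file.path(dir, "snp_info_chr1.csv")))
  chr1 <- readr::read_csv(file.path(dir, "snp_region_chr1.csv"),
                          show_col_types = FALSE)
  expect_setequal(chr1$snp_id, sprintf("s%d", 1:5))
  gene_chr3 <- readr::read_csv(file.path(dir, "gene_info_chr3.csv"),
                               show_col_types = FALSE)
  expect_equal(gene_chr3$gene_id, "g3")
})
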