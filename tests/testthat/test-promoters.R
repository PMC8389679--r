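tx_row <- function(chrom = "chr1", strand = "+", tss = 10000L,
                   gene = "g1", txid = "t1") {
  tibble::tibble(gene_id = gene, gene_name = gene, transcript_id = txid,
                 chrom = chrom, strand = strand, tss = tss)
}

test_that("promoter windows span upstream/downstream extents strand-aware", {
  w <- promoter_windows(tx_row(strand = "+", tss = 10000L))
  expect_equal(c(w$start, w$end), c(2500L, 12500L))
  expect_equal(w$end - w$start, 10000L)          # 10 kb window
  w <- promoter_windows(tx_row(strand = "-", tss = 10000L))
  expect_equal(c(w$start, w$end), c(7500L, 17500L))
  # clipping at the chromosome start and end
  w <- promoter_windows(tx_row(strand = "+", tss = 100L))
  expect_equal(c(w$start, w$end), c(1L, 2600L))
  w <- promoter_windows(tx_row(strand = "-", tss = 900L),
                        chrom_lengths = c(chr1 = 5000L))
  expect_equal(c(w$start, w$end), c(1L, 5000L))
  expect_error(promoter_windows(tx_row(), upstream_bp = -1), "non-negative")
})

test_that("TSS distances are signed along the direction of transcription", {
  plus <- promoter_windows(tx_row(strand = "+", tss = 10000L))
  minus <- promoter_windows(tx_row(strand = "-", tss = 10000L, gene = "g2",
                                   txid = "t2"))
  snps <- tibble::tibble(
    snp_id = c("at_tss", "up115_minus"),
    chrom = "chr1",
    pos = c(10000L, 10115L)
  )
  rows <- map_snps_to_promoters(rbind(plus, minus), snps)
  expect_equal(rows$dist_tss[rows$snp_id == "at_tss" & rows$gene_id == "g1"], 0L)
  # 115 bp 5' of a minus-strand gene lies at pos = tss + 115 -> -115
  expect_equal(rows$dist_tss[rows$snp_id == "up115_minus" & rows$gene_id == "g2"],
               -115L)
  # the same SNP is reported once per containing promoter
  expect_equal(sum(rows$snp_id == "at_tss"), 2)
})

test_that("SNP assignment equals the all-pairs containment oracle", {
  set.seed(31)
  n_win <- 100L
  n_snp <- 1000L
  tx <- tibble::tibble(
    gene_id = sprintf("g%03d", 1:n_win),
    gene_name = sprintf("g%03d", 1:n_win),
    transcript_id = sprintf("t%03d", 1:n_win),
    chrom = sample(c("chr1", "chr2"), n_win, replace = TRUE),
    strand = sample(c("+", "-"), n_win, replace = TRUE),
    tss = sample(8000:200000, n_win)
  )
  windows <- promoter_windows(tx)
  snps <- tibble::tibble(
    snp_id = sprintf("s%04d", 1:n_snp),
    chrom = sample(c("chr1", "chr2"), n_snp, replace = TRUE),
    pos = sample(1:210000, n_snp, replace = TRUE)
  )
  got <- map_snps_to_promoters(windows, snps)
  got <- got[order(got$snp_id, got$transcript_id), ]
  want <- oracle_overlap(windows, snps)
  expect_equal(got$snp_id, want$snp_id)
  expect_equal(got$transcript_id, want$transcript_id)
  expect_equal(got$dist_tss, want$dist_tss)
  # every emitted distance respects the window bounds
  expect_true(all(got$dist_tss >= -7500 & got$dist_tss <= 2500))
})

test_that("narrowing the promoter yields a subset of assignments", {
  set.seed(32)
  tx <- tibble::tibble(
    gene_id = sprintf("g%d", 1:20), gene_name = sprintf("g%d", 1:20),
    transcript_id = sprintf("t%d", 1:20),
    chrom = "chr1", strand = sample(c("+", "-"), 20, replace = TRUE),
    tss = sample(10000:100000, 20)
  )
  snps <- tibble::tibble(snp_id = sprintf("s%d", 1:500), chrom = "chr1",
                         pos = sample(1:110000, 500))
  wide <- map_snps_to_promoters(promoter_windows(tx), snps)
  narrow <- map_snps_to_promoters(
    promoter_windows(tx, upstream_bp = 750, downstream_bp = 250), snps)
  key <- function(d) paste(d$snp_id, d$transcript_id)
  expect_true(all(key(narrow) %in% key(wide)))
  expect_true(all(narrow$dist_tss >= -750 & narrow$dist_tss <= 250))
})

test_that("BED export is 0-based half-open", {
  w <- promoter_windows(tx_row(strand = "+", tss = 10000L))
  bed_file <- tempfile(fileext = ".bed")
  windows_to_bed(w, bed_file)
  bed <- readr::read_tsv(bed_file, col_names = FALSE, show_col_types = FALSE)
  expect_equal(bed$X2, 2499)   # start shifted by one
  expect_equal(bed$X3, 12500)  # end unchanged
  expect_equal(bed$X3 - bed$X2, w$end - w$start + 1)
})
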