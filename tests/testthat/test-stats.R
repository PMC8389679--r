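test_that("per-chromosome counts match the hand-built store and conserve totals", {
  con <- example_store()
  on.exit(DBI::dbDisconnect(con))
  counts <- per_chromosome_counts(con)
  expect_equal(counts$chrom, c("chr1", "chr2", "chr3"))
  expect_equal(counts$n_snps, c(5L, 2L, 0L))
  expect_equal(counts$n_genes, c(1L, 1L, 1L))
  # rSNPs: s1..s5 on chr1 qualify (s4 is a score-change), chr2's s6 is no-effect
  expect_equal(counts$n_rsnps, c(5L, 0L, 0L))
  si <- DBI::dbReadTable(con, "snp_info")
  expect_equal(sum(counts$n_snps), nrow(si))
  gi <- DBI::dbReadTable(con, "gene_info")
  expect_equal(sum(counts$n_genes), nrow(gi))
})

test_that("rSNPs per gene split upstream/downstream and average over genes", {
  con <- example_store()
  on.exit(DBI::dbDisconnect(con))
  rpg <- rsnps_per_gene(con)
  chr1 <- rpg[rpg$chrom == "chr1", ]
  # g1 carries 3 upstream (dist < 0) and 2 downstream (dist >= 0) rSNPs
  expect_equal(chr1$mean_up, 3)
  expect_equal(chr1$mean_down, 2)
  expect_equal(rpg$mean_up[rpg$chrom == "chr2"], 0)
  expect_equal(rpg$mean_down[rpg$chrom == "chr3"], 0)
  # overall mean = distinct rSNP-gene pairs / total genes = 5 / 3
  expect_equal(attr(rpg, "overall_mean"), 5 / 3)
  # and it equals the gene-count-weighted mean of per-chromosome pair rates
  pairs_per_chrom <- c(5, 0, 0)
  expect_equal(attr(rpg, "overall_mean"),
               sum(pairs_per_chrom) / sum(rpg$n_genes))
})

test_that("distance histogram bins half-open from the range start", {
  con <- example_store()
  on.exit(DBI::dbDisconnect(con))
  h <- distance_histogram(con, bin_width = 50, range = c(-750, 250))
  expect_s3_class(h, "distance_histogram")
  # the rSNP at -115 falls in [-150, -100)
  expect_equal(h$count[h$bin_start == -150], 1L)
  expect_equal(h$count[h$bin_start == -100], 0L)
  # dist 0 is downstream: first non-negative bin
  expect_equal(h$count[h$bin_start == 0], 1L)
  # conservation within range: s3 (-115), s4 (0) are the in-range rSNP rows
  expect_equal(sum(h$count), 2L)

  full <- distance_histogram(con)   # -7500..2500 by 500
  expect_equal(sum(full$count), 5L)
  expect_equal(full$count[full$bin_start == -7500], 0L)  # [-7500, -7000) is empty
  expect_equal(full$count[full$bin_start == -7000], 1L)  # s1 at exactly -7000
  expect_error(distance_histogram(con, bin_width = 300, range = c(-750, 250)),
               "divide")
})

test_that("uniformly planted distances give an approximately flat histogram", {
  con <- create_store()
  on.exit(DBI::dbDisconnect(con))
  set.seed(71)
  n <- 5000L
  d <- sample(-7500:2499, n, replace = TRUE)
  snp_info <- tibble::tibble(snp_id = sprintf("s%d", 1:n), chrom = "chr1",
                             pos = seq_len(n), ref = "A", alt = "C")
  gene_info <- tibble::tibble(gene_id = "g1", gene_name = "g1", chrom = "chr1",
                              start = 1L, end = 10L, strand = "+")
  snp_region <- tibble::tibble(snp_id = snp_info$snp_id, gene_id = "g1",
                               transcript_id = "t1", dist_tss = d)
  tfbs <- tibble::tibble(snp_id = snp_info$snp_id, pwm_id = "V$X_01",
                         strand = "+", start = 1L, allele_presence = "ref_only",
                         ref_mss = 1, ref_css = 1, alt_mss = NA_real_,
                         alt_css = NA_real_, consequence = "loss")
  write_results(con, snp_info, gene_info, snp_region, tfbs)
  h <- distance_histogram(con)
  expect_equal(sum(h$count), n)
  p <- stats::chisq.test(h$count)$p.value
  expect_gt(p, 0.001)
})

test_that("statistics are pure functions of the store", {
  con <- example_store()
  on.exit(DBI::dbDisconnect(con))
  expect_identical(per_chromosome_counts(con), per_chromosome_counts(con))
  expect_identical(rsnps_per_gene(con), rsnps_per_gene(con))
  expect_identical(distance_histogram(con), distance_histogram(con))
})

test_that("stat plots build without error", {
  con <- example_store()
  on.exit(DBI::dbDisconnect(con))
  p1 <- ggplot2::autoplot(distance_histogram(con))
  p2 <- ggplot2::autoplot(per_chromosome_counts(con))
  expect_s3_class(p1, "ggplot")
  expect_s3_class(p2, "ggplot")
})
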