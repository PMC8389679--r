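test_that("a motif spanning the SNP is predicted for the matching allele only", {
  set.seed(51)
  pair <- random_flank_pair()
  # PWM consensus = the reference subsequence covering the SNP (pos 20..29)
  lib <- make_lib(sharp_freq(substr(pair$ref, 20, 29)), id = "V$PLANT_01")
  hits <- scan_alleles(lib, pair$ref, pair$alt, snp_index = pair$snp_index)
  ref_hits <- hits[hits$allele == "ref", ]
  alt_hits <- hits[hits$allele == "alt", ]
  expect_true(any(ref_hits$start == 20 & ref_hits$strand == "+" &
                    ref_hits$mss == 1))
  expect_false(any(alt_hits$start == 20 & alt_hits$strand == "+"))
})

test_that("sites not covering the SNP are identical across alleles and dropped", {
  set.seed(52)
  pair <- random_flank_pair()
  # motif entirely 5' of the SNP (positions 1..10)
  lib <- make_lib(sharp_freq(substr(pair$ref, 1, 10)), id = "V$LEFT_01")
  unfiltered <- scan_alleles(lib, pair$ref, pair$alt, snp_index = pair$snp_index,
                             require_snp_overlap = FALSE)
  u_ref <- unfiltered[unfiltered$allele == "ref" & unfiltered$start == 1, ]
  u_alt <- unfiltered[unfiltered$allele == "alt" & unfiltered$start == 1, ]
  expect_equal(nrow(u_ref), 1)
  expect_equal(u_ref[c("pwm_id", "start", "strand", "mss", "css")],
               u_alt[c("pwm_id", "start", "strand", "mss", "css")])
  filtered <- scan_alleles(lib, pair$ref, pair$alt, snp_index = pair$snp_index)
  expect_false(any(filtered$start == 1))
})

test_that("scanning equals the exhaustive (pwm, offset, strand) oracle", {
  set.seed(53)
  lib <- random_library(10, widths = 4:8)
  for (rep in 1:5) {
    pair <- random_flank_pair()
    for (overlap in c(TRUE, FALSE)) {
      got <- scan_alleles(lib, pair$ref, pair$alt, snp_index = pair$snp_index,
                          require_snp_overlap = overlap)
      for (al in c("ref", "alt")) {
        g <- got[got$allele == al, c("pwm_id", "start", "strand", "mss", "css")]
        g <- g[order(g$pwm_id, g$start, g$strand), ]
        w <- oracle_scan_seq(lib, if (al == "ref") pair$ref else pair$alt,
                             pair$snp_index, require_overlap = overlap)
        expect_equal(g$pwm_id, w$pwm_id)
        expect_equal(g$start, w$start)
        expect_equal(g$strand, w$strand)
        expect_equal(g$mss, w$mss, tolerance = 1e-12)
        expect_equal(g$css, w$css, tolerance = 1e-12)
      }
    }
  }
})

test_that("reverse-complementing the flank mirrors the hit set (involution)", {
  set.seed(54)
  lib <- random_library(6, widths = 5:9)
  pair <- random_flank_pair()
  n <- nchar(pair$ref)
  rc <- function(s) as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  fwd <- scan_alleles(lib, pair$ref, pair$alt, snp_index = pair$snp_index)
  rev <- scan_alleles(lib, rc(pair$ref), rc(pair$alt),
                      snp_index = n - pair$snp_index + 1)
  # map forward hits into reverse-flank coordinates
  width_of <- setNames(lib$width, lib$id)
  mirrored <- tibble::tibble(
    allele = fwd$allele,
    pwm_id = fwd$pwm_id,
    start = n - (fwd$start + width_of[fwd$pwm_id] - 1L) + 1L,
    strand = ifelse(fwd$strand == "+", "-", "+"),
    mss = fwd$mss, css = fwd$css
  )
  sort_hits <- function(d) d[order(d$allele, d$pwm_id, d$start, d$strand),
                             c("allele", "pwm_id", "start", "strand", "mss", "css")]
  expect_equal(as.data.frame(sort_hits(mirrored)), as.data.frame(sort_hits(rev)),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("identical alleles give identical hit sets", {
  set.seed(55)
  lib <- random_library(5, widths = 4:7)
  pair <- random_flank_pair()
  hits <- scan_alleles(lib, pair$ref, pair$ref, snp_index = pair$snp_index)
  cols <- c("pwm_id", "start", "strand", "mss", "css")
  expect_equal(as.data.frame(hits[hits$allele == "ref", cols]),
               as.data.frame(hits[hits$allele == "alt", cols]),
               ignore_attr = TRUE)
})

test_that("every reported hit respects cutoffs and covers the SNP", {
  set.seed(56)
  lib <- random_library(8, widths = 4:9, mss_cutoff = 0.7, css_cutoff = 0.65)
  for (rep in 1:10) {
    pair <- random_flank_pair()
    hits <- scan_alleles(lib, pair$ref, pair$alt, snp_index = pair$snp_index)
    if (nrow(hits) == 0) next
    cut <- lib[match(hits$pwm_id, lib$id), ]
    expect_true(all(hits$mss >= cut$mss_cutoff))
    expect_true(all(hits$css >= cut$css_cutoff))
    expect_true(all(hits$start <= pair$snp_index &
                      hits$start + cut$width - 1 >= pair$snp_index))
  }
})

test_that("PWMs wider than the flank are skipped with a warning", {
  lib <- make_lib(random_freq(60), id = "V$WIDE_01")
  pair <- random_flank_pair()
  expect_warning(hits <- scan_alleles(lib, pair$ref, pair$alt), "wider")
  expect_equal(nrow(hits), 0)
})

test_that("mismatched or multiply-differing sequences are rejected", {
  lib <- make_lib(random_freq(4))
  expect_error(scan_alleles(lib, "ACGT", "ACG"), "equal length")
  expect_error(scan_alleles(lib, "AAAAA", "CCCCC", snp_index = 3), "differ")
})
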