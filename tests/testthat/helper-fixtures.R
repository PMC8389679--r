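# in-code fixture builders shared across test files

# one-matrix library from an explicit frequency/count matrix
make_lib <- function(freq, id = "V$TEST_01", mss_cutoff = 0.95, css_cutoff = 0.90) {
  pwm_library(id, list(freq), mss_cutoff = mss_cutoff, css_cutoff = css_cutoff)
}

# near-deterministic matrix matching a consensus string (0.91 / 3 x 0.03)
sharp_freq <- function(consensus) {
  bases <- strsplit(consensus, "")[[1]]
  m <- matrix(0.03, nrow = length(bases), ncol = 4,
              dimnames = list(NULL, c("A", "C", "G", "T")))
  m[cbind(seq_along(bases), match(bases, c("A", "C", "G", "T")))] <- 0.91
  m
}

# random row-normalized frequency matrix
random_freq <- function(width) {
  m <- matrix(stats::runif(width * 4), nrow = width)
  m / rowSums(m)
}

random_library <- function(n, widths, mss_cutoff = 0.75, css_cutoff = 0.70) {
  pwm_library(sprintf("V$RND%03d_01", seq_len(n)),
              lapply(sample(widths, n, replace = TRUE), random_freq),
              mss_cutoff = mss_cutoff, css_cutoff = css_cutoff)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# flank pair differing at the centre base
random_flank_pair <- function(n = 51) {
  ref <- random_dna(n)
  i <- (n + 1) %/% 2
  alt <- ref
  old <- substr(ref, i, i)
  substr(alt, i, i) <- sample(setdiff(c("A", "C", "G", "T"), old), 1)
  list(ref = ref, alt = alt, snp_index = i)
}

write_gff3 <- function(lines, path = tempfile(fileext = ".gff3")) {
  writeLines(c("##gff-version 3", lines), path)
  path
}

write_vcf <- function(rows, path = tempfile(fileext = ".vcf"),
                      contigs = c(chr1 = 100000L, chr2 = 100000L)) {
  writeLines(c("##fileformat=VCFv4.2",
               sprintf("##contig=<ID=%s,length=%d>", names(contigs), contigs),
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
               rows), path)
  path
}

# a populated in-memory store with hand-checkable content:
#   chr1: gene g1 (+, 3 up + 2 down rSNPs), chr2: gene g2 (-, 1 no-effect SNP)
#   chr3: gene g3 with no SNPs at all
example_store <- function() {
  con <- create_store()
  snp_info <- tibble::tibble(
    snp_id = sprintf("s%d", 1:7),
    chrom = c(rep("chr1", 5), "chr2", "chr2"),
    pos = c(1000L, 2000L, 3000L, 8100L, 9000L, 5000L, 6000L),
    ref = "A", alt = "C"
  )
  gene_info <- tibble::tibble(
    gene_id = c("g1", "g2", "g3"),
    gene_name = c("alpha", "beta", "gamma"),
    chrom = c("chr1", "chr2", "chr3"),
    start = c(8000L, 4000L, 100L), end = c(9500L, 6000L, 2000L),
    strand = c("+", "-", "+")
  )
  snp_region <- tibble::tibble(
    snp_id = sprintf("s%d", 1:7),
    gene_id = c(rep("g1", 5), "g2", "g2"),
    transcript_id = c(rep("t1", 5), "t2", "t2"),
    dist_tss = c(-7000L, -6000L, -115L, 0L, 900L, 1000L, 0L)
  )
  tfbs_results <- tibble::tibble(
    snp_id = c("s1", "s2", "s3", "s4", "s5", "s6"),
    pwm_id = "V$X_01", strand = "+", start = 20L,
    allele_presence = c("ref_only", "alt_only", "both", "both", "ref_only", "both"),
    ref_mss = c(0.99, NA, 0.99, 0.98, 0.99, 0.97),
    ref_css = c(0.99, NA, 0.99, 0.98, 0.99, 0.97),
    alt_mss = c(NA, 0.99, 0.96, 0.96, NA, 0.97),
    alt_css = c(NA, 0.99, 0.96, 0.96, NA, 0.97),
    consequence = c("loss", "gain", "score_change", "score_change", "loss", "no_effect")
  )
  write_results(con, snp_info, gene_info, snp_region, tfbs_results)
  con
}
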