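#' Run the full rSNP detection pipeline
#'
#' Loads the four inputs, builds promoter windows, assigns SNPs to
#' promoters, extracts 51-bp allele flanks, predicts TFBSs on both alleles
#' and both strands, classifies consequences, and (optionally) persists the
#' four result tables in an SQLite store.
#'
#' @param genome FASTA path or a [Biostrings::DNAStringSet].
#' @param annotation GFF3/GTF path, or a list with elements `transcripts`
#'   and `genes` (tibbles as from [read_transcript_tss()] /
#'   [read_gene_info()]).
#' @param vcf VCF path or a SNP tibble from [read_snp_catalog()].
#' @param pwms TRANSFAC-dialect path or a [pwm_library()] tibble.
#' @param db optional path for a persistent store; the tables are always
#'   available in the returned object.
#' @param upstream_bp,downstream_bp promoter extents (defaults 7500/2500).
#' @param half_width flank half-width (default 25, i.e. 51-bp flanks).
#' @param digits score comparison precision for classification.
#' @param cutoff_profile optional path to a per-matrix cutoff profile
#'   ([read_cutoff_profile()]).
#' @return an object of class `rsnp_scan`: a list with `tables` (the four
#'   result tibbles), `flanks`, `counts`, `n_rsnps` and `params`. Use
#'   [tidy()] for the consequence records and [glance()] for a one-row
#'   summary.
#' @export
run_pipeline <- function(genome, annotation, vcf, pwms, db = NULL,
                         upstream_bp = 7500, downstream_bp = 2500,
                         half_width = 25, digits = score_digits(),
                         cutoff_profile = NULL) {
  if (is.character(genome)) genome <- read_genome(genome)
  lens <- chrom_lengths(genome)
  if (is.character(annotation)) {
    transcripts <- read_transcript_tss(annotation, chrom_lengths = lens)
    genes <- read_gene_info(annotation, chrom_lengths = lens)
  } else {
    transcripts <- annotation$transcripts
    genes <- annotation$genes
  }
  snps <- if (is.character(vcf)) read_snp_catalog(vcf) else as_tibble(vcf)
  if (is.character(pwms)) pwms <- read_pwm_library(pwms, dialect = "transfac")
  if (!is.null(cutoff_profile)) {
    pwms <- apply_cutoff_profile(pwms, read_cutoff_profile(cutoff_profile))
  }

  windows <- promoter_windows(transcripts, upstream_bp = upstream_bp,
                              downstream_bp = downstream_bp,
                              chrom_lengths = lens)
  region <- map_snps_to_promoters(windows, snps)
  promoter_snps <- snps[snps$snp_id %in% region$snp_id, ]
  flanks <- extract_flanks(genome, promoter_snps, half_width = half_width)
  tfbs <- annotate_consequences(pwms, flanks, digits = digits)

  tables <- list(
    snp_info = snps[, c("snp_id", "chrom", "pos", "ref", "alt")],
    gene_info = genes[, c("gene_id", "gene_name", "chrom", "start", "end", "strand")],
    snp_region = region[, c("snp_id", "gene_id", "transcript_id", "dist_tss")],
    tfbs_results = tfbs[, c("snp_id", "pwm_id", "strand", "start",
                            "allele_presence", "ref_mss", "ref_css",
                            "alt_mss", "alt_css", "consequence")]
  )
  if (!is.null(db)) {
    con <- create_store(db)
    on.exit(DBI::dbDisconnect(con), add = TRUE)
    write_results(con, tables$snp_info, tables$gene_info, tables$snp_region,
                  tables$tfbs_results)
  }
  rsnps <- unique(tfbs$snp_id[tfbs$consequence %in% c("loss", "gain", "score_change")])
  out <- list(
    tables = tables,
    flanks = flanks,
    counts = vapply(tables, nrow, integer(1)),
    n_rsnps = length(rsnps),
    rsnp_ids = sort(rsnps),
    db = db,
    params = list(upstream_bp = upstream_bp, downstream_bp = downstream_bp,
                  half_width = half_width, digits = digits)
  )
  class(out) <- "rsnp_scan"
  out
}

#' @exportS3Method base::print
print.rsnp_scan <- function(x, ...) {
  cat("rSNP scan\n")
  cat(sprintf("  promoter window : -%d / +%d bp around the TSS\n",
              x$params$upstream_bp, x$params$downstream_bp))
  cat(sprintf("  snp_info        : %d SNPs\n", x$counts[["snp_info"]]))
  cat(sprintf("  gene_info       : %d genes\n", x$counts[["gene_info"]]))
  cat(sprintf("  snp_region      : %d SNP-promoter pairs\n", x$counts[["snp_region"]]))
  cat(sprintf("  tfbs_results    : %d SNP-site consequence records\n",
              x$counts[["tfbs_results"]]))
  cat(sprintf("  rSNPs           : %d\n", x$n_rsnps))
  invisible(x)
}

#' Tidy the consequence records of a pipeline run
#'
#' @param x an `rsnp_scan` object.
#' @param ... ignored.
#' @return the `tfbs_results` tibble.
#' @export
tidy.rsnp_scan <- function(x, ...) {
  x$tables$tfbs_results
}

#' One-row summary of a pipeline run
#'
#' @param x an `rsnp_scan` object.
#' @param ... ignored.
#' @return one-row tibble with table counts, rSNP count and the consequence
#'   class breakdown.
#' @export
glance.rsnp_scan <- function(x, ...) {
  cons <- x$tables$tfbs_results$consequence
  tibble(
    n_snps = x$counts[["snp_info"]],
    n_genes = x$counts[["gene_info"]],
    n_snp_region = x$counts[["snp_region"]],
    n_tfbs_records = x$counts[["tfbs_results"]],
    n_rsnps = x$n_rsnps,
    n_loss = sum(cons == "loss"),
    n_gain = sum(cons == "gain"),
    n_score_change = sum(cons == "score_change"),
    n_no_effect = sum(cons == "no_effect")
  )
}
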