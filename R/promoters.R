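#' Build strand-aware promoter windows around TSSs
#'
#' The promoter of a transcript spans `upstream_bp` bases 5' of the TSS and
#' `downstream_bp` bases 3' of it, in the direction of transcription
#' (defaults 7.5 kb upstream, 2.5 kb downstream). On the + strand the window
#' is `[tss - upstream_bp, tss + downstream_bp]`; on the - strand it is
#' mirrored. Windows are clipped to `[1, chromosome length]`.
#'
#' @param transcripts tibble as from [read_transcript_tss()] (requires
#'   `chrom`, `strand`, `tss`; id columns are carried through).
#' @param upstream_bp,downstream_bp non-negative extents in bp.
#' @param chrom_lengths optional named vector used to clip window ends.
#' @return the input with added columns `start`, `end` (1-based closed
#'   genomic bounds) and `upstream_bp`, `downstream_bp`.
#' @export
promoter_windows <- function(transcripts, upstream_bp = 7500,
                             downstream_bp = 2500, chrom_lengths = NULL) {
  assert_cols(transcripts, c("chrom", "strand", "tss"), "transcripts")
  if (upstream_bp < 0 || downstream_bp < 0) {
    abort("upstream_bp and downstream_bp must be non-negative")
  }
  w <- as_tibble(transcripts)
  plus <- w$strand == "+"
  w$start <- pmax(1L, as.integer(ifelse(plus, w$tss - upstream_bp, w$tss - downstream_bp)))
  w$end <- as.integer(ifelse(plus, w$tss + downstream_bp, w$tss + upstream_bp))
  if (!is.null(chrom_lengths)) {
    len <- unname(chrom_lengths[w$chrom])
    if (anyNA(len)) {
      abort(sprintf("chromosome(s) missing from chrom_lengths: %s",
                    paste(unique(w$chrom[is.na(len)]), collapse = ", ")))
    }
    w$end <- pmin(w$end, as.integer(len))
  }
  w$upstream_bp <- as.integer(upstream_bp)
  w$downstream_bp <- as.integer(downstream_bp)
  w
}

#' Assign SNPs to the promoter windows containing them
#'
#' Emits one row per (SNP, window) containment pair: a SNP falling in k
#' overlapping promoters yields k rows. The signed TSS distance is measured
#' in the direction of transcription — `pos - tss` on the + strand,
#' `tss - pos` on the - strand — so negative values lie upstream of the TSS
#' and 0 is the TSS base itself.
#'
#' @param windows tibble from [promoter_windows()].
#' @param snps tibble from [read_snp_catalog()].
#' @return tibble with columns `snp_id`, `gene_id`, `gene_name`,
#'   `transcript_id`, `chrom`, `pos`, `strand`, `tss`, `dist_tss`.
#' @export
map_snps_to_promoters <- function(windows, snps) {
  assert_cols(windows, c("chrom", "strand", "tss", "start", "end"), "windows")
  assert_cols(snps, c("snp_id", "chrom", "pos"), "snps")
  if (nrow(windows) == 0 || nrow(snps) == 0) {
    return(tibble(snp_id = character(0), gene_id = character(0),
                  gene_name = character(0), transcript_id = character(0),
                  chrom = character(0), pos = integer(0), strand = character(0),
                  tss = integer(0), dist_tss = integer(0)))
  }
  w_gr <- GenomicRanges::GRanges(windows$chrom,
                                 IRanges::IRanges(windows$start, windows$end))
  s_gr <- GenomicRanges::GRanges(snps$chrom, IRanges::IRanges(snps$pos, snps$pos))
  ov <- GenomicRanges::findOverlaps(s_gr, w_gr, ignore.strand = TRUE)
  si <- S4Vectors::queryHits(ov)
  wi <- S4Vectors::subjectHits(ov)
  out <- tibble(
    snp_id = snps$snp_id[si],
    gene_id = (windows$gene_id %||% rep(NA_character_, nrow(windows)))[wi],
    gene_name = (windows$gene_name %||% rep(NA_character_, nrow(windows)))[wi],
    transcript_id = (windows$transcript_id %||% rep(NA_character_, nrow(windows)))[wi],
    chrom = snps$chrom[si],
    pos = snps$pos[si],
    strand = windows$strand[wi],
    tss = windows$tss[wi],
    dist_tss = as.integer(ifelse(windows$strand[wi] == "+",
                                 snps$pos[si] - windows$tss[wi],
                                 windows$tss[wi] - snps$pos[si]))
  )
  dplyr::arrange(out, .data$chrom, .data$pos, .data$gene_id, .data$transcript_id)
}

#' Export promoter windows as BED
#'
#' BED uses 0-based half-open coordinates; internal coordinates are 1-based
#' closed, so starts are shifted by one.
#'
#' @param windows tibble from [promoter_windows()].
#' @param path output file.
#' @return the path, invisibly.
#' @export
windows_to_bed <- function(windows, path) {
  assert_cols(windows, c("chrom", "start", "end", "strand"), "windows")
  bed <- tibble(
    chrom = windows$chrom,
    start = windows$start - 1L,
    end = windows$end,
    name = windows$transcript_id %||% ".",
    score = 0L,
    strand = windows$strand
  )
  readr::write_tsv(bed, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}
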