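#' Extract reference and alternate flanking sequences around SNPs
#'
#' For each SNP the reference flank spans `half_width` bases on each side of
#' the SNP (51 bp total with the default 25, SNP at position 26); the
#' alternate flank is identical except for the alternate allele at the SNP
#' position. Flanks truncated by a chromosome end are discarded with status
#' `"short"`, flanks containing a non-ACGT character (assembly gaps) with
#' status `"gap"`, and SNPs whose stated reference allele disagrees with the
#' genome base with status `"ref_mismatch"` (a sign of catalog/assembly
#' version drift). Sequences are uppercased, so soft-masked bases are kept.
#'
#' @param genome [Biostrings::DNAStringSet] from [read_genome()].
#' @param snps tibble with `snp_id`, `chrom`, `pos`, `ref`, `alt`.
#' @param half_width flank half-width in bp (default 25).
#' @return the input rows with added columns `ref_seq`, `alt_seq` (NA for
#'   discarded rows), `snp_index` (= `half_width + 1`) and `status` in
#'   `ok`, `short`, `gap`, `ref_mismatch`. Discard counts are reported.
#' @export
extract_flanks <- function(genome, snps, half_width = 25) {
  assert_cols(snps, c("snp_id", "chrom", "pos", "ref", "alt"), "snps")
  missing_chrom <- setdiff(unique(snps$chrom), names(genome))
  if (length(missing_chrom) > 0) {
    abort(sprintf("chromosome(s) absent from the genome: %s",
                  paste(missing_chrom, collapse = ", ")))
  }
  hw <- as.integer(half_width)
  idx <- hw + 1L
  out <- as_tibble(snps)
  out$ref_seq <- NA_character_
  out$alt_seq <- NA_character_
  out$snp_index <- idx
  out$status <- "ok"

  for (ch in unique(out$chrom)) {
    rows <- which(out$chrom == ch)
    chrom_seq <- toupper(as.character(genome[[ch]]))
    len <- nchar(chrom_seq)
    pos <- out$pos[rows]
    short <- pos - hw < 1L | pos + hw > len
    out$status[rows[short]] <- "short"
    ok <- rows[!short]
    if (length(ok) == 0) next
    seqs <- substring(chrom_seq, out$pos[ok] - hw, out$pos[ok] + hw)
    gap <- grepl("[^ACGT]", seqs)
    mism <- !gap & substring(seqs, idx, idx) != out$ref[ok]
    out$status[ok[gap]] <- "gap"
    out$status[ok[mism]] <- "ref_mismatch"
    keep <- !gap & !mism
    out$ref_seq[ok[keep]] <- seqs[keep]
    alt <- seqs[keep]
    substring(alt, idx, idx) <- out$alt[ok[keep]]
    out$alt_seq[ok[keep]] <- alt
  }

  dropped <- table(out$status[out$status != "ok"])
  if (length(dropped) > 0) {
    inform(sprintf("discarded %d flank(s): %s", sum(dropped),
                   paste(sprintf("%s=%d", names(dropped), dropped), collapse = ", ")))
  }
  out
}
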