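#' Read a reference genome
#'
#' @param path FASTA file (optionally gzipped).
#' @return a [Biostrings::DNAStringSet] named by chromosome (FASTA
#'   descriptions after the first whitespace are dropped).
#' @export
read_genome <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

#' Chromosome lengths of a genome
#'
#' @param genome a [Biostrings::DNAStringSet] as from [read_genome()].
#' @return named integer vector of sequence lengths.
#' @export
chrom_lengths <- function(genome) {
  setNames(Biostrings::width(genome), names(genome))
}

#' Load transcripts and their transcription start sites
#'
#' Reads a GFF3 or GTF annotation and returns one row per transcript with
#' its TSS: the feature start on the + strand, the feature end on the -
#' strand. Transcript isoforms of the same gene that share chromosome,
#' strand and TSS are collapsed to a single entry (their promoters would be
#' identical); isoforms with distinct TSSs are kept as separate entries.
#'
#' @param path annotation file; format is inferred from the extension
#'   (`.gff`, `.gff3`, `.gtf`, optionally gzipped).
#' @param chrom_lengths optional named vector (see [chrom_lengths()]); when
#'   supplied, transcripts on chromosomes absent from it are skipped with a
#'   warning.
#' @return tibble with columns `gene_id`, `gene_name`, `transcript_id`,
#'   `chrom`, `strand`, `start`, `end`, `tss`, `n_isoforms` (number of
#'   transcripts collapsed into the row).
#' @export
read_transcript_tss <- function(path, chrom_lengths = NULL) {
  gr <- rtracklayer::import(path)
  md <- S4Vectors::mcols(gr)
  type <- as.character(md$type)
  is_tx <- type %in% c("mRNA", "transcript") | grepl("_transcript$", type)
  tx <- gr[is_tx]
  if (length(tx) == 0) abort("annotation contains no transcript/mRNA features")
  mtx <- S4Vectors::mcols(tx)

  gene_id <- if (!is.null(mtx$gene_id)) as.character(mtx$gene_id) else NA_character_
  if (all(is.na(gene_id)) || is.null(mtx$gene_id)) {
    gene_id <- first_or_na(mtx$Parent)
  } else {
    need <- is.na(gene_id)
    if (any(need)) gene_id[need] <- first_or_na(mtx$Parent)[need]
  }
  gene_id <- sub("^gene:", "", gene_id)

  transcript_id <- if (!is.null(mtx$transcript_id)) {
    as.character(mtx$transcript_id)
  } else {
    as.character(mtx$ID)
  }

  gene_name <- rep(NA_character_, length(tx))
  if (!is.null(mtx$gene_name)) gene_name <- as.character(mtx$gene_name)
  # fall back to the Name attribute of gene features, then to gene_id
  genes <- gr[type == "gene"]
  if (length(genes) > 0) {
    mg <- S4Vectors::mcols(genes)
    gid <- sub("^gene:", "", if (!is.null(mg$gene_id) && !all(is.na(mg$gene_id)))
      as.character(mg$gene_id) else as.character(mg$ID))
    gname <- if (!is.null(mg$Name)) as.character(mg$Name) else gid
    lookup <- setNames(gname, gid)
    need <- is.na(gene_name)
    gene_name[need] <- unname(lookup[gene_id[need]])
  }
  gene_name <- ifelse(is.na(gene_name), gene_id, gene_name)

  out <- tibble(
    gene_id = gene_id,
    gene_name = gene_name,
    transcript_id = transcript_id,
    chrom = as.character(GenomicRanges::seqnames(tx)),
    strand = as.character(GenomicRanges::strand(tx)),
    start = GenomicRanges::start(tx),
    end = GenomicRanges::end(tx)
  )

  no_strand <- !out$strand %in% c("+", "-")
  if (any(no_strand)) {
    warn(sprintf("skipped %d transcript(s) without a strand", sum(no_strand)))
    out <- out[!no_strand, ]
  }
  if (!is.null(chrom_lengths)) {
    off <- !out$chrom %in% names(chrom_lengths)
    if (any(off)) {
      warn(sprintf("skipped %d transcript(s) on chromosomes absent from the genome: %s",
                   sum(off), paste(unique(out$chrom[off]), collapse = ", ")))
      out <- out[!off, ]
    }
  }
  if (nrow(out) == 0) abort("no usable transcripts after filtering")

  out$tss <- ifelse(out$strand == "+", out$start, out$end)
  out |>
    dplyr::arrange(.data$chrom, .data$tss, .data$gene_id, .data$transcript_id) |>
    dplyr::group_by(.data$gene_id, .data$chrom, .data$strand, .data$tss) |>
    dplyr::summarise(
      gene_name = dplyr::first(.data$gene_name),
      transcript_id = dplyr::first(.data$transcript_id),
      start = min(.data$start),
      end = max(.data$end),
      n_isoforms = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::select("gene_id", "gene_name", "transcript_id", "chrom", "strand",
                  "start", "end", "tss", "n_isoforms") |>
    dplyr::arrange(.data$chrom, .data$tss, .data$gene_id)
}

first_or_na <- function(x) {
  if (is.null(x)) return(NA_character_)
  vapply(as.list(x), function(p) if (length(p) > 0) as.character(p[[1]]) else NA_character_,
         character(1))
}

#' Gene-level annotation table
#'
#' One row per gene with its name and genomic span, for the `gene_info`
#' store table. Uses explicit gene features when the annotation has them and
#' otherwise summarizes transcript spans.
#'
#' @inheritParams read_transcript_tss
#' @return tibble with columns `gene_id`, `gene_name`, `chrom`, `start`,
#'   `end`, `strand`.
#' @export
read_gene_info <- function(path, chrom_lengths = NULL) {
  gr <- rtracklayer::import(path)
  md <- S4Vectors::mcols(gr)
  type <- as.character(md$type)
  genes <- gr[type == "gene"]
  if (length(genes) > 0) {
    mg <- S4Vectors::mcols(genes)
    gid <- sub("^gene:", "", if (!is.null(mg$gene_id) && !all(is.na(mg$gene_id)))
      as.character(mg$gene_id) else as.character(mg$ID))
    gname <- if (!is.null(mg$Name)) as.character(mg$Name) else
      if (!is.null(mg$gene_name)) as.character(mg$gene_name) else gid
    out <- tibble(
      gene_id = gid,
      gene_name = ifelse(is.na(gname), gid, gname),
      chrom = as.character(GenomicRanges::seqnames(genes)),
      start = GenomicRanges::start(genes),
      end = GenomicRanges::end(genes),
      strand = as.character(GenomicRanges::strand(genes))
    )
  } else {
    tx <- read_transcript_tss(path, chrom_lengths = chrom_lengths)
    out <- tx |>
      dplyr::group_by(.data$gene_id) |>
      dplyr::summarise(
        gene_name = dplyr::first(.data$gene_name),
        chrom = dplyr::first(.data$chrom),
        start = min(.data$start),
        end = max(.data$end),
        strand = dplyr::first(.data$strand),
        .groups = "drop"
      )
  }
  if (!is.null(chrom_lengths)) out <- out[out$chrom %in% names(chrom_lengths), ]
  dplyr::arrange(out, .data$chrom, .data$start, .data$gene_id)
}

#' Load a SNP catalog from VCF
#'
#' Keeps only biallelic substitutions: insertions, deletions and symbolic
#' alleles are discarded, and multiallelic records are split into one record
#' per alternate allele before filtering. Records without an identifier
#' receive a synthetic `chrom:pos:ref:alt` id.
#'
#' @param path VCF file (plain or bgzipped).
#' @return tibble with columns `snp_id`, `chrom`, `pos`, `ref`, `alt`.
#'   The discarded allele pairs are attached as the `discarded` attribute
#'   (a tibble with a `reason` column) and their count is reported.
#' @export
read_snp_catalog <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- v@fix[, c("CHROM", "POS", "ID", "REF", "ALT"), drop = FALSE]
  df <- tibble(
    chrom = as.character(fix[, "CHROM"]),
    pos = as.integer(fix[, "POS"]),
    id = as.character(fix[, "ID"]),
    ref = toupper(as.character(fix[, "REF"])),
    alt = toupper(as.character(fix[, "ALT"]))
  )
  df <- tidyr::separate_rows(df, "alt", sep = ",")
  n_pairs <- nrow(df)

  keep <- nchar(df$ref) == 1 & nchar(df$alt) == 1 &
    df$ref %in% DNA_BASES & df$alt %in% DNA_BASES & df$ref != df$alt
  discarded <- df[!keep, ]
  discarded$reason <- dplyr::case_when(
    nchar(discarded$ref) != 1 | nchar(discarded$alt) != 1 ~ "indel",
    !(discarded$ref %in% DNA_BASES) | !(discarded$alt %in% DNA_BASES) ~ "symbolic_or_ambiguous",
    TRUE ~ "ref_equals_alt"
  )
  out <- df[keep, ]
  no_id <- is.na(out$id) | out$id %in% c("", ".")
  out$snp_id <- ifelse(no_id,
                       paste(out$chrom, out$pos, out$ref, out$alt, sep = ":"),
                       out$id)
  out <- dplyr::select(out, "snp_id", "chrom", "pos", "ref", "alt")
  if (nrow(discarded) > 0) {
    inform(sprintf("discarded %d of %d allele pair(s) (non-SNP alleles)",
                   nrow(discarded), n_pairs))
  }
  attr(out, "discarded") <- as_tibble(discarded)
  out
}
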