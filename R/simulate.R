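#' Generate a synthetic fixture with planted regulatory SNPs
#'
#' Writes a fully synthetic genome (FASTA), gene annotation (GFF3), SNP
#' catalog (VCF) and PWM library (TRANSFAC dialect) plus a JSON manifest of
#' planted ground truth, so the whole pipeline can be exercised without any
#' external download. Background sequence is i.i.d. with configurable GC
#' content; genes are placed non-overlapping so each SNP belongs to exactly
#' one promoter.
#'
#' Planted events use near-deterministic PWMs (consensus base frequency
#' 0.91, others 0.03) whose consensus is written across the SNP so that a
#' single mismatch reliably crosses the default cutoffs:
#' \itemize{
#'   \item \strong{loss}: the genome carries the consensus; the alternate
#'     allele breaks it, so the site is predicted for the reference only.
#'   \item \strong{gain}: mirrored — the reference breaks the consensus and
#'     the alternate completes it.
#'   \item \strong{score_change}: the matrix column at the SNP tolerates two
#'     bases (frequencies 0.55/0.36), keeping both alleles above cutoff with
#'     distinct scores.
#' }
#' Half of the events are planted on the reverse strand. After planting,
#' every SNP flank is re-scanned and background (non-motif, non-SNP) bases
#' are deterministically resampled in the rare case a chance motif match
#' would make the manifest incomplete; the output is therefore exact ground
#' truth. Everything is deterministic under `seed`.
#'
#' @param dir output directory (created if needed).
#' @param seed integer RNG seed.
#' @param n_chroms,chrom_len number and length (bp) of chromosomes.
#' @param n_genes total genes, distributed across chromosomes.
#' @param n_snps total SNPs: the planted ones, one neutral SNP per remaining
#'   gene promoter, and any remainder placed outside all promoters.
#' @param n_pwms library size; must cover the planted events, the rest are
#'   unplanted decoys.
#' @param plant named integer vector with desired counts per consequence
#'   class (`loss`, `gain`, `score_change`).
#' @param upstream,downstream promoter extents (bp) the fixture is designed
#'   for.
#' @param motif_width width of generated PWMs; must not exceed
#'   `half_width + 1` so a SNP-overlapping site always fits in the flank.
#' @param half_width flank half-width the pipeline will use.
#' @param gc background GC content in (0, 1).
#' @return invisibly, a list with `dir`, `paths` (named file paths), `seed`,
#'   `params`, `events` (tibble of planted events: `snp_id`, `gene_id`,
#'   `pwm_id`, `chrom`, `pos`, `strand`, `expected_start`,
#'   `expected_consequence`, `dist_tss`) and `counts` (per-chromosome gene
#'   and SNP totals).
#' @export
simulate_fixture <- function(dir, seed = 1L, n_chroms = 3L, chrom_len = 300000L,
                             n_genes = 30L, n_snps = 40L, n_pwms = 18L,
                             plant = c(loss = 5L, gain = 5L, score_change = 5L),
                             upstream = 7500L, downstream = 2500L,
                             motif_width = 10L, half_width = 25L, gc = 0.5) {
  plant <- plant[c("loss", "gain", "score_change")]
  plant[is.na(plant)] <- 0L
  names(plant) <- c("loss", "gain", "score_change")
  n_ev <- sum(plant)
  if (n_pwms < n_ev) abort("n_pwms must be at least the number of planted events")
  if (n_genes < n_ev) abort("n_genes must be at least the number of planted events")
  if (n_snps < n_ev) abort("n_snps must be at least the number of planted events")
  if (motif_width < 3) abort("motif_width must be at least 3")
  if (motif_width > half_width + 1L) {
    abort("motif_width must not exceed half_width + 1, or planted sites cannot fit the flank")
  }
  withr::local_seed(as.integer(seed), .rng_kind = "Mersenne-Twister",
                    .rng_normal_kind = "Inversion", .rng_sample_kind = "Rejection")

  ## gene layout: evenly spread, promoters disjoint
  chrom_names <- sprintf("chr%d", seq_len(n_chroms))
  gene_chrom_idx <- sort(rep_len(seq_len(n_chroms), n_genes))
  tss0 <- upstream + 600L
  step <- upstream + downstream + 5100L
  genes <- tibble(
    gene_id = sprintf("G%04d", seq_len(n_genes)),
    gene_name = paste0("gene", seq_len(n_genes)),
    transcript_id = sprintf("T%04d", seq_len(n_genes)),
    chrom = chrom_names[gene_chrom_idx],
    strand = rep_len(c("+", "-"), n_genes)
  )
  genes$tss <- unlist(lapply(split(seq_len(n_genes), gene_chrom_idx), function(ix) {
    tss0 + (seq_along(ix) - 1L) * step
  }), use.names = FALSE)
  if (any(genes$tss + upstream + 600L > chrom_len)) {
    abort("chrom_len too small for n_genes; increase chrom_len or reduce n_genes")
  }
  genes$start <- ifelse(genes$strand == "+", genes$tss, genes$tss - 1500L)
  genes$end <- ifelse(genes$strand == "+", genes$tss + 1500L, genes$tss)

  ## background genome as per-chromosome character vectors
  p_bg <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  chrom_seq <- lapply(seq_len(n_chroms), function(i) {
    sample(DNA_BASES, chrom_len, replace = TRUE, prob = p_bg)
  })
  names(chrom_seq) <- chrom_names

  ## PWMs: planted first, then decoys
  consensus <- replicate(n_pwms, sample(DNA_BASES, motif_width, replace = TRUE),
                         simplify = FALSE)
  pwm_ids <- sprintf("V$SIM%03d_01", seq_len(n_pwms))
  event_type <- rep(names(plant), times = plant)
  snp_offset <- integer(n_pwms)   # motif position over the SNP, planted PWMs only
  counts_list <- vector("list", n_pwms)
  alt_motif_base <- character(n_pwms)
  for (k in seq_len(n_pwms)) {
    cons <- consensus[[k]]
    m <- matrix(3L, nrow = motif_width, ncol = 4, dimnames = list(NULL, DNA_BASES))
    m[cbind(seq_len(motif_width), match(cons, DNA_BASES))] <- 91L
    if (k <= n_ev) {
      j <- sample(2:(motif_width - 1L), 1)
      snp_offset[k] <- j
      others <- setdiff(DNA_BASES, cons[j])
      if (event_type[k] == "score_change") {
        second <- sample(others, 1)
        rest <- setdiff(others, second)
        m[j, ] <- 0L
        m[j, cons[j]] <- 55L
        m[j, second] <- 36L
        m[j, rest[1]] <- 6L
        m[j, rest[2]] <- 3L
        alt_motif_base[k] <- second
      } else {
        alt_motif_base[k] <- sample(others, 1)
      }
    }
    counts_list[[k]] <- m
  }

  ## planted events: one per gene, genes 1..n_ev
  events <- tibble(
    type = event_type,
    pwm_id = pwm_ids[seq_len(n_ev)],
    gene_row = seq_len(n_ev)
  )
  snp_rows <- vector("list", 0)
  dist_pool <- c(seq(-upstream + 600L, -300L, by = 1L), seq(300L, downstream - 600L, by = 1L))
  for (e in seq_len(n_ev)) {
    g <- genes[events$gene_row[e], ]
    L <- motif_width
    j <- snp_offset[e]
    cons <- consensus[[e]]
    dist <- sample(dist_pool, 1)
    pos <- if (g$strand == "+") g$tss + dist else g$tss - dist
    orient <- if (e %% 2L == 1L) "+" else "-"

    motif <- cons
    genome_base_motif <- switch(events$type[e],
      loss = cons[j],
      gain = alt_motif_base[e],
      score_change = cons[j]
    )
    alt_base_motif <- switch(events$type[e],
      loss = alt_motif_base[e],
      gain = cons[j],
      score_change = alt_motif_base[e]
    )
    motif[j] <- genome_base_motif

    if (orient == "+") {
      s <- pos - j + 1L
      written <- motif
      ref_fwd <- genome_base_motif
      alt_fwd <- alt_base_motif
    } else {
      s <- pos - (L - j)
      written <- rev(comp_base(motif))
      ref_fwd <- comp_base(genome_base_motif)
      alt_fwd <- comp_base(alt_base_motif)
    }
    chrom_seq[[g$chrom]][s:(s + L - 1L)] <- written

    snp_rows[[length(snp_rows) + 1]] <- tibble(
      chrom = g$chrom, pos = pos, ref = ref_fwd, alt = alt_fwd,
      kind = "planted", event = e,
      gene_id = g$gene_id, pwm_id = events$pwm_id[e],
      expected_strand = orient,
      expected_start = if (orient == "+") half_width + 2L - j else half_width + 1L - L + j,
      expected_consequence = events$type[e],
      dist_tss = dist, motif_start = s, motif_end = s + L - 1L
    )
  }

  ## neutral promoter SNPs: one per remaining gene
  n_neutral <- min(n_genes, n_snps) - n_ev
  if (n_neutral > 0) {
    for (g_idx in seq(n_ev + 1L, n_ev + n_neutral)) {
      g <- genes[g_idx, ]
      dist <- sample(dist_pool, 1)
      pos <- if (g$strand == "+") g$tss + dist else g$tss - dist
      ref <- chrom_seq[[g$chrom]][pos]
      alt <- sample(setdiff(DNA_BASES, ref), 1)
      snp_rows[[length(snp_rows) + 1]] <- tibble(
        chrom = g$chrom, pos = pos, ref = ref, alt = alt,
        kind = "neutral_promoter", event = NA_integer_,
        gene_id = g$gene_id, pwm_id = NA_character_,
        expected_strand = NA_character_, expected_start = NA_integer_,
        expected_consequence = "none", dist_tss = dist,
        motif_start = NA_integer_, motif_end = NA_integer_
      )
    }
  }

  ## intergenic SNPs in the tail of each chromosome, beyond every promoter
  n_inter <- n_snps - n_ev - n_neutral
  if (n_inter > 0) {
    last_prom_end <- max(genes$tss) + upstream + downstream
    base_pos <- last_prom_end + 2000L
    if (base_pos + n_inter * 200L + half_width >= chrom_len) {
      abort("chrom_len too small to place intergenic SNPs clear of promoters")
    }
    for (k in seq_len(n_inter)) {
      ch <- chrom_names[((k - 1L) %% n_chroms) + 1L]
      pos <- base_pos + ((k - 1L) %/% n_chroms) * 200L
      ref <- chrom_seq[[ch]][pos]
      alt <- sample(setdiff(DNA_BASES, ref), 1)
      snp_rows[[length(snp_rows) + 1]] <- tibble(
        chrom = ch, pos = pos, ref = ref, alt = alt,
        kind = "intergenic", event = NA_integer_,
        gene_id = NA_character_, pwm_id = NA_character_,
        expected_strand = NA_character_, expected_start = NA_integer_,
        expected_consequence = "none", dist_tss = NA_integer_,
        motif_start = NA_integer_, motif_end = NA_integer_
      )
    }
  }

  snps <- dplyr::bind_rows(snp_rows)
  snps <- dplyr::arrange(snps, .data$chrom, .data$pos)
  snps$snp_id <- sprintf("rs%07d", 1000000L + seq_len(nrow(snps)))

  ## library as the parser will see it (counts/100 are exact frequencies)
  lib <- pwm_library(pwm_ids, counts_list)

  ## scrub chance motif matches so the manifest is complete ground truth
  chrom_seq <- scrub_accidental_hits(chrom_seq, snps, lib, half_width, p_bg)

  ## write files
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    genome = file.path(dir, "genome.fa"),
    annotation = file.path(dir, "genes.gff3"),
    vcf = file.path(dir, "snps.vcf"),
    pwms = file.path(dir, "pwms.transfac"),
    manifest = file.path(dir, "manifest.json")
  )
  dna <- Biostrings::DNAStringSet(vapply(chrom_seq, paste, "", collapse = ""))
  names(dna) <- chrom_names
  Biostrings::writeXStringSet(dna, paths$genome, width = 70L)
  write_fixture_gff3(genes, paths$annotation)
  write_fixture_vcf(snps, setNames(rep(chrom_len, n_chroms), chrom_names), paths$vcf)
  write_fixture_transfac(pwm_ids, counts_list, paths$pwms)

  events_out <- snps[snps$kind == "planted",
                     c("snp_id", "gene_id", "pwm_id", "chrom", "pos",
                       "expected_strand", "expected_start",
                       "expected_consequence", "dist_tss")]
  names(events_out)[names(events_out) == "expected_strand"] <- "strand"
  counts <- snps |>
    dplyr::count(.data$chrom, name = "n_snps") |>
    dplyr::left_join(dplyr::count(genes, .data$chrom, name = "n_genes"), by = "chrom")
  manifest <- list(
    seed = as.integer(seed),
    params = list(n_chroms = n_chroms, chrom_len = chrom_len, n_genes = n_genes,
                  n_snps = nrow(snps), n_pwms = n_pwms, plant = as.list(plant),
                  upstream = upstream, downstream = downstream,
                  motif_width = motif_width, half_width = half_width, gc = gc),
    counts = counts,
    events = events_out,
    neutral_snp_ids = snps$snp_id[snps$kind != "planted"]
  )
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(list(dir = dir, paths = paths, seed = as.integer(seed),
                 params = manifest$params, genes = genes, snps = snps,
                 events = events_out, counts = counts))
}

# rescan every SNP flank; resample background bases wherever an unplanned
# (snp, allele, pwm, start, strand) hit appears, so planted events are the
# complete truth
scrub_accidental_hits <- function(chrom_seq, snps, lib, half_width, p_bg) {
  expected_keys <- function(row) {
    if (row$kind != "planted") return(character(0))
    key <- paste(row$pwm_id, row$expected_start, row$expected_strand)
    switch(row$expected_consequence,
      loss = paste("ref", key),
      gain = paste("alt", key),
      score_change = c(paste("ref", key), paste("alt", key))
    )
  }
  for (iter in 1:30) {
    dirty <- FALSE
    for (i in seq_len(nrow(snps))) {
      row <- snps[i, ]
      lo <- row$pos - half_width
      hi <- row$pos + half_width
      if (lo < 1 || hi > length(chrom_seq[[row$chrom]])) next
      ref_seq <- paste(chrom_seq[[row$chrom]][lo:hi], collapse = "")
      alt_seq <- ref_seq
      substring(alt_seq, half_width + 1L, half_width + 1L) <- row$alt
      hits <- scan_alleles(lib, ref_seq, alt_seq, snp_index = half_width + 1L)
      got <- paste(hits$allele, hits$pwm_id, hits$start, hits$strand)
      extra <- setdiff(got, expected_keys(row))
      missing <- setdiff(expected_keys(row), got)
      if (length(missing) > 0) {
        abort(sprintf("planted event for %s not recoverable; infeasible plant",
                      row$chrom))
      }
      if (length(extra) > 0) {
        dirty <- TRUE
        resample <- setdiff(lo:hi, row$pos)
        if (!is.na(row$motif_start)) {
          resample <- setdiff(resample, row$motif_start:row$motif_end)
        }
        chrom_seq[[row$chrom]][resample] <-
          sample(DNA_BASES, length(resample), replace = TRUE, prob = p_bg)
      }
    }
    if (!dirty) return(chrom_seq)
  }
  abort("could not scrub accidental motif matches after 30 passes")
}

write_fixture_gff3 <- function(genes, path) {
  lines <- c("##gff-version 3")
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    lines <- c(lines,
      sprintf("%s\trsnpscan\tgene\t%d\t%d\t.\t%s\t.\tID=%s;Name=%s",
              g$chrom, g$start, g$end, g$strand, g$gene_id, g$gene_name),
      sprintf("%s\trsnpscan\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
              g$chrom, g$start, g$end, g$strand, g$transcript_id, g$gene_id))
  }
  writeLines(lines, path)
}

write_fixture_vcf <- function(snps, chrom_len, path) {
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s,length=%d>", names(chrom_len), chrom_len),
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- sprintf("%s\t%d\t%s\t%s\t%s\t.\t.\t.",
                  snps$chrom, snps$pos, snps$snp_id, snps$ref, snps$alt)
  writeLines(c(hdr, body), path)
}

write_fixture_transfac <- function(ids, counts_list, path) {
  lines <- c("VV  rsnpscan synthetic PWM library", "//")
  for (k in seq_along(ids)) {
    m <- counts_list[[k]]
    lines <- c(lines,
      sprintf("ID  %s", ids[k]),
      sprintf("P0%7s%7s%7s%7s", "A", "C", "G", "T"),
      sprintf("%02d%7d%7d%7d%7d", seq_len(nrow(m)),
              m[, "A"], m[, "C"], m[, "G"], m[, "T"]),
      "XX", "//")
  }
  writeLines(lines, path)
}
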