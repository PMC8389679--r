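# summary statistics over a populated store

rsnp_snp_ids <- function(con) {
  DBI::dbGetQuery(con, "SELECT DISTINCT snp_id FROM tfbs_results
                        WHERE consequence IN ('loss','gain','score_change')")$snp_id
}

#' Per-chromosome SNP, gene and rSNP counts
#'
#' @param con store connection from [create_store()].
#' @return tibble (class `chrom_counts`) with columns `chrom`, `n_snps`,
#'   `n_genes`, `n_rsnps`; chromosomes known only from one table appear with
#'   zeros in the others.
#' @export
per_chromosome_counts <- function(con) {
  si <- read_store_table(con, "snp_info")
  gi <- read_store_table(con, "gene_info")
  rs <- rsnp_snp_ids(con)
  chroms <- sort(unique(c(si$chrom, gi$chrom)))
  out <- tibble(
    chrom = chroms,
    n_snps = vapply(chroms, function(ch) sum(si$chrom == ch), integer(1),
                    USE.NAMES = FALSE),
    n_genes = vapply(chroms, function(ch) sum(gi$chrom == ch), integer(1),
                     USE.NAMES = FALSE),
    n_rsnps = vapply(chroms, function(ch) {
      sum(si$chrom == ch & si$snp_id %in% rs)
    }, integer(1), USE.NAMES = FALSE)
  )
  class(out) <- c("chrom_counts", class(out))
  out
}

#' Average rSNPs per gene, split by promoter side
#'
#' Counts distinct rSNP-gene pairs via `snp_region`, splitting each pair
#' into the upstream (`dist_tss < 0`) or downstream (`dist_tss >= 0`)
#' promoter, and averages over all genes of each chromosome (genes without
#' rSNPs count with zero). The overall mean — total distinct rSNP-gene
#' pairs divided by total genes — is attached as the `overall_mean`
#' attribute.
#'
#' @param con store connection.
#' @return tibble with columns `chrom`, `n_genes`, `mean_up`, `sd_up`,
#'   `mean_down`, `sd_down`; attribute `overall_mean`.
#' @export
rsnps_per_gene <- function(con) {
  gi <- read_store_table(con, "gene_info")
  sr <- read_store_table(con, "snp_region")
  rs <- rsnp_snp_ids(con)
  pairs <- sr[sr$snp_id %in% rs, c("snp_id", "gene_id", "dist_tss")]
  pairs$side <- ifelse(pairs$dist_tss < 0, "up", "down")
  pairs <- dplyr::distinct(pairs, .data$snp_id, .data$gene_id, .data$side)

  per_gene <- gi[, c("gene_id", "chrom")]
  cnt <- pairs |>
    dplyr::count(.data$gene_id, .data$side) |>
    tidyr::pivot_wider(names_from = "side", values_from = "n", values_fill = 0L)
  per_gene$up <- 0L
  per_gene$down <- 0L
  i <- match(per_gene$gene_id, cnt$gene_id)
  if ("up" %in% names(cnt)) per_gene$up[!is.na(i)] <- cnt$up[i[!is.na(i)]]
  if ("down" %in% names(cnt)) per_gene$down[!is.na(i)] <- cnt$down[i[!is.na(i)]]

  out <- per_gene |>
    dplyr::group_by(.data$chrom) |>
    dplyr::summarise(
      n_genes = dplyr::n(),
      mean_up = mean(.data$up), sd_up = sd(.data$up),
      mean_down = mean(.data$down), sd_down = sd(.data$down),
      .groups = "drop"
    )
  n_pairs <- nrow(dplyr::distinct(pairs, .data$snp_id, .data$gene_id))
  attr(out, "overall_mean") <- if (nrow(gi) > 0) n_pairs / nrow(gi) else NA_real_
  out
}

#' Histogram of rSNP distances to the TSS
#'
#' Bins the `dist_tss` of rSNP rows in `snp_region` into half-open
#' `[lo, lo + bin_width)` bins ascending from `range[1]`; rows at or beyond
#' `range[2]` are outside the histogram. Defaults reproduce a whole-promoter
#' view (-7.5 kb to +2.5 kb in 500 bp bins); `bin_width = 50` with
#' `range = c(-750, 250)` gives the proximal-promoter view.
#'
#' @param con store connection.
#' @param bin_width bin width in bp; must divide the range length.
#' @param range length-2 numeric, `[lo, hi)` in dist_tss space.
#' @return tibble (class `distance_histogram`) with `bin_start`, `bin_end`,
#'   `count`; attributes `bin_width` and `range`.
#' @export
distance_histogram <- function(con, bin_width = 500, range = c(-7500, 2500)) {
  if (length(range) != 2 || range[2] <= range[1]) {
    abort("`range` must be c(lo, hi) with hi > lo")
  }
  span <- range[2] - range[1]
  if (bin_width <= 0 || span %% bin_width != 0) {
    abort(sprintf("bin_width (%s) must divide the range length (%s)",
                  bin_width, span))
  }
  sr <- read_store_table(con, "snp_region")
  rs <- rsnp_snp_ids(con)
  d <- sr$dist_tss[sr$snp_id %in% rs]
  d <- d[d >= range[1] & d < range[2]]
  starts <- seq(range[1], range[2] - bin_width, by = bin_width)
  bin <- range[1] + bin_width * floor((d - range[1]) / bin_width)
  out <- tibble(
    bin_start = starts,
    bin_end = starts + bin_width,
    count = vapply(starts, function(s) sum(bin == s), integer(1))
  )
  attr(out, "bin_width") <- bin_width
  attr(out, "range") <- range
  class(out) <- c("distance_histogram", class(out))
  out
}

#' @describeIn distance_histogram bar-chart of the binned TSS distances.
#' @param object a `distance_histogram`.
#' @param ... ignored.
#' @export
autoplot.distance_histogram <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = (.data$bin_start + .data$bin_end) / 2, y = .data$count)) +
    ggplot2::geom_col(width = attr(object, "bin_width"), fill = "steelblue") +
    ggplot2::labs(x = "distance to TSS (bp)", y = "rSNPs",
                  title = "rSNP distribution relative to the TSS") +
    ggplot2::theme_minimal()
}

#' @describeIn per_chromosome_counts faceted bar-chart of the per-chromosome
#'   counts.
#' @param object a `chrom_counts` tibble.
#' @param ... ignored.
#' @export
autoplot.chrom_counts <- function(object, ...) {
  long <- tidyr::pivot_longer(as_tibble(object), c("n_snps", "n_genes", "n_rsnps"),
                              names_to = "measure", values_to = "n")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$chrom, y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~measure, scales = "free_y") +
    ggplot2::labs(x = "chromosome", y = "count") +
    ggplot2::theme_minimal()
}
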