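#' Classify a SNP's consequences on predicted TFBSs
#'
#' Two TFBS predictions are the same site when their PWM, start position and
#' strand are equal for both alleles. Matched sites are `no_effect` when
#' both scores (MSS and CSS) are equal for both alleles at the comparison
#' precision and `score_change` otherwise; a site predicted only for the
#' reference allele is a `loss`, only for the alternate a `gain`. A CSS-only
#' difference with equal MSS counts as `score_change` (no-effect demands
#' both scores equal); the `score_component` column records which score
#' moved so such calls remain auditable.
#'
#' @param ref_hits,alt_hits hit tibbles from [scan_alleles()] for the two
#'   alleles of one SNP (columns `pwm_id`, `start`, `strand`, `mss`, `css`;
#'   an `allele` column, if present, is ignored).
#' @param digits decimal places at which scores are compared (default 3,
#'   the conventional score-reporting precision; override globally with
#'   `options(rsnpscan.score_digits = )`).
#' @return tibble with one row per site: `snp_id` (when available in the
#'   input), `pwm_id`, `strand`, `start`, `allele_presence` in
#'   `ref_only`/`alt_only`/`both`, `ref_mss`, `ref_css`, `alt_mss`,
#'   `alt_css` (NA on the absent side), `consequence` in
#'   `no_effect`/`score_change`/`loss`/`gain`, and `score_component`.
#' @export
classify_consequences <- function(ref_hits, alt_hits, digits = score_digits()) {
  ref <- prep_hits(ref_hits, "ref")
  alt <- prep_hits(alt_hits, "alt")
  snp_id <- unique(c(ref$snp_id, alt$snp_id))
  snp_id <- snp_id[!is.na(snp_id)]
  if (length(snp_id) > 1) {
    abort("hits from multiple SNPs supplied; classify one SNP at a time")
  }
  j <- dplyr::full_join(
    dplyr::select(ref, "pwm_id", "start", "strand", "ref_mss", "ref_css"),
    dplyr::select(alt, "pwm_id", "start", "strand", "alt_mss", "alt_css"),
    by = c("pwm_id", "start", "strand")
  )
  mss_eq <- round(j$ref_mss, digits) == round(j$alt_mss, digits)
  css_eq <- round(j$ref_css, digits) == round(j$alt_css, digits)
  presence <- dplyr::case_when(
    !is.na(j$ref_mss) & !is.na(j$alt_mss) ~ "both",
    !is.na(j$ref_mss) ~ "ref_only",
    TRUE ~ "alt_only"
  )
  consequence <- dplyr::case_when(
    presence == "ref_only" ~ "loss",
    presence == "alt_only" ~ "gain",
    mss_eq & css_eq ~ "no_effect",
    TRUE ~ "score_change"
  )
  score_component <- dplyr::case_when(
    consequence != "score_change" ~ NA_character_,
    !mss_eq & !css_eq ~ "mss+css",
    !mss_eq ~ "mss",
    TRUE ~ "css"
  )
  out <- tibble(
    snp_id = if (length(snp_id) == 1) snp_id else NA_character_,
    pwm_id = j$pwm_id,
    strand = j$strand,
    start = j$start,
    allele_presence = presence,
    ref_mss = j$ref_mss, ref_css = j$ref_css,
    alt_mss = j$alt_mss, alt_css = j$alt_css,
    consequence = consequence,
    score_component = score_component
  )
  dplyr::arrange(out, .data$pwm_id, .data$start, .data$strand)
}

prep_hits <- function(hits, side) {
  if (is.null(hits) || nrow(hits) == 0) {
    hits <- tibble(snp_id = character(0), pwm_id = character(0),
                   start = integer(0), strand = character(0),
                   mss = numeric(0), css = numeric(0))
  }
  assert_cols(hits, c("pwm_id", "start", "strand", "mss", "css"),
              sprintf("%s_hits", side))
  key <- paste(hits$pwm_id, hits$start, hits$strand)
  if (anyDuplicated(key)) {
    abort(sprintf("duplicate (pwm_id, start, strand) key in %s_hits: %s",
                  side, key[duplicated(key)][1]))
  }
  out <- as_tibble(hits)
  if (!"snp_id" %in% names(out)) out$snp_id <- NA_character_
  names(out)[names(out) == "mss"] <- paste0(side, "_mss")
  names(out)[names(out) == "css"] <- paste0(side, "_css")
  out
}

#' Is a SNP regulatory?
#'
#' An rSNP is a SNP causing a loss or gain of TFBS or a score-change for at
#' least one TFBS.
#'
#' @param records consequence records of one SNP
#'   ([classify_consequences()] output).
#' @return single logical.
#' @export
flag_rsnp <- function(records) {
  if (is.null(records) || nrow(records) == 0) return(FALSE)
  assert_cols(records, "consequence", "records")
  if ("snp_id" %in% names(records)) {
    ids <- unique(records$snp_id[!is.na(records$snp_id)])
    if (length(ids) > 1) abort("records from multiple SNPs; use rsnp_flags()")
  }
  any(records$consequence %in% c("loss", "gain", "score_change"))
}

#' rSNP flags for a multi-SNP consequence table
#'
#' @param records consequence records with a `snp_id` column.
#' @return tibble with `snp_id`, `is_rsnp`.
#' @export
rsnp_flags <- function(records) {
  assert_cols(records, c("snp_id", "consequence"), "records")
  records |>
    dplyr::group_by(.data$snp_id) |>
    dplyr::summarise(
      is_rsnp = any(.data$consequence %in% c("loss", "gain", "score_change")),
      .groups = "drop"
    )
}

#' Scan and classify every SNP in a flank table
#'
#' Convenience wrapper: runs [scan_alleles()] and [classify_consequences()]
#' for each usable flank and binds the per-SNP records.
#'
#' @inheritParams scan_flanks
#' @inheritParams classify_consequences
#' @return consequence-record tibble across all SNPs.
#' @export
annotate_consequences <- function(pwms, flanks, digits = score_digits(),
                                  require_snp_overlap = TRUE) {
  hits <- scan_flanks(pwms, flanks, require_snp_overlap = require_snp_overlap)
  if (nrow(hits) == 0) return(empty_consequences())
  out <- hits |>
    dplyr::group_by(.data$snp_id) |>
    dplyr::group_map(function(h, key) {
      rec <- classify_consequences(h[h$allele == "ref", ],
                                   h[h$allele == "alt", ], digits = digits)
      rec$snp_id <- key$snp_id
      rec
    }) |>
    dplyr::bind_rows()
  dplyr::arrange(out, .data$snp_id, .data$pwm_id, .data$start, .data$strand)
}

empty_consequences <- function() {
  tibble(snp_id = character(0), pwm_id = character(0), strand = character(0),
         start = integer(0), allele_presence = character(0),
         ref_mss = numeric(0), ref_css = numeric(0),
         alt_mss = numeric(0), alt_css = numeric(0),
         consequence = character(0), score_component = character(0))
}
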