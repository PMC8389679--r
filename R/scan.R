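#' Predict TFBSs on both alleles of a SNP flank
#'
#' Every start offset of every PWM is scored on the forward sequence and on
#' its reverse complement; hits on the minus strand are reported in
#' forward-sequence coordinates with `strand == "-"`. A site is kept when
#' both its MSS and CSS reach the matrix's cutoffs. By default only sites
#' whose span covers the SNP position are reported: sites not overlapping
#' the SNP are provably identical between the two alleles and cannot change
#' any consequence call.
#'
#' @param pwms a [pwm_library()] tibble.
#' @param ref_seq,alt_seq equal-length flank sequences differing only at the
#'   SNP position.
#' @param snp_index 1-based SNP position within the flank (defaults to the
#'   center base).
#' @param snp_id optional identifier carried into the output.
#' @param require_snp_overlap drop hits whose span does not cover
#'   `snp_index` (default TRUE).
#' @return tibble with columns `snp_id` (if given), `allele` (`"ref"` or
#'   `"alt"`), `pwm_id`, `start` (1-based offset in the flank), `strand`,
#'   `mss`, `css`.
#' @export
scan_alleles <- function(pwms, ref_seq, alt_seq, snp_index = NULL,
                         snp_id = NULL, require_snp_overlap = TRUE) {
  if (!is_single_string(ref_seq) || !is_single_string(alt_seq)) {
    abort("ref_seq and alt_seq must be single strings")
  }
  n <- nchar(ref_seq)
  if (nchar(alt_seq) != n) abort("ref_seq and alt_seq must have equal length")
  snp_index <- as.integer(snp_index %||% ((n + 1L) %/% 2L))
  if (snp_index < 1L || snp_index > n) {
    abort("snp_index out of range")
  }
  diffs <- which(strsplit(ref_seq, "")[[1]] != strsplit(alt_seq, "")[[1]])
  if (!identical(diffs, snp_index) && length(diffs) > 0) {
    abort("ref_seq and alt_seq must differ exactly at snp_index")
  }
  too_wide <- pwms$width > n
  if (any(too_wide)) {
    warn(sprintf("skipping PWM(s) wider than the %d-bp sequence: %s",
                 n, paste(pwms$id[too_wide], collapse = ", ")))
    pwms <- pwms[!too_wide, ]
  }
  ref <- scan_one_seq(pwms, ref_seq, snp_index, require_snp_overlap)
  alt <- scan_one_seq(pwms, alt_seq, snp_index, require_snp_overlap)
  out <- dplyr::bind_rows(
    dplyr::mutate(ref, allele = "ref"),
    dplyr::mutate(alt, allele = "alt")
  )
  if (!is.null(snp_id)) out <- dplyr::mutate(out, snp_id = snp_id)
  dplyr::relocate(out, dplyr::any_of("snp_id"), "allele")
}

# scan one sequence with every PWM, both strands, in forward coordinates
scan_one_seq <- function(pwms, seq, snp_index, require_snp_overlap) {
  n <- nchar(seq)
  res <- vector("list", nrow(pwms))
  for (k in seq_len(nrow(pwms))) {
    p <- as_pwm_row(pwms[k, ])
    L <- p$width
    starts <- seq_len(n - L + 1L)
    if (require_snp_overlap) {
      starts <- starts[starts <= snp_index & starts + L - 1L >= snp_index]
      if (length(starts) == 0) next
    }
    subs <- substring(seq, starts, starts + L - 1L)
    fwd <- score_engine(p$freq, p$info, p$core_start, subs)
    rev <- score_engine(p$freq, p$info, p$core_start, revcomp(subs))
    keep_f <- fwd$mss >= p$mss_cutoff & fwd$css >= p$css_cutoff
    keep_r <- rev$mss >= p$mss_cutoff & rev$css >= p$css_cutoff
    res[[k]] <- tibble(
      pwm_id = p$id,
      start = c(starts[keep_f], starts[keep_r]),
      strand = c(rep("+", sum(keep_f)), rep("-", sum(keep_r))),
      mss = c(fwd$mss[keep_f], rev$mss[keep_r]),
      css = c(fwd$css[keep_f], rev$css[keep_r])
    )
  }
  out <- dplyr::bind_rows(res)
  if (nrow(out) == 0) {
    return(tibble(pwm_id = character(0), start = integer(0),
                  strand = character(0), mss = numeric(0), css = numeric(0)))
  }
  dplyr::arrange(out, .data$pwm_id, .data$start, .data$strand)
}

#' Scan every usable flank in a flank table
#'
#' Applies [scan_alleles()] to each row of an [extract_flanks()] table with
#' status `"ok"`.
#'
#' @param pwms a [pwm_library()] tibble.
#' @param flanks tibble from [extract_flanks()].
#' @inheritParams scan_alleles
#' @return tibble of hits across all SNPs (with `snp_id` and `allele`
#'   columns).
#' @export
scan_flanks <- function(pwms, flanks, require_snp_overlap = TRUE) {
  assert_cols(flanks, c("snp_id", "ref_seq", "alt_seq", "snp_index", "status"),
              "flanks")
  ok <- flanks[flanks$status == "ok", ]
  res <- purrr::pmap(
    list(ok$ref_seq, ok$alt_seq, ok$snp_index, ok$snp_id),
    function(r, a, i, id) {
      scan_alleles(pwms, r, a, snp_index = i, snp_id = id,
                   require_snp_overlap = require_snp_overlap)
    }
  )
  out <- dplyr::bind_rows(res)
  if (nrow(out) == 0) {
    return(tibble(snp_id = character(0), allele = character(0),
                  pwm_id = character(0), start = integer(0),
                  strand = character(0), mss = numeric(0), css = numeric(0)))
  }
  out
}
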