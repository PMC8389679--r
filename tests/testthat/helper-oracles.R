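# Independent oracles: deliberately naive re-implementations used only to
# check package output. They share no code with the package internals.

oracle_base_index <- c(A = 1L, C = 2L, G = 3L, T = 4L)

oracle_info_row <- function(fr) {
  s <- 0
  for (b in 1:4) if (fr[b] > 0) s <- s + fr[b] * log(4 * fr[b])
  s
}

oracle_core_start <- function(freq) {
  L <- nrow(freq)
  if (L <= 5) return(1L)
  best <- -Inf; best_i <- 1L
  for (i in 1:(L - 4)) {
    tot <- 0
    for (k in i:(i + 4)) tot <- tot + oracle_info_row(freq[k, ])
    if (tot > best + 1e-15) { best <- tot; best_i <- i }
  }
  best_i
}

# direct summation over the stated positions of a site sequence
oracle_score_positions <- function(freq, seq, positions) {
  chars <- strsplit(seq, "")[[1]]
  cur <- mn <- mx <- 0
  for (i in positions) {
    I <- oracle_info_row(freq[i, ])
    cur <- cur + I * freq[i, oracle_base_index[chars[i]]]
    mn <- mn + I * min(freq[i, ])
    mx <- mx + I * max(freq[i, ])
  }
  if (mx - mn <= 1e-12) return(1)
  unname((cur - mn) / (mx - mn))
}

oracle_mss_css <- function(freq, seq) {
  L <- nrow(freq)
  core <- if (L < 5) 1:L else {
    cs <- oracle_core_start(freq)
    cs:(cs + 4)
  }
  list(mss = oracle_score_positions(freq, seq, 1:L),
       css = oracle_score_positions(freq, seq, core))
}

oracle_revcomp <- function(s) {
  paste(rev(chartr("ACGT", "TGCA", strsplit(s, "")[[1]])), collapse = "")
}

# exhaustive (pwm, offset, strand) scan of one sequence
oracle_scan_seq <- function(pwms, seq, snp_index, require_overlap = TRUE) {
  rows <- list()
  n <- nchar(seq)
  for (k in seq_len(nrow(pwms))) {
    freq <- pwms$freq[[k]]
    L <- nrow(freq)
    if (L > n) next
    for (start in 1:(n - L + 1)) {
      if (require_overlap && (start > snp_index || start + L - 1 < snp_index)) next
      sub <- substr(seq, start, start + L - 1)
      for (strand in c("+", "-")) {
        s2 <- if (strand == "+") sub else oracle_revcomp(sub)
        sc <- oracle_mss_css(freq, s2)
        if (sc$mss >= pwms$mss_cutoff[k] && sc$css >= pwms$css_cutoff[k]) {
          rows[[length(rows) + 1]] <- data.frame(
            pwm_id = pwms$id[k], start = start, strand = strand,
            mss = sc$mss, css = sc$css, stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(pwm_id = character(0), start = integer(0),
                      strand = character(0), mss = numeric(0), css = numeric(0))
  }
  out[order(out$pwm_id, out$start, out$strand), , drop = FALSE]
}

# all-pairs containment check of SNPs in promoter windows
oracle_overlap <- function(windows, snps) {
  rows <- list()
  for (w in seq_len(nrow(windows))) {
    hit <- snps$chrom == windows$chrom[w] &
      snps$pos >= windows$start[w] & snps$pos <= windows$end[w]
    if (!any(hit)) next
    d <- if (windows$strand[w] == "+") snps$pos[hit] - windows$tss[w]
         else windows$tss[w] - snps$pos[hit]
    rows[[length(rows) + 1]] <- data.frame(
      snp_id = snps$snp_id[hit], transcript_id = windows$transcript_id[w],
      dist_tss = as.integer(d), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(snp_id = character(0), transcript_id = character(0),
                      dist_tss = integer(0))
  }
  out[order(out$snp_id, out$transcript_id), , drop = FALSE]
}
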