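#' Score candidate sites against a PWM
#'
#' Computes the MATCH-style matrix similarity score (MSS) and core similarity
#' score (CSS) for fixed-width sequences. With information weights
#' \eqn{I(i)}, the running score of a sequence is
#' \eqn{Current = \sum_i I(i) f(i, s_i)}; `Min`/`Max` replace
#' \eqn{f(i, s_i)} by the per-position minimum/maximum frequency, and
#' \eqn{MSS = (Current - Min)/(Max - Min)}. The CSS applies the same formula
#' restricted to the 5-position core window. Both scores lie in `[0, 1]`;
#' 1 denotes an exact match of the sequence with the PWM consensus and 0 the
#' per-position minimum everywhere. A fully uninformative matrix (or core)
#' has `Max == Min`; its score is defined as 1 and a warning is raised.
#'
#' @param pwm a one-row [pwm_library()] tibble.
#' @param seq character vector of sequences, each exactly `pwm$width` long,
#'   over the alphabet A, C, G, T.
#' @return tibble with columns `seq`, `mss`, `css`, one row per input
#'   sequence.
#' @export
#' @examples
#' m <- matrix(c(0.7, 0.1, 0.1, 0.1,
#'               0.1, 0.7, 0.1, 0.1), ncol = 4, byrow = TRUE)
#' lib <- pwm_library("V$TOY_01", list(m))
#' score_site(lib, c("AC", "TG"))
score_site <- function(pwm, seq) {
  p <- as_pwm_row(pwm)
  sc <- score_engine(p$freq, p$info, p$core_start, seq)
  tibble(seq = seq, mss = sc$mss, css = sc$css)
}

# vectorized scoring workhorse: freq (L x 4), info (L), core_start scalar,
# seqs character vector of length-L strings
score_engine <- function(freq, info, core_start, seqs) {
  L <- nrow(freq)
  n <- length(seqs)
  if (n == 0) return(list(mss = numeric(0), css = numeric(0)))
  if (any(nchar(seqs) != L)) {
    abort(sprintf("sequence length must equal PWM width (%d)", L))
  }
  chars <- matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
                  ncol = L, byrow = TRUE)
  bi <- matrix(match(chars, DNA_BASES), ncol = L)
  if (anyNA(bi)) abort("sequences must contain only A, C, G, T")

  fw <- freq * info                      # information-weighted frequencies
  core <- core_positions(core_start, L)
  in_core <- seq_len(L) %in% core
  cur_all <- numeric(n)
  cur_core <- numeric(n)
  # Min/Max accumulate position-by-position alongside Current so that a
  # consensus sequence reproduces Max (and an anti-consensus Min) exactly
  mn_all <- mx_all <- mn_core <- mx_core <- 0
  for (i in seq_len(L)) {
    row <- unname(fw[i, ])
    v <- row[bi[, i]]
    cur_all <- cur_all + v
    mn_all <- mn_all + min(row)
    mx_all <- mx_all + max(row)
    if (in_core[i]) {
      cur_core <- cur_core + v
      mn_core <- mn_core + min(row)
      mx_core <- mx_core + max(row)
    }
  }
  mss <- normalize_score(cur_all, mn_all, mx_all, n, "matrix")
  css <- normalize_score(cur_core, mn_core, mx_core, n, "core")
  list(mss = mss, css = css)
}

normalize_score <- function(current, mn, mx, n, what) {
  if (mx - mn <= 1e-12) {
    warn(sprintf("fully uninformative %s: score defined as 1.0", what),
         class = "rsnpscan_uninformative_pwm")
    return(rep(1, n))
  }
  clamp01((current - mn) / (mx - mn))
}

#' Consensus and anti-consensus sequences of a PWM
#'
#' The consensus takes the highest-frequency base at every position (MSS 1
#' by construction); the anti-consensus takes the lowest-frequency base
#' (MSS 0). Ties resolve to the alphabetically first base.
#'
#' @inheritParams score_site
#' @return a single string.
#' @export
consensus_seq <- function(pwm) {
  p <- as_pwm_row(pwm)
  paste(DNA_BASES[apply(p$freq, 1, which.max)], collapse = "")
}

#' @rdname consensus_seq
#' @export
anticonsensus_seq <- function(pwm) {
  p <- as_pwm_row(pwm)
  paste(DNA_BASES[apply(p$freq, 1, which.min)], collapse = "")
}
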