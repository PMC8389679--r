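# shared internal helpers

clamp01 <- function(x) pmin(pmax(x, 0), 1)

# reverse complement for plain character vectors; Biostrings does the work
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

comp_base <- function(x) chartr("ACGT", "TGCA", x)

# comparison precision for score equality; shared by classification and
# reporting (MATCH prints three decimals)
score_digits <- function() getOption("rsnpscan.score_digits", 3L)

assert_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss) > 0) {
    abort(sprintf("%s is missing required column(s): %s",
                  what, paste(miss, collapse = ", ")))
  }
  invisible(df)
}

is_single_string <- function(x) is.character(x) && length(x) == 1 && !is.na(x)
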