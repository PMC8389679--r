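#' Build a PWM library tibble
#'
#' A PWM library is a tibble with one row per position weight matrix and
#' list-columns holding the numeric content. Each frequency matrix has one
#' row per motif position and columns A, C, G, T, with rows summing to 1.
#' The per-position information content
#' \eqn{I(i) = \sum_b f(i,b)\,\ln(4 f(i,b))} (with \eqn{0 \ln 0 := 0})
#' weights the similarity scores, and the core is the 5-position window with
#' maximal total information (leftmost on ties; the whole matrix when the
#' width is below 5).
#'
#' @param id character vector of matrix identifiers (e.g. `"V$AP2ALPHA_03"`).
#' @param freq list of numeric matrices (positions x 4, columns A,C,G,T);
#'   counts are accepted and normalized row-wise to frequencies.
#' @param mss_cutoff,css_cutoff minimum matrix / core similarity scores a
#'   site must reach to be reported as a TFBS; recycled across matrices.
#' @param pseudocount value added to every cell before normalization
#'   (default 0; zero frequencies are legal).
#'
#' @return A tibble of class `pwm_library` with columns `id`, `width`,
#'   `mss_cutoff`, `css_cutoff`, `core_start` and list-columns `freq`
#'   (normalized frequency matrix) and `info` (information vector).
#' @export
#' @examples
#' m <- matrix(c(8, 0, 0, 0,
#'               0, 8, 0, 0,
#'               2, 2, 2, 2), ncol = 4, byrow = TRUE)
#' pwm_library("V$TOY_01", list(m))
pwm_library <- function(id, freq, mss_cutoff = 0.95, css_cutoff = 0.90,
                        pseudocount = 0) {
  if (!is.character(id)) abort("`id` must be a character vector")
  if (!is.list(freq) || length(freq) != length(id)) {
    abort("`freq` must be a list of matrices, one per id")
  }
  if (anyDuplicated(id)) {
    abort(sprintf("duplicate PWM id(s): %s",
                  paste(unique(id[duplicated(id)]), collapse = ", ")))
  }
  norm <- purrr::map2(freq, id, normalize_freq, pseudocount = pseudocount)
  info <- purrr::map(norm, pwm_information)
  out <- tibble(
    id = id,
    width = vapply(norm, nrow, integer(1)),
    mss_cutoff = rep_len(mss_cutoff, length(id)),
    css_cutoff = rep_len(css_cutoff, length(id)),
    core_start = vapply(info, find_core_start, integer(1)),
    freq = norm,
    info = info
  )
  class(out) <- c("pwm_library", class(out))
  out
}

normalize_freq <- function(m, id, pseudocount = 0) {
  m <- as.matrix(m)
  if (ncol(m) != 4) abort(sprintf("PWM '%s': frequency matrix must have 4 columns", id))
  storage.mode(m) <- "double"
  if (any(m < 0)) abort(sprintf("PWM '%s': negative entries are not allowed", id))
  m <- m + pseudocount
  rs <- rowSums(m)
  if (any(rs == 0)) {
    abort(sprintf("PWM '%s': position %d has zero total count",
                  id, which(rs == 0)[1]))
  }
  m <- m / rs
  dimnames(m) <- list(NULL, DNA_BASES)
  m
}

# I(i) = sum_b f(i,b) ln(4 f(i,b)), with 0 ln 0 := 0
pwm_information <- function(freq) {
  z <- freq * log(4 * freq)
  z[freq == 0] <- 0
  unname(rowSums(z))
}

# start of the 5-position window maximizing total information;
# leftmost window wins ties, whole matrix when width < 5
find_core_start <- function(info) {
  L <- length(info)
  if (L <= 5L) return(1L)
  win <- vapply(seq_len(L - 4L), function(i) sum(info[i:(i + 4L)]), numeric(1))
  as.integer(which.max(win))
}

core_positions <- function(core_start, width) {
  if (width < 5L) seq_len(width) else seq.int(core_start, core_start + 4L)
}

#' Information vector of a PWM
#'
#' @param pwm a one-row [pwm_library()] tibble (or a row index into one).
#' @return numeric vector of per-position information contents, in
#'   `[0, ln 4]`.
#' @export
information_vector <- function(pwm) {
  p <- as_pwm_row(pwm)
  p$info
}

#' Core window start of a PWM
#'
#' The core is the run of five consecutive positions with the highest total
#' information content (the most-conserved stretch); ties resolve to the
#' leftmost window and matrices narrower than five positions use every
#' position as core.
#'
#' @inheritParams information_vector
#' @return 1-based start index of the core window.
#' @export
core_window <- function(pwm) {
  p <- as_pwm_row(pwm)
  p$core_start
}

# accept a one-row pwm_library tibble and unwrap list columns
as_pwm_row <- function(pwm) {
  assert_cols(pwm, c("id", "width", "freq", "info", "core_start"), "pwm")
  if (nrow(pwm) != 1) abort("expected exactly one PWM (a one-row library tibble)")
  list(
    id = pwm$id[[1]], width = pwm$width[[1]], freq = pwm$freq[[1]],
    info = pwm$info[[1]], core_start = pwm$core_start[[1]],
    mss_cutoff = pwm$mss_cutoff[[1]] %||% 0.95,
    css_cutoff = pwm$css_cutoff[[1]] %||% 0.90
  )
}

#' Parse a PWM library from text
#'
#' Supports the TRANSFAC flat-file dialect (`ID`/`P0` rows, `//` block
#' separators) and JASPAR PFM files (`>` headers followed by four base rows,
#' bracketed or plain). Counts are converted to frequencies by row
#' normalization; matrix identifiers are preserved verbatim.
#'
#' @param text a single string or character vector of lines.
#' @param dialect `"transfac"` or `"jaspar_pfm"`.
#' @inheritParams pwm_library
#' @return a [pwm_library()] tibble.
#' @export
parse_pwm_library <- function(text, dialect = c("transfac", "jaspar_pfm"),
                              mss_cutoff = 0.95, css_cutoff = 0.90,
                              pseudocount = 0) {
  dialect <- match.arg(dialect)
  lines <- if (length(text) == 1) strsplit(text, "\n", fixed = TRUE)[[1]] else text
  parsed <- switch(dialect,
    transfac = parse_transfac_lines(lines),
    jaspar_pfm = parse_jaspar_lines(lines)
  )
  if (length(parsed$id) == 0) abort("no PWM blocks found in input")
  pwm_library(parsed$id, parsed$freq, mss_cutoff = mss_cutoff,
              css_cutoff = css_cutoff, pseudocount = pseudocount)
}

#' Read a PWM library file
#'
#' @param path file path.
#' @inheritParams parse_pwm_library
#' @return a [pwm_library()] tibble.
#' @export
read_pwm_library <- function(path, dialect = c("transfac", "jaspar_pfm"), ...) {
  parse_pwm_library(readLines(path, warn = FALSE), dialect = dialect, ...)
}

parse_transfac_lines <- function(lines) {
  ids <- character(0)
  freqs <- list()
  cur_id <- NA_character_
  cur_order <- DNA_BASES
  cur_rows <- list()
  flush <- function() {
    if (!is.na(cur_id) && length(cur_rows) > 0) {
      m <- do.call(rbind, cur_rows)
      colnames(m) <- cur_order
      ids <<- c(ids, cur_id)
      freqs <<- c(freqs, list(m[, DNA_BASES, drop = FALSE]))
    } else if (!is.na(cur_id) && length(cur_rows) == 0) {
      abort(sprintf("TRANSFAC block '%s' has no position rows", cur_id))
    }
    cur_id <<- NA_character_
    cur_rows <<- list()
    cur_order <<- DNA_BASES
  }
  for (ln in lines) {
    ln <- sub("\\s+$", "", ln)
    if (grepl("^//", ln)) {
      flush()
    } else if (grepl("^ID\\s+", ln)) {
      if (!is.na(cur_id)) flush()
      cur_id <- sub("^ID\\s+(\\S+).*$", "\\1", ln)
    } else if (is.na(cur_id) && grepl("^AC\\s+", ln)) {
      cur_id <- sub("^AC\\s+(\\S+).*$", "\\1", ln)
    } else if (grepl("^P[0O]\\b", ln)) {
      toks <- strsplit(trimws(sub("^P[0O]", "", ln)), "\\s+")[[1]]
      toks <- toupper(toks[toks != ""])
      if (!setequal(toks, DNA_BASES)) {
        abort(sprintf("TRANSFAC block '%s': unrecognized P0 header", cur_id))
      }
      cur_order <- toks
    } else if (grepl("^[0-9]+\\s", ln) && !is.na(cur_id)) {
      toks <- strsplit(trimws(ln), "\\s+")[[1]]
      vals <- suppressWarnings(as.numeric(toks[2:5]))
      if (anyNA(vals)) {
        abort(sprintf("TRANSFAC block '%s': malformed position row '%s'", cur_id, ln))
      }
      cur_rows[[length(cur_rows) + 1]] <- vals
    }
  }
  flush()
  list(id = ids, freq = freqs)
}

parse_jaspar_lines <- function(lines) {
  lines <- lines[trimws(lines) != ""]
  hdr <- grep("^>", lines)
  if (length(hdr) == 0) abort("no '>' headers found in JASPAR PFM input")
  ids <- character(0)
  freqs <- list()
  bounds <- c(hdr, length(lines) + 1L)
  for (k in seq_along(hdr)) {
    id <- strsplit(sub("^>\\s*", "", lines[hdr[k]]), "\\s+")[[1]][1]
    body <- lines[seq(hdr[k] + 1L, bounds[k + 1L] - 1L)]
    if (length(body) < 4) abort(sprintf("JASPAR block '%s': expected 4 base rows", id))
    body <- body[1:4]
    labels <- toupper(sub("^\\s*([ACGTacgt])\\s*\\[?.*$", "\\1", body))
    rows <- lapply(body, function(b) {
      b <- gsub("^\\s*[ACGTacgt]?\\s*\\[?", "", b)
      b <- gsub("\\]\\s*$", "", b)
      vals <- suppressWarnings(as.numeric(strsplit(trimws(b), "\\s+")[[1]]))
      if (anyNA(vals)) abort(sprintf("JASPAR block '%s': malformed row '%s'", id, b))
      vals
    })
    if (length(unique(lengths(rows))) != 1) {
      abort(sprintf("JASPAR block '%s': base rows have unequal lengths", id))
    }
    by_base <- do.call(rbind, rows)   # 4 x L, one row per base
    if (all(labels %in% DNA_BASES) && !anyDuplicated(labels)) {
      rownames(by_base) <- labels
      by_base <- by_base[DNA_BASES, , drop = FALSE]
    }
    ids <- c(ids, id)
    freqs <- c(freqs, list(t(by_base)))
  }
  list(id = ids, freq = freqs)
}

#' Read a per-matrix cutoff profile
#'
#' A tab- or comma-separated file with columns `id`, `mss_cutoff`,
#' `css_cutoff`, one row per matrix to override.
#'
#' @param path file path.
#' @return tibble with the three columns.
#' @export
read_cutoff_profile <- function(path) {
  prof <- readr::read_delim(path, show_col_types = FALSE, progress = FALSE)
  assert_cols(prof, c("id", "mss_cutoff", "css_cutoff"), "cutoff profile")
  as_tibble(prof[, c("id", "mss_cutoff", "css_cutoff")])
}

#' Apply a cutoff profile to a PWM library
#'
#' @param pwms a [pwm_library()] tibble.
#' @param profile tibble as returned by [read_cutoff_profile()].
#' @return the library with per-matrix cutoffs overridden; profile rows whose
#'   id is absent from the library are reported with a warning.
#' @export
apply_cutoff_profile <- function(pwms, profile) {
  assert_cols(profile, c("id", "mss_cutoff", "css_cutoff"), "cutoff profile")
  unknown <- setdiff(profile$id, pwms$id)
  if (length(unknown) > 0) {
    warn(sprintf("cutoff profile names %d unknown matrix id(s): %s",
                 length(unknown), paste(head(unknown, 5), collapse = ", ")))
  }
  i <- match(pwms$id, profile$id)
  hit <- !is.na(i)
  pwms$mss_cutoff[hit] <- profile$mss_cutoff[i[hit]]
  pwms$css_cutoff[hit] <- profile$css_cutoff[i[hit]]
  pwms
}

#' @exportS3Method base::print
print.pwm_library <- function(x, ...) {
  cat(sprintf("# PWM library: %d matrices, widths %d-%d\n",
              nrow(x), min(x$width), max(x$width)))
  NextMethod()
}
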