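#' Create or open a results store
#'
#' A single-file SQLite database with the four-table schema:
#' `snp_info(snp_id, chrom, pos, ref, alt)`,
#' `gene_info(gene_id, gene_name, chrom, start, end, strand)`,
#' `snp_region(snp_id, gene_id, transcript_id, dist_tss)` linking SNPs to
#' promoters, and `tfbs_results(snp_id, pwm_id, strand, start,
#' allele_presence, ref_mss, ref_css, alt_mss, alt_css, consequence)` with
#' one row per classified SNP-site pair.
#'
#' @param path database file, or `":memory:"` for a transient store.
#' @return an open DBI connection; close it with [DBI::dbDisconnect()].
#' @export
create_store <- function(path = ":memory:") {
  con <- DBI::dbConnect(RSQLite::SQLite(), path)
  DBI::dbExecute(con, "CREATE TABLE IF NOT EXISTS snp_info (
    snp_id TEXT PRIMARY KEY, chrom TEXT NOT NULL, pos INTEGER NOT NULL,
    ref TEXT NOT NULL, alt TEXT NOT NULL)")
  DBI::dbExecute(con, "CREATE TABLE IF NOT EXISTS gene_info (
    gene_id TEXT PRIMARY KEY, gene_name TEXT, chrom TEXT NOT NULL,
    \"start\" INTEGER, \"end\" INTEGER, strand TEXT)")
  DBI::dbExecute(con, "CREATE TABLE IF NOT EXISTS snp_region (
    snp_id TEXT NOT NULL, gene_id TEXT NOT NULL, transcript_id TEXT,
    dist_tss INTEGER NOT NULL)")
  DBI::dbExecute(con, "CREATE TABLE IF NOT EXISTS tfbs_results (
    snp_id TEXT NOT NULL, pwm_id TEXT NOT NULL, strand TEXT NOT NULL,
    \"start\" INTEGER NOT NULL, allele_presence TEXT NOT NULL,
    ref_mss REAL, ref_css REAL, alt_mss REAL, alt_css REAL,
    consequence TEXT NOT NULL)")
  DBI::dbExecute(con, "CREATE INDEX IF NOT EXISTS idx_region_snp ON snp_region(snp_id)")
  DBI::dbExecute(con, "CREATE INDEX IF NOT EXISTS idx_region_gene ON snp_region(gene_id)")
  DBI::dbExecute(con, "CREATE INDEX IF NOT EXISTS idx_tfbs_snp ON tfbs_results(snp_id)")
  con
}

store_tables <- c("snp_info", "gene_info", "snp_region", "tfbs_results")

table_columns <- list(
  snp_info = c("snp_id", "chrom", "pos", "ref", "alt"),
  gene_info = c("gene_id", "gene_name", "chrom", "start", "end", "strand"),
  snp_region = c("snp_id", "gene_id", "transcript_id", "dist_tss"),
  tfbs_results = c("snp_id", "pwm_id", "strand", "start", "allele_presence",
                   "ref_mss", "ref_css", "alt_mss", "alt_css", "consequence")
)

#' Write result tables into a store
#'
#' Inserts are atomic: referential integrity is checked first (every
#' `snp_region` key must exist in `snp_info` and `gene_info`; every
#' `tfbs_results` SNP must exist in `snp_region`) and any violation rolls
#' the whole transaction back.
#'
#' @param con store connection from [create_store()].
#' @param snp_info,gene_info,snp_region,tfbs_results tibbles matching the
#'   schema (missing optional tables may be NULL or empty).
#' @return named integer vector of rows inserted per table.
#' @export
write_results <- function(con, snp_info = NULL, gene_info = NULL,
                          snp_region = NULL, tfbs_results = NULL) {
  tabs <- list(snp_info = snp_info, gene_info = gene_info,
               snp_region = snp_region, tfbs_results = tfbs_results)
  tabs <- lapply(names(tabs), function(nm) {
    cols <- table_columns[[nm]]
    x <- tabs[[nm]]
    if (is.null(x)) {
      return(as_tibble(setNames(rep(list(character(0)), length(cols)), cols)))
    }
    assert_cols(x, cols, nm)
    as_tibble(x)[, cols]
  })
  names(tabs) <- store_tables

  known_snps <- c(DBI::dbGetQuery(con, "SELECT snp_id FROM snp_info")$snp_id,
                  tabs$snp_info$snp_id)
  known_genes <- c(DBI::dbGetQuery(con, "SELECT gene_id FROM gene_info")$gene_id,
                   tabs$gene_info$gene_id)
  region_snps <- c(DBI::dbGetQuery(con, "SELECT snp_id FROM snp_region")$snp_id,
                   tabs$snp_region$snp_id)
  if (nrow(tabs$snp_region) > 0) {
    bad <- setdiff(tabs$snp_region$snp_id, known_snps)
    if (length(bad) > 0) {
      abort(sprintf("snp_region references unknown snp_id(s): %s",
                    paste(head(bad, 5), collapse = ", ")))
    }
    bad <- setdiff(tabs$snp_region$gene_id, known_genes)
    if (length(bad) > 0) {
      abort(sprintf("snp_region references unknown gene_id(s): %s",
                    paste(head(bad, 5), collapse = ", ")))
    }
  }
  if (nrow(tabs$tfbs_results) > 0) {
    bad <- setdiff(tabs$tfbs_results$snp_id, region_snps)
    if (length(bad) > 0) {
      abort(sprintf("tfbs_results references snp_id(s) absent from snp_region: %s",
                    paste(head(bad, 5), collapse = ", ")))
    }
  }

  DBI::dbWithTransaction(con, {
    for (nm in store_tables) {
      if (nrow(tabs[[nm]]) > 0) {
        DBI::dbAppendTable(con, nm, as.data.frame(tabs[[nm]]))
      }
    }
  })
  vapply(tabs, nrow, integer(1))
}

read_store_table <- function(con, name) {
  as_tibble(DBI::dbReadTable(con, name))
}

#' Query a results store
#'
#' Four query modes mirror the lookup styles of a variant database front
#' end: by SNP identifier, by exact position (`"chrom:pos"`), by chromosome
#' region (`"chrom:start-end"`), or by gene (stable id or gene name). The
#' promoter window can be narrowed post hoc: with `upstream`/`downstream`
#' set, only `snp_region` rows with `-upstream <= dist_tss <= downstream`
#' are kept, and the other tables are restricted to the SNPs/genes that
#' remain linked.
#'
#' @param con store connection.
#' @param by one of `"rsid"`, `"position"`, `"region"`, `"gene"`.
#' @param key character key(s); format depends on `by`.
#' @param upstream,downstream optional promoter-narrowing bounds in bp.
#' @return named list of four tibbles (`snp_info`, `gene_info`,
#'   `snp_region`, `tfbs_results`); unknown keys give empty tables.
#' @export
query_store <- function(con, by = c("rsid", "position", "region", "gene"),
                        key, upstream = NULL, downstream = NULL) {
  by <- match.arg(by)
  if (!is.character(key) || length(key) < 1) abort("`key` must be character")
  snp_info <- read_store_table(con, "snp_info")
  gene_info <- read_store_table(con, "gene_info")
  snp_region <- read_store_table(con, "snp_region")
  tfbs <- read_store_table(con, "tfbs_results")

  if (by == "gene") {
    genes <- gene_info[gene_info$gene_id %in% key | gene_info$gene_name %in% key, ]
    region <- snp_region[snp_region$gene_id %in% genes$gene_id, ]
    region <- narrow_region(region, upstream, downstream)
    snps <- snp_info[snp_info$snp_id %in% region$snp_id, ]
  } else {
    snps <- switch(by,
      rsid = snp_info[snp_info$snp_id %in% key, ],
      position = {
        p <- parse_locus(key, need_range = FALSE)
        dplyr::semi_join(snp_info, p, by = c("chrom", "pos"))
      },
      region = {
        p <- parse_locus(key, need_range = TRUE)
        keep <- rep(FALSE, nrow(snp_info))
        for (i in seq_len(nrow(p))) {
          keep <- keep | (snp_info$chrom == p$chrom[i] &
                            snp_info$pos >= p$start[i] & snp_info$pos <= p$end[i])
        }
        snp_info[keep, ]
      }
    )
    region <- snp_region[snp_region$snp_id %in% snps$snp_id, ]
    region <- narrow_region(region, upstream, downstream)
    genes <- gene_info[gene_info$gene_id %in% region$gene_id, ]
  }
  list(
    snp_info = snps,
    gene_info = genes,
    snp_region = region,
    tfbs_results = tfbs[tfbs$snp_id %in% region$snp_id, ]
  )
}

narrow_region <- function(region, upstream, downstream) {
  if (is.null(upstream) && is.null(downstream)) return(region)
  up <- upstream %||% Inf
  down <- downstream %||% Inf
  region[region$dist_tss >= -up & region$dist_tss <= down, ]
}

parse_locus <- function(key, need_range) {
  if (need_range) {
    m <- regmatches(key, regexec("^([^:]+):([0-9]+)-([0-9]+)$", key))
    bad <- vapply(m, length, integer(1)) != 4
    if (any(bad)) {
      abort(sprintf("malformed region '%s'; expected 'chrom:start-end'", key[bad][1]))
    }
    tibble(chrom = vapply(m, `[`, "", 2),
           start = as.integer(vapply(m, `[`, "", 3)),
           end = as.integer(vapply(m, `[`, "", 4)))
  } else {
    m <- regmatches(key, regexec("^([^:]+):([0-9]+)$", key))
    bad <- vapply(m, length, integer(1)) != 3
    if (any(bad)) {
      abort(sprintf("malformed position '%s'; expected 'chrom:pos'", key[bad][1]))
    }
    tibble(chrom = vapply(m, `[`, "", 2),
           pos = as.integer(vapply(m, `[`, "", 3)))
  }
}

#' Export store tables to CSV
#'
#' Writes one RFC-4180 CSV per table, either whole or chromosome-wise
#' (`<table>_<chrom>.csv`, mirroring per-chromosome bulk downloads; rows of
#' `snp_region`/`tfbs_results` follow their SNP's chromosome).
#'
#' @param con store connection.
#' @param dir output directory (created if needed).
#' @param by_chromosome split files by chromosome (default FALSE).
#' @return invisible character vector of files written.
#' @export
store_export_csv <- function(con, dir, by_chromosome = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tabs <- setNames(lapply(store_tables, read_store_table, con = con), store_tables)
  files <- character(0)
  if (!by_chromosome) {
    for (nm in store_tables) {
      f <- file.path(dir, paste0(nm, ".csv"))
      readr::write_csv(tabs[[nm]], f, progress = FALSE)
      files <- c(files, f)
    }
  } else {
    snp_chrom <- setNames(tabs$snp_info$chrom, tabs$snp_info$snp_id)
    chroms <- sort(unique(c(tabs$snp_info$chrom, tabs$gene_info$chrom)))
    for (ch in chroms) {
      slices <- list(
        snp_info = tabs$snp_info[tabs$snp_info$chrom == ch, ],
        gene_info = tabs$gene_info[tabs$gene_info$chrom == ch, ],
        snp_region = tabs$snp_region[snp_chrom[tabs$snp_region$snp_id] == ch, ],
        tfbs_results = tabs$tfbs_results[snp_chrom[tabs$tfbs_results$snp_id] == ch, ]
      )
      for (nm in store_tables) {
        f <- file.path(dir, sprintf("%s_%s.csv", nm, ch))
        readr::write_csv(slices[[nm]], f, progress = FALSE)
        files <- c(files, f)
      }
    }
  }
  invisible(files)
}

#' Import CSV exports into a new store
#'
#' @param dir directory holding `snp_info.csv`, `gene_info.csv`,
#'   `snp_region.csv`, `tfbs_results.csv` as written by
#'   [store_export_csv()].
#' @param path database file for the new store (default in-memory).
#' @return an open store connection.
#' @export
store_import_csv <- function(dir, path = ":memory:") {
  con <- create_store(path)
  tabs <- lapply(store_tables, function(nm) {
    f <- file.path(dir, paste0(nm, ".csv"))
    if (!file.exists(f)) abort(sprintf("missing CSV export: %s", f))
    readr::read_csv(f, show_col_types = FALSE, progress = FALSE)
  })
  names(tabs) <- store_tables
  write_results(con, tabs$snp_info, tabs$gene_info, tabs$snp_region,
                tabs$tfbs_results)
  con
}
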