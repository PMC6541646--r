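PHAGE_GROUPS <- c("cos", "pac", "5093", "987", "unknown")

#' Read a phage metadata table
#'
#' Tab-separated table with one row per phage and the columns
#' `phage`, `host_strains` (whitespace-separated strain ids), `group`
#' (`cos`, `pac`, `5093`, `987` or `unknown`), `year` (`N/A` allowed),
#' `country`, `product`, `genome_size` (bp), `n_orfs`, `gc` (percent),
#' `accession`. Malformed numeric cells raise an error naming the row and
#' column; `N/A` years become missing values.
#'
#' @param path TSV file path.
#' @return a tibble; `host_strains` is a list column of character vectors.
#' @export
read_metadata <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                        na = character())
  required <- c("phage", "host_strains", "group", "year", "country",
                "product", "genome_size", "n_orfs", "gc")
  miss <- setdiff(required, names(df))
  if (length(miss)) abort(paste("metadata is missing columns:",
                                paste(miss, collapse = ", ")))
  parse_num <- function(x, col, integer = FALSE, na_ok = FALSE) {
    x[x %in% c("N/A", "NA", "")] <- NA
    out <- suppressWarnings(as.numeric(x))
    bad <- which(is.na(out) & !is.na(x))
    if (length(bad)) {
      abort(sprintf("malformed numeric value '%s' in column '%s', row %d",
                    x[bad[1]], col, bad[1]))
    }
    if (!na_ok && anyNA(out)) {
      abort(sprintf("missing value in column '%s'", col))
    }
    if (integer) as.integer(out) else out
  }
  if (nrow(df) == 0L) {
    return(tibble(phage = character(), host_strains = list(),
                  group = character(), year = integer(), country = character(),
                  product = character(), genome_size = integer(),
                  n_orfs = integer(), gc = double(), accession = character()))
  }
  group <- df$group
  bad_group <- setdiff(unique(group), PHAGE_GROUPS)
  if (length(bad_group)) abort(paste("unknown phage group:",
                                     paste(bad_group, collapse = ", ")))
  out <- tibble(
    phage = df$phage,
    host_strains = strsplit(trimws(df$host_strains), "\\s+"),
    group = group,
    year = parse_num(df$year, "year", integer = TRUE, na_ok = TRUE),
    country = dplyr::na_if(df$country, "N/A"),
    product = df$product,
    genome_size = parse_num(df$genome_size, "genome_size", integer = TRUE),
    n_orfs = parse_num(df$n_orfs, "n_orfs", integer = TRUE),
    gc = parse_num(df$gc, "gc"),
    accession = if ("accession" %in% names(df)) df$accession else NA_character_
  )
  if (any(out$genome_size <= 0) || any(out$n_orfs <= 0) ||
      any(out$gc <= 0 | out$gc >= 100)) {
    abort("genome_size and n_orfs must be positive and gc strictly in (0, 100)")
  }
  if (any(lengths(out$host_strains) == 0L)) {
    abort("every phage needs at least one host strain")
  }
  out
}

#' Summary statistics over a phage metadata table
#'
#' @param rows a metadata tibble as returned by [read_metadata()].
#' @return an object of class `metadata_summary` with the record count,
#'   per-group counts, ORF count mean (raw and rounded)/min/max, mean genome
#'   size in kb, and the number of phages listing each host strain.
#' @export
summarize_metadata <- function(rows) {
  if (nrow(rows) == 0L) abort("empty metadata table")
  strains <- unlist(rows$host_strains)
  structure(list(
    n_records = nrow(rows),
    group_counts = table(factor(rows$group, levels = PHAGE_GROUPS)),
    orf_mean = mean(rows$n_orfs),
    orf_mean_rounded = as.integer(round(mean(rows$n_orfs))),
    orf_min = min(rows$n_orfs),
    orf_max = max(rows$n_orfs),
    size_mean_kb = mean(rows$genome_size) / 1000,
    phages_per_strain = dplyr::count(tibble(strain = strains), .data$strain,
                                     name = "n_phages")
  ), class = "metadata_summary")
}

#' @export
print.metadata_summary <- function(x, ...) {
  cat("Phage metadata summary:", x$n_records, "records\n")
  gc <- x$group_counts[x$group_counts > 0]
  cat("  groups:", paste(names(gc), gc, sep = "=", collapse = ", "), "\n")
  cat(sprintf("  ORFs: %d-%d (mean %.1f, ~%d); genome %.1f kb mean\n",
              x$orf_min, x$orf_max, x$orf_mean, x$orf_mean_rounded,
              x$size_mean_kb))
  invisible(x)
}

#' Host-range table from metadata
#'
#' @param rows metadata tibble.
#' @return long tibble `phage`, `strain`, one row per listed host.
#' @export
host_range_from_metadata <- function(rows) {
  tidyr::unnest(dplyr::select(rows, "phage", strain = "host_strains"),
                "strain")
}

#' Read a host-range table
#'
#' Long TSV with columns `phage`, `strain`, one row per phage-strain
#' infection link (the format [write_population()] emits).
#'
#' @param path TSV file path.
#' @return tibble `phage`, `strain`.
#' @export
read_host_range <- function(path) {
  df <- readr::read_tsv(path, col_types = "cc")
  if (!all(c("phage", "strain") %in% names(df))) {
    abort("host-range table needs columns phage, strain")
  }
  if (any(!nzchar(df$phage)) || any(!nzchar(df$strain)) || anyNA(df)) {
    abort("phage and strain ids must be non-empty")
  }
  df
}

#' Bundled study tables
#'
#' `phage_metadata()` returns the characteristics of the 55 newly sequenced
#' CHPC phages (host strains, group, isolation year/place, genome size, ORF
#' count, GC, accession). `rbp_genotype_table()` returns the 43-phage analysis
#' set with each phage's RBP phylogeny cluster (I-VII) and its host strain's
#' EPS (A-F) and RGP (A-E) genotype.
#'
#' @return a tibble.
#' @export
phage_metadata <- function() {
  read_metadata(system.file("extdata", "phage_metadata.tsv",
                            package = "phagepan", mustWork = TRUE))
}

#' @rdname phage_metadata
#' @export
rbp_genotype_table <- function() {
  readr::read_tsv(system.file("extdata", "rbp_genotype_table.tsv",
                              package = "phagepan", mustWork = TRUE),
                  col_types = "ccccc")
}
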