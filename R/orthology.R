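#' Orthology threshold presets
#'
#' Thresholds applied to every pairwise alignment before best-hit selection.
#' The phage-pangenome preset requires 50% identity and 50% coverage; the
#' operon preset lowers identity to 40% (horizontally transferred operon
#' genes diverge faster) but demands 80% coverage. `coverage_mode = "both"`
#' applies the coverage floor to both sequences; `"one"` accepts a hit when
#' either sequence reaches it. `kmer_min` is the shared distinct 4-mer count
#' under which a pair is skipped without alignment (0 disables the
#' prefilter).
#'
#' @param min_identity,min_coverage fractions in (0, 1].
#' @param similarity near-best expansion factor; only the strict value 1
#'   (reciprocal best hits only) is implemented.
#' @param coverage_mode `"both"` (default) or `"one"`.
#' @param kmer_min integer >= 0.
#' @param scoring an [align_scoring()].
#' @return an `orthology_params` object.
#' @export
orthology_params <- function(min_identity = 0.5, min_coverage = 0.5,
                             similarity = 1, coverage_mode = c("both", "one"),
                             kmer_min = 3, scoring = align_scoring()) {
  stopifnot(min_identity > 0, min_identity <= 1,
            min_coverage > 0, min_coverage <= 1, kmer_min >= 0)
  if (!identical(as.numeric(similarity), 1)) {
    abort("only similarity = 1 (strict reciprocal best hits) is implemented")
  }
  structure(list(min_identity = min_identity, min_coverage = min_coverage,
                 similarity = 1, coverage_mode = match.arg(coverage_mode),
                 kmer_min = as.integer(kmer_min), scoring = scoring),
            class = "orthology_params")
}

#' @rdname orthology_params
#' @export
operon_params <- function(...) {
  orthology_params(min_identity = 0.40, min_coverage = 0.80, ...)
}

check_proteome <- function(proteome) {
  need <- c("genome", "gene", "protein")
  if (!all(need %in% names(proteome))) {
    abort("proteome table needs columns genome, gene, protein")
  }
  if (nrow(proteome) == 0L) abort("empty proteome table")
  if (anyDuplicated(gene_uid(proteome$genome, proteome$gene))) {
    abort("gene ids must be unique within each genome")
  }
  n_empty <- dplyr::count(proteome, .data$genome)
  invisible(proteome)
}

#' All-vs-all proteome comparison
#'
#' Globally aligns every protein against every protein of every *other*
#' genome (self-genome pairs are excluded, matching reciprocal-best-hit
#' semantics) and retains alignments passing the identity and coverage
#' thresholds. Hits are reported in both directions, so each retained
#' unordered pair contributes two rows.
#'
#' @param proteome tibble with columns `genome`, `gene`, `protein`.
#' @param params an [orthology_params()].
#' @return tibble of hits: `query`, `subject` (qualified `genome|gene` ids),
#'   `query_genome`, `subject_genome`, `identity`, `cov_q`, `cov_s`, `score`.
#' @export
all_vs_all <- function(proteome, params = orthology_params()) {
  check_proteome(proteome)
  if (length(unique(proteome$genome)) < 2L) {
    abort("need proteins from at least two genomes")
  }
  seqs <- toupper(proteome$protein)
  if (any(!nzchar(seqs))) abort("empty protein sequence in proteome")
  gid <- match(proteome$genome, unique(proteome$genome))
  hits <- cpp_all_vs_all(seqs, gid, params$scoring$matrix,
                         params$scoring$gap_open, params$scoring$gap_extend,
                         params$min_identity, params$min_coverage,
                         params$kmer_min,
                         params$coverage_mode == "both")
  uid <- gene_uid(proteome$genome, proteome$gene)
  fwd <- tibble(query = uid[hits$query], subject = uid[hits$subject],
                query_genome = proteome$genome[hits$query],
                subject_genome = proteome$genome[hits$subject],
                identity = hits$identity, cov_q = hits$cov_q,
                cov_s = hits$cov_s, score = hits$score)
  rev <- tibble(query = fwd$subject, subject = fwd$query,
                query_genome = fwd$subject_genome,
                subject_genome = fwd$query_genome,
                identity = fwd$identity, cov_q = fwd$cov_s,
                cov_s = fwd$cov_q, score = fwd$score)
  dplyr::arrange(dplyr::bind_rows(fwd, rev), .data$query, .data$subject)
}

#' Reciprocal (bidirectional) best hits
#'
#' For every query gene and target genome the highest-scoring retained hit is
#' the best hit (ties broken by lexicographic subject id); an undirected edge
#' is kept when two genes are each other's best hit.
#'
#' @param hits hit table from [all_vs_all()].
#' @return tibble of edges `gene_a`, `gene_b` (qualified ids, `gene_a <
#'   gene_b`).
#' @export
bbh_edges <- function(hits) {
  if (nrow(hits) == 0L) {
    return(tibble(gene_a = character(), gene_b = character()))
  }
  best <- hits |>
    dplyr::arrange(.data$query, .data$subject_genome,
                   dplyr::desc(.data$score), .data$subject) |>
    dplyr::distinct(.data$query, .data$subject_genome, .keep_all = TRUE) |>
    dplyr::select("query", "subject")
  key <- paste(best$query, best$subject, sep = "\r")
  mutual <- best[paste(best$subject, best$query, sep = "\r") %in% key, ]
  e <- tibble(gene_a = pmin(mutual$query, mutual$subject),
              gene_b = pmax(mutual$query, mutual$subject))
  dplyr::arrange(dplyr::distinct(e), .data$gene_a, .data$gene_b)
}

#' Ortholog groups as connected components of the best-hit graph
#'
#' Genes untouched by any edge become singleton groups ("unique genes").
#' Group ids are the lexicographically smallest member id, which doubles as
#' the representative.
#'
#' @param edges edge tibble from [bbh_edges()].
#' @param all_genes character vector of all qualified gene ids (so isolated
#'   genes are kept); a proteome tibble is also accepted.
#' @return tibble `group_id`, `gene`.
#' @export
ortholog_groups <- function(edges, all_genes) {
  if (is.data.frame(all_genes)) {
    all_genes <- gene_uid(all_genes$genome, all_genes$gene)
  }
  all_genes <- sort(unique(c(all_genes, edges$gene_a, edges$gene_b)))
  comp <- setNames(seq_along(all_genes), all_genes)
  if (nrow(edges) > 0L) {
    g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                       vertices = all_genes)
    comp <- igraph::components(g)$membership[all_genes]
  }
  out <- tibble(gene = all_genes, comp = unname(comp)) |>
    dplyr::group_by(.data$comp) |>
    dplyr::mutate(group_id = min(.data$gene)) |>
    dplyr::ungroup() |>
    dplyr::select("group_id", "gene") |>
    dplyr::arrange(.data$group_id, .data$gene)
  out
}

#' Write hit table / ortholog groups as TSV
#' @param x a hit or group tibble.
#' @param path file path.
#' @export
write_orthology <- function(x, path) {
  readr::write_tsv(x, path)
  invisible(path)
}
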