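new_pangenome_matrix <- function(m) {
  stopifnot(is.logical(m), !is.null(rownames(m)), !is.null(colnames(m)))
  structure(m, class = c("pangenome_matrix", "matrix"))
}

unclass_matrix <- function(x) {
  m <- unclass(x)
  attr(m, "class") <- NULL
  m
}

#' Genome x ortholog-group presence/absence matrix
#'
#' A cell is `TRUE` when the genome carries at least one member of the group
#' (paralogs collapse to a single presence). Columns are sorted by group id;
#' rows by genome id unless `genomes` supplies an order.
#'
#' @param groups tibble from [ortholog_groups()] (`group_id`, `gene` with
#'   qualified `genome|gene` ids).
#' @param genomes optional character vector of genomes to include (errors if
#'   a member gene maps to a genome not listed).
#' @return a `pangenome_matrix` (logical matrix with dimnames).
#' @export
build_matrix <- function(groups, genomes = NULL) {
  if (nrow(groups) == 0L) abort("no ortholog groups")
  gen <- uid_genome(groups$gene)
  if (is.null(genomes)) {
    genomes <- sort(unique(gen))
  } else if (length(orphan <- setdiff(unique(gen), genomes))) {
    abort(paste("genes map to unknown genomes:",
                paste(orphan, collapse = ", ")))
  }
  gids <- sort(unique(groups$group_id))
  m <- matrix(FALSE, length(genomes), length(gids),
              dimnames = list(genomes, gids))
  m[cbind(match(gen, genomes), match(groups$group_id, gids))] <- TRUE
  new_pangenome_matrix(m)
}

#' @export
print.pangenome_matrix <- function(x, ...) {
  m <- unclass_matrix(x)
  cat("Pangenome matrix:", nrow(m), "genomes x", ncol(m), "ortholog groups\n")
  cat("  fill:", sprintf("%.1f%%", 100 * mean(m)), "\n")
  invisible(x)
}

#' @export
as_tibble.pangenome_matrix <- function(x, ...) {
  m <- unclass_matrix(x)
  dplyr::bind_cols(tibble(genome = rownames(m)),
                   as_tibble(m + 0L, .name_repair = "minimal"))
}

#' Jaccard distances between genome gene-content profiles
#'
#' `d(i, j) = 1 - |i AND j| / |i OR j|` over the presence/absence rows.
#'
#' @param matrix a `pangenome_matrix` (or logical/0-1 matrix with rownames).
#' @return a [stats::dist].
#' @export
jaccard_distances <- function(matrix) {
  m <- unclass_matrix(matrix)
  storage.mode(m) <- "logical"
  if (nrow(m) < 2L) abort("need at least two genomes")
  if (sum(rowSums(m) == 0L) >= 2L) {
    abort("two all-zero rows: Jaccard distance undefined")
  }
  dist(m, method = "binary")
}

#' UPGMA dendrogram
#'
#' Average-linkage agglomeration over a distance matrix via
#' [stats::hclust()]; merge heights are the inter-cluster average distances
#' and are non-decreasing. Use [dendrogram_tree()] for the ultrametric tree,
#' whose node heights are half the merge heights so that leaf-to-leaf path
#' lengths reproduce the input distances.
#'
#' @param d a [stats::dist] or symmetric matrix with zero diagonal.
#' @return an `hclust` object.
#' @export
upgma <- function(d) {
  if (!inherits(d, "dist")) {
    m <- as.matrix(d)
    if (!isSymmetric(unname(m)) || any(diag(m) != 0)) {
      abort("distance matrix must be symmetric with zero diagonal")
    }
    d <- as.dist(m)
  }
  if (anyNA(d) || any(!is.finite(d))) abort("non-finite distance")
  if (any(d < 0)) abort("negative distance")
  hclust(d, method = "average")
}

#' @rdname upgma
#' @param hc an `hclust` from [upgma()].
#' @export
dendrogram_tree <- function(hc) {
  ape::as.phylo(hc)
}

#' Cut a dendrogram into clusters
#'
#' Standard [stats::cutree()] cut at `k` clusters or at `height`; exactly one
#' of the two must be given. Cluster labels are renumbered deterministically:
#' cluster 1 contains the alphabetically smallest leaf, and so on.
#'
#' @param hc an `hclust`.
#' @param k number of clusters.
#' @param height cut height.
#' @return tibble `leaf`, `cluster` (integer).
#' @export
cut_dendrogram <- function(hc, k = NULL, height = NULL) {
  if (is.null(k) == is.null(height)) {
    abort("give exactly one of `k` or `height`")
  }
  if (!is.null(k) && (k < 1 || k > length(hc$labels))) {
    abort("`k` must be between 1 and the number of leaves")
  }
  cl <- if (is.null(height)) cutree(hc, k = k) else cutree(hc, h = height)
  first_leaf <- vapply(split(names(cl), cl), min, "")
  relabel <- rank(first_leaf, ties.method = "first")
  out <- tibble(leaf = names(cl),
                cluster = as.integer(relabel[as.character(cl)]))
  dplyr::arrange(out, .data$leaf)
}

#' Pangenome summary statistics
#'
#' Counts the pangenome size, unique (singleton-column) genes, per-cluster
#' core genes (columns present in every genome of the cluster), the global
#' core, and near-core columns missing from at most `max_missing` genomes
#' overall.
#'
#' @param matrix a `pangenome_matrix`.
#' @param cluster_labels tibble `leaf`/`genome`, `cluster` covering all rows
#'   (e.g. from [cut_dendrogram()]); `NULL` treats all genomes as one
#'   cluster.
#' @param max_missing near-core tolerance (default 1 genome).
#' @return object of class `pangenome_stats`.
#' @export
pangenome_stats <- function(matrix, cluster_labels = NULL, max_missing = 1) {
  m <- unclass_matrix(matrix)
  if (is.null(cluster_labels)) {
    cluster_labels <- tibble(leaf = rownames(m), cluster = 1L)
  }
  names(cluster_labels)[1] <- "leaf"
  if (!all(rownames(m) %in% cluster_labels$leaf)) {
    abort("cluster labels must cover every genome")
  }
  cl <- setNames(cluster_labels$cluster, cluster_labels$leaf)[rownames(m)]
  col_n <- colSums(m)
  core_by_group <- lapply(split(rownames(m), cl), function(rows) {
    colnames(m)[colSums(m[rows, , drop = FALSE]) == length(rows)]
  })
  n_missing <- nrow(m) - col_n
  near <- which(n_missing > 0 & n_missing <= max_missing)
  structure(list(
    n_pangenome_groups = ncol(m),
    n_unique = sum(col_n == 1L),
    unique_fraction = mean(col_n == 1L),
    n_global_core = sum(col_n == nrow(m)),
    core_by_group = core_by_group,
    near_core = tibble(group_id = colnames(m)[near],
                       n_missing = as.integer(n_missing[near]))
  ), class = "pangenome_stats")
}

#' @export
print.pangenome_stats <- function(x, ...) {
  cat("Pangenome:", x$n_pangenome_groups, "ortholog groups;",
      x$n_unique, sprintf("unique (%.0f%%);", 100 * x$unique_fraction),
      x$n_global_core, "global core\n")
  for (g in names(x$core_by_group)) {
    cat("  cluster", g, "core genes:", length(x$core_by_group[[g]]), "\n")
  }
  if (nrow(x$near_core)) {
    cat("  near-core columns:", nrow(x$near_core), "\n")
  }
  invisible(x)
}

#' @export
glance.pangenome_stats <- function(x, ...) {
  tibble(n_pangenome_groups = x$n_pangenome_groups, n_unique = x$n_unique,
         unique_fraction = x$unique_fraction,
         n_global_core = x$n_global_core,
         n_near_core = nrow(x$near_core))
}

#' Heatmap-style plot of a presence/absence matrix
#'
#' @param object a `pangenome_matrix`.
#' @param ... ignored.
#' @return a ggplot.
#' @export
autoplot.pangenome_matrix <- function(object, ...) {
  df <- tidyr::pivot_longer(as_tibble(object), -"genome",
                            names_to = "group", values_to = "present")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$genome,
                                   fill = factor(.data$present))) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_manual(values = c(`0` = "white", `1` = "firebrick"),
                               name = "present") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank()) +
    ggplot2::labs(x = "ortholog group", y = NULL)
}
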