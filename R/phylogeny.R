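#' Concatenate per-gene core alignments
#'
#' Joins one multiple alignment per core gene into a single supermatrix, one
#' row per genome, genes in lexicographic name order (so the result is
#' independent of input order). Every alignment must contain every genome:
#' a missing row contradicts the definition of a core gene.
#'
#' @param alignments named list of `phage_msa`, one per core ortholog group.
#' @return a `phage_msa` with rows of total length `sum(lengths)`.
#' @export
concatenate_core <- function(alignments) {
  if (length(alignments) == 0L) abort("no alignments given")
  if (is.null(names(alignments))) abort("`alignments` must be named")
  alignments <- alignments[order(names(alignments))]
  labs <- sort(names(alignments[[1]]))
  for (nm in names(alignments)) {
    if (!setequal(names(alignments[[nm]]), labs)) {
      abort(paste0("alignment '", nm, "' does not cover every genome: ",
                   "not a core gene set"))
    }
  }
  rows <- vapply(labs, function(l) {
    paste(vapply(alignments, function(a) unclass(a)[[l]], ""), collapse = "")
  }, "")
  new_msa(rows)
}

#' Neighbor-joining tree
#'
#' Standard Saitou-Nei neighbor joining (via ape), followed by a cleanup pass
#' that clamps negative branch lengths to zero and moves the deficit onto the
#' sister branch so path lengths through the parent are preserved. Exactly
#' consistent on additive distance matrices.
#'
#' @param d a [stats::dist] or symmetric matrix, at least 3 taxa.
#' @return an unrooted [ape::phylo] tree.
#' @export
neighbor_joining <- function(d) {
  m <- as.matrix(d)
  if (nrow(m) < 3L) abort("neighbor joining needs at least 3 taxa")
  if (!isSymmetric(unname(m))) abort("distance matrix must be symmetric")
  tr <- ape::nj(as.dist(m))
  neg <- which(tr$edge.length < 0)
  for (e in neg) {
    parent <- tr$edge[e, 1]
    sib <- setdiff(which(tr$edge[, 1] == parent), e)
    if (length(sib)) {
      tr$edge.length[sib[1]] <- tr$edge.length[sib[1]] + tr$edge.length[e]
    }
    tr$edge.length[e] <- 0
  }
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' NJ tree from a protein alignment
#'
#' Convenience: Poisson-corrected distances ([msa_distances()]) followed by
#' [neighbor_joining()].
#'
#' @param msa a `phage_msa` with >= 3 rows.
#' @param correction passed to [msa_distances()].
#' @param cap_undefined passed to [msa_distances()].
#' @export
msa_nj_tree <- function(msa, correction = "poisson", cap_undefined = FALSE) {
  neighbor_joining(msa_distances(msa, correction, cap_undefined))
}

#' Bootstrap support for an alignment-derived NJ tree
#'
#' Resamples alignment columns with replacement, rebuilds the NJ tree for
#' each replicate, and annotates the original tree's internal edges with the
#' percentage of replicates containing the same bipartition. Deterministic
#' given `seed`.
#'
#' @param msa a `phage_msa` (>= 2 columns, >= 4 rows for internal edges).
#' @param n_reps number of replicates (>= 1).
#' @param seed integer seed.
#' @param correction distance correction, as in [msa_distances()].
#' @return the NJ tree with `node.label` holding supports in `[0, 100]`.
#' @export
bootstrap_support <- function(msa, n_reps = 100, seed = 1,
                              correction = "poisson") {
  stopifnot(n_reps >= 1)
  cols <- nchar(unclass(msa)[[1]])
  if (cols < 2L) abort("alignment must have more than one column")
  mat <- msa_matrix(msa)
  rownames(mat) <- names(msa)
  tree_from <- function(m) {
    rows <- setNames(apply(m, 1, paste, collapse = ""), rownames(m))
    msa_nj_tree(new_msa(rows), correction, cap_undefined = TRUE)
  }
  base_tree <- tree_from(mat)
  reps <- with_seed(seed, {
    lapply(seq_len(n_reps), function(i) {
      tree_from(mat[, sample.int(cols, cols, replace = TRUE), drop = FALSE])
    })
  })
  counts <- ape::prop.clades(base_tree, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0
  base_tree$node.label <- round(100 * counts / n_reps, 1)
  base_tree
}

#' Select receptor-binding proteins for phylogeny
#'
#' Picks each genome's RBP by annotation (product string match) and excludes
#' RBPs whose best global-alignment identity against every other RBP falls
#' below `min_similarity` (boundary closed: exactly the threshold is kept),
#' since no homology-based phylogeny can be built for them. Genomes without
#' an RBP annotation are recorded as excluded with reason `"not found"`.
#'
#' @param proteome tibble `genome`, `gene`, `product`, `protein`.
#' @param min_similarity identity threshold, default 0.30.
#' @param product_pattern regular expression matched (case-insensitively)
#'   against the `product` column.
#' @param scoring an [align_scoring()].
#' @return an `rbp_set`: list with `included` (named character vector of RBP
#'   sequences) and `excluded` (tibble `genome`, `reason`, `max_identity`).
#' @export
select_rbps <- function(proteome, min_similarity = 0.30,
                        product_pattern = "receptor binding protein",
                        scoring = align_scoring()) {
  stopifnot(min_similarity >= 0, min_similarity <= 1)
  cand <- proteome |>
    dplyr::filter(grepl(product_pattern, .data$product, ignore.case = TRUE)) |>
    dplyr::arrange(.data$genome, .data$gene) |>
    dplyr::distinct(.data$genome, .keep_all = TRUE)
  missing <- setdiff(unique(proteome$genome), cand$genome)
  excluded <- tibble(genome = missing,
                     reason = rep("not found", length(missing)),
                     max_identity = rep(NA_real_, length(missing)))
  seqs <- setNames(toupper(cand$protein), cand$genome)
  if (length(seqs) >= 2L) {
    hits <- cpp_all_vs_all(unname(seqs), seq_along(seqs), scoring$matrix,
                           scoring$gap_open, scoring$gap_extend,
                           0, 0, 0L, TRUE)
    best <- rep(0, length(seqs))
    for (r in seq_len(nrow(hits))) {
      q <- hits$query[r]; s <- hits$subject[r]
      best[q] <- max(best[q], hits$identity[r])
      best[s] <- max(best[s], hits$identity[r])
    }
    low <- best < min_similarity
    if (any(low)) {
      excluded <- dplyr::bind_rows(excluded,
        tibble(genome = names(seqs)[low], reason = "low similarity",
               max_identity = best[low]))
      seqs <- seqs[!low]
    }
  }
  structure(list(included = seqs,
                 excluded = dplyr::arrange(excluded, .data$genome)),
            class = "rbp_set")
}

#' @export
print.rbp_set <- function(x, ...) {
  cat("RBP set:", length(x$included), "included,",
      nrow(x$excluded), "excluded\n")
  if (nrow(x$excluded)) print(x$excluded)
  invisible(x)
}

#' Patristic distances on a tree
#'
#' Sum of branch lengths along the path between every pair of leaves.
#'
#' @param tree an [ape::phylo].
#' @return symmetric matrix with leaf labels.
#' @export
patristic_distances <- function(tree) {
  ape::cophenetic.phylo(tree)
}

#' Tree-based cluster (lineage) assignment
#'
#' Single-linkage clustering of leaves on patristic distances, cut at
#' `threshold`: two leaves share a lineage when connected by a chain of
#' leaves with consecutive patristic distances at or below the threshold.
#' Lineages are labelled with roman numerals ordered by their alphabetically
#' smallest leaf.
#'
#' @param tree an [ape::phylo] with branch lengths.
#' @param threshold positive patristic distance.
#' @return tibble `leaf`, `cluster` (roman numeral character).
#' @export
tree_clusters <- function(tree, threshold) {
  stopifnot(threshold > 0)
  pd <- patristic_distances(tree)
  hc <- hclust(as.dist(pd), method = "single")
  cl <- cutree(hc, h = threshold)
  first_leaf <- vapply(split(names(cl), cl), min, "")
  relabel <- rank(first_leaf, ties.method = "first")
  lab <- roman_labels(max(relabel))
  out <- tibble(leaf = names(cl),
                cluster = lab[relabel[as.character(cl)]])
  dplyr::arrange(out, .data$leaf)
}
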