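#' Flanking marker definitions for the eps and rgp operons
#'
#' The eps (exocellular polysaccharide) cluster lies between `epsA` and a
#' predicted membrane protein (TMS6); the rgp (rhamnose-containing
#' polysaccharide) cluster between `radC` and a bactoprenol glucosyl
#' transferase.
#'
#' @param kind `"eps"` or `"rgp"`.
#' @return a `marker_pair` list with `name`, `left_product`, `right_product`.
#' @export
marker_pair <- function(kind = c("eps", "rgp")) {
  kind <- match.arg(kind)
  def <- switch(kind,
    eps = list(left = "epsA", right = "predicted membrane protein (TMS6)"),
    rgp = list(left = "radC", right = "bactoprenol glucosyl transferase"))
  structure(list(name = kind, left_product = def$left,
                 right_product = def$right), class = "marker_pair")
}

find_marker <- function(genes, product, scoring, marker_seq = NULL,
                        min_marker_identity = 0.5) {
  hit <- which(genes$product == product)
  if (length(hit) == 0L && !is.null(marker_seq)) {
    ids <- vapply(genes$protein, function(p) {
      global_align(p, marker_seq, scoring)$identity
    }, 0)
    hit <- which(ids >= min_marker_identity)
  }
  hit
}

#' Locate a polysaccharide operon between its flanking markers
#'
#' Markers are found by exact product-string match (the annotation path); for
#' genomes annotated with other vocabularies, supply the marker protein
#' sequences and they are called by global-alignment identity >= 0.5. When
#' both markers sit on one contig the cluster is the genes strictly between
#' them (either marker order), `complete = TRUE`. When they sit on two
#' contigs the cluster is read from each marker towards its contig end on the
#' marker's downstream side (strand-aware), `complete = FALSE`, with a
#' warning. A marker found more than once is an error; a marker missing
#' entirely yields a non-fatal typing failure (`found = FALSE`).
#'
#' @param genes annotated gene tibble of one strain ([read_genome()] output:
#'   `gene`, `contig`, `start`, `end`, `strand`, `product`, `protein`).
#' @param markers a [marker_pair()].
#' @param strain strain id recorded in the result (default: `genome` column).
#' @param marker_seqs optional named list/vector with elements `left`,
#'   `right`: marker protein sequences for the homology path.
#' @param scoring an [align_scoring()] for the homology path.
#' @return an `operon_cluster`: list with `strain`, `kind`, `genes` (tibble,
#'   markers excluded, in operon order), `complete`, `n_contigs`, `found`,
#'   `reason`.
#' @export
locate_cluster <- function(genes, markers, strain = NULL, marker_seqs = NULL,
                           scoring = align_scoring()) {
  strain <- strain %||% genes$genome[1]
  genes <- dplyr::arrange(genes, .data$contig, .data$start)
  li <- find_marker(genes, markers$left_product, scoring, marker_seqs$left)
  ri <- find_marker(genes, markers$right_product, scoring, marker_seqs$right)
  fail <- function(reason) {
    structure(list(strain = strain, kind = markers$name,
                   genes = genes[0, ], complete = NA, n_contigs = 0L,
                   found = FALSE, reason = reason),
              class = "operon_cluster")
  }
  if (length(li) > 1L || length(ri) > 1L) {
    abort(paste0("marker found more than once in strain ", strain,
                 " (", markers$name, " cluster)"))
  }
  if (length(li) == 0L || length(ri) == 0L) {
    side <- c("left", "right")[c(length(li) == 0L, length(ri) == 0L)]
    return(fail(paste(paste(side, collapse = "+"), "marker not found")))
  }
  ok <- function(rows, complete, n_contigs) {
    structure(list(strain = strain, kind = markers$name,
                   genes = rows, complete = complete,
                   n_contigs = n_contigs, found = TRUE, reason = NA_character_),
              class = "operon_cluster")
  }
  if (genes$contig[li] == genes$contig[ri]) {
    lo <- min(li, ri); hi <- max(li, ri)
    rows <- genes[seq(lo, hi), ][-c(1, hi - lo + 1), ]
    return(ok(rows, complete = TRUE, n_contigs = 1L))
  }
  # two contigs: walk from each marker towards its contig end, downstream of
  # the marker on its own strand (left marker) / upstream (right marker)
  warn(paste0("strain ", strain, ": ", markers$name,
              " markers on two contigs; cluster may be incomplete"))
  take_side <- function(idx, downstream) {
    ctg <- genes$contig[idx]
    on_ctg <- which(genes$contig == ctg)
    fwd <- genes$strand[idx] != "-"
    after <- if (downstream == fwd) on_ctg[on_ctg > idx] else on_ctg[on_ctg < idx]
    genes[after, ]
  }
  rows <- dplyr::bind_rows(take_side(li, downstream = TRUE),
                           take_side(ri, downstream = FALSE))
  rows <- dplyr::distinct(rows)
  ok(rows, complete = FALSE, n_contigs = 2L)
}

#' @export
print.operon_cluster <- function(x, ...) {
  if (!x$found) {
    cat("Operon", x$kind, "in", x$strain, ": not found (", x$reason, ")\n")
  } else {
    cat("Operon", x$kind, "in", x$strain, ":", nrow(x$genes), "genes,",
        if (isTRUE(x$complete)) "complete" else "partial",
        sprintf("(%d contig%s)\n", x$n_contigs, if (x$n_contigs > 1) "s" else ""))
  }
  invisible(x)
}

#' Strain x operon-gene presence/absence matrix
#'
#' Runs the orthology machinery over the extracted operon genes of several
#' strains under the operon preset (40% identity, 80% coverage) and builds
#' the presence/absence matrix used for genotype assignment.
#'
#' @param clusters list of `operon_cluster` objects of one kind; clusters
#'   with `found = FALSE` are dropped.
#' @param params an [orthology_params()]; default [operon_params()].
#' @return a `pangenome_matrix` (strains x operon ortholog groups).
#' @export
operon_matrix <- function(clusters, params = operon_params()) {
  clusters <- Filter(function(x) isTRUE(x$found), clusters)
  if (length(clusters) < 2L) {
    abort("need extracted operon clusters from at least two strains")
  }
  kinds <- unique(vapply(clusters, `[[`, "", "kind"))
  if (length(kinds) != 1L) abort("clusters mix eps and rgp kinds")
  proteome <- dplyr::bind_rows(lapply(clusters, function(x) {
    tibble(genome = x$strain, gene = x$genes$gene, protein = x$genes$protein)
  }))
  hits <- all_vs_all(proteome, params)
  groups <- ortholog_groups(bbh_edges(hits), proteome)
  build_matrix(groups, genomes = vapply(clusters, `[[`, "", "strain"))
}

#' Assign genotype letters by operon gene content
#'
#' Jaccard + UPGMA clustering of the operon presence/absence matrix, cut at
#' `k` clusters or at `height` (default height 0.5). Letters are assigned
#' A, B, ... in decreasing cluster size, ties broken by the alphabetically
#' smallest strain.
#'
#' @param matrix a `pangenome_matrix` from [operon_matrix()].
#' @param k number of genotypes (optional).
#' @param height cut height when `k` is not given (default 0.5).
#' @return tibble `strain`, `genotype`; the dendrogram is kept in attribute
#'   `"dendrogram"`.
#' @export
assign_genotypes <- function(matrix, k = NULL, height = 0.5) {
  m <- unclass_matrix(matrix)
  if (!is.null(k) && k > nrow(m)) abort("`k` exceeds the strain count")
  hc <- upgma(jaccard_distances(matrix))
  cl <- if (is.null(k)) cutree(hc, h = height) else cutree(hc, k = k)
  size <- table(cl)
  first_leaf <- vapply(split(names(cl), cl), min, "")
  o <- order(-as.integer(size), first_leaf)
  relabel <- setNames(seq_along(o), names(size)[o])
  out <- tibble(strain = names(cl),
                genotype = LETTERS[relabel[as.character(cl)]])
  out <- dplyr::arrange(out, .data$strain)
  attr(out, "dendrogram") <- hc
  out
}

#' Type strains by their eps and rgp operon gene content
#'
#' End-to-end convenience: locates both operons in every strain, builds both
#' operon matrices, assigns EPS and RGP genotype letters, and reports
#' completeness flags.
#'
#' @param strain_genes tibble of annotated genes for all strains (columns
#'   `genome`, `gene`, `contig`, `start`, `end`, `strand`, `product`,
#'   `protein`).
#' @param k_eps,k_rgp optional cluster counts; default height cut.
#' @param height cut height used when `k` is not given.
#' @param params orthology preset for operon genes.
#' @return tibble `strain`, `eps_genotype`, `rgp_genotype`, `eps_complete`,
#'   `rgp_complete` (NA letters for strains whose markers were not found).
#' @export
type_strains <- function(strain_genes, k_eps = NULL, k_rgp = NULL,
                         height = 0.5, params = operon_params()) {
  strains <- unique(strain_genes$genome)
  one_kind <- function(kind, k) {
    mp <- marker_pair(kind)
    cl <- lapply(strains, function(s) {
      locate_cluster(dplyr::filter(strain_genes, .data$genome == s), mp,
                     strain = s)
    })
    names(cl) <- strains
    mat <- operon_matrix(cl, params)
    gt <- assign_genotypes(mat, k = k, height = height)
    complete <- vapply(cl, function(x) isTRUE(x$complete), NA)
    dplyr::left_join(tibble(strain = strains, complete = complete),
                     gt, by = "strain")
  }
  eps <- one_kind("eps", k_eps)
  rgp <- one_kind("rgp", k_rgp)
  tibble(strain = strains,
         eps_genotype = eps$genotype[match(strains, eps$strain)],
         rgp_genotype = rgp$genotype[match(strains, rgp$strain)],
         eps_complete = eps$complete[match(strains, eps$strain)],
         rgp_complete = rgp$complete[match(strains, rgp$strain)])
}
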