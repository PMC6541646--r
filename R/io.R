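#' Read an annotated genome (nucleotide FASTA + GFF3)
#'
#' Extracts every CDS feature, translates it with the standard bacterial
#' genetic code (table 11, reverse-complementing minus-strand features) and
#' returns one record per gene. Coordinates are converted from 1-based
#' inclusive GFF3 to the package's internal 0-based half-open convention
#' (`start`, `end`). A trailing stop codon is stripped from the translation;
#' CDS whose length is not a multiple of three or that contain an internal
#' stop are dropped with a warning.
#'
#' @param fasta_path nucleotide FASTA; contig names must match the GFF3
#'   `seqid` column.
#' @param gff_path GFF3 annotation with CDS features carrying `ID` and
#'   `product` attributes.
#' @param genome_id genome identifier recorded in the output; defaults to the
#'   FASTA file name without extension.
#' @return a tibble with columns `genome`, `gene`, `contig`, `start`, `end`,
#'   `strand`, `product`, `protein`, in coordinate order.
#' @export
read_genome <- function(fasta_path, gff_path, genome_id = NULL) {
  contigs <- Biostrings::readDNAStringSet(fasta_path)
  names(contigs) <- sub("\\s.*$", "", names(contigs))
  genome_id <- genome_id %||% sub("\\.[^.]*$", "", basename(fasta_path))
  gr <- rtracklayer::import(gff_path)
  gr <- gr[gr$type == "CDS"]
  if (length(gr) == 0L) {
    return(tibble(genome = character(), gene = character(),
                  contig = character(), start = integer(), end = integer(),
                  strand = character(), product = character(),
                  protein = character()))
  }
  seqid <- as.character(GenomicRanges::seqnames(gr))
  missing_contig <- setdiff(unique(seqid), names(contigs))
  if (length(missing_contig)) {
    abort(paste0("GFF3 refers to contigs absent from the FASTA: ",
                 paste(missing_contig, collapse = ", ")))
  }
  o <- order(seqid, GenomicRanges::start(gr))
  gr <- gr[o]; seqid <- seqid[o]
  ids <- gr$ID %||% paste0("cds", seq_along(gr))
  prods <- gr$product %||% rep(NA_character_, length(gr))
  keep <- logical(length(gr))
  prot <- character(length(gr))
  code <- Biostrings::getGeneticCode("11")
  for (k in seq_along(gr)) {
    s <- GenomicRanges::start(gr)[k]; e <- GenomicRanges::end(gr)[k]
    nt <- Biostrings::subseq(contigs[[seqid[k]]], s, e)
    if ((e - s + 1) %% 3 != 0) {
      warn(paste0("CDS ", ids[k], ": length not a multiple of 3; record dropped"))
      next
    }
    if (as.character(GenomicRanges::strand(gr))[k] == "-") {
      nt <- Biostrings::reverseComplement(nt)
    }
    aa <- as.character(Biostrings::translate(nt, genetic.code = code,
                                             no.init.codon = TRUE,
                                             if.fuzzy.codon = "X"))
    aa <- sub("\\*$", "", aa)
    if (grepl("*", aa, fixed = TRUE)) {
      warn(paste0("CDS ", ids[k], ": internal stop codon; record dropped"))
      next
    }
    keep[k] <- TRUE
    prot[k] <- aa
  }
  tibble(
    genome = genome_id,
    gene = ids[keep],
    contig = seqid[keep],
    start = GenomicRanges::start(gr)[keep] - 1L,
    end = GenomicRanges::end(gr)[keep],
    strand = as.character(GenomicRanges::strand(gr))[keep],
    product = prods[keep],
    protein = prot[keep]
  )
}

#' Write an annotated genome back to FASTA + GFF3
#'
#' Inverse of [read_genome()] at the coordinate level: internal 0-based
#' half-open intervals are emitted as 1-based inclusive GFF3.
#'
#' @param contigs named character vector of contig nucleotide sequences.
#' @param genes tibble with columns `gene`, `contig`, `start`, `end`,
#'   `strand`, `product` (internal coordinates).
#' @param fasta_path,gff_path output paths.
#' @export
write_genome <- function(contigs, genes, fasta_path, gff_path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(contigs), fasta_path)
  gr <- GenomicRanges::GRanges(
    seqnames = genes$contig,
    ranges = IRanges::IRanges(start = genes$start + 1L, end = genes$end),
    strand = genes$strand)
  gr$type <- "CDS"
  gr$phase <- 0L
  gr$ID <- genes$gene
  gr$product <- genes$product
  gr$source <- "phagepan"
  rtracklayer::export(gr, gff_path, format = "gff3")
  invisible(gff_path)
}

#' Read/write a multi-protein FASTA proteome
#'
#' Headers use the `genome_id|gene_id` convention, so a single file can hold
#' several pre-translated proteomes and skip nucleotide translation entirely.
#'
#' @param path FASTA path.
#' @return `read_proteins()`: tibble with `genome`, `gene`, `protein`.
#' @export
read_proteins <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  hdr <- sub("\\s.*$", "", names(x))
  if (!all(grepl("|", hdr, fixed = TRUE))) {
    abort("protein FASTA headers must be of the form genome_id|gene_id")
  }
  tibble(genome = uid_genome(hdr), gene = uid_gene(hdr),
         protein = as.character(x))
}

#' @rdname read_proteins
#' @param proteome tibble with `genome`, `gene`, `protein` columns.
#' @export
write_proteins <- function(proteome, path) {
  seqs <- setNames(proteome$protein, gene_uid(proteome$genome, proteome$gene))
  Biostrings::writeXStringSet(Biostrings::AAStringSet(seqs), path)
  invisible(path)
}

#' Newick tree I/O
#'
#' Thin wrappers over ape's newick reader/writer that enforce unique leaf
#' labels and branch lengths printed to six significant digits, so a
#' write/read round trip preserves topology, labels and lengths to 1e-6.
#'
#' @param tree an [ape::phylo] tree.
#' @param path file path.
#' @export
write_newick <- function(tree, path) {
  if (anyDuplicated(tree$tip.label)) abort("duplicate leaf labels")
  ape::write.tree(tree, file = path, digits = 6)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) {
  tr <- tryCatch(ape::read.tree(path),
                 error = function(e) abort(paste("newick parse error:",
                                                 conditionMessage(e))))
  if (is.null(tr)) abort("newick parse error")
  tr
}

#' Presence/absence matrix I/O
#'
#' TSV with the genome id in the first column and one 0/1 column per ortholog
#' group; the round trip is lossless.
#'
#' @param matrix a `pangenome_matrix` (see [build_matrix()]).
#' @param path file path.
#' @export
write_matrix <- function(matrix, path) {
  m <- unclass_matrix(matrix)
  if (nrow(m) == 0L || ncol(m) == 0L) abort("refusing to write an empty matrix")
  if (anyDuplicated(rownames(m))) abort("duplicated genome id")
  df <- data.frame(genome = rownames(m), m + 0L, check.names = FALSE)
  readr::write_tsv(df, path)
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  if (ncol(df) < 2L || nrow(df) == 0L) abort("empty or malformed matrix file")
  g <- as.character(df[[1]])
  if (anyDuplicated(g)) abort("duplicated genome id in matrix file")
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!all(m %in% c(0, 1))) abort("matrix cells must be 0 or 1")
  storage.mode(m) <- "logical"
  rownames(m) <- g
  new_pangenome_matrix(m)
}
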