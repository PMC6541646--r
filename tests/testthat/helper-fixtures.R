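# fixture builders: tiny FASTA/GFF genomes and proteome tables, built in code

write_tiny_genome <- function(dir, contigs, features) {
  fasta <- file.path(dir, "g.fna")
  gff <- file.path(dir, "g.gff")
  writeLines(unlist(lapply(names(contigs), function(nm) {
    c(paste0(">", nm), contigs[[nm]])
  })), fasta)
  rows <- vapply(seq_len(nrow(features)), function(i) {
    f <- features[i, ]
    paste(f$seqid, "test", "CDS", f$start, f$end, ".", f$strand, "0",
          paste0("ID=", f$id, ";product=", f$product), sep = "\t")
  }, "")
  writeLines(c("##gff-version 3", rows), gff)
  list(fasta = fasta, gff = gff)
}

# proteome tibble from a named list genome -> named protein vector
proteome_tbl <- function(x, products = NULL) {
  dplyr::bind_rows(lapply(names(x), function(g) {
    tibble::tibble(genome = g, gene = names(x[[g]]),
                   protein = unname(x[[g]]),
                   product = if (is.null(products)) "hypothetical protein"
                             else products[[g]])
  }))
}

new_msa_for_test <- function(rows) phagepan:::new_msa(rows)

# small simulation config used where full desk scale is not needed
small_sim_config <- function(seed = 1, ...) {
  sim_config(genomes_per_group = c(5, 4, 3, 3),
             genes_per_genome = c(18, 24),
             group_pool_size = 40,
             shared_pool_size = 8,
             core_genes_per_group = 8,
             n_strains = 12,
             seed = seed, ...)
}
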