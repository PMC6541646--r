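#' Simulation configuration
#'
#' Defaults emulate the statistical structure of the dairy streptococcal
#' phage-host system the pipeline is built for: four phage groups with
#' genome sizes of 40-63 genes drawn from group-specific gene pools plus a
#' small shared pool (mosaicism), 13 core genes per group, one RBP per
#' genome built from a group-conserved N-terminal region and a
#' lineage-specific variable (VR2) region, and host strains carrying eps and
#' rgp operons whose gene content is genotype-specific (13-22 eps genes,
#' 14-20 rgp genes) between fixed flanking markers. Host range links each
#' phage to strains of the eps genotype matched to its RBP lineage.
#'
#' @param n_groups number of phage groups.
#' @param genomes_per_group genomes per group (length `n_groups`).
#' @param genes_per_genome inclusive integer range of genes per genome.
#' @param group_pool_size ancestral protein families per group pool.
#' @param shared_pool_size families shared across all groups.
#' @param core_genes_per_group families carried by every genome of a group.
#' @param n_rbp_lineages RBP lineages, assigned round-robin to groups.
#' @param n_strains number of host strains.
#' @param n_eps_genotypes,n_rgp_genotypes genotype counts.
#' @param eps_genes_range,rgp_genes_range genes per operon cluster.
#' @param eps_pool_size,rgp_pool_size operon gene family pool sizes.
#' @param rbp_nterm_len,rbp_vr2_len lengths of the conserved and variable
#'   RBP regions (aa).
#' @param rbp_vr2_divergence per-site substitution probability between a
#'   lineage VR2 and the group-ancestral VR2.
#' @param within_lineage_divergence per-site substitution probability of
#'   every gene copy (and of an RBP relative to its lineage VR2).
#' @param host_range_noise probability that a phage's hosts are drawn from a
#'   non-matched genotype.
#' @param hosts_per_phage inclusive range of hosts per phage.
#' @param protein_length_range inclusive range of family protein lengths.
#' @param seed master seed; all randomness flows from it through per-object
#'   substreams.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_groups = 4,
                       genomes_per_group = c(20, 10, 4, 4),
                       genes_per_genome = c(40, 63),
                       group_pool_size = 120,
                       shared_pool_size = 20,
                       core_genes_per_group = 13,
                       n_rbp_lineages = 6,
                       n_strains = 23,
                       n_eps_genotypes = 6,
                       n_rgp_genotypes = 5,
                       eps_genes_range = c(13, 22),
                       rgp_genes_range = c(14, 20),
                       eps_pool_size = 30,
                       rgp_pool_size = 30,
                       rbp_nterm_len = 100,
                       rbp_vr2_len = 200,
                       rbp_vr2_divergence = 0.4,
                       within_lineage_divergence = 0.05,
                       host_range_noise = 0,
                       hosts_per_phage = c(1, 2),
                       protein_length_range = c(100, 400),
                       seed = 1) {
  cfg <- as.list(environment())
  stopifnot(n_groups >= 1, length(genomes_per_group) == n_groups,
            all(genomes_per_group >= 1),
            length(genes_per_genome) == 2,
            genes_per_genome[1] <= genes_per_genome[2],
            core_genes_per_group >= 1,
            core_genes_per_group + 1 <= genes_per_genome[1],
            n_rbp_lineages >= 1, n_strains >= 1,
            n_eps_genotypes >= 1, n_rgp_genotypes >= 1,
            eps_pool_size >= eps_genes_range[2],
            rgp_pool_size >= rgp_genes_range[2],
            rbp_vr2_divergence >= 0, rbp_vr2_divergence <= 1,
            within_lineage_divergence >= 0, within_lineage_divergence <= 1,
            host_range_noise >= 0, host_range_noise <= 1)
  max_accessory <- genes_per_genome[2] - core_genes_per_group - 1
  if (group_pool_size - core_genes_per_group + shared_pool_size < max_accessory) {
    abort("gene pools too small for the configured genes_per_genome range")
  }
  structure(cfg, class = "sim_config")
}

random_protein <- function(len) {
  paste(sample(AA_ALPHABET, len, replace = TRUE), collapse = "")
}

#' Point-mutate a protein sequence
#'
#' Each position is independently substituted with probability `rate` by a
#' uniformly chosen *different* residue of the 20-letter amino-acid
#' alphabet; length is preserved. With `rate = 1` no position keeps its
#' original residue.
#'
#' @param seq protein sequence.
#' @param rate substitution probability per site, in `[0, 1]`.
#' @param seed optional seed; `NULL` uses (and advances) the current RNG
#'   stream.
#' @export
mutate_sequence <- function(seq, rate, seed = NULL) {
  stopifnot(rate >= 0, rate <= 1)
  if (!is.null(seed)) return(with_seed(seed, mutate_sequence(seq, rate)))
  ch <- strsplit(seq, "")[[1]]
  hit <- which(stats::runif(length(ch)) < rate)
  if (length(hit)) {
    old <- match(ch[hit], AA_ALPHABET)
    shift <- sample.int(length(AA_ALPHABET) - 1L, length(hit), replace = TRUE)
    ch[hit] <- AA_ALPHABET[(old - 1L + shift) %% length(AA_ALPHABET) + 1L]
  }
  paste(ch, collapse = "")
}

# fixed literal marker proteins, identical across all simulations
marker_sequences <- function() {
  mk <- function(name, len) {
    with_seed(sub_seed(20190529, paste0("marker_", name)), random_protein(len))
  }
  list(eps_left = mk("epsA", 240),
       eps_right = mk("tms6", 180),
       rgp_left = mk("radC", 220),
       rgp_right = mk("bgt", 260))
}

# number of genes of one genome; own substream so it can be replayed cheaply
genome_gene_count <- function(config, genome_id) {
  rng <- seq(config$genes_per_genome[1], config$genes_per_genome[2])
  with_seed(sub_seed(config$seed, paste0("count_", genome_id)),
            rng[sample.int(length(rng), 1)])
}

# assign coordinates on a single contig: 50 bp spacer, nt length 3*(aa+1)
lay_out <- function(genes) {
  len_nt <- 3L * (nchar(genes$protein) + 1L)
  start <- integer(nrow(genes))
  pos <- 50L
  for (i in seq_len(nrow(genes))) {
    start[i] <- pos
    pos <- pos + len_nt[i] + 50L
  }
  genes$contig <- "c1"
  genes$start <- start
  genes$end <- start + len_nt
  genes
}

#' Simulate a phage population with hosts and planted truth
#'
#' Generates annotated phage genomes, annotated host strains, a host-range
#' table, and the planted ground truth (group, RBP lineage, genotypes,
#' matched lineage-genotype pairs). Fully deterministic given
#' `config$seed`; every genome and strain draws from its own seed substream,
#' so enlarging the population does not perturb existing members.
#'
#' @param config a [sim_config()].
#' @return a `phage_population` list with tibbles `genomes` (annotated phage
#'   genes incl. `family` ground-truth tags), `strains`, `host_range`
#'   (`phage`, `strain`), `truth`, and the `config`.
#' @export
simulate_population <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  seed <- config$seed
  plen <- function() sample(seq(config$protein_length_range[1],
                                config$protein_length_range[2]), 1)
  make_pool <- function(stream, fam_ids) {
    with_seed(sub_seed(seed, stream), {
      setNames(vapply(fam_ids, function(f) random_protein(plen()), ""),
               fam_ids)
    })
  }
  shared_pool <- make_pool("pool_shared",
                           sprintf("SHF%03d", seq_len(config$shared_pool_size)))
  group_pools <- lapply(seq_len(config$n_groups), function(g) {
    make_pool(paste0("pool_group", g),
              sprintf("G%dF%03d", g, seq_len(config$group_pool_size)))
  })
  hk_pool <- make_pool("pool_hk", sprintf("HKF%02d", 1:10))
  eps_pool <- make_pool("pool_eps",
                        sprintf("EPSF%03d", seq_len(config$eps_pool_size)))
  rgp_pool <- make_pool("pool_rgp",
                        sprintf("RGPF%03d", seq_len(config$rgp_pool_size)))

  # RBP scaffolds: group-conserved N-terminus, per-lineage VR2
  lineage_group <- rep(seq_len(config$n_groups),
                       length.out = config$n_rbp_lineages)
  rbp_nterm <- vapply(seq_len(config$n_groups), function(g) {
    with_seed(sub_seed(seed, paste0("rbp_nterm_g", g)),
              random_protein(config$rbp_nterm_len))
  }, "")
  vr2_anc <- vapply(seq_len(config$n_groups), function(g) {
    with_seed(sub_seed(seed, paste0("rbp_vr2_g", g)),
              random_protein(config$rbp_vr2_len))
  }, "")
  vr2_lineage <- vapply(seq_len(config$n_rbp_lineages), function(l) {
    mutate_sequence(vr2_anc[lineage_group[l]], config$rbp_vr2_divergence,
                    seed = sub_seed(seed, paste0("vr2_lineage", l)))
  }, "")
  matched_eps <- ((seq_len(config$n_rbp_lineages) - 1) %%
                    config$n_eps_genotypes) + 1

  # phage genomes
  genome_rows <- list()
  truth_group <- list()
  for (g in seq_len(config$n_groups)) {
    pool <- group_pools[[g]]
    core_f <- names(pool)[seq_len(config$core_genes_per_group)]
    acc_pool <- c(pool[-seq_len(config$core_genes_per_group)], shared_pool)
    lineages_g <- which(lineage_group == g)
    for (k in seq_len(config$genomes_per_group[g])) {
      id <- sprintf("P%d_%02d", g, k)
      n_genes <- genome_gene_count(config, id)
      rows <- with_seed(sub_seed(seed, paste0("genome_", id)), {
        lineage <- lineages_g[sample.int(length(lineages_g), 1)]
        acc_f <- names(acc_pool)[sample.int(length(acc_pool),
                                            n_genes - length(core_f) - 1L)]
        fams <- sample(c(core_f, acc_f))
        rbp_at <- sample.int(length(fams) + 1L, 1)
        fam_seq <- c(pool, shared_pool)[fams]
        prot <- vapply(fam_seq, mutate_sequence,
                       "", rate = config$within_lineage_divergence)
        rbp <- paste0(rbp_nterm[g],
                      mutate_sequence(vr2_lineage[lineage],
                                      config$within_lineage_divergence))
        fam_all <- append(fams, sprintf("RBP_G%d", g), after = rbp_at - 1L)
        prot_all <- append(unname(prot), rbp, after = rbp_at - 1L)
        prod_all <- ifelse(fam_all == sprintf("RBP_G%d", g),
                           "receptor binding protein",
                           paste("hypothetical protein", fam_all))
        strand <- sample(c("+", "-"), length(fam_all), replace = TRUE,
                         prob = c(0.8, 0.2))
        list(tbl = tibble(
          genome = id,
          gene = sprintf("%s_g%02d", id, seq_along(fam_all)),
          family = fam_all, product = prod_all, protein = prot_all,
          strand = strand), lineage = lineage)
      })
      genome_rows[[id]] <- lay_out(rows$tbl)
      truth_group[[id]] <- tibble(genome = id, group = g,
                                  rbp_lineage = rows$lineage)
    }
  }
  genomes <- dplyr::bind_rows(genome_rows)
  truth_g <- dplyr::bind_rows(truth_group)

  # genotype-specific operon gene subsets (sorted: fixed operon gene order)
  geno_subset <- function(kind, pool, n_geno, rng) {
    lapply(seq_len(n_geno), function(j) {
      with_seed(sub_seed(seed, paste0(kind, "_genotype", j)), {
        sz <- sample(seq(rng[1], rng[2]), 1)
        sort(names(pool)[sample.int(length(pool), sz)])
      })
    })
  }
  eps_geno <- geno_subset("eps", eps_pool, config$n_eps_genotypes,
                          config$eps_genes_range)
  rgp_geno <- geno_subset("rgp", rgp_pool, config$n_rgp_genotypes,
                          config$rgp_genes_range)
  mk <- marker_sequences()

  strain_rows <- list()
  strain_truth <- list()
  for (i in seq_len(config$n_strains)) {
    id <- sprintf("S%02d", i)
    e <- ((i - 1) %% config$n_eps_genotypes) + 1
    r <- ((i - 1) %% config$n_rgp_genotypes) + 1
    rows <- with_seed(sub_seed(seed, paste0("strain_", id)), {
      hk <- names(hk_pool)[sample.int(length(hk_pool), 5)]
      mut <- function(fams, pool) {
        vapply(pool[fams], mutate_sequence, "",
               rate = config$within_lineage_divergence)
      }
      fam <- c(hk[1:3],
               "epsA", eps_geno[[e]], "TMS6",
               hk[4:5],
               "radC", rgp_geno[[r]], "BGT")
      prot <- c(mut(hk[1:3], hk_pool),
                mk$eps_left, mut(eps_geno[[e]], eps_pool), mk$eps_right,
                mut(hk[4:5], hk_pool),
                mk$rgp_left, mut(rgp_geno[[r]], rgp_pool), mk$rgp_right)
      prod <- dplyr::case_when(
        fam == "epsA" ~ "epsA",
        fam == "TMS6" ~ "predicted membrane protein (TMS6)",
        fam == "radC" ~ "radC",
        fam == "BGT" ~ "bactoprenol glucosyl transferase",
        startsWith(fam, "EPSF") ~ paste("eps biosynthesis protein", fam),
        startsWith(fam, "RGPF") ~ paste("rgp biosynthesis protein", fam),
        .default = paste("hypothetical protein", fam))
      tibble(genome = id, gene = sprintf("%s_g%02d", id, seq_along(fam)),
             family = fam, product = prod, protein = unname(prot),
             strand = "+")
    })
    strain_rows[[id]] <- lay_out(rows)
    strain_truth[[id]] <- tibble(strain = id, eps_genotype = e,
                                 rgp_genotype = r)
  }
  strains <- dplyr::bind_rows(strain_rows)
  truth_s <- dplyr::bind_rows(strain_truth)

  # host range: strains of the matched eps genotype, flipped with noise
  hr <- list()
  for (gid in truth_g$genome) {
    lineage <- truth_g$rbp_lineage[truth_g$genome == gid]
    hr[[gid]] <- with_seed(sub_seed(seed, paste0("host_", gid)), {
      matched <- truth_s$strain[truth_s$eps_genotype == matched_eps[lineage]]
      cand <- matched
      if (config$host_range_noise > 0 &&
          stats::runif(1) < config$host_range_noise) {
        cand <- setdiff(truth_s$strain, matched)
      }
      nh <- sample(seq(config$hosts_per_phage[1],
                       config$hosts_per_phage[2]), 1)
      nh <- min(nh, length(cand))
      tibble(phage = gid, strain = sort(cand[sample.int(length(cand), nh)]))
    })
  }
  host_range <- dplyr::bind_rows(hr)

  structure(list(
    genomes = genomes,
    strains = strains,
    host_range = host_range,
    truth = list(
      genome_group = dplyr::select(truth_g, "genome", "group"),
      rbp_lineage = dplyr::select(truth_g, "genome", lineage = "rbp_lineage"),
      strain_genotypes = truth_s,
      matched_pairs = tibble(lineage = seq_len(config$n_rbp_lineages),
                             eps_genotype = matched_eps)
    ),
    config = config
  ), class = "phage_population")
}

#' @export
print.phage_population <- function(x, ...) {
  cat("Simulated population:",
      length(unique(x$genomes$genome)), "phage genomes,",
      length(unique(x$strains$genome)), "strains,",
      nrow(x$host_range), "host-range links\n")
  invisible(x)
}

# one codon per amino acid (bacterial code 11 compatible); stop TAA
CODON_OF <- c(A = "GCT", C = "TGT", D = "GAT", E = "GAA", F = "TTT",
              G = "GGT", H = "CAT", I = "ATT", K = "AAA", L = "CTG",
              M = "ATG", N = "AAT", P = "CCG", Q = "CAA", R = "CGT",
              S = "TCT", T = "ACT", V = "GTT", W = "TGG", Y = "TAT")

reverse_translate <- function(aa) {
  paste0(paste(CODON_OF[strsplit(aa, "")[[1]]], collapse = ""), "TAA")
}

contig_from_genes <- function(genes) {
  stopifnot(length(unique(genes$contig)) == 1L)
  genes <- dplyr::arrange(genes, .data$start)
  total <- max(genes$end) + 50L
  nt <- strsplit(paste(rep("ACGTT", ceiling(total / 5)), collapse = ""),
                 "")[[1]][seq_len(total)]
  for (i in seq_len(nrow(genes))) {
    cds <- reverse_translate(genes$protein[i])
    if (genes$strand[i] == "-") {
      cds <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(cds)))
    }
    nt[seq(genes$start[i] + 1L, genes$end[i])] <- strsplit(cds, "")[[1]]
  }
  paste(nt, collapse = "")
}

#' Write a simulated population to disk
#'
#' Serializes a [simulate_population()] result to the formats the readers
#' consume: per-genome nucleotide FASTA + GFF3 under `genomes/` and
#' `strains/`, pre-translated multi-protein FASTA files, the host-range TSV,
#' ground-truth TSVs, and the configuration echo `config.used`. Writing is
#' deterministic: the same population writes byte-identical files.
#'
#' @param pop a `phage_population`.
#' @param dir output directory (created).
#' @return `dir`, invisibly.
#' @export
write_population <- function(pop, dir) {
  for (d in file.path(dir, c("genomes", "strains"))) {
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
  }
  write_set <- function(genes_all, subdir) {
    for (id in unique(genes_all$genome)) {
      genes <- dplyr::filter(genes_all, .data$genome == id)
      ctg <- setNames(contig_from_genes(genes), paste0(id, "_c1"))
      genes$contig <- paste0(id, "_c1")
      write_genome(ctg, genes,
                   file.path(dir, subdir, paste0(id, ".fna")),
                   file.path(dir, subdir, paste0(id, ".gff")))
    }
    write_proteins(genes_all, file.path(dir, paste0(subdir, ".faa")))
  }
  write_set(pop$genomes, "genomes")
  write_set(pop$strains, "strains")
  readr::write_tsv(pop$host_range, file.path(dir, "host_range.tsv"))
  readr::write_tsv(pop$truth$genome_group |>
                     dplyr::left_join(pop$truth$rbp_lineage, by = "genome"),
                   file.path(dir, "truth_phages.tsv"))
  readr::write_tsv(pop$truth$strain_genotypes,
                   file.path(dir, "truth_strains.tsv"))
  cfg <- pop$config
  scal <- vapply(cfg, function(v) paste(v, collapse = " "), "")
  writeLines(paste0(names(cfg), "=", scal), file.path(dir, "config.used"))
  invisible(dir)
}
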