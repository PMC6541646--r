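# hand-built strain gene table: products carry the marker annotations
strain_genes_fixture <- function(n_between = 6, strand = "+", reversed = FALSE,
                                 strain = "S1") {
  prods <- c("houseA", "epsA", paste0("mid", seq_len(n_between)),
             "predicted membrane protein (TMS6)", "houseB")
  if (reversed) prods <- rev(prods)
  n <- length(prods)
  tibble::tibble(
    genome = strain, gene = sprintf("%s_g%02d", strain, seq_len(n)),
    contig = "c1",
    start = seq(0L, by = 400L, length.out = n),
    end = seq(300L, by = 400L, length.out = n),
    strand = strand, product = prods,
    protein = vapply(seq_len(n), function(i) rand_protein(80), ""))
}

test_that("genes strictly between the markers are extracted on one contig", {
  set.seed(501)
  genes <- strain_genes_fixture(n_between = 6)
  cl <- locate_cluster(genes, marker_pair("eps"))
  expect_true(cl$found)
  expect_true(cl$complete)
  expect_equal(cl$n_contigs, 1L)
  expect_equal(nrow(cl$genes), 6L)
  expect_equal(cl$genes$product, paste0("mid", 1:6))
})

test_that("marker order and contig orientation do not change the gene set", {
  set.seed(502)
  fwd <- strain_genes_fixture(n_between = 4)
  # same operon, coordinates flipped end to end (reverse orientation)
  rev_tbl <- strain_genes_fixture(n_between = 4, strand = "-", reversed = TRUE)
  rev_tbl$protein <- rev(fwd$protein)
  cl_f <- locate_cluster(fwd, marker_pair("eps"))
  cl_r <- locate_cluster(rev_tbl, marker_pair("eps"))
  expect_setequal(cl_r$genes$product, cl_f$genes$product)
  expect_true(cl_r$complete)
})

test_that("markers on two contigs give a partial cluster with a warning", {
  set.seed(503)
  genes <- strain_genes_fixture(n_between = 4)
  # split between mid2 and mid3: epsA..mid2 on c1, mid3..TMS6 (+trailing) on c2
  genes$contig <- c("c1", "c1", "c1", "c1", "c2", "c2", "c2", "c2")
  expect_warning(cl <- locate_cluster(genes, marker_pair("eps")),
                 "two contigs")
  expect_false(cl$complete)
  expect_equal(cl$n_contigs, 2L)
  # mid1..mid2 downstream of epsA; mid3..mid4 upstream of TMS6; houseB sits
  # beyond TMS6 and is not collected
  expect_setequal(cl$genes$product, paste0("mid", 1:4))
})

test_that("missing markers fail softly, duplicated markers loudly", {
  set.seed(504)
  genes <- strain_genes_fixture()
  none <- genes[!genes$product %in% "epsA", ]
  cl <- locate_cluster(none, marker_pair("eps"))
  expect_false(cl$found)
  expect_match(cl$reason, "left")
  dup <- dplyr::bind_rows(genes, genes[genes$product == "epsA", ])
  expect_error(locate_cluster(dup, marker_pair("eps")), "more than once")
})

test_that("marker proteins can be called by homology when annotations differ", {
  set.seed(505)
  genes <- strain_genes_fixture()
  marker_seq <- genes$protein[genes$product == "epsA"]
  tms6_seq <- genes$protein[genes$product == "predicted membrane protein (TMS6)"]
  genes$product[genes$product == "epsA"] <- "unannotated orf"
  genes$product[genes$product ==
                  "predicted membrane protein (TMS6)"] <- "membrane thing"
  cl <- locate_cluster(genes, marker_pair("eps"),
                       marker_seqs = list(left = marker_seq,
                                          right = tms6_seq))
  expect_true(cl$found)
  expect_equal(nrow(cl$genes), 6L)
})

test_that("identical operons give identical matrix rows", {
  set.seed(506)
  shared <- setNames(vapply(1:5, function(i) rand_protein(120), ""),
                     paste0("f", 1:5))
  mk_cluster <- function(strain) {
    genes <- tibble::tibble(
      genome = strain, gene = paste0(strain, "_g", 1:5), contig = "c1",
      start = seq(0, by = 500, length.out = 5),
      end = seq(400, by = 500, length.out = 5),
      strand = "+", product = names(shared), protein = unname(shared))
    structure(list(strain = strain, kind = "eps", genes = genes,
                   complete = TRUE, n_contigs = 1L, found = TRUE,
                   reason = NA_character_), class = "operon_cluster")
  }
  m <- operon_matrix(list(mk_cluster("sA"), mk_cluster("sB")))
  mm <- unclass(m)
  expect_equal(unname(mm["sA", ]), unname(mm["sB", ]))
  expect_equal(ncol(mm), 5L)
  expect_error(operon_matrix(list(mk_cluster("sA"))), "two strains")
})

test_that("the 40 percent preset merges what the 50 percent preset separates", {
  set.seed(507)
  a <- rand_protein(200)
  b <- mutate_sequence(a, 0.58)  # pairwise identity lands between 0.4 and 0.5
  id <- global_align(a, b)$identity
  expect_gt(id, 0.40); expect_lt(id, 0.50)
  pr <- proteome_tbl(list(s1 = c(g = a), s2 = c(g = b)))
  g40 <- ortholog_groups(bbh_edges(all_vs_all(
    pr, orthology_params(0.40, 0.80, kmer_min = 0))), pr)
  g50 <- ortholog_groups(bbh_edges(all_vs_all(
    pr, orthology_params(0.50, 0.80, kmer_min = 0))), pr)
  expect_equal(length(unique(g40$group_id)), 1L)
  expect_equal(length(unique(g50$group_id)), 2L)
})

test_that("genotype letters follow size then smallest-strain order", {
  m <- matrix(c(1, 0, 1, 0,
                1, 0, 1, 0,
                1, 0, 1, 0,
                0, 1, 0, 1,
                1, 1, 0, 0), nrow = 5, byrow = TRUE,
              dimnames = list(paste0("s", 1:5), paste0("og", 1:4)))
  pm <- phagepan:::new_pangenome_matrix(m == 1)
  gt <- assign_genotypes(pm, k = 3)
  expect_equal(gt$genotype[gt$strain %in% c("s1", "s2", "s3")],
               c("A", "A", "A"))
  expect_equal(sort(unique(gt$genotype)), c("A", "B", "C"))
  one <- assign_genotypes(pm, k = 1)
  expect_equal(unique(one$genotype), "A")
  all_own <- assign_genotypes(pm, k = 5)
  expect_equal(sort(all_own$genotype), LETTERS[1:5])
  expect_error(assign_genotypes(pm, k = 9), "exceeds")
})

test_that("planted genotypes are recovered and discordant strain pairs exist", {
  pop <- simulate_population(small_sim_config(seed = 12))
  cfg <- pop$config
  gt <- type_strains(pop$strains, k_eps = cfg$n_eps_genotypes,
                     k_rgp = cfg$n_rgp_genotypes)
  ts <- pop$truth$strain_genotypes
  expect_equal(ari(gt$eps_genotype[match(ts$strain, gt$strain)],
                   ts$eps_genotype), 1)
  expect_equal(ari(gt$rgp_genotype[match(ts$strain, gt$strain)],
                   ts$rgp_genotype), 1)
  expect_true(all(gt$eps_complete) && all(gt$rgp_complete))
  # the EPS and RGP typings are genuinely independent: some strain pair
  # shares an EPS genotype but not an RGP genotype
  pairs <- utils::combn(nrow(gt), 2)
  same_eps <- gt$eps_genotype[pairs[1, ]] == gt$eps_genotype[pairs[2, ]]
  same_rgp <- gt$rgp_genotype[pairs[1, ]] == gt$rgp_genotype[pairs[2, ]]
  expect_true(any(same_eps & !same_rgp))
})

test_that("operon cluster sizes land in the configured (study-like) range", {
  pop <- simulate_population(sim_config(seed = 13))
  mp <- marker_pair("eps")
  sizes <- vapply(unique(pop$strains$genome), function(s) {
    nrow(locate_cluster(dplyr::filter(pop$strains, genome == s), mp,
                        strain = s)$genes)
  }, 0)
  expect_true(all(sizes >= 13 & sizes <= 22))
  expect_gte(mean(sizes), 13)
})
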