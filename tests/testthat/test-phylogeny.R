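test_that("core alignments concatenate in gene order, independent of input order", {
  a1 <- new_msa_for_test(c(g1 = "ACDE", g2 = "AC-E"))
  a2 <- new_msa_for_test(c(g2 = "WWW", g1 = "W-W"))
  cc <- concatenate_core(list(og2 = a2, og1 = a1))
  expect_equal(unclass(cc)[["g1"]], "ACDEW-W")
  expect_equal(unclass(cc)[["g2"]], "AC-EWWW")
  cc2 <- concatenate_core(list(og1 = a1, og2 = a2))
  expect_identical(unclass(cc), unclass(cc2))
  expect_identical(unclass(concatenate_core(list(og1 = a1)))[["g1"]], "ACDE")
  a3 <- new_msa_for_test(c(g1 = "AA"))
  expect_error(concatenate_core(list(og1 = a1, og3 = a3)), "core")
})

test_that("neighbor joining is exact on the worked additive example", {
  d <- matrix(c(0, 3, 8, 9,
                3, 0, 9, 10,
                8, 9, 0, 9,
                9, 10, 9, 0), 4,
              dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  tr <- neighbor_joining(d)
  expect_equal(as.numeric(ape::dist.topo(ape::unroot(tr), ape::read.tree(
    text = "((A:1,B:2):3,C:4,D:5);"))), 0)
  expect_equal(as.matrix(ape::cophenetic.phylo(tr))[rownames(d), colnames(d)],
               d)
  tip_len <- setNames(
    tr$edge.length[match(seq_along(tr$tip.label), tr$edge[, 2])],
    tr$tip.label)
  expect_equal(tip_len[c("A", "B", "C", "D")],
               c(A = 1, B = 2, C = 4, D = 5))
})

test_that("three taxa resolve by the closed form", {
  d <- matrix(c(0, 3, 5,
                3, 0, 4,
                5, 4, 0), 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- neighbor_joining(d)
  tip_len <- setNames(
    tr$edge.length[match(seq_along(tr$tip.label), tr$edge[, 2])],
    tr$tip.label)
  # a = (3 + 5 - 4)/2 = 2, b = 1, c = 3
  expect_equal(tip_len[c("A", "B", "C")], c(A = 2, B = 1, C = 3))
  expect_error(neighbor_joining(d[1:2, 1:2]), "3 taxa")
})

test_that("random additive matrices are recovered with Robinson-Foulds 0", {
  set.seed(301)
  for (case in 1:100) {
    ra <- random_additive(sample(4:10, 1))
    tr <- neighbor_joining(ra$d)
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(ra$tree), tr)), 0)
    co <- as.matrix(ape::cophenetic.phylo(tr))[rownames(ra$d), colnames(ra$d)]
    expect_equal(co, ra$d, tolerance = 1e-8)
  }
})

test_that("negative NJ branches are clamped with the deficit moved to the sister", {
  # near-degenerate distances force a negative internal estimate
  d <- matrix(c(0, 0.1, 0.4, 0.4,
                0.1, 0, 0.4, 0.4,
                0.4, 0.4, 0, 0.1,
                0.4, 0.4, 0.1, 0), 4,
              dimnames = list(letters[1:4], letters[1:4]))
  d["a", "c"] <- d["c", "a"] <- 0.38
  tr <- neighbor_joining(d)
  expect_true(all(tr$edge.length >= 0))
})

test_that("patristic distances equal brute-force path summation", {
  set.seed(302)
  for (case in 1:20) {
    tr <- ape::rtree(sample(4:12, 1))
    got <- patristic_distances(tr)
    exp <- bf_patristic(tr)[rownames(got), colnames(got)]
    expect_equal(got, exp, tolerance = 1e-10)
  }
})

test_that("a clean split alignment bootstraps to 100 percent", {
  rows <- c(t1 = paste0(strrep("A", 40), "CDEF"),
            t2 = paste0(strrep("A", 40), "CDEW"),
            t3 = paste0(strrep("T", 40), "CDEF"),
            t4 = paste0(strrep("T", 40), "CDEW"))
  tr <- bootstrap_support(new_msa_for_test(rows), n_reps = 50, seed = 9)
  # the t1/t2 vs t3/t4 split is present in every replicate
  split_node <- ape::getMRCA(tr, c("t1", "t2"))
  if (split_node == ape::Ntip(tr) + 1) split_node <- ape::getMRCA(tr, c("t3", "t4"))
  expect_equal(as.numeric(tr$node.label[split_node - ape::Ntip(tr)]), 100)
})

test_that("bootstrap is deterministic and n_reps = 1 gives 0/100 supports", {
  set.seed(303)
  base <- rand_protein(80)
  rows <- setNames(vapply(1:5, function(i) mutate_sequence(base, 0.2), ""),
                   paste0("t", 1:5))
  msa <- new_msa_for_test(rows)
  t1 <- bootstrap_support(msa, n_reps = 25, seed = 4)
  t2 <- bootstrap_support(msa, n_reps = 25, seed = 4)
  expect_identical(t1$node.label, t2$node.label)
  tr1 <- bootstrap_support(msa, n_reps = 1, seed = 4)
  expect_true(all(tr1$node.label %in% c(0, 100)))
  expect_error(bootstrap_support(new_msa_for_test(c(a = "A", b = "C")),
                                 n_reps = 5), "one column")
})

test_that("bootstrap supports are invariant to leaf order", {
  set.seed(304)
  base <- rand_protein(60)
  rows <- setNames(vapply(1:5, function(i) mutate_sequence(base, 0.25), ""),
                   paste0("t", 1:5))
  msa1 <- new_msa_for_test(rows)
  msa2 <- new_msa_for_test(rows[c(3, 1, 5, 2, 4)])
  t1 <- bootstrap_support(msa1, n_reps = 20, seed = 6)
  t2 <- bootstrap_support(msa2, n_reps = 20, seed = 6)
  expect_equal(as.numeric(ape::dist.topo(t1, t2)), 0)
  expect_equal(sort(as.numeric(t1$node.label)),
               sort(as.numeric(t2$node.label)))
})

test_that("RBP selection keeps homologs and excludes outliers and absences", {
  set.seed(305)
  base <- rand_protein(200)
  pr <- dplyr::bind_rows(
    proteome_tbl(list(p1 = c(r = base),
                      p2 = c(r = mutate_sequence(base, 0.1)),
                      p3 = c(r = mutate_sequence(base, 0.1))),
                 products = list(p1 = "receptor binding protein",
                                 p2 = "receptor binding protein",
                                 p3 = "receptor binding protein")),
    proteome_tbl(list(p4 = c(r = rand_protein(200)),
                      p5 = c(x = rand_protein(100))),
                 products = list(p4 = "receptor binding protein",
                                 p5 = "tail protein")))
  rs <- select_rbps(pr)
  expect_setequal(names(rs$included), c("p1", "p2", "p3"))
  expect_setequal(rs$excluded$genome, c("p4", "p5"))
  expect_equal(rs$excluded$reason[rs$excluded$genome == "p5"], "not found")
  expect_lt(rs$excluded$max_identity[rs$excluded$genome == "p4"], 0.3)
})

test_that("the similarity boundary is closed: identity exactly at threshold stays", {
  set.seed(306)
  a <- rand_protein(100)
  b <- mutate_sequence(a, 0.65)
  pr <- proteome_tbl(list(p1 = c(r = a), p2 = c(r = b)),
                     products = list(p1 = "receptor binding protein",
                                     p2 = "receptor binding protein"))
  id <- global_align(a, b)$identity
  at <- select_rbps(pr, min_similarity = id)
  expect_equal(length(at$included), 2L)
  above <- select_rbps(pr, min_similarity = id + 1e-9)
  expect_equal(length(above$included), 0L)
})

test_that("tree clustering behaves at threshold extremes", {
  set.seed(307)
  tr <- ape::rtree(8)
  diam <- max(patristic_distances(tr))
  one <- tree_clusters(tr, threshold = diam + 1)
  expect_equal(unique(one$cluster), "I")
  tiny <- tree_clusters(tr, threshold = min(patristic_distances(tr)[
    upper.tri(matrix(0, 8, 8))]) / 2)
  expect_equal(length(unique(tiny$cluster)), 8L)
})

test_that("planted RBP lineages are recovered from the tree", {
  set.seed(308)
  nterm <- rand_protein(100)
  anc <- rand_protein(200)
  vr2 <- vapply(1:3, function(l) mutate_sequence(anc, 0.4), "")
  seqs <- unlist(lapply(1:3, function(l) {
    setNames(vapply(1:4, function(i) {
      paste0(nterm, mutate_sequence(vr2[l], 0.05))
    }, ""), paste0("L", l, "_", 1:4))
  }))
  truth <- rep(1:3, each = 4)
  tr <- msa_nj_tree(progressive_msa(seqs))
  cl <- tree_clusters(tr, threshold = 0.3)
  expect_equal(ari(cl$cluster[match(names(seqs), cl$leaf)], truth), 1)
})
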