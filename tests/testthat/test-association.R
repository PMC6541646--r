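test_that("worked examples match subset enumeration", {
  expect_equal(hypergeom_pmf(10, 4, 3, 1), 0.5)          # 4 * 15 / 120
  expect_equal(prob_all_successes(5, 3, 2), 0.3)         # 3 / 10
  expect_equal(prob_at_least(6, 3, 3, 3), 0.05)          # 1 / 20
  expect_equal(hypergeom_pmf(10, 2, 5, 4), 0)            # k > K
  expect_equal(prob_all_successes(7, 7, 4), 1)           # K = N
  expect_equal(prob_at_least(9, 4, 3, 0), 1)
})

test_that("probabilities agree with exhaustive enumeration for N <= 12", {
  set.seed(601)
  for (case in 1:40) {
    N <- sample(2:12, 1)
    K <- sample(0:N, 1)
    n <- sample(0:N, 1)
    for (k in 0:n) {
      expect_equal(hypergeom_pmf(N, K, n, k), enum_hyper_pmf(N, K, n, k),
                   tolerance = 1e-12)
    }
    k_min <- sample(0:n, 1)
    expect_equal(prob_at_least(N, K, n, k_min),
                 sum(vapply(k_min:n, function(k) enum_hyper_pmf(N, K, n, k),
                            0)),
                 tolerance = 1e-12)
    expect_equal(prob_all_successes(N, K, n), enum_hyper_pmf(N, K, n, n),
                 tolerance = 1e-12)
  }
})

test_that("the pmf normalizes and matches the stock distribution function", {
  set.seed(602)
  for (case in 1:25) {
    N <- sample(2:60, 1); K <- sample(0:N, 1); n <- sample(0:N, 1)
    pmf <- vapply(0:n, function(k) hypergeom_pmf(N, K, n, k), 0)
    expect_equal(sum(pmf), 1, tolerance = 1e-12)
    expect_equal(pmf, stats::dhyper(0:n, K, N - K, n), tolerance = 1e-12)
  }
})

test_that("all-successes probability is monotone in draw and success counts", {
  set.seed(603)
  for (case in 1:20) {
    N <- sample(5:40, 1); K <- sample(1:N, 1)
    n_seq <- 0:min(K, N)
    p_n <- vapply(n_seq, function(n) prob_all_successes(N, K, n), 0)
    expect_true(all(diff(p_n) <= 1e-15))
    n <- sample(1:N, 1)
    p_K <- vapply(n:N, function(K2) prob_all_successes(N, K2, n), 0)
    expect_true(all(diff(p_K) >= -1e-15))
  }
})

test_that("out-of-range arguments are rejected", {
  expect_error(hypergeom_pmf(5, 6, 2, 1), "K <= N")
  expect_error(hypergeom_pmf(5, 3, 6, 1), "n <= N")
  expect_error(prob_at_least(5, 3, 2, 3), "k <= n")
})

test_that("the cluster I+II draw is all EPS A/D hosts and the bound holds", {
  t2 <- rbp_genotype_table()
  strains <- dplyr::distinct(t2, strain = host_strain, eps_genotype)
  at <- build_association(dplyr::select(t2, phage, rbp_cluster, host_strain),
                          strains, clusters = c("I", "II"),
                          genotypes = c("A", "D"))
  expect_equal(at$N, 43L)
  expect_equal(at$K, 22L)
  expect_equal(at$n, 16L)
  expect_equal(at$k_obs, 16L)
  expect_equal(at$rule, "all-successes")
  # frozen oracle value: C(22,16) / C(43,16) = 33 / 117285338
  expect_equal(at$p, 33 / 117285338, tolerance = 1e-12)
  expect_lt(at$p, 3e-7)
})

test_that("the cluster III+IV draw misses exactly one B/C host and the bound holds", {
  t2 <- rbp_genotype_table()
  strains <- dplyr::distinct(t2, strain = host_strain, eps_genotype)
  at <- build_association(dplyr::select(t2, phage, rbp_cluster, host_strain),
                          strains, clusters = c("III", "IV"),
                          genotypes = c("B", "C"))
  expect_equal(at$K, 18L)
  expect_equal(at$n, 11L)
  expect_equal(at$k_obs, 10L)
  expect_equal(at$rule, "at-least-10")
  # frozen oracle value: (C(18,10) C(25,1) + C(18,11)) / C(43,11)
  expect_equal(at$p, 1698 / 8675723, tolerance = 1e-12)
  expect_lt(at$p, 2e-4)
  pt <- build_association(dplyr::select(t2, phage, rbp_cluster, host_strain),
                          strains, clusters = c("III", "IV"),
                          genotypes = c("B", "C"), tail = "point")
  expect_lt(pt$p, at$p)
  expect_lt(pt$p, 2e-4)
})

test_that("association construction is row-order invariant and handles edge draws", {
  t2 <- rbp_genotype_table()
  strains <- dplyr::distinct(t2, strain = host_strain, eps_genotype)
  shuffled <- t2[sample(nrow(t2)), ]
  a1 <- build_association(dplyr::select(t2, phage, rbp_cluster, host_strain),
                          strains, c("I", "II"), c("A", "D"))
  a2 <- build_association(dplyr::select(shuffled, phage, rbp_cluster,
                                        host_strain),
                          strains, c("I", "II"), c("A", "D"))
  expect_equal(tidy(a1), tidy(a2))
  empty <- build_association(dplyr::select(t2, phage, rbp_cluster, host_strain),
                             strains, clusters = "XXX", genotypes = "A")
  expect_equal(empty$n, 0L)
  expect_equal(empty$p, 1)
  expect_error(build_association(
    dplyr::select(t2, phage, rbp_cluster, host_strain),
    strains[-1, ], c("I", "II"), c("A", "D")), "without a genotype")
})

test_that("a multi-host phage is a success only when all hosts match", {
  phages <- tibble::tibble(phage = c("P1", "P2"),
                           rbp_cluster = c("I", "I"),
                           hosts = list(c("S1", "S2"), "S1"))
  strains <- tibble::tibble(strain = c("S1", "S2"),
                            eps_genotype = c("A", "B"))
  at <- build_association(phages, strains, "I", "A")
  expect_equal(at$K, 1L)
  expect_equal(at$k_obs, 1L)
})

test_that("tidy and glance summarize the test object", {
  at <- build_association(
    tibble::tibble(phage = c("P1", "P2"), rbp_cluster = c("I", "II"),
                   host_strain = c("S1", "S2")),
    tibble::tibble(strain = c("S1", "S2"), eps_genotype = c("A", "B")),
    clusters = "I", genotypes = "A")
  td <- tidy(at)
  expect_equal(td$N, 2L)
  expect_equal(td$rule, "all-successes")
  expect_equal(glance(at)$p, td$p)
})

test_that("shared-host cases are counted and concordance scored", {
  labels <- tibble::tibble(phage = c("P1", "P2", "P3", "P4"),
                           cluster = c("I", "I", "II", "III"))
  hr <- tibble::tibble(phage = c("P1", "P2", "P3", "P4"),
                       strain = c("S1", "S1", "S2", "S3"))
  res <- shared_host_concordance(labels, hr)
  expect_equal(res$n_cases, 1L)
  expect_equal(res$n_concordant, 1L)
  labels2 <- labels; labels2$cluster[2] <- "IV"
  res2 <- shared_host_concordance(labels2, hr)
  expect_equal(res2$n_cases, 1L)
  expect_equal(res2$n_concordant, 0L)
  # overlap mode chains phages sharing any strain
  hr3 <- tibble::tibble(phage = c("P1", "P2", "P2", "P3"),
                        strain = c("S1", "S1", "S2", "S2"))
  res3 <- shared_host_concordance(labels, hr3, mode = "overlap")
  expect_equal(res3$n_cases, 1L)
  expect_equal(res3$cases$phages, "P1 P2 P3")
})

test_that("noise-free synthetic populations are fully concordant", {
  pop <- simulate_population(small_sim_config(seed = 15))
  labels <- dplyr::rename(pop$truth$rbp_lineage, phage = genome,
                          cluster = lineage)
  res <- shared_host_concordance(labels, pop$host_range)
  expect_gte(res$n_cases, 1L)
  expect_equal(res$n_concordant, res$n_cases)
})
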