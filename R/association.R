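# Exact hypergeometric machinery. Probabilities are ratios of products of
# binomial coefficients; to keep them exact well beyond 64-bit integer range
# the factorials are expanded into prime powers (Legendre's formula), all
# cancellation happens on the integer exponents, and only the final product
# of prime powers is evaluated in floating point.

primes_upto <- function(n) {
  if (n < 2) return(integer())
  s <- rep(TRUE, n); s[1] <- FALSE
  for (p in seq_len(floor(sqrt(n)))) {
    if (p >= 2 && s[p]) s[seq(p * p, n, by = p)] <- FALSE
  }
  which(s)
}

# exponent of prime p in n!
fact_exp <- function(n, p) {
  e <- 0; q <- p
  while (q <= n) { e <- e + n %/% q; q <- q * p }
  e
}

# exact value of prod choose(top[i], bot[i]) / prod choose(topd[j], botd[j])
choose_ratio <- function(top, bot, topd, botd) {
  nmax <- max(c(top, topd, 1))
  ps <- primes_upto(nmax)
  expo <- vapply(ps, function(p) {
    e <- 0
    for (i in seq_along(top)) {
      e <- e + fact_exp(top[i], p) - fact_exp(bot[i], p) -
        fact_exp(top[i] - bot[i], p)
    }
    for (j in seq_along(topd)) {
      e <- e - fact_exp(topd[j], p) + fact_exp(botd[j], p) +
        fact_exp(topd[j] - botd[j], p)
    }
    e
  }, 0)
  prod(as.numeric(ps)^expo)
}

check_hyper_args <- function(N, K, n, k = NULL) {
  stopifnot(length(N) == 1, length(K) == 1, length(n) == 1)
  if (N < 0 || K < 0 || K > N || n < 0 || n > N) {
    abort("need 0 <= K <= N and 0 <= n <= N")
  }
  if (!is.null(k) && (k < 0 || k > n)) abort("need 0 <= k <= n")
}

#' Exact sampling-without-replacement probabilities
#'
#' Probability mass and tail functions of the hypergeometric distribution:
#' drawing `n` items without replacement from a population of `N` containing
#' `K` successes. All three are evaluated by exact integer (prime-exponent)
#' arithmetic: `hypergeom_pmf()` is `C(K,k) C(N-K,n-k) / C(N,n)`,
#' `prob_all_successes()` is `C(K,n)/C(N,n)` (the chance that *every* drawn
#' item is a success), and `prob_at_least()` sums the pmf for
#' `k = k_min, ..., n`.
#'
#' @param N population size.
#' @param K successes in the population.
#' @param n draw size.
#' @param k,k_min observed / minimum successes among the drawn.
#' @return a probability.
#' @examples
#' hypergeom_pmf(10, 4, 3, 1)   # 0.5
#' prob_all_successes(5, 3, 2)  # 0.3
#' @export
hypergeom_pmf <- function(N, K, n, k) {
  check_hyper_args(N, K, n, k)
  if (k > K || (n - k) > (N - K)) return(0)
  choose_ratio(top = c(K, N - K), bot = c(k, n - k), topd = N, botd = n)
}

#' @rdname hypergeom_pmf
#' @export
prob_all_successes <- function(N, K, n) {
  check_hyper_args(N, K, n)
  if (n > K) return(0)
  choose_ratio(top = K, bot = n, topd = N, botd = n)
}

#' @rdname hypergeom_pmf
#' @export
prob_at_least <- function(N, K, n, k_min) {
  check_hyper_args(N, K, n, k_min)
  if (k_min <= 0) return(1)
  ks <- seq(k_min, n)
  sum(vapply(ks, function(k) hypergeom_pmf(N, K, n, k), 0))
}

#' Association between RBP lineages and host polysaccharide genotypes
#'
#' Builds the exact sampling-without-replacement test for the question "are
#' the phages of these RBP clusters concentrated on hosts of these
#' genotypes?". The population is all `N` phages in the table; a phage is a
#' success when *every* listed host strain carries one of the designated
#' genotype letters; the draw is the `n` phages of the designated clusters.
#' When all drawn phages are successes the all-successes rule
#' `C(K,n)/C(N,n)` is applied; otherwise the upper tail from the observed
#' count (or the point probability with `tail = "point"`).
#'
#' @param phages tibble with columns `phage`, `rbp_cluster`, and either
#'   `host_strain` (one strain per row) or `hosts` (list column).
#' @param strains tibble mapping `strain` to genotype letters (columns
#'   `strain` and `eps_genotype` and/or `rgp_genotype`).
#' @param clusters character vector of RBP cluster labels drawn.
#' @param genotypes character vector of designated genotype letters.
#' @param genotype_kind `"eps"` or `"rgp"`.
#' @param tail `"upper"` (default) or `"point"`; only used when not all
#'   drawn phages are successes.
#' @return an `assoc_test` with fields `N`, `K`, `n`, `k_obs`, `rule`, `p`
#'   (see [tidy.assoc_test()]).
#' @export
build_association <- function(phages, strains, clusters, genotypes,
                              genotype_kind = c("eps", "rgp"),
                              tail = c("upper", "point")) {
  genotype_kind <- match.arg(genotype_kind)
  tail <- match.arg(tail)
  gcol <- paste0(genotype_kind, "_genotype")
  if (!gcol %in% names(strains)) {
    abort(paste0("`strains` lacks column ", gcol))
  }
  if (!"hosts" %in% names(phages)) {
    if (!"host_strain" %in% names(phages)) {
      abort("`phages` needs a `hosts` list column or a `host_strain` column")
    }
    phages <- phages |>
      dplyr::group_by(.data$phage, .data$rbp_cluster) |>
      dplyr::summarise(hosts = list(unique(.data$host_strain)),
                       .groups = "drop")
  }
  lookup <- setNames(strains[[gcol]], strains$strain)
  all_hosts <- unique(unlist(phages$hosts))
  orphans <- all_hosts[is.na(lookup[all_hosts]) | !all_hosts %in% names(lookup)]
  if (length(orphans)) {
    abort(paste("host strains without a genotype:",
                paste(sort(unique(orphans)), collapse = ", ")))
  }
  success <- vapply(phages$hosts,
                    function(h) all(lookup[h] %in% genotypes), NA)
  drawn <- phages$rbp_cluster %in% clusters
  N <- nrow(phages); K <- sum(success)
  n <- sum(drawn); k_obs <- sum(success & drawn)
  if (k_obs == n) {
    rule <- "all-successes"
    p <- prob_all_successes(N, K, n)
  } else if (tail == "upper") {
    rule <- sprintf("at-least-%d", k_obs)
    p <- prob_at_least(N, K, n, k_obs)
  } else {
    rule <- sprintf("point-%d", k_obs)
    p <- hypergeom_pmf(N, K, n, k_obs)
  }
  structure(list(clusters = clusters, genotypes = genotypes,
                 genotype_kind = genotype_kind,
                 N = N, K = K, n = n, k_obs = k_obs, rule = rule, p = p),
            class = "assoc_test")
}

#' @export
print.assoc_test <- function(x, ...) {
  cat(sprintf(
    "RBP cluster {%s} vs %s genotype {%s}\n  N=%d phages, K=%d with matching hosts, n=%d drawn, %d successes\n  rule %s, p = %.4g\n",
    paste(x$clusters, collapse = ","), x$genotype_kind,
    paste(x$genotypes, collapse = ","), x$N, x$K, x$n, x$k_obs, x$rule, x$p))
  invisible(x)
}

#' Tidiers for association tests
#'
#' @param x an `assoc_test`.
#' @param ... ignored.
#' @return a one-row tibble.
#' @export
tidy.assoc_test <- function(x, ...) {
  tibble(clusters = paste(x$clusters, collapse = ","),
         genotype_kind = x$genotype_kind,
         genotypes = paste(x$genotypes, collapse = ","),
         N = x$N, K = x$K, n = x$n, k_obs = x$k_obs,
         rule = x$rule, p = x$p)
}

#' @rdname tidy.assoc_test
#' @export
glance.assoc_test <- function(x, ...) {
  tibble(N = x$N, K = x$K, n = x$n, k_obs = x$k_obs, p = x$p)
}

#' Shared-host concordance between phage clusters and host range
#'
#' A *case* is a set of two or more phages with an identical host-strain set
#' (default) or, with `mode = "overlap"`, a maximal set of phages connected
#' by sharing at least one strain. A case is concordant when all its phages
#' carry the same cluster label.
#'
#' @param cluster_labels tibble `phage`/`leaf`, `cluster`.
#' @param host_range long tibble `phage`, `strain`.
#' @param mode `"identical"` or `"overlap"`.
#' @return list with `n_cases`, `n_concordant` and a `cases` tibble
#'   (`case`, `phages`, `clusters`, `concordant`).
#' @export
shared_host_concordance <- function(cluster_labels, host_range,
                                    mode = c("identical", "overlap")) {
  mode <- match.arg(mode)
  names(cluster_labels)[1] <- "phage"
  lab <- setNames(cluster_labels$cluster, cluster_labels$phage)
  if (!all(host_range$phage %in% names(lab))) {
    abort("cluster labels must cover every phage in the host range")
  }
  sets <- lapply(split(host_range$strain, host_range$phage),
                 function(s) sort(unique(s)))
  if (mode == "identical") {
    key <- vapply(sets, paste, "", collapse = " ")
    grp <- split(names(sets), key)
  } else {
    g <- igraph::graph_from_data_frame(host_range, directed = FALSE)
    memb <- igraph::components(g)$membership
    ph <- names(sets)
    grp <- split(ph, memb[ph])
  }
  grp <- grp[lengths(grp) >= 2L]
  grp <- lapply(unname(grp), sort)
  cases <- tibble(
    case = seq_along(grp),
    phages = vapply(grp, paste, "", collapse = " "),
    clusters = vapply(grp, function(p) paste(sort(unique(lab[p])),
                                             collapse = " "), ""),
    concordant = vapply(grp, function(p) length(unique(lab[p])) == 1L, NA)
  )
  list(n_cases = nrow(cases), n_concordant = sum(cases$concordant),
       cases = cases)
}
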