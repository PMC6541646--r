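# Independent oracles used by unit and acceptance tests. These deliberately
# avoid the package's own algorithms: alignment scores come from exhaustive
# enumeration, hypergeometric probabilities from subset enumeration,
# ortholog groups from a hand-rolled union-find, patristic distances from
# path walking.

# maximum global alignment score by enumerating every alignment (no DP
# matrices shared with the implementation); gap of length L costs
# open + L * ext, charged per gap run
bf_align_score <- function(a, b, S, open, ext) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  na <- length(ca); nb <- length(cb)
  best <- -Inf
  rec <- function(i, j, last, acc) {
    if (i > na && j > nb) {
      if (acc > best) best <<- acc
      return(invisible(NULL))
    }
    if (i <= na && j <= nb) rec(i + 1, j + 1, 0L, acc + S[ca[i], cb[j]])
    if (i <= na) rec(i + 1, j, 1L, acc - (if (last == 1L) ext else open + ext))
    if (j <= nb) rec(i, j + 1, 2L, acc - (if (last == 2L) ext else open + ext))
  }
  rec(1L, 1L, 0L, 0)
  best
}

# hypergeometric pmf by enumerating every n-subset of 1..N
enum_hyper_pmf <- function(N, K, n, k) {
  if (n == 0) return(as.numeric(k == 0))
  subsets <- utils::combn(N, n)
  mean(colSums(subsets <= K) == k)
}

# union-find partition of `genes` under `edges` (tibble gene_a, gene_b)
uf_partition <- function(edges, genes) {
  parent <- setNames(genes, genes)
  find <- function(x) {
    while (parent[[x]] != x) {
      parent[[x]] <<- parent[[parent[[x]]]]
      x <- parent[[x]]
    }
    x
  }
  if (nrow(edges)) {
    for (r in seq_len(nrow(edges))) {
      ra <- find(edges$gene_a[r]); rb <- find(edges$gene_b[r])
      if (ra != rb) parent[[max(ra, rb)]] <- min(ra, rb)
    }
  }
  roots <- vapply(genes, find, "")
  split(genes, roots)
}

# leaf-to-leaf path lengths by walking the tree's edge list
bf_patristic <- function(tree) {
  n_nodes <- max(tree$edge)
  adj <- vector("list", n_nodes)
  for (e in seq_len(nrow(tree$edge))) {
    u <- tree$edge[e, 1]; v <- tree$edge[e, 2]; w <- tree$edge.length[e]
    adj[[u]] <- rbind(adj[[u]], c(v, w))
    adj[[v]] <- rbind(adj[[v]], c(u, w))
  }
  ntip <- length(tree$tip.label)
  out <- matrix(0, ntip, ntip, dimnames = list(tree$tip.label, tree$tip.label))
  for (s in seq_len(ntip)) {
    dist_to <- rep(NA_real_, n_nodes)
    dist_to[s] <- 0
    queue <- s
    while (length(queue)) {
      u <- queue[1]; queue <- queue[-1]
      for (r in seq_len(NROW(adj[[u]]))) {
        v <- adj[[u]][r, 1]
        if (is.na(dist_to[v])) {
          dist_to[v] <- dist_to[u] + adj[[u]][r, 2]
          queue <- c(queue, v)
        }
      }
    }
    out[s, ] <- dist_to[seq_len(ntip)]
  }
  out
}

rand_protein <- function(len, alphabet = strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# random additive distance matrix with its generating tree
random_additive <- function(n) {
  tr <- ape::rtree(n)
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.1, 2)
  list(tree = tr, d = ape::cophenetic.phylo(tr))
}
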