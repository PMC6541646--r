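#' Alignment scoring parameters
#'
#' Scoring used by every pairwise and progressive alignment in the package.
#' The default is BLOSUM62 with affine gaps costing `gap_open + L * gap_extend`
#' for a gap of length `L` (open 11, extend 1, the usual protein-search
#' scoring). Supplying `match`/`mismatch` instead builds a simple two-value
#' matrix over the 26 letters, which is convenient for small hand-checked
#' examples.
#'
#' @param matrix a substitution matrix with single-letter dimnames, or the
#'   name `"BLOSUM62"`.
#' @param gap_open,gap_extend non-negative gap penalties.
#' @param match,mismatch optional scalar scores; if given they override
#'   `matrix`.
#' @return an object of class `align_scoring`.
#' @export
align_scoring <- function(matrix = "BLOSUM62", gap_open = 11, gap_extend = 1,
                          match = NULL, mismatch = NULL) {
  if (!is.null(match)) {
    if (is.null(mismatch)) abort("`mismatch` required when `match` is given")
    m <- base::matrix(mismatch, 26, 26,
                      dimnames = list(LETTERS, LETTERS))
    diag(m) <- match
  } else if (is.character(matrix)) {
    if (!identical(matrix, "BLOSUM62")) {
      abort("only 'BLOSUM62' is available by name")
    }
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    m <- e$BLOSUM62
  } else {
    m <- matrix
  }
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    abort("substitution matrix must have letter dimnames")
  }
  stopifnot(gap_open >= 0, gap_extend >= 0)
  structure(list(matrix = m, gap_open = gap_open, gap_extend = gap_extend),
            class = "align_scoring")
}

check_seq <- function(x, what) {
  stopifnot_scalar_string(x, what)
  x <- toupper(x)
  bad <- setdiff(strsplit(x, "")[[1]], LETTERS)
  if (length(bad)) abort(paste0("`", what, "` has non-letter characters: ",
                                paste(unique(bad), collapse = " ")))
  x
}

path_to_gapped <- function(chars, path) {
  out <- rep("-", length(path))
  out[path > 0] <- chars[path[path > 0]]
  paste(out, collapse = "")
}

#' Optimal global pairwise alignment
#'
#' Needleman-Wunsch alignment with affine gap penalties, exact over the full
#' dynamic-programming lattice. Identity is counted over columns where both
#' rows carry a residue; `coverage_a`/`coverage_b` are the fractions of each
#' ungapped sequence aligned opposite a residue of the other.
#'
#' @param a,b protein sequences (non-empty strings).
#' @param scoring an [align_scoring()] object.
#' @return an object of class `pairwise_alignment` with elements `aligned_a`,
#'   `aligned_b`, `score`, `identity`, `coverage_a`, `coverage_b`.
#' @examples
#' global_align("ACDEFG", "ACDEFG")$identity
#' @export
global_align <- function(a, b, scoring = align_scoring()) {
  a <- check_seq(a, "a"); b <- check_seq(b, "b")
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  S <- scoring$matrix[ca, cb, drop = FALSE]
  res <- cpp_dp_align(S, scoring$gap_open, scoring$gap_extend)
  pa <- res$path_a; pb <- res$path_b
  both <- pa > 0 & pb > 0
  n_both <- sum(both)
  n_ident <- sum(ca[pa[both]] == cb[pb[both]])
  structure(list(
    aligned_a = path_to_gapped(ca, pa),
    aligned_b = path_to_gapped(cb, pb),
    score = res$score,
    identity = if (n_both > 0) n_ident / n_both else 0,
    coverage_a = n_both / length(ca),
    coverage_b = n_both / length(cb)
  ), class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat("Global alignment  score", format(x$score), "\n")
  cat(" ", x$aligned_a, "\n ", x$aligned_b, "\n")
  cat(sprintf("  identity %.3f  coverage %.3f / %.3f\n",
              x$identity, x$coverage_a, x$coverage_b))
  invisible(x)
}

new_msa <- function(rows) {
  stopifnot(length(unique(nchar(rows))) == 1L)
  structure(rows, class = "phage_msa")
}

#' @export
print.phage_msa <- function(x, ...) {
  cat("Multiple alignment:", length(x), "rows x", nchar(x[[1]]), "columns\n")
  show <- head(seq_along(x), 10)
  for (i in show) {
    cat(sprintf(" %-18s %s\n", names(x)[i],
                substr(x[[i]], 1, 60)))
  }
  if (length(x) > 10) cat(" ...\n")
  invisible(x)
}

msa_matrix <- function(msa) {
  do.call(rbind, strsplit(unclass(msa), ""))
}

# residue-frequency profile of an alignment (rows label x columns),
# letters of `alpha`, gaps contribute zero mass
msa_profile <- function(rows, alpha) {
  m <- do.call(rbind, strsplit(rows, ""))
  L <- ncol(m)
  p <- matrix(0, L, length(alpha), dimnames = list(NULL, alpha))
  for (k in seq_along(alpha)) p[, k] <- colSums(m == alpha[k])
  p / nrow(m)
}

merge_alignments <- function(rows_a, rows_b, scoring) {
  alpha <- rownames(scoring$matrix)
  pa <- msa_profile(rows_a, alpha)
  pb <- msa_profile(rows_b, alpha)
  S <- pa %*% scoring$matrix[alpha, alpha] %*% t(pb)
  res <- cpp_dp_align(S, scoring$gap_open, scoring$gap_extend)
  ia <- res$path_a; ib <- res$path_b
  expand <- function(rows, idx) {
    m <- do.call(rbind, strsplit(rows, ""))
    out <- matrix("-", nrow(m), length(idx))
    out[, idx > 0] <- m[, idx[idx > 0], drop = FALSE]
    setNames(apply(out, 1, paste, collapse = ""), names(rows))
  }
  c(expand(rows_a, ia), expand(rows_b, ib))
}

#' Progressive multiple alignment
#'
#' Profile-based progressive alignment along a UPGMA guide tree built from
#' pairwise alignment identities. Deterministic: sequences are processed in
#' lexicographic label order, so the result does not depend on input order.
#' With two sequences the result equals [global_align()].
#'
#' @param seqs named character vector (or named list) of protein sequences.
#' @param scoring an [align_scoring()] object.
#' @return a `phage_msa`: named character vector of equal-length gapped rows.
#' @export
progressive_msa <- function(seqs, scoring = align_scoring()) {
  seqs <- unlist(seqs)
  if (is.null(names(seqs)) || anyDuplicated(names(seqs))) {
    abort("`seqs` must have unique names")
  }
  seqs <- vapply(seqs, check_seq, "", what = "seqs")
  seqs <- seqs[order(names(seqs))]
  n <- length(seqs)
  if (n == 1L) return(new_msa(seqs))
  if (n == 2L) {
    al <- global_align(seqs[[1]], seqs[[2]], scoring)
    return(new_msa(setNames(c(al$aligned_a, al$aligned_b), names(seqs))))
  }
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      d[i, j] <- d[j, i] <- 1 - global_align(seqs[[i]], seqs[[j]], scoring)$identity
    }
  }
  hc <- hclust(as.dist(d), method = "average")
  clusters <- lapply(seq_len(n), function(i) seqs[i])
  merged <- vector("list", n - 1)
  for (s in seq_len(n - 1)) {
    pick <- function(k) if (k < 0) clusters[[-k]] else merged[[k]]
    merged[[s]] <- merge_alignments(pick(hc$merge[s, 1]), pick(hc$merge[s, 2]),
                                    scoring)
  }
  out <- merged[[n - 1]]
  new_msa(out[order(names(out))])
}

#' Uncorrected p-distance between two alignment rows
#'
#' Proportion of mismatched residues over columns where both rows carry a
#' residue. Errors when the rows share no comparable column.
#'
#' @param msa a `phage_msa`.
#' @param i,j row labels (or indices).
#' @return the p-distance in `[0, 1]`.
#' @export
pdistance <- function(msa, i, j) {
  a <- strsplit(unclass(msa)[[i]], "")[[1]]
  b <- strsplit(unclass(msa)[[j]], "")[[1]]
  both <- a != "-" & b != "-"
  if (!any(both)) abort("no comparable (gap-free) columns between rows")
  mean(a[both] != b[both])
}

#' Poisson-corrected protein distance
#'
#' `-log(1 - p)` with `p` capped at 0.95 so saturated pairs stay finite.
#'
#' @param p p-distance(s) in `[0, 1]`.
#' @export
poisson_distance <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  -log(1 - pmin(p, 0.95))
}

#' All pairwise distances of a multiple alignment
#'
#' @param msa a `phage_msa`.
#' @param correction `"poisson"` (default) or `"p"` for the raw p-distance.
#' @param cap_undefined treat row pairs with no comparable column as the
#'   saturation cap (p = 0.95) instead of erroring; used by bootstrap
#'   resampling where replicates can lose all shared columns of a pair.
#' @return a [stats::dist] with the row labels.
#' @export
msa_distances <- function(msa, correction = c("poisson", "p"),
                          cap_undefined = FALSE) {
  correction <- match.arg(correction)
  n <- length(msa)
  d <- matrix(0, n, n, dimnames = list(names(msa), names(msa)))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      p <- if (cap_undefined) {
        tryCatch(pdistance(msa, i, j), error = function(e) 0.95)
      } else {
        pdistance(msa, i, j)
      }
      d[i, j] <- d[j, i] <- if (correction == "poisson") poisson_distance(p) else p
    }
  }
  as.dist(d)
}

#' Read/write a multiple alignment as aligned FASTA
#' @param msa a `phage_msa`.
#' @param path file path.
#' @export
write_msa <- function(msa, path) {
  Biostrings::writeXStringSet(
    Biostrings::BStringSet(setNames(unclass(msa), names(msa))), path)
  invisible(path)
}

#' @rdname write_msa
#' @export
read_msa <- function(path) {
  x <- Biostrings::readBStringSet(path)
  new_msa(setNames(as.character(x), names(x)))
}
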