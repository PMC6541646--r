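# internal helpers shared across modules

AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# Deterministic substream seed from a master seed and a stream name, so each
# genome/strain draws from its own stream and adding one does not perturb the
# others. Plain polynomial string hash folded with the master seed; kept
# strictly below 2^31.
sub_seed <- function(seed, name) {
  codes <- utf8ToInt(name)
  h <- 0
  for (cc in codes) h <- (h * 31 + cc) %% 2147483647
  (h + (seed %% 2147483647) * 10007) %% 2147483647
}

# evaluate expr under a temporary RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

stopifnot_scalar_string <- function(x, what) {
  if (!is.character(x) || length(x) != 1L || is.na(x) || !nzchar(x)) {
    abort(paste0("`", what, "` must be a single non-empty string"))
  }
}

# qualified gene id <genome>|<gene>
gene_uid <- function(genome, gene) {
  if (any(grepl("|", c(genome, gene), fixed = TRUE))) {
    abort("genome and gene ids must not contain '|'")
  }
  paste(genome, gene, sep = "|")
}

uid_genome <- function(uid) sub("\\|.*$", "", uid)
uid_gene <- function(uid) sub("^[^|]*\\|", "", uid)

roman_labels <- function(n) as.character(utils::as.roman(seq_len(n)))
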