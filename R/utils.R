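# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded package functions do not
#' disturb the caller's RNG stream.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

#' Derive a deterministic per-stage seed from a global seed
#'
#' Mixes a polynomial rolling hash of the stage label with the global seed;
#' the result is always a valid 32-bit seed and every intermediate stays
#' below 2^53, so the arithmetic is exact in doubles. Used to fan one run
#' seed out to the pipeline stages.
#'
#' @param seed Integer global seed.
#' @param stage Character label of the consuming stage.
#' @return An integer seed in `[0, 2^31)`.
#' @export
child_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- 5381
  for (b in utf8ToInt(stage)) h <- (h * 131 + b) %% 2147483647
  as.integer((h + as.numeric(seed) * 48271) %% 2147483647)
}

# Translate a CDS (character scalar) under the standard genetic code.
# Returns the amino-acid string, stops as "*".
translate_cds <- function(cds) {
  n <- nchar(cds)
  stopifnot(n %% 3 == 0)
  if (n == 0L) return("")
  codons <- substring(cds, seq(1L, n, 3L), seq(3L, n, 3L))
  aa <- Biostrings::GENETIC_CODE[codons]
  aa[is.na(aa)] <- "X"
  paste0(aa, collapse = "")
}

split_codons <- function(cds) {
  n <- nchar(cds)
  if (n == 0L) return(character(0))
  substring(cds, seq(1L, n, 3L), seq(3L, n, 3L))
}

# Strip a trailing stop codon if present.
strip_stop <- function(cds) {
  n <- nchar(cds)
  if (n >= 3L && n %% 3L == 0L &&
      substr(cds, n - 2L, n) %in% c("TAA", "TAG", "TGA"))
    substr(cds, 1L, n - 3L) else cds
}

read_fasta_aa <- function(path) Biostrings::readAAStringSet(path)
read_fasta_dna <- function(path) Biostrings::readDNAStringSet(path)

write_fasta <- function(seqs, path) {
  if (is.character(seqs)) {
    stopifnot(!is.null(names(seqs)))
    lines <- character(0)
    for (i in seq_along(seqs)) {
      s <- seqs[[i]]
      body <- substring(s, seq(1L, max(nchar(s), 1L), 70L),
                        pmin(seq(70L, nchar(s) + 69L, 70L), nchar(s)))
      if (nchar(s) == 0L) body <- character(0)
      lines <- c(lines, paste0(">", names(seqs)[i]), body)
    }
    writeLines(lines, path)
  } else {
    Biostrings::writeXStringSet(seqs, path)
  }
  invisible(path)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.delim(path, stringsAsFactors = FALSE, ...)
}

# Adjusted Rand index between two labelings given as vectors of cluster ids
# aligned on the same elements. Hubert & Arabie normalization.
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  if (length(a) == 0L) return(NA_real_)
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_a <- sum(ch2(rowSums(tab)))
  sum_b <- sum(ch2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / ch2(n)
  mx <- (sum_a + sum_b) / 2
  if (mx == expected) return(1)
  (sum_ij - expected) / (mx - expected)
}

pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\t")
}
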