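# All-vs-all protein similarity: windowed-entropy low-complexity masking,
# Smith-Waterman local alignment (BLOSUM62), Karlin-Altschul E-values, and a
# non-redundant pair list ready for Markov clustering.

blosum62_matrix <- function(zero_x = TRUE) {
  mat <- get_blosum62()
  if (zero_x) {
    mat["X", ] <- 0
    mat[, "X"] <- 0
  }
  mat
}

get_blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

#' Mask low-complexity protein segments
#'
#' Slides a window along the sequence; every residue inside a window whose
#' Shannon entropy (log2, over the 20-letter alphabet) falls below
#' `entropy_threshold` is replaced by `X`. Masked positions score 0 against
#' anything during alignment (the BLOSUM62 matrix used by [build_pair_list()]
#' has its X row/column zeroed). A simplified stand-in for the SEG filter.
#'
#' @param protein Amino-acid string.
#' @param window Window length in residues (>= 3).
#' @param entropy_threshold Bits; windows below this are masked.
#' @return The masked amino-acid string.
#' @export
mask_low_complexity <- function(protein, window = 12L, entropy_threshold = 2.2) {
  stopifnot(window >= 3L)
  n <- nchar(protein)
  if (n < window) return(protein)
  aa <- strsplit(protein, "")[[1]]
  mask <- logical(n)
  for (i in seq_len(n - window + 1L)) {
    w <- aa[i:(i + window - 1L)]
    p <- table(w) / window
    h <- -sum(p * log2(p))
    if (h < entropy_threshold) mask[i:(i + window - 1L)] <- TRUE
  }
  aa[mask] <- "X"
  paste0(aa, collapse = "")
}

#' Local protein alignment (Smith-Waterman, affine gaps)
#'
#' Thin wrapper over Biostrings' pairwise alignment with a gap of length k
#' costing `gap_open + k * gap_extend`. Traceback is deterministic.
#'
#' @param a,b Amino-acid strings (non-empty).
#' @param matrix Substitution matrix (default BLOSUM62 with X scoring 0).
#' @param gap_open,gap_extend Positive gap penalties.
#' @return List with `score`, `a_aln`, `b_aln` (aligned substrings with `-`).
#' @export
align_pair <- function(a, b, matrix = blosum62_matrix(),
                       gap_open = 11, gap_extend = 1) {
  stopifnot(nchar(a) > 0, nchar(b) > 0)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = matrix, gapOpening = gap_open,
    gapExtension = gap_extend, type = "local")
  sc <- Biostrings::score(pa)
  if (sc <= 0) {
    return(list(score = 0, a_aln = "", b_aln = ""))
  }
  list(score = sc,
       a_aln = as.character(Biostrings::alignedPattern(pa)),
       b_aln = as.character(Biostrings::alignedSubject(pa)))
}

#' Karlin-Altschul E-value for a local alignment score
#'
#' `E = k * len_a * db_residues * exp(-lambda * score)` with gapped BLOSUM62
#' conventions as defaults. A deterministic stand-in for BLAST's statistic;
#' only its logarithm feeds the MCL edge weight.
#'
#' @param score Raw alignment score (>= 0).
#' @param len_a Query length in residues.
#' @param db_residues Total residues in the database searched.
#' @param lambda,k Karlin-Altschul parameters.
#' @export
estimate_evalue <- function(score, len_a, db_residues,
                            lambda = 0.267, k = 0.041) {
  stopifnot(all(score >= 0))
  k * len_a * db_residues * exp(-lambda * score)
}

#' Build the non-redundant all-vs-all similarity pair list
#'
#' Aligns every unordered pair of proteins (after optional low-complexity
#' masking), converts scores to E-values, keeps pairs with E <=
#' `evalue_cutoff`, and returns one edge per unordered pair with gene_a <
#' gene_b, sorted by (gene_a, gene_b). Self matches never appear. The MCL
#' edge weight `min(ceil, -mul * ln E)` is attached to each edge.
#'
#' @param catalog A `gene_catalog`.
#' @param evalue_cutoff Maximum E-value for a retained edge.
#' @param top_hits_per_gene Keep an edge only if it ranks within the top k
#'   scores of at least one endpoint (`Inf` keeps all).
#' @param mask Apply [mask_low_complexity()] before alignment.
#' @param gap_open,gap_extend Gap penalties.
#' @param mul,ceiling_weight Parameters of [edge_weight()].
#' @return data.frame of class `similarity_edges` with columns gene_a,
#'   gene_b, score, evalue, weight.
#' @export
build_pair_list <- function(catalog, evalue_cutoff = 1e-5,
                            top_hits_per_gene = Inf, mask = TRUE,
                            gap_open = 11, gap_extend = 1,
                            mul = 0.4343, ceiling_weight = 200) {
  stopifnot(inherits(catalog, "gene_catalog"), n_genes(catalog) > 0)
  prots <- catalog$protein
  if (mask) prots <- vapply(prots, mask_low_complexity, "")
  ids <- names(prots)
  nseq <- length(prots)
  empty <- data.frame(gene_a = character(0), gene_b = character(0),
                      score = numeric(0), evalue = numeric(0),
                      weight = numeric(0), stringsAsFactors = FALSE)
  class(empty) <- c("similarity_edges", class(empty))
  if (nseq < 2L) return(empty)
  db_residues <- sum(nchar(catalog$protein))
  mat <- blosum62_matrix()
  set <- Biostrings::AAStringSet(prots)
  rows <- vector("list", nseq - 1L)
  for (i in seq_len(nseq - 1L)) {
    js <- (i + 1L):nseq
    sc <- Biostrings::pairwiseAlignment(
      set[js], set[[i]], substitutionMatrix = mat,
      gapOpening = gap_open, gapExtension = gap_extend,
      type = "local", scoreOnly = TRUE)
    sc <- pmax(sc, 0)
    ev <- estimate_evalue(sc, nchar(prots[[i]]), db_residues)
    keep <- ev <= evalue_cutoff
    if (any(keep)) {
      a <- rep(ids[i], sum(keep)); b <- ids[js][keep]
      swap <- a > b
      rows[[i]] <- data.frame(
        gene_a = ifelse(swap, b, a), gene_b = ifelse(swap, a, b),
        score = sc[keep], evalue = ev[keep], stringsAsFactors = FALSE)
    }
  }
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows) == 0L) return(empty)
  edges <- do.call(rbind, rows)
  # one edge per unordered pair, best score wins
  edges <- edges[order(edges$gene_a, edges$gene_b, -edges$score), ]
  edges <- edges[!duplicated(paste(edges$gene_a, edges$gene_b)), ]
  if (is.finite(top_hits_per_gene)) {
    edges <- filter_top_hits(edges, top_hits_per_gene)
  }
  edges$weight <- edge_weight(edges$evalue, mul = mul, ceil = ceiling_weight)
  edges <- edges[order(edges$gene_a, edges$gene_b), , drop = FALSE]
  rownames(edges) <- NULL
  class(edges) <- c("similarity_edges", class(edges))
  edges
}

filter_top_hits <- function(edges, k) {
  long <- rbind(data.frame(g = edges$gene_a, i = seq_len(nrow(edges)),
                           score = edges$score),
                data.frame(g = edges$gene_b, i = seq_len(nrow(edges)),
                           score = edges$score))
  keep <- unlist(lapply(split(long, long$g), function(d) {
    d$i[order(-d$score)][seq_len(min(k, nrow(d)))]
  }))
  edges[sort(unique(keep)), , drop = FALSE]
}

#' Read / write pair lists in 12-column BLAST tabular layout
#'
#' `read_pair_list()` accepts real BLAST `-outfmt 6` output (qseqid sseqid
#' pident length mismatch gapopen qstart qend sstart send evalue bitscore),
#' drops self matches, collapses redundant hits to the best-scoring one per
#' unordered pair, and attaches MCL edge weights. `write_pair_list()` emits
#' the same layout; only columns 1, 2, 11 and 12 carry information computed
#' by this package, the positional columns are written as 0.
#'
#' @param path File path.
#' @param mul,ceiling_weight See [edge_weight()].
#' @return `read_pair_list()`: a `similarity_edges` data.frame.
#' @export
read_pair_list <- function(path, mul = 0.4343, ceiling_weight = 200) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  stopifnot(ncol(df) >= 12)
  df <- df[df[[1]] != df[[2]], , drop = FALSE]
  a <- pmin(df[[1]], df[[2]]); b <- pmax(df[[1]], df[[2]])
  edges <- data.frame(gene_a = a, gene_b = b, score = df[[12]],
                      evalue = df[[11]], stringsAsFactors = FALSE)
  edges <- edges[order(edges$gene_a, edges$gene_b, -edges$score), ]
  edges <- edges[!duplicated(paste(edges$gene_a, edges$gene_b)), ]
  edges$weight <- edge_weight(edges$evalue, mul = mul, ceil = ceiling_weight)
  rownames(edges) <- NULL
  class(edges) <- c("similarity_edges", class(edges))
  edges
}

#' @rdname read_pair_list
#' @param edges A `similarity_edges` data.frame.
#' @export
write_pair_list <- function(edges, path) {
  out <- data.frame(edges$gene_a, edges$gene_b, 0, 0, 0, 0, 0, 0, 0, 0,
                    edges$evalue, edges$score)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
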