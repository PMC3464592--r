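# Pairwise Ks/Ka estimation: global protein alignment, back-translation to a
# codon alignment, and NG86 counting (see ng86.R).

#' Global protein alignment (Needleman-Wunsch, affine gaps)
#'
#' @param a,b Amino-acid strings (non-empty).
#' @param matrix Substitution matrix; default plain BLOSUM62.
#' @param gap_open,gap_extend Positive gap penalties (CLUSTALW-like defaults).
#' @return List with `score`, `a_aln`, `b_aln` (equal-length strings with
#'   `-` gaps).
#' @export
global_align_protein <- function(a, b, matrix = get_blosum62(),
                                 gap_open = 10, gap_extend = 0.5) {
  stopifnot(nchar(a) > 0, nchar(b) > 0)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = matrix, gapOpening = gap_open,
    gapExtension = gap_extend, type = "global")
  list(score = Biostrings::score(pa),
       a_aln = as.character(Biostrings::alignedPattern(pa)),
       b_aln = as.character(Biostrings::alignedSubject(pa)))
}

#' Back-translate a protein alignment to a codon alignment
#'
#' Maps residue i of each aligned protein to codon i of its CDS (trailing
#' stop codons are stripped first); protein gaps become codon gaps. Columns
#' where either codon contains a character outside A/C/G/T are flagged
#' `excluded` and do not count toward `n_compared`.
#'
#' @param a_aln,b_aln Aligned protein strings of equal length.
#' @param cds_a,cds_b Unaligned CDS strings; after stop stripping each must
#'   be exactly 3x the ungapped protein length.
#' @param pair Character vector of the two gene ids (for reporting).
#' @return Object of class `codon_alignment`: `codons_a`, `codons_b`
#'   (character vectors, `NA` at gaps), `excluded`, `n_compared`, `pair`.
#' @export
back_translate <- function(a_aln, b_aln, cds_a, cds_b,
                           pair = c("a", "b")) {
  stopifnot(nchar(a_aln) == nchar(b_aln))
  cds_a <- strip_stop(cds_a)
  cds_b <- strip_stop(cds_b)
  ra <- strsplit(a_aln, "")[[1]]
  rb <- strsplit(b_aln, "")[[1]]
  ung_a <- sum(ra != "-")
  ung_b <- sum(rb != "-")
  if (nchar(cds_a) != 3L * ung_a)
    stop("back_translate: CDS length of ", pair[1],
         " does not match its aligned protein (", nchar(cds_a), " nt vs ",
         ung_a, " residues)")
  if (nchar(cds_b) != 3L * ung_b)
    stop("back_translate: CDS length of ", pair[2],
         " does not match its aligned protein (", nchar(cds_b), " nt vs ",
         ung_b, " residues)")
  codons_of <- function(res, cds) {
    codons <- split_codons(cds)
    out <- rep(NA_character_, length(res))
    out[res != "-"] <- codons
    out
  }
  ca <- codons_of(ra, cds_a)
  cb <- codons_of(rb, cds_b)
  bad <- function(x) !is.na(x) & !grepl("^[ACGT]{3}$", x)
  excluded <- bad(ca) | bad(cb)
  n_compared <- sum(!is.na(ca) & !is.na(cb) & !excluded)
  structure(list(codons_a = ca, codons_b = cb, excluded = excluded,
                 n_compared = n_compared, pair = pair),
            class = "codon_alignment")
}

#' Align two genes and estimate Ks/Ka
#'
#' Convenience wrapper: global protein alignment, back-translation, NG86.
#' @param catalog A `gene_catalog`.
#' @param gene_a,gene_b Gene ids in the catalog.
#' @inheritParams ng86_pair
#' @inheritParams global_align_protein
#' @return A `ks_result` row (see [ng86_pair()]).
#' @export
ks_for_pair <- function(catalog, gene_a, gene_b, min_codons = 30L,
                        gap_open = 10, gap_extend = 0.5) {
  aln <- global_align_protein(catalog$protein[[gene_a]],
                              catalog$protein[[gene_b]],
                              gap_open = gap_open, gap_extend = gap_extend)
  caln <- back_translate(aln$a_aln, aln$b_aln,
                         catalog$cds[[gene_a]], catalog$cds[[gene_b]],
                         pair = c(gene_a, gene_b))
  ng86_pair(caln, min_codons = min_codons)
}

#' Pairwise Ks for every member pair of a duplication set
#'
#' Computes a `ks_result` for each unordered member pair and the arithmetic
#' mean Ks over pairs with `status == "ok"` (`NA` when no pair is ok).
#'
#' @param s A `duplication_set`.
#' @param catalog A `gene_catalog`.
#' @inheritParams ks_for_pair
#' @return List with `pairs` (data.frame of ks_result rows, plus set_id) and
#'   `mean_ks`.
#' @export
set_pairwise_ks <- function(s, catalog, min_codons = 30L,
                            gap_open = 10, gap_extend = 0.5) {
  stopifnot(inherits(s, "duplication_set"))
  m <- s$members
  rows <- list()
  for (i in seq_len(length(m) - 1L)) {
    for (j in (i + 1L):length(m)) {
      rows[[length(rows) + 1L]] <-
        ks_for_pair(catalog, m[i], m[j], min_codons = min_codons,
                    gap_open = gap_open, gap_extend = gap_extend)
    }
  }
  pairs <- do.call(rbind, rows)
  pairs <- cbind(set_id = s$set_id, pairs, stringsAsFactors = FALSE)
  ok <- pairs$status == "ok"
  list(pairs = pairs,
       mean_ks = if (any(ok)) mean(pairs$ks[ok]) else NA_real_)
}

#' Pairwise Ks table for a list of duplication sets
#'
#' @param sets List of `duplication_set`s (classified or not).
#' @param catalog A `gene_catalog`.
#' @inheritParams ks_for_pair
#' @return data.frame with one row per member pair: set_id, set_size, the
#'   ks_result columns, and `label` if the sets carry pair classifications.
#' @export
sets_pairwise_ks <- function(sets, catalog, min_codons = 30L,
                             gap_open = 10, gap_extend = 0.5) {
  out <- lapply(sets, function(s) {
    res <- set_pairwise_ks(s, catalog, min_codons = min_codons,
                           gap_open = gap_open, gap_extend = gap_extend)
    df <- res$pairs
    df$set_size <- length(s$members)
    if (!is.null(s$pair_labels)) {
      key <- pair_key(s$pair_labels$gene_a, s$pair_labels$gene_b)
      df$label <- s$pair_labels$label[match(pair_key(df$gene_a, df$gene_b),
                                            key)]
    } else {
      df$label <- NA_character_
    }
    df
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write a pairwise Ks table as TSV
#' @param ks_table Output of [sets_pairwise_ks()].
#' @param path Output path.
#' @export
write_ks_table <- function(ks_table, path) {
  cols <- c("gene_a", "gene_b", "set_id", "set_size", "label", "n_compared",
            "S", "N", "Sd", "Nd", "ps", "pn", "ka", "ks", "status")
  write_tsv(ks_table[, intersect(cols, names(ks_table))], path)
}

#' Write / read a codon alignment as aligned FASTA
#' @param aln A `codon_alignment`.
#' @param path File path.
#' @export
write_codon_alignment <- function(aln, path) {
  to_str <- function(x) paste0(ifelse(is.na(x), "---", x), collapse = "")
  seqs <- c(to_str(aln$codons_a), to_str(aln$codons_b))
  names(seqs) <- aln$pair
  write_fasta(seqs, path)
}

#' @rdname write_codon_alignment
#' @export
read_codon_alignment <- function(path) {
  seqs <- as.character(read_fasta_dna(path))
  stopifnot(length(seqs) == 2L)
  split3 <- function(s) {
    cods <- split_codons(s)
    cods[cods == "---"] <- NA_character_
    cods
  }
  ca <- split3(seqs[[1]])
  cb <- split3(seqs[[2]])
  bad <- function(x) !is.na(x) & !grepl("^[ACGT]{3}$", x)
  excluded <- bad(ca) | bad(cb)
  structure(list(codons_a = ca, codons_b = cb, excluded = excluded,
                 n_compared = sum(!is.na(ca) & !is.na(cb) & !excluded),
                 pair = names(seqs)),
            class = "codon_alignment")
}
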