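# Shotgun-assembly collapse simulation: fragment a reference into fixed
# length error-free reads, reassemble with a greedy exact-overlap assembler,
# and map contigs back to the reference to count paralog collapse events.

#' Fragment a reference into error-free reads
#'
#' Draws `round(coverage * L / read_length)` reads of fixed length at
#' uniformly random start positions on the forward strand (shotgun model;
#' `tiling = TRUE` instead places reads end to end at exact offsets).
#'
#' @param reference Nucleotide string, length >= `read_length`.
#' @param read_length Read length in bp.
#' @param coverage Fold coverage.
#' @param seed RNG seed.
#' @param tiling Exact tiling instead of random starts.
#' @return List of class `read_set`: `reads` (character vector), `starts`,
#'   `read_length`, `coverage`, `seed`.
#' @export
fragment <- function(reference, read_length = 500L, coverage = 10,
                     seed = 1L, tiling = FALSE) {
  L <- nchar(reference)
  stopifnot(L >= read_length)
  n <- round(coverage * L / read_length)
  starts <- if (tiling) {
    s <- seq(1L, L, by = read_length)
    pmin(s, L - read_length + 1L)
  } else {
    with_seed(seed, sample.int(L - read_length + 1L, n, replace = TRUE))
  }
  reads <- substring(reference, starts, starts + read_length - 1L)
  structure(list(reads = reads, starts = starts,
                 read_length = as.integer(read_length),
                 coverage = coverage, seed = seed),
            class = "read_set")
}

#' Greedy exact-overlap assembly
#'
#' Repeatedly merges the pair of reads/contigs with the longest exact
#' suffix-prefix overlap of at least `min_overlap` bp (ties broken
#' lexicographically; contained reads absorbed) until no merge is possible.
#' Deterministic and independent of read order.
#'
#' @param reads A `read_set` or character vector of reads.
#' @param min_overlap Minimum exact overlap for a merge (bp).
#' @return Character vector of contigs, sorted.
#' @export
greedy_assemble <- function(reads, min_overlap = 50L) {
  if (inherits(reads, "read_set")) reads <- reads$reads
  stopifnot(is.character(reads))
  if (length(reads) == 0L) return(character(0))
  .greedy_assemble_cpp(reads, as.integer(min_overlap))
}

#' Map contigs back to a reference
#'
#' A contig maps when it aligns to the reference with identity at least
#' `min_identity` over at least `min_cov` of its length. Error-free contigs
#' are found by exact substring search; imperfect (e.g. chimeric) contigs
#' fall back to seed-and-extend local alignment. When `repeats` describes
#' planted repeat copies, collapse events are counted: for each repeat
#' family, `copies - occurrences` of the repeat unit across all contigs
#' (floored at 0).
#'
#' @param contigs Character vector of contigs.
#' @param reference Reference nucleotide string.
#' @param min_identity Identity threshold.
#' @param min_cov Minimum aligned fraction of the contig length.
#' @param repeats Optional data.frame with columns family, start, end
#'   (1-based inclusive copy intervals on the reference).
#' @return List of class `contig_mapping`: `table` (data.frame contig_id,
#'   length, ref_start, identity, mapped), `mapped_fraction`,
#'   `covered_fraction` (reference bases under mapped exact contigs),
#'   `collapse_events`.
#' @export
map_contigs <- function(contigs, reference, min_identity = 0.98,
                        min_cov = 0.9, repeats = NULL) {
  n <- length(contigs)
  ref_len <- nchar(reference)
  covered <- logical(ref_len)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    ctg <- contigs[i]
    len <- nchar(ctg)
    hit <- regexpr(ctg, reference, fixed = TRUE)
    if (hit[1] > 0) {
      rows[[i]] <- data.frame(contig_id = sprintf("contig%05d", i),
                              length = len, ref_start = as.integer(hit[1]),
                              identity = 1, mapped = TRUE)
      covered[hit[1]:(hit[1] + len - 1L)] <- TRUE
      next
    }
    aln <- seed_extend_map(ctg, reference, min_identity, min_cov)
    rows[[i]] <- data.frame(contig_id = sprintf("contig%05d", i),
                            length = len, ref_start = aln$ref_start,
                            identity = aln$identity, mapped = aln$mapped)
    if (aln$mapped && !is.na(aln$ref_start)) {
      covered[aln$ref_start:min(ref_len, aln$ref_start + len - 1L)] <- TRUE
    }
  }
  tab <- do.call(rbind, rows)
  collapse <- NA_integer_
  if (!is.null(repeats)) {
    collapse <- 0L
    for (fam in unique(repeats$family)) {
      rf <- repeats[repeats$family == fam, , drop = FALSE]
      unit <- substr(reference, rf$start[1], rf$end[1])
      occ <- sum(vapply(contigs, function(ctg) {
        m <- gregexpr(unit, ctg, fixed = TRUE)[[1]]
        if (m[1] == -1) 0L else length(m)
      }, 0L))
      collapse <- collapse + max(0L, nrow(rf) - occ)
    }
  }
  structure(list(table = tab,
                 mapped_fraction = if (n > 0) mean(tab$mapped) else NA_real_,
                 covered_fraction = mean(covered),
                 collapse_events = collapse),
            class = "contig_mapping")
}

# Seed-and-extend fallback for contigs that are not exact substrings:
# try exact 60-bp seeds along the contig; align the contig to a window
# around each seed hit and keep the best identity.
seed_extend_map <- function(ctg, reference, min_identity, min_cov) {
  len <- nchar(ctg)
  seed_len <- min(60L, len)
  seed_at <- unique(pmax(1L, pmin(len - seed_len + 1L,
    as.integer(seq(1L, len - seed_len + 1L, length.out = 5L)))))
  best <- list(ref_start = NA_integer_, identity = 0, mapped = FALSE)
  for (s in seed_at) {
    seed <- substr(ctg, s, s + seed_len - 1L)
    hits <- gregexpr(seed, reference, fixed = TRUE)[[1]]
    if (hits[1] == -1) next
    for (h in hits) {
      wstart <- max(1L, h - s - 100L)
      wend <- min(nchar(reference), h + (len - s) + 100L)
      window <- substr(reference, wstart, wend)
      pa <- Biostrings::pairwiseAlignment(
        Biostrings::DNAString(ctg), Biostrings::DNAString(window),
        type = "local", substitutionMatrix =
          Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2),
        gapOpening = 5, gapExtension = 2)
      identity <- Biostrings::pid(pa, type = "PID1") / 100
      pat <- Biostrings::pattern(pa)
      span <- Biostrings::end(pat) - Biostrings::start(pat) + 1L
      if (identity > best$identity && span >= min_cov * len) {
        best <- list(
          ref_start = wstart + Biostrings::start(Biostrings::subject(pa)) - 1L,
          identity = identity,
          mapped = identity >= min_identity)
      }
    }
  }
  best
}

#' Write reads or contigs as FASTA
#' @param x A `read_set` or character vector.
#' @param path Output path.
#' @param prefix Sequence name prefix.
#' @export
write_reads <- function(x, path, prefix = "seq") {
  seqs <- if (inherits(x, "read_set")) x$reads else x
  names(seqs) <- sprintf("%s%05d", prefix, seq_along(seqs))
  write_fasta(seqs, path)
}

#' Write a contig mapping report as TSV
#' @param mapping A `contig_mapping`.
#' @param path Output path.
#' @export
write_mapping <- function(mapping, path) {
  write_tsv(mapping$table, path)
}
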