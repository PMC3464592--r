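# Three-way, non-exclusive duplication-type classification:
# tandem (same chromosome, gap < 10 kb), intra-chromosomal (same chromosome,
# gap >= 10 kb), inter-chromosomal (different chromosomes).

#' Intergenic distance between two genes
#'
#' The gap in base pairs between the closest boundaries of the two gene
#' spans: `max(0, max(start_a, start_b) - min(end_a, end_b) - 1)`. Zero for
#' overlapping or abutting spans; `NA` when the genes sit on different
#' chromosomes. Strand is ignored.
#'
#' @param a,b Single-row gene records (chromosome, start, end), e.g. rows of
#'   `catalog$genes`.
#' @return Base pairs, or `NA_real_` across chromosomes.
#' @export
gene_distance <- function(a, b) {
  if (a$chromosome != b$chromosome) return(NA_real_)
  max(0, max(a$start, b$start) - min(a$end, b$end) - 1)
}

#' Classify one gene pair by duplication type
#'
#' `inter` when the genes lie on different chromosomes; `tandem` when on the
#' same chromosome at a gap strictly below `tandem_threshold`; `intra`
#' otherwise (a gap of exactly the threshold is intra).
#'
#' @param a,b Gene records as in [gene_distance()].
#' @param tandem_threshold Gap threshold in bp (default 10 kb).
#' @return List with `same_chromosome`, `distance`, `label`.
#' @export
classify_pair <- function(a, b, tandem_threshold = 10000) {
  d <- gene_distance(a, b)
  if (is.na(d)) {
    label <- "inter"; same <- FALSE
  } else {
    same <- TRUE
    label <- if (d < tandem_threshold) "tandem" else "intra"
  }
  list(same_chromosome = same, distance = d, label = label)
}

#' Classify every member pair of a duplication set
#'
#' Labels all unordered member pairs with [classify_pair()]; the set-level
#' labels are the union of the pair labels, and a set is `mixed` when it
#' carries more than one label. With `require_adjacent = TRUE` a pair is only
#' tandem if, additionally, no other catalog gene lies fully between the two
#' spans on the same chromosome.
#'
#' @param s A `duplication_set`.
#' @param catalog A `gene_catalog` containing every member.
#' @param tandem_threshold Gap threshold in bp.
#' @param require_adjacent Disqualify tandem pairs with intervening genes.
#' @return The set with `pair_labels` (data.frame gene_a, gene_b,
#'   same_chromosome, distance, label), `set_labels` and `mixed` filled.
#' @export
classify_set <- function(s, catalog, tandem_threshold = 10000,
                         require_adjacent = FALSE) {
  stopifnot(inherits(s, "duplication_set"), inherits(catalog, "gene_catalog"))
  g <- catalog$genes
  missing <- setdiff(s$members, g$gene_id)
  if (length(missing))
    stop("classify_set: set ", s$set_id, " member(s) missing from catalog: ",
         paste(missing, collapse = ", "))
  m <- s$members
  rows <- list()
  for (i in seq_len(length(m) - 1L)) {
    for (j in (i + 1L):length(m)) {
      ga <- g[g$gene_id == m[i], ]
      gb <- g[g$gene_id == m[j], ]
      cl <- classify_pair(ga, gb, tandem_threshold)
      if (cl$label == "tandem" && require_adjacent &&
          has_intervening_gene(ga, gb, g)) {
        cl$label <- "intra"
      }
      rows[[length(rows) + 1L]] <- data.frame(
        gene_a = m[i], gene_b = m[j],
        same_chromosome = cl$same_chromosome,
        distance = if (is.na(cl$distance)) NA_real_ else cl$distance,
        label = cl$label, stringsAsFactors = FALSE)
    }
  }
  s$pair_labels <- do.call(rbind, rows)
  s$set_labels <- sort(unique(s$pair_labels$label))
  s$mixed <- length(s$set_labels) > 1L
  s
}

has_intervening_gene <- function(ga, gb, genes) {
  lo <- min(ga$end, gb$end)
  hi <- max(ga$start, gb$start)
  if (hi <= lo) return(FALSE)
  between <- genes$chromosome == ga$chromosome &
    genes$start > lo & genes$end < hi &
    !(genes$gene_id %in% c(ga$gene_id, gb$gene_id))
  any(between)
}

#' Classify a list of duplication sets
#' @inheritParams classify_set
#' @param sets List of `duplication_set`s.
#' @return The list with labels filled.
#' @export
classify_sets <- function(sets, catalog, tandem_threshold = 10000,
                          require_adjacent = FALSE) {
  lapply(sets, classify_set, catalog = catalog,
         tandem_threshold = tandem_threshold,
         require_adjacent = require_adjacent)
}

#' Per-set and per-pair classification tables
#'
#' @param sets Classified `duplication_set`s.
#' @return `set_type_table()`: data.frame set_id, size, labels
#'   (semicolon-joined), mixed. `pair_type_table()`: data.frame set_id,
#'   gene_a, gene_b, same_chromosome, distance, label.
#' @export
set_type_table <- function(sets) {
  data.frame(
    set_id = vapply(sets, function(s) s$set_id, ""),
    size = vapply(sets, function(s) length(s$members), 0L),
    labels = vapply(sets, function(s) paste(s$set_labels, collapse = ";"), ""),
    mixed = vapply(sets, function(s) isTRUE(s$mixed), TRUE),
    stringsAsFactors = FALSE)
}

#' @rdname set_type_table
#' @export
pair_type_table <- function(sets) {
  do.call(rbind, lapply(sets, function(s) {
    cbind(set_id = s$set_id, s$pair_labels, stringsAsFactors = FALSE)
  }))
}
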