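# Summary statistics and distribution profiles of duplication sets:
# genome-level summary, set-size distribution, Ks histograms and grouped
# mean-Ks tables.

#' Genome-level duplication summary
#'
#' Counts genes, duplication sets, mean set size, and the number (and
#' percentage of sets) carrying each of the three non-exclusive type labels,
#' plus mixed sets. Percentages are over `n_sets`.
#'
#' @param sets Classified `duplication_set`s.
#' @param catalog A `gene_catalog` (for the total gene count).
#' @return List of class `duplication_summary`.
#' @export
summarize_duplications <- function(sets, catalog = NULL) {
  n_sets <- length(sets)
  sizes <- vapply(sets, function(s) length(s$members), 0L)
  has_label <- function(lab)
    sum(vapply(sets, function(s) lab %in% s$set_labels, TRUE))
  n_inter <- if (n_sets) has_label("inter") else 0L
  n_intra <- if (n_sets) has_label("intra") else 0L
  n_tandem <- if (n_sets) has_label("tandem") else 0L
  n_mixed <- if (n_sets)
    sum(vapply(sets, function(s) isTRUE(s$mixed), TRUE)) else 0L
  pct <- function(x) if (n_sets > 0) 100 * x / n_sets else NA_real_
  structure(list(
    n_genes = if (!is.null(catalog)) n_genes(catalog) else NA_integer_,
    n_duplicated_genes = sum(sizes),
    n_sets = n_sets,
    mean_set_size = if (n_sets > 0) sum(sizes) / n_sets else NA_real_,
    n_inter = n_inter, pct_inter = pct(n_inter),
    n_intra = n_intra, pct_intra = pct(n_intra),
    n_tandem = n_tandem, pct_tandem = pct(n_tandem),
    n_mixed = n_mixed, pct_mixed = pct(n_mixed)),
    class = "duplication_summary")
}

#' @export
print.duplication_summary <- function(x, ...) {
  cat("Genes:                 ", x$n_genes, "\n")
  cat("Duplicated genes:      ", x$n_duplicated_genes, "\n")
  cat("Duplication sets:      ", x$n_sets, "\n")
  cat("Mean set size:         ", round(x$mean_set_size, 2), "\n")
  cat(sprintf("Inter-chromosomal sets: %d (%.1f%%)\n", x$n_inter, x$pct_inter))
  cat(sprintf("Intra-chromosomal sets: %d (%.1f%%)\n", x$n_intra, x$pct_intra))
  cat(sprintf("Tandem sets:            %d (%.1f%%)\n", x$n_tandem, x$pct_tandem))
  cat(sprintf("Mixed sets:             %d (%.1f%%)\n", x$n_mixed, x$pct_mixed))
  invisible(x)
}

#' Duplication-set size distribution
#'
#' Per set size k: the number of sets of that size and the fraction of all
#' duplicated genes they contain (`k * count / total duplicated genes`).
#' Sizes above `max_size_bin` are pooled into one tail bin.
#'
#' @param sets List of `duplication_set`s.
#' @param max_size_bin Largest individually reported size.
#' @return data.frame with columns size (character; tail is ">max"), n_sets,
#'   n_genes, fraction_of_duplicated_genes.
#' @export
set_size_distribution <- function(sets, max_size_bin = 25L) {
  sizes <- vapply(sets, function(s) length(s$members), 0L)
  total_genes <- sum(sizes)
  if (length(sizes) == 0L)
    return(data.frame(size = character(0), n_sets = integer(0),
                      n_genes = integer(0),
                      fraction_of_duplicated_genes = numeric(0)))
  main <- sizes[sizes <= max_size_bin]
  tail_sizes <- sizes[sizes > max_size_bin]
  tab <- table(main)
  df <- data.frame(size = names(tab),
                   n_sets = as.integer(tab),
                   n_genes = as.integer(names(tab)) * as.integer(tab),
                   stringsAsFactors = FALSE)
  if (length(tail_sizes)) {
    df <- rbind(df, data.frame(size = paste0(">", max_size_bin),
                               n_sets = length(tail_sizes),
                               n_genes = sum(tail_sizes)))
  }
  df$fraction_of_duplicated_genes <- df$n_genes / total_genes
  df
}

#' Histogram of pairwise Ks values
#'
#' Bins `status == "ok"` Ks values into fixed-width bins on `[0, max_ks]`
#' (values above `max_ks` go into an overflow bin); saturated and too-short
#' pairs are counted separately, never silently dropped.
#'
#' @param ks_table data.frame with columns ks and status
#'   (see [sets_pairwise_ks()]).
#' @param bin_width Bin width in Ks units.
#' @param max_ks Upper edge of the last regular bin.
#' @return List of class `ks_histogram`: bin_edges, counts, fractions
#'   (of ok pairs), n_ok, n_overflow, n_saturated, n_too_short.
#' @export
ks_histogram <- function(ks_table, bin_width = 0.25, max_ks = 6.0) {
  edges <- seq(0, max_ks, by = bin_width)
  ok <- ks_table$status == "ok" & !is.na(ks_table$ks)
  v <- ks_table$ks[ok]
  inb <- v[v <= max_ks]
  counts <- if (length(inb))
    as.integer(table(cut(inb, breaks = edges, right = FALSE,
                         include.lowest = FALSE)))
  else integer(length(edges) - 1L)
  # cut() with right=FALSE drops values exactly at max_ks; fold them in
  counts[length(counts)] <- counts[length(counts)] + sum(inb == max_ks)
  n_ok <- length(v)
  structure(list(bin_edges = edges, counts = counts,
                 fractions = if (n_ok > 0) counts / n_ok else counts * 0,
                 n_ok = n_ok,
                 n_overflow = sum(v > max_ks),
                 n_saturated = sum(ks_table$status == "saturated"),
                 n_too_short = sum(ks_table$status == "too_short")),
            class = "ks_histogram")
}

#' Fraction of ok pairs with Ks at or below a threshold
#'
#' @param ks_table data.frame with ks and status columns.
#' @param threshold Ks threshold (default 1.0, the "recent duplicate" rule).
#' @return `#(ok pairs with ks <= threshold) / #(ok pairs)`; `NaN` with no
#'   ok pairs.
#' @export
fraction_ks_below <- function(ks_table, threshold = 1.0) {
  ok <- ks_table$status == "ok" & !is.na(ks_table$ks)
  sum(ks_table$ks[ok] <= threshold) / sum(ok)
}

#' Mean Ks grouped by duplication-set size
#'
#' @param ks_table Output of [sets_pairwise_ks()] (needs set_size, ks,
#'   status).
#' @return data.frame set_size, mean_ks, n_pairs; empty groups omitted.
#' @export
mean_ks_by_size <- function(ks_table) {
  ok <- ks_table[ks_table$status == "ok" & !is.na(ks_table$ks), , drop = FALSE]
  if (nrow(ok) == 0L)
    return(data.frame(set_size = integer(0), mean_ks = numeric(0),
                      n_pairs = integer(0)))
  agg <- stats::aggregate(ks ~ set_size, data = ok, FUN = mean)
  cnt <- stats::aggregate(ks ~ set_size, data = ok, FUN = length)
  out <- data.frame(set_size = agg$set_size, mean_ks = agg$ks,
                    n_pairs = cnt$ks)
  out[order(out$set_size), , drop = FALSE]
}

#' Mean Ks grouped by set size and pair duplication type
#'
#' @param ks_table Output of [sets_pairwise_ks()] on classified sets (needs
#'   label column).
#' @return data.frame set_size, label, mean_ks, n_pairs.
#' @export
mean_ks_by_size_and_type <- function(ks_table) {
  ok <- ks_table[ks_table$status == "ok" & !is.na(ks_table$ks) &
                   !is.na(ks_table$label), , drop = FALSE]
  if (nrow(ok) == 0L)
    return(data.frame(set_size = integer(0), label = character(0),
                      mean_ks = numeric(0), n_pairs = integer(0)))
  agg <- stats::aggregate(ks ~ set_size + label, data = ok, FUN = mean)
  cnt <- stats::aggregate(ks ~ set_size + label, data = ok, FUN = length)
  out <- data.frame(set_size = agg$set_size, label = agg$label,
                    mean_ks = agg$ks, n_pairs = cnt$ks,
                    stringsAsFactors = FALSE)
  out[order(out$set_size, out$label), , drop = FALSE]
}

#' Mean Ks per duplication type
#' @param ks_table Output of [sets_pairwise_ks()] on classified sets.
#' @return data.frame label, mean_ks, n_pairs.
#' @export
mean_ks_by_type <- function(ks_table) {
  ok <- ks_table[ks_table$status == "ok" & !is.na(ks_table$ks) &
                   !is.na(ks_table$label), , drop = FALSE]
  if (nrow(ok) == 0L)
    return(data.frame(label = character(0), mean_ks = numeric(0),
                      n_pairs = integer(0)))
  agg <- stats::aggregate(ks ~ label, data = ok, FUN = mean)
  cnt <- stats::aggregate(ks ~ label, data = ok, FUN = length)
  data.frame(label = agg$label, mean_ks = agg$ks, n_pairs = cnt$ks,
             stringsAsFactors = FALSE)
}

#' Barplot of a Ks histogram
#' @param x A `ks_histogram`.
#' @param ... Passed to [graphics::barplot()].
#' @export
plot.ks_histogram <- function(x, ...) {
  mids <- utils::head(x$bin_edges, -1) + diff(x$bin_edges) / 2
  graphics::barplot(x$counts, names.arg = format(mids), las = 2,
                    xlab = "Ks", ylab = "gene pairs", ...)
  invisible(x)
}
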