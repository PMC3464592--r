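# Markov clustering of the weighted similarity graph into duplication sets.

#' MCL edge weight from an E-value
#'
#' `weight = min(ceil, max(0, -mul * ln(evalue)))`, with `weight = ceil` for
#' an E-value of exactly zero. With the default `mul = 0.4343` (= log10 e)
#' this is `min(ceil, -log10 E)`.
#'
#' @param evalue E-value(s), >= 0.
#' @param mul Multiplier applied to the natural log.
#' @param ceil Weight cap.
#' @export
edge_weight <- function(evalue, mul = 0.4343, ceil = 200) {
  if (any(is.na(evalue)) || any(evalue < 0))
    stop("edge_weight: evalue must be >= 0")
  w <- ifelse(evalue == 0, ceil, pmin(ceil, pmax(0, -mul * log(evalue))))
  as.numeric(w)
}

#' Markov clustering (MCL) of a weighted undirected graph
#'
#' Builds a column-stochastic transition matrix from the edge weights, with a
#' self-loop on every node equal to its maximum incident edge weight, then
#' alternates expansion (matrix power) and inflation (element-wise power
#' followed by column renormalization), pruning entries below
#' `prune_threshold`, until the matrix change falls below `tol` or `max_iter`
#' is reached. Clusters are read off as connected components of the non-zero
#' structure of the limit matrix, which merges overlapping attractor systems
#' into a strict partition. Deterministic given the input edge order.
#'
#' @param edges data.frame with columns gene_a, gene_b, weight (all > 0), or
#'   a `similarity_edges` object.
#' @param inflation Inflation exponent (> 1).
#' @param expansion Expansion power (integer >= 2).
#' @param prune_threshold Entries below this are zeroed each iteration.
#' @param max_iter,tol Convergence controls.
#' @return List of class `mcl_result`: `clusters` (list of character vectors,
#'   ordered by smallest member), `converged`, `iterations`, and
#'   `max_col_dev`, the per-iteration maximum deviation of any column sum
#'   from 1 measured after inflation.
#' @export
mcl <- function(edges, inflation = 2, expansion = 2L,
                prune_threshold = 1e-5, max_iter = 100L, tol = 1e-6) {
  stopifnot(inflation > 1, expansion >= 2L)
  if (is.null(edges) || nrow(edges) == 0L) {
    return(structure(list(clusters = list(), converged = TRUE,
                          iterations = 0L, max_col_dev = numeric(0)),
                     class = "mcl_result"))
  }
  stopifnot(all(edges$weight > 0), all(edges$gene_a != edges$gene_b))
  g <- igraph::graph_from_data_frame(
    edges[, c("gene_a", "gene_b")], directed = FALSE)
  comps <- igraph::components(g)
  membership <- comps$membership
  clusters <- list()
  all_dev <- numeric(0)
  conv <- TRUE
  iters <- 0L
  for (ci in seq_len(comps$no)) {
    nodes <- sort(names(membership)[membership == ci])
    sub <- edges[edges$gene_a %in% nodes & edges$gene_b %in% nodes, ,
                 drop = FALSE]
    res <- mcl_component(nodes, sub, inflation, expansion,
                         prune_threshold, max_iter, tol)
    clusters <- c(clusters, res$clusters)
    all_dev <- c(all_dev, res$col_dev)
    conv <- conv && res$converged
    iters <- max(iters, res$iterations)
  }
  firsts <- vapply(clusters, function(cl) cl[1], "")
  clusters <- clusters[order(firsts)]
  if (!conv)
    warning("mcl: not converged after ", max_iter, " iterations; ",
            "returning current interpretation")
  structure(list(clusters = clusters, converged = conv, iterations = iters,
                 max_col_dev = all_dev),
            class = "mcl_result")
}

mcl_component <- function(nodes, edges, inflation, expansion,
                          prune_threshold, max_iter, tol) {
  n <- length(nodes)
  if (n == 1L)
    return(list(clusters = list(nodes), converged = TRUE, iterations = 0L,
                col_dev = numeric(0)))
  M <- matrix(0, n, n, dimnames = list(nodes, nodes))
  ia <- match(edges$gene_a, nodes)
  ib <- match(edges$gene_b, nodes)
  M[cbind(ia, ib)] <- pmax(M[cbind(ia, ib)], edges$weight)
  M[cbind(ib, ia)] <- pmax(M[cbind(ib, ia)], edges$weight)
  diag(M) <- apply(M, 1L, max)               # self-loop regularization
  M <- sweep(M, 2L, colSums(M), "/")
  col_dev <- numeric(0)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    E <- M
    for (p in seq_len(expansion - 1L)) E <- E %*% M
    E <- E ^ inflation
    E[E < prune_threshold] <- 0
    cs <- colSums(E)
    cs[cs == 0] <- 1
    E <- sweep(E, 2L, cs, "/")
    col_dev <- c(col_dev, max(abs(colSums(E) - 1)))
    delta <- max(abs(E - M))
    M <- E
    if (delta < tol) { converged <- TRUE; break }
  }
  nz <- M > 0
  adj <- nz | t(nz)
  gi <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  mem <- igraph::components(gi)$membership
  cl <- split(nodes, mem)
  cl <- lapply(unname(cl), sort)
  list(clusters = cl, converged = converged, iterations = it,
       col_dev = col_dev)
}

#' Duplication sets from an MCL partition
#'
#' Clusters with at least `min_size` members become `duplication_set`s;
#' smaller clusters (singletons) are non-duplicated genes and are dropped.
#' Sets are ordered by their lexicographically smallest member and numbered
#' DS0001, DS0002, ... in that order, which is stable for a given clustering.
#'
#' @param partition An `mcl_result` or a list of character vectors.
#' @param min_size Minimum cluster size retained.
#' @return List of `duplication_set` objects.
#' @export
clusters_to_sets <- function(partition, min_size = 2L) {
  clusters <- if (inherits(partition, "mcl_result")) partition$clusters
              else partition
  clusters <- lapply(clusters, function(cl) sort(as.character(cl)))
  clusters <- clusters[vapply(clusters, length, 0L) >= min_size]
  firsts <- vapply(clusters, function(cl) cl[1], "")
  clusters <- clusters[order(firsts)]
  lapply(seq_along(clusters), function(i) {
    structure(list(set_id = sprintf("DS%04d", i),
                   members = clusters[[i]],
                   pair_labels = NULL, set_labels = NULL, mixed = NA),
              class = "duplication_set")
  })
}

#' @export
print.duplication_set <- function(x, ...) {
  cat(x$set_id, " (", length(x$members), " genes)",
      if (!is.null(x$set_labels))
        paste0(" [", paste(x$set_labels, collapse = ";"),
               if (isTRUE(x$mixed)) ", mixed" else "", "]"),
      ": ", paste(x$members, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Write duplication sets as TSV (set_id, size, members)
#' @param sets List of `duplication_set`s.
#' @param path Output path.
#' @export
write_sets <- function(sets, path) {
  df <- data.frame(
    set_id = vapply(sets, function(s) s$set_id, ""),
    size = vapply(sets, function(s) length(s$members), 0L),
    members = vapply(sets, function(s) paste(s$members, collapse = ","), ""))
  write_tsv(df, path)
}
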