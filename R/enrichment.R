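# GO-term over/under-representation: OBO 1.2 parsing, is_a ancestor
# propagation on the DAG, two-sided Fisher's exact test by hypergeometric
# point-probability summation, and Bonferroni / Sidak / Benjamini-Hochberg
# corrections.

#' Parse an OBO 1.2 ontology file into a DAG
#'
#' Consumes id, name, namespace, is_a, alt_id and is_obsolete tags of [Term]
#' stanzas. Obsolete terms are dropped; alt_ids become aliases of their
#' primary term. A cycle among is_a relations is a hard error.
#'
#' @param path Path to an .obo file.
#' @return Object of class `go_dag`: `terms` (data.frame term_id, name,
#'   namespace), `parents` (named list of is_a parent ids), `alias` (named
#'   character vector alt_id -> term_id).
#' @export
parse_obo <- function(path) {
  lines <- readLines(path, warn = FALSE)
  term_starts <- which(lines == "[Term]")
  ids <- character(0); nms <- character(0); nsp <- character(0)
  parents <- list(); alias <- character(0); obsolete <- character(0)
  bounds <- c(term_starts, length(lines) + 1L)
  for (k in seq_along(term_starts)) {
    block <- lines[(bounds[k] + 1L):(bounds[k + 1L] - 1L)]
    block <- block[!grepl("^\\[", block)]
    get1 <- function(tag) {
      v <- sub(paste0("^", tag, ": *"), "", grep(paste0("^", tag, ":"),
                                                 block, value = TRUE))
      if (length(v)) v[1] else NA_character_
    }
    id <- get1("id")
    if (is.na(id)) next
    if (identical(get1("is_obsolete"), "true")) {
      obsolete <- c(obsolete, id)
      next
    }
    isa <- sub("^is_a: *", "", grep("^is_a:", block, value = TRUE))
    isa <- sub(" *!.*$", "", isa)
    alts <- sub("^alt_id: *", "", grep("^alt_id:", block, value = TRUE))
    ids <- c(ids, id)
    nms <- c(nms, get1("name"))
    nsp <- c(nsp, get1("namespace"))
    parents[[id]] <- isa
    if (length(alts)) alias[alts] <- id
  }
  # drop is_a links to obsolete/unknown parents
  parents <- lapply(parents, function(p) intersect(p, ids))
  # cycle check
  el <- do.call(rbind, lapply(ids, function(id) {
    if (length(parents[[id]]))
      cbind(id, parents[[id]]) else NULL
  }))
  if (!is.null(el) && nrow(el)) {
    g <- igraph::graph_from_edgelist(el, directed = TRUE)
    if (!igraph::is_dag(g)) {
      cyc <- names(igraph::feedback_arc_set(g))
      stop("parse_obo: is_a cycle detected involving: ",
           paste(utils::head(unique(c(el[, 1], el[, 2])), 10), collapse = ", "))
    }
  }
  structure(list(terms = data.frame(term_id = ids, name = nms,
                                    namespace = nsp,
                                    stringsAsFactors = FALSE),
                 parents = parents, alias = alias,
                 obsolete = obsolete),
            class = "go_dag")
}

#' All is_a ancestors of a term
#' @param dag A `go_dag`.
#' @param term_id Term id (alt_ids are resolved).
#' @return Character vector of ancestor term ids (excluding the term itself).
#' @export
go_ancestors <- function(dag, term_id) {
  term_id <- resolve_term(dag, term_id)
  seen <- character(0)
  frontier <- dag$parents[[term_id]] %||% character(0)
  while (length(frontier)) {
    seen <- union(seen, frontier)
    frontier <- setdiff(unique(unlist(dag$parents[frontier])), seen)
  }
  seen
}

resolve_term <- function(dag, term_id) {
  if (term_id %in% names(dag$alias)) dag$alias[[term_id]] else term_id
}

#' Propagate gene annotations up the DAG
#'
#' Each gene's term set is unioned with every is_a ancestor (leaf-to-root
#' closure). Annotations to obsolete or unknown terms are dropped with a
#' warning.
#'
#' @param annotations data.frame with columns gene_id, term_id, or a named
#'   list gene -> character vector of term ids.
#' @param dag A `go_dag`.
#' @return Named list gene -> character vector of term ids (closed).
#' @export
propagate_annotations <- function(annotations, dag) {
  if (is.data.frame(annotations)) {
    annotations <- split(annotations$term_id, annotations$gene_id)
  }
  known <- dag$terms$term_id
  closure_cache <- new.env(parent = emptyenv())
  closed_of <- function(t) {
    if (!is.null(closure_cache[[t]])) return(closure_cache[[t]])
    v <- c(t, go_ancestors(dag, t))
    closure_cache[[t]] <- v
    v
  }
  dropped <- character(0)
  out <- lapply(annotations, function(terms) {
    terms <- vapply(unique(terms), function(t) resolve_term(dag, t), "")
    bad <- !(terms %in% known)
    if (any(bad)) dropped <<- union(dropped, terms[bad])
    terms <- terms[!bad]
    if (length(terms) == 0L) return(character(0))
    sort(unique(unlist(lapply(terms, closed_of))))
  })
  if (length(dropped))
    warning("propagate_annotations: dropped annotations to obsolete/unknown ",
            "terms: ", paste(dropped, collapse = ", "))
  out
}

#' Two-sided Fisher's exact test for a study/population term count
#'
#' The study set is a subset of the population. Under the hypergeometric
#' null, the two-sided p-value sums the point probabilities of every study
#' count whose probability does not exceed that of the observed one (the
#' point-probability rule, with the conventional 1 + 1e-7 tie tolerance).
#'
#' @param study_count Annotated genes in the study set.
#' @param study_n Study set size.
#' @param pop_count Annotated genes in the population.
#' @param pop_n Population size.
#' @param alternative "two.sided" (default), "greater" or "less".
#' @return List with `p` and `direction` ("over" when the study frequency
#'   exceeds the population frequency, else "under").
#' @export
fisher_exact <- function(study_count, study_n, pop_count, pop_n,
                         alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  if (study_n > pop_n || study_count > study_n || pop_count > pop_n ||
      study_count > pop_count ||
      study_count < max(0, study_n - (pop_n - pop_count)))
    stop("fisher_exact: inconsistent counts (study must be a subset of the ",
         "population)")
  m <- pop_count
  n <- pop_n - pop_count
  k <- study_n
  support <- max(0L, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  obs <- stats::dhyper(study_count, m, n, k)
  p <- switch(alternative,
    two.sided = sum(probs[probs <= obs * (1 + 1e-7)]),
    greater = sum(probs[support >= study_count]),
    less = sum(probs[support <= study_count]))
  p <- min(1, p)
  dir <- if (pop_n > 0 && study_n > 0 &&
             study_count / study_n > pop_count / pop_n) "over" else "under"
  list(p = p, direction = dir)
}

#' GO-term enrichment of a study set against a population
#'
#' Propagates annotations up the DAG, then tests every term annotated to at
#' least one population gene with [fisher_exact()]. Bonferroni, Sidak and
#' Benjamini-Hochberg corrections are computed over the m tested terms.
#'
#' @param study_genes Character vector, subset of `pop_genes`.
#' @param pop_genes Character vector, the population.
#' @param annotations data.frame (gene_id, term_id) or named list.
#' @param dag A `go_dag`.
#' @param alternative Passed to [fisher_exact()].
#' @param namespace Optional namespace filter (e.g. "biological_process");
#'   default tests all namespaces together.
#' @return data.frame sorted by raw p: term_id, name, namespace,
#'   study_count, study_n, pop_count, pop_n, direction, p, p_bonferroni,
#'   p_sidak, p_fdr_bh.
#' @export
enrich <- function(study_genes, pop_genes, annotations, dag,
                   alternative = "two.sided", namespace = NULL) {
  stopifnot(all(study_genes %in% pop_genes))
  closed <- propagate_annotations(annotations, dag)
  closed <- closed[names(closed) %in% pop_genes]
  pop_terms <- table(unlist(closed))
  if (!is.null(namespace)) {
    keep <- dag$terms$term_id[dag$terms$namespace %in% namespace]
    pop_terms <- pop_terms[names(pop_terms) %in% keep]
  }
  terms <- names(pop_terms)
  m <- length(terms)
  study_closed <- closed[names(closed) %in% study_genes]
  study_terms <- table(unlist(study_closed))
  study_n <- length(study_genes)
  pop_n <- length(pop_genes)
  if (m == 0L)
    return(data.frame(term_id = character(0), name = character(0),
                      namespace = character(0), study_count = integer(0),
                      study_n = integer(0), pop_count = integer(0),
                      pop_n = integer(0), direction = character(0),
                      p = numeric(0), p_bonferroni = numeric(0),
                      p_sidak = numeric(0), p_fdr_bh = numeric(0)))
  rows <- lapply(terms, function(t) {
    sc <- if (t %in% names(study_terms)) as.integer(study_terms[[t]]) else 0L
    pc <- as.integer(pop_terms[[t]])
    ft <- fisher_exact(sc, study_n, pc, pop_n, alternative = alternative)
    data.frame(term_id = t, study_count = sc, study_n = study_n,
               pop_count = pc, pop_n = pop_n, direction = ft$direction,
               p = ft$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_bonferroni <- pmin(1, out$p * m)
  out$p_sidak <- 1 - (1 - pmin(out$p, 1))^m
  out$p_fdr_bh <- stats::p.adjust(out$p, method = "BH")
  ti <- match(out$term_id, dag$terms$term_id)
  out <- cbind(out[, "term_id", drop = FALSE],
               name = dag$terms$name[ti],
               namespace = dag$terms$namespace[ti],
               out[, setdiff(names(out), "term_id")])
  out <- out[order(out$p, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write an enrichment table as TSV
#' @param enrichment_table Output of [enrich()].
#' @param path Output path.
#' @export
write_enrichment <- function(enrichment_table, path) {
  write_tsv(enrichment_table, path)
}

#' Read a two-column gene-to-GO annotation TSV
#'
#' Expects columns gene_id and term_id (with or without a header line).
#' @param path File path.
#' @return data.frame with columns gene_id, term_id.
#' @export
read_annotations <- function(path) {
  first <- readLines(path, n = 1L)
  header <- grepl("gene_id", first)
  df <- utils::read.delim(path, header = header, stringsAsFactors = FALSE)
  names(df)[1:2] <- c("gene_id", "term_id")
  df[, 1:2]
}
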