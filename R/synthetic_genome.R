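# Synthetic annotated genomes with planted duplication histories.
#
# Generates multi-chromosome gene catalogs in which duplication sets of
# controlled size, chromosomal arrangement (tandem / intra / inter / wgd /
# mixed) and codon-level divergence (targeted NG86 Ks) are planted among
# mutually non-homologous background genes, together with the ground truth
# needed to score every pipeline stage.

#' Random coding sequence
#'
#' Uniform random sense codons (stops excluded), starting with ATG.
#' @param length_codons Number of codons.
#' @param seed RNG seed.
#' @return Nucleotide string of length `3 * length_codons`.
#' @export
random_cds <- function(length_codons, seed) {
  stopifnot(length_codons >= 1)
  with_seed(seed, {
    sense <- sense_codons()
    body <- sample(sense, length_codons - 1L, replace = TRUE)
    paste0(c("ATG", body), collapse = "")
  })
}

#' Random DNA sequence
#' @param n Length in bp.
#' @param seed RNG seed.
#' @export
random_dna <- function(n, seed) {
  with_seed(seed, paste0(sample(NUCS, n, replace = TRUE), collapse = ""))
}

# Largest target Ks estimable for a sequence of n_codons codons before the
# required synonymous proportion comes within a 1/n_codons relative margin
# of the Jukes-Cantor saturation limit 0.75.
ks_saturation_bound <- function(n_codons) {
  p_max <- 0.75 * (1 - 1 / n_codons)
  -0.75 * log(1 - 4 * p_max / 3)
}

#' Evolve a paralog to a target synonymous divergence
#'
#' Proposes random single-nucleotide changes on a copy of `cds`; changes
#' creating stop codons are rejected outright, synonymous changes are always
#' accepted and nonsynonymous changes are accepted with probability `omega`.
#' After every accepted change the NG86 Ks between original and mutant is
#' updated incrementally; the walk stops the first time the estimate reaches
#' `target_ks`. If the observed synonymous proportion reaches the
#' Jukes-Cantor limit (0.75) first, the walk stops there and the returned
#' copy carries `status = "saturated"`.
#'
#' @param cds Coding sequence (no internal stops; trailing stop allowed).
#' @param target_ks Target NG86 Ks (>= 0); must be below the saturation
#'   bound for the sequence length (see error message).
#' @param omega Acceptance probability for nonsynonymous changes (Ka/Ks-like
#'   constraint, >= 0).
#' @param seed RNG seed.
#' @return The mutated CDS string with attributes `realized_ks`, `status`
#'   ("ok" or "saturated") and `n_accepted`.
#' @export
evolve_paralog <- function(cds, target_ks, omega, seed) {
  stopifnot(target_ks >= 0, omega >= 0)
  cds <- strip_stop(cds)
  if (target_ks == 0) {
    return(structure(cds, realized_ks = 0, status = "ok", n_accepted = 0L))
  }
  tb <- ng86_tables()
  orig <- split_codons(cds)
  L <- length(orig)
  bound <- ks_saturation_bound(L)
  if (target_ks >= bound)
    stop("evolve_paralog: target_ks ", target_ks,
         " is at or beyond the saturation bound ", round(bound, 3),
         " for ", L, " codons; use a lower target or a longer sequence")
  walk <- function() {
    mut <- orig
    so <- tb$sites[orig]
    sm <- so
    sd_col <- rep(0, L); nd_col <- rep(0, L)
    used <- rep(TRUE, L)
    n_used <- L
    Sd <- 0; Nd <- 0; So_sum <- sum(so); Sm_sum <- sum(sm)
    max_prop <- 4000L * L * max(1, ceiling(target_ks))
    n_acc <- 0L
    for (step in seq_len(max_prop)) {
      pos <- sample.int(3L * L, 1L)
      ci <- (pos - 1L) %/% 3L + 1L
      off <- (pos - 1L) %% 3L + 1L
      cod <- mut[ci]
      ref <- substr(cod, off, off)
      alt <- sample(setdiff(NUCS, ref), 1L)
      newcod <- cod
      substr(newcod, off, off) <- alt
      if (newcod %in% STOP_CODONS) next
      syn <- tb$SD[cod, newcod] == 1   # single-nt change: direct classification
      if (!syn && stats::runif(1) > omega) next
      # accept: update column ci
      n_acc <- n_acc + 1L
      if (used[ci]) {
        Sd <- Sd - sd_col[ci]; Nd <- Nd - nd_col[ci]
        So_sum <- So_sum - so[ci]; Sm_sum <- Sm_sum - sm[ci]
        n_used <- n_used - 1L
      }
      mut[ci] <- newcod
      sm[ci] <- tb$sites[newcod]
      nsd <- tb$SD[orig[ci], newcod]
      if (is.na(nsd)) {
        used[ci] <- FALSE
        sd_col[ci] <- 0; nd_col[ci] <- 0
      } else {
        used[ci] <- TRUE
        sd_col[ci] <- nsd
        nd_col[ci] <- tb$ND[orig[ci], newcod]
        Sd <- Sd + nsd; Nd <- Nd + nd_col[ci]
        So_sum <- So_sum + so[ci]; Sm_sum <- Sm_sum + sm[ci]
        n_used <- n_used + 1L
      }
      S <- (So_sum + Sm_sum) / 2
      if (S <= 0) next
      ps <- Sd / S
      if (ps >= 0.75) {
        return(structure(paste0(mut, collapse = ""),
                         realized_ks = NA_real_, status = "saturated",
                         n_accepted = n_acc))
      }
      ks <- -0.75 * log(1 - 4 * ps / 3)
      if (ks >= target_ks) {
        return(structure(paste0(mut, collapse = ""),
                         realized_ks = ks, status = "ok",
                         n_accepted = n_acc))
      }
    }
    stop("evolve_paralog: target_ks ", target_ks, " not reached after ",
         max_prop, " proposals (omega too small or target too high?)")
  }
  with_seed(seed, walk())
}

#' Simulation configuration for a synthetic genome
#'
#' Defaults describe the standard benchmark genome: 8 chromosomes, 300
#' mutually non-homologous background genes, and 40 planted duplication sets
#' of sizes 2-6 spanning all arrangement types, with divergence cohorts at
#' Ks 0.3 (recent) and 2.0 (old) plus a 4-set mixed cohort at 1.0. Eight
#' chromosomes are needed so that inter-chromosomal sets of up to 6 members
#' can place every copy on a distinct chromosome.
#'
#' @param n_chromosomes Number of chromosomes.
#' @param n_background_genes Background (non-duplicated) gene count.
#' @param gene_length_mean,gene_length_min Gene length in codons; lengths are
#'   drawn uniformly on `[min, 2*mean - min]`.
#' @param intergenic_gap_mean Mean gap between consecutive genes (bp).
#' @param planted_sets data.frame with columns size, type (tandem, intra,
#'   inter, wgd, mixed), target_ks, omega. A `wgd` row of size n plants n
#'   size-2 cross-chromosome sets at a shared target Ks.
#' @param tandem_spacing Gap between tandem array neighbors (bp, < 10000
#'   with margin so that all pairwise gaps stay below 10 kb).
#' @param intra_spacing Minimum gap before an intra-set member (bp, > 10000).
#' @param seed RNG seed.
#' @export
sim_config <- function(n_chromosomes = 8L,
                       n_background_genes = 300L,
                       gene_length_mean = 300L,
                       gene_length_min = 150L,
                       intergenic_gap_mean = 2000,
                       planted_sets = default_planted_sets(),
                       tandem_spacing = 2000,
                       intra_spacing = 50000,
                       seed = 1L) {
  stopifnot(tandem_spacing < 10000, intra_spacing >= 10000,
            all(planted_sets$size >= 2), all(planted_sets$target_ks >= 0))
  structure(list(n_chromosomes = as.integer(n_chromosomes),
                 n_background_genes = as.integer(n_background_genes),
                 gene_length_mean = gene_length_mean,
                 gene_length_min = gene_length_min,
                 intergenic_gap_mean = intergenic_gap_mean,
                 planted_sets = planted_sets,
                 tandem_spacing = tandem_spacing,
                 intra_spacing = intra_spacing,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' @rdname sim_config
#' @export
default_planted_sets <- function() {
  rbind(
    data.frame(size = c(2L, 2L, 3L, 2L, 2L, 3L, 2L, 2L, 4L, 2L),
               type = "tandem", target_ks = 0.3, omega = 0.2),
    data.frame(size = c(2L, 2L, 3L, 2L, 2L, 2L, 3L, 2L, 2L, 2L),
               type = "intra",
               target_ks = rep(c(0.3, 2.0), 5), omega = 0.2),
    data.frame(size = c(2L, 3L, 4L, 5L, 6L, 2L, 3L, 4L, 2L, 2L),
               type = "inter", target_ks = 2.0, omega = 0.2),
    data.frame(size = c(3L, 4L, 3L, 4L),
               type = "mixed", target_ks = 1.0, omega = 0.2),
    data.frame(size = 6L, type = "wgd", target_ks = 2.0, omega = 0.2))
}

#' Simulate an annotated genome with planted duplication sets
#'
#' Lays background genes and planted sets on chromosomes honoring the
#' per-type spacing rules (tandem arrays with all pairwise gaps < 10 kb;
#' intra members on one chromosome separated by > 10 kb; inter and wgd
#' copies on distinct chromosomes), then realizes each set from a random
#' ancestor CDS whose copies are evolved to the set's target Ks with
#' [evolve_paralog()] (divergence applied to the copies, ancestor kept).
#'
#' @param config A [sim_config()].
#' @return List of class `synthetic_genome`: `catalog` (a `gene_catalog`)
#'   and `truth` (class `synthetic_truth`: `sets` data.frame with set_key,
#'   type, target_ks, size, members; `pairs` data.frame with gene_a, gene_b,
#'   target_ks (NA for copy-copy pairs of sets larger than 2), set_key;
#'   `membership` named vector gene -> set_key for planted genes).
#' @export
simulate_genome <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  ps <- config$planted_sets
  seed0 <- config$seed

  # expand wgd rows into size-2 cross-chromosome sets
  expanded <- list()
  for (i in seq_len(nrow(ps))) {
    if (ps$type[i] == "wgd") {
      for (j in seq_len(ps$size[i]))
        expanded[[length(expanded) + 1L]] <-
          data.frame(size = 2L, type = "wgd", target_ks = ps$target_ks[i],
                     omega = ps$omega[i])
    } else {
      expanded[[length(expanded) + 1L]] <- ps[i, ]
    }
  }
  ps <- if (length(expanded)) do.call(rbind, expanded) else ps[0, ]
  rownames(ps) <- NULL
  n_sets <- nrow(ps)

  gene_len <- function(k, seed) with_seed(seed, {
    lo <- config$gene_length_min
    hi <- 2L * config$gene_length_mean - config$gene_length_min
    sample(lo:hi, k, replace = TRUE)
  })

  # realize sequences per set
  sets <- vector("list", n_sets)
  for (i in seq_len(n_sets)) {
    k <- ps$size[i]
    L <- gene_len(1L, child_seed(seed0, paste0("len", i)))
    anc <- random_cds(L, child_seed(seed0, paste0("anc", i)))
    members <- sprintf("dup%03d_m%d", i, seq_len(k))
    seqs <- c(anc, vapply(seq_len(k - 1L), function(j) {
      as.character(evolve_paralog(anc, ps$target_ks[i], ps$omega[i],
                                  child_seed(seed0, paste0("ev", i, "_", j))))
    }, ""))
    names(seqs) <- members
    sets[[i]] <- list(key = sprintf("P%03d", i), type = ps$type[i],
                      target_ks = ps$target_ks[i], members = members,
                      cds = seqs)
  }

  bg_len <- gene_len(config$n_background_genes, child_seed(seed0, "bglen"))
  bg_ids <- sprintf("bg%04d", seq_len(config$n_background_genes))
  bg_cds <- vapply(seq_len(config$n_background_genes), function(i)
    random_cds(bg_len[i], child_seed(seed0, paste0("bg", i))), "")
  names(bg_cds) <- bg_ids

  # assign blocks to chromosomes; a block is a vector of gene ids laid out
  # consecutively (tandem arrays) with a minimum gap before each gene
  chroms <- sprintf("chr%02d", seq_len(config$n_chromosomes))
  blocks <- stats::setNames(vector("list", length(chroms)), chroms)
  add_block <- function(chr, genes, gaps_before) {
    blocks[[chr]][[length(blocks[[chr]]) + 1L]] <<-
      list(genes = genes, gaps = gaps_before)
  }
  rr <- function(i) chroms[(i - 1L) %% length(chroms) + 1L]
  for (i in seq_len(n_sets)) {
    st <- sets[[i]]
    k <- length(st$members)
    if (st$type %in% c("inter", "wgd") && k > length(chroms))
      stop("simulate_genome: inter set of size ", k, " needs at least ",
           k, " chromosomes")
    if (st$type == "mixed" && k - 2L > length(chroms) - 1L)
      stop("simulate_genome: mixed set of size ", k, " needs at least ",
           k - 1L, " chromosomes")
    switch(st$type,
      tandem = add_block(rr(i), st$members,
                         c(NA, rep(config$tandem_spacing, k - 1L))),
      intra = {
        for (m in st$members)
          add_block(rr(i), m, config$intra_spacing)
      },
      inter = ,
      wgd = {
        for (j in seq_len(k))
          add_block(rr(i + j - 1L), st$members[j], NA)
      },
      mixed = {
        add_block(rr(i), st$members[1:2],
                  c(NA, config$tandem_spacing))
        for (j in 3:k)
          add_block(rr(i + j - 2L), st$members[j], NA)
      },
      stop("simulate_genome: unknown planted set type ", st$type))
  }
  for (i in seq_along(bg_ids)) add_block(rr(i), bg_ids[i], NA)

  all_cds <- c(bg_cds, unlist(lapply(sets, function(s) s$cds)))
  lens_nt <- nchar(all_cds)

  # lay out each chromosome: shuffle block order, then walk left to right
  rows <- list()
  chrom_len <- stats::setNames(numeric(length(chroms)), chroms)
  for (chr in chroms) {
    bl <- blocks[[chr]]
    if (length(bl) == 0L) { chrom_len[chr] <- 20000; next }
    ord <- with_seed(child_seed(seed0, paste0("ord", chr)),
                     sample.int(length(bl)))
    bl <- bl[ord]
    gaps_rand <- with_seed(child_seed(seed0, paste0("gap", chr)),
      pmax(200, round(stats::rexp(sum(vapply(bl, function(b)
        length(b$genes), 0L)), 1 / config$intergenic_gap_mean))))
    gi <- 0L
    cursor <- 0L
    for (b in bl) {
      for (j in seq_along(b$genes)) {
        gi <- gi + 1L
        gap <- b$gaps[j]
        gap <- if (is.na(gap)) gaps_rand[gi] else gap
        start <- cursor + gap + 1L
        gid <- b$genes[j]
        end <- start + lens_nt[[gid]] - 1L
        rows[[length(rows) + 1L]] <- data.frame(
          gene_id = gid, chromosome = chr, start = start, end = end,
          strand = if (gi %% 2L == 0L) "-" else "+",
          stringsAsFactors = FALSE)
        cursor <- end
      }
    }
    chrom_len[chr] <- cursor + 10000
  }
  genes <- do.call(rbind, rows)
  prots <- vapply(all_cds, translate_cds, "")
  catalog <- gene_catalog(genes, all_cds, prots, chrom_len)

  expected_labels <- c(tandem = "tandem", intra = "intra", inter = "inter",
                       wgd = "inter", mixed = "inter;tandem")
  truth_sets <- do.call(rbind, lapply(sets, function(s)
    data.frame(set_key = s$key, type = s$type, target_ks = s$target_ks,
               size = length(s$members),
               members = paste(s$members, collapse = ","),
               expected_labels = expected_labels[[s$type]],
               stringsAsFactors = FALSE)))
  truth_pairs <- do.call(rbind, lapply(sets, function(s) {
    m <- s$members
    out <- list()
    for (i in seq_len(length(m) - 1L)) for (j in (i + 1L):length(m)) {
      out[[length(out) + 1L]] <- data.frame(
        gene_a = m[i], gene_b = m[j],
        target_ks = if (i == 1L) s$target_ks else NA_real_,
        set_key = s$key, stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
  }))
  membership <- unlist(lapply(sets, function(s)
    stats::setNames(rep(s$key, length(s$members)), s$members)))

  # invariant: every planted tandem pair's realized gap < 10 kb
  check_tandem_gaps(catalog, sets)

  truth <- structure(list(sets = truth_sets, pairs = truth_pairs,
                          membership = membership,
                          background = bg_ids),
                     class = "synthetic_truth")
  structure(list(catalog = catalog, truth = truth),
            class = "synthetic_genome")
}

check_tandem_gaps <- function(catalog, sets) {
  g <- catalog$genes
  for (s in sets) {
    if (!(s$type %in% c("tandem"))) next
    m <- s$members
    for (i in seq_len(length(m) - 1L)) for (j in (i + 1L):length(m)) {
      ga <- g[g$gene_id == m[i], ]; gb <- g[g$gene_id == m[j], ]
      d <- gene_distance(ga, gb)
      if (is.na(d) || d >= 10000)
        stop("simulate_genome: planted tandem pair ", m[i], "/", m[j],
             " realized gap ", d, " violates the 10 kb rule")
    }
  }
}

#' Synthetic GO DAG and annotations with planted enrichment
#'
#' Builds a small random is_a DAG and a two-column gene-to-term annotation
#' table in which each enriched term annotates the study genes at
#' `study_freq` and the remaining population genes at `pop_freq`; all other
#' terms annotate genes at a common background rate. The study set defaults
#' to the members of low-Ks planted sets (target Ks <= 1), the population to
#' all planted duplicate genes.
#'
#' @param truth A `synthetic_truth`, or a list with elements `study_genes`
#'   and `pop_genes`.
#' @param dag_size Number of non-root terms.
#' @param enriched_terms data.frame with columns study_freq, pop_freq (one
#'   row per planted enriched term); may be empty for a null configuration.
#' @param seed RNG seed.
#' @return List: `annotations` (data.frame gene_id, term_id), `obo_lines`
#'   (character, OBO 1.2), `dag` (parsed `go_dag`), `study_genes`,
#'   `pop_genes`, `enriched` (planted term ids).
#' @export
make_go_annotations <- function(truth, dag_size = 50L,
                                enriched_terms =
                                  data.frame(study_freq = 0.8,
                                             pop_freq = 0.1),
                                seed = 1L) {
  if (inherits(truth, "synthetic_truth")) {
    low <- truth$sets$set_key[truth$sets$target_ks <= 1.0]
    study_genes <- names(truth$membership)[truth$membership %in% low]
    pop_genes <- names(truth$membership)
  } else {
    study_genes <- truth$study_genes
    pop_genes <- truth$pop_genes
  }
  stopifnot(all(study_genes %in% pop_genes))
  n_enriched <- if (is.null(enriched_terms)) 0L else nrow(enriched_terms)
  stopifnot(dag_size >= n_enriched + 1L)
  term_ids <- sprintf("GO:SYN%04d", seq_len(dag_size))
  root <- "GO:SYN0000"
  n_plain <- dag_size - n_enriched
  with_seed(seed, {
    parents <- lapply(seq_len(dag_size), function(i) {
      pool <- c(root, term_ids[seq_len(min(i - 1L, n_plain))])
      if (length(pool) == 1L) root else sample(pool, 1L)
    })
    obo <- c("format-version: 1.2", "")
    add_term <- function(id, name, isa) {
      c("[Term]", paste0("id: ", id), paste0("name: ", name),
        "namespace: biological_process",
        paste0("is_a: ", isa, " ! parent"), "")
    }
    obo <- c(obo, "[Term]", paste0("id: ", root), "name: synthetic root",
             "namespace: biological_process", "")
    for (i in seq_len(dag_size))
      obo <- c(obo, add_term(term_ids[i], paste0("synthetic term ", i),
                             parents[[i]]))
    # enriched terms are the last-generated terms: parents are only ever
    # sampled among earlier terms, so these are guaranteed DAG leaves and
    # background annotations to other terms never propagate into them
    enriched <- if (n_enriched > 0L)
      term_ids[seq(dag_size - n_enriched + 1L, dag_size)] else character(0)
    other_terms <- setdiff(term_ids, enriched)
    ann <- list()
    annotate <- function(genes, term) {
      if (length(genes))
        ann[[length(ann) + 1L]] <<- data.frame(gene_id = genes,
                                               term_id = term,
                                               stringsAsFactors = FALSE)
    }
    for (e in seq_len(n_enriched)) {
      sf <- enriched_terms$study_freq[e]
      pf <- enriched_terms$pop_freq[e]
      rest <- setdiff(pop_genes, study_genes)
      annotate(study_genes[stats::runif(length(study_genes)) < sf],
               enriched[e])
      annotate(rest[stats::runif(length(rest)) < pf], enriched[e])
    }
    # background annotations: every gene gets 1-3 random non-enriched terms
    for (g in pop_genes) {
      k <- sample(1:3, 1L)
      for (t in sample(other_terms, k)) annotate(g, t)
    }
    annotations <- do.call(rbind, ann)
    annotations <- annotations[order(annotations$gene_id,
                                     annotations$term_id), ]
    rownames(annotations) <- NULL
    tmp <- tempfile(fileext = ".obo")
    writeLines(obo, tmp)
    dag <- parse_obo(tmp)
    unlink(tmp)
    list(annotations = annotations, obo_lines = obo, dag = dag,
         study_genes = study_genes, pop_genes = pop_genes,
         enriched = enriched)
  })
}

#' Write a synthetic genome to disk
#'
#' Emits the GFF3 + CDS/protein FASTA via [write_catalog()], the truth as
#' JSON, and (optionally) annotations TSV + OBO.
#' @param sim A `synthetic_genome`.
#' @param dir Output directory.
#' @param go Optional result of [make_go_annotations()].
#' @export
write_synthetic_genome <- function(sim, dir, go = NULL) {
  paths <- write_catalog(sim$catalog, dir, prefix = "synthetic")
  truth_path <- file.path(dir, "truth.json")
  jsonlite::write_json(list(sets = sim$truth$sets, pairs = sim$truth$pairs,
                            membership = as.list(sim$truth$membership)),
                       truth_path, auto_unbox = TRUE, digits = NA)
  out <- c(paths, truth = truth_path)
  if (!is.null(go)) {
    ann_path <- file.path(dir, "annotations.tsv")
    write_tsv(go$annotations, ann_path)
    obo_path <- file.path(dir, "synthetic.obo")
    writeLines(go$obo_lines, obo_path)
    out <- c(out, annotations = ann_path, obo = obo_path)
  }
  invisible(out)
}
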