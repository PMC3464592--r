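# End-to-end orchestration: catalog -> similarity -> MCL -> classification
# -> Ks -> profiles -> enrichment, with a YAML-serializable configuration,
# a run manifest, and (for synthetic genomes) a truth-comparison report.

#' Pipeline configuration
#'
#' Either `input` (paths to GFF3 + CDS FASTA + protein FASTA, and optionally
#' obo/annotations) or `synthetic` (a [sim_config()]) must be provided.
#'
#' @param input Named list: gff, cds_fasta, protein_fasta, and optionally
#'   obo, annotations (paths).
#' @param synthetic A [sim_config()]; used when `input` is NULL.
#' @param similarity,mcl,classify,ks,enrichment Stage parameter lists;
#'   missing entries take the documented defaults.
#' @param out_dir Output directory (NULL: nothing written to disk).
#' @param seed Global seed, fanned out deterministically to the stages.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(input = NULL, synthetic = sim_config(),
                            similarity = list(), mcl = list(),
                            classify = list(), ks = list(),
                            enrichment = list(), out_dir = NULL, seed = 1L) {
  defaults <- list(
    similarity = list(evalue_cutoff = 1e-5, mask = TRUE,
                      gap_open = 11, gap_extend = 1),
    mcl = list(inflation = 2, mul = 0.4343, ceil = 200,
               prune_threshold = 1e-5, max_iter = 100L, tol = 1e-6),
    classify = list(tandem_threshold = 10000, require_adjacent = FALSE),
    ks = list(min_codons = 30L, gap_open = 10, gap_extend = 0.5),
    enrichment = list(study_ks_threshold = 1.0, alternative = "two.sided"))
  merge1 <- function(user, def) utils::modifyList(def, user)
  cfg <- list(input = input, synthetic = synthetic,
              similarity = merge1(similarity, defaults$similarity),
              mcl = merge1(mcl, defaults$mcl),
              classify = merge1(classify, defaults$classify),
              ks = merge1(ks, defaults$ks),
              enrichment = merge1(enrichment, defaults$enrichment),
              out_dir = out_dir, seed = as.integer(seed))
  stopifnot(cfg$similarity$evalue_cutoff > 0, cfg$mcl$inflation > 1,
            cfg$classify$tandem_threshold > 0, cfg$ks$min_codons >= 1)
  structure(cfg, class = "pipeline_config")
}

#' Read / write a pipeline configuration as YAML
#'
#' The round-trip `read_pipeline_config(write_pipeline_config(cfg))`
#' reproduces the configuration exactly.
#' @param config A `pipeline_config`.
#' @param path YAML file path.
#' @export
write_pipeline_config <- function(config, path) {
  x <- unclass(config)
  if (!is.null(x$synthetic)) {
    s <- unclass(x$synthetic)
    s$planted_sets <- lapply(seq_len(nrow(s$planted_sets)), function(i)
      as.list(s$planted_sets[i, ]))
    x$synthetic <- s
  }
  yaml::write_yaml(x, path, precision = 15)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- yaml::read_yaml(path)
  syn <- NULL
  if (!is.null(x$synthetic)) {
    s <- x$synthetic
    ps <- do.call(rbind, lapply(s$planted_sets, as.data.frame))
    ps$size <- as.integer(ps$size)
    syn <- sim_config(n_chromosomes = s$n_chromosomes,
                      n_background_genes = s$n_background_genes,
                      gene_length_mean = s$gene_length_mean,
                      gene_length_min = s$gene_length_min,
                      intergenic_gap_mean = s$intergenic_gap_mean,
                      planted_sets = ps,
                      tandem_spacing = s$tandem_spacing,
                      intra_spacing = s$intra_spacing,
                      seed = s$seed)
  }
  pipeline_config(input = x$input, synthetic = syn,
                  similarity = x$similarity, mcl = x$mcl,
                  classify = x$classify, ks = x$ks,
                  enrichment = x$enrichment,
                  out_dir = x$out_dir, seed = x$seed)
}

# Small deterministic string hash for the run manifest (polynomial rolling
# hash mod a Mersenne prime; exact in double arithmetic).
config_hash <- function(s) {
  h <- 5381
  for (b in utf8ToInt(s)) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Run the full duplication-profiling pipeline
#'
#' Executes catalog loading (or synthetic genome generation), similarity
#' search, Markov clustering, duplication-type classification, pairwise Ks
#' estimation, profiling, and (when annotations are available) GO
#' enrichment of the genes in recent (low-Ks) pairs against all duplicated
#' genes. With an `out_dir` every stage table is written as TSV plus a JSON
#' manifest with the config hash, seed and per-stage record counts.
#' Rerunning with an identical configuration reproduces all outputs.
#'
#' @param config A [pipeline_config()].
#' @return List of class `pipeline_result`: catalog, edges, sets (classified),
#'   ks_table, summary, profiles (size_distribution, ks_histogram,
#'   fraction_ks_below, mean_ks_by_size, mean_ks_by_size_and_type,
#'   mean_ks_by_type), enrichment (NULL if skipped), truth_report (NULL for
#'   file input), manifest.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  truth <- NULL
  go <- NULL
  if (!is.null(config$input)) {
    catalog <- load_catalog(config$input$gff, config$input$cds_fasta,
                            config$input$protein_fasta)
  } else {
    syn <- config$synthetic
    syn$seed <- child_seed(config$seed, "synthetic")
    sim <- simulate_genome(syn)
    catalog <- sim$catalog
    truth <- sim$truth
    go <- make_go_annotations(truth,
                              seed = child_seed(config$seed, "go"))
  }
  catalog <- filter_catalog(catalog)

  sp <- config$similarity
  edges <- build_pair_list(catalog, evalue_cutoff = sp$evalue_cutoff,
                           mask = sp$mask, gap_open = sp$gap_open,
                           gap_extend = sp$gap_extend,
                           mul = config$mcl$mul,
                           ceiling_weight = config$mcl$ceil)

  mp <- config$mcl
  part <- mcl(edges, inflation = mp$inflation,
              prune_threshold = mp$prune_threshold,
              max_iter = mp$max_iter, tol = mp$tol)
  sets <- clusters_to_sets(part)
  sets <- classify_sets(sets, catalog,
                        tandem_threshold = config$classify$tandem_threshold,
                        require_adjacent = config$classify$require_adjacent)

  kp <- config$ks
  ks_table <- if (length(sets))
    sets_pairwise_ks(sets, catalog, min_codons = kp$min_codons,
                     gap_open = kp$gap_open, gap_extend = kp$gap_extend)
  else NULL

  summary <- summarize_duplications(sets, catalog)
  profiles <- list(
    size_distribution = set_size_distribution(sets),
    ks_histogram = if (!is.null(ks_table)) ks_histogram(ks_table) else NULL,
    fraction_ks_below = if (!is.null(ks_table))
      fraction_ks_below(ks_table,
                        config$enrichment$study_ks_threshold) else NA_real_,
    mean_ks_by_size = if (!is.null(ks_table))
      mean_ks_by_size(ks_table) else NULL,
    mean_ks_by_size_and_type = if (!is.null(ks_table))
      mean_ks_by_size_and_type(ks_table) else NULL,
    mean_ks_by_type = if (!is.null(ks_table))
      mean_ks_by_type(ks_table) else NULL)

  enr <- NULL
  enrichment_skipped <- TRUE
  ann <- NULL; dag <- NULL
  if (!is.null(go)) {
    ann <- go$annotations; dag <- go$dag
  } else if (!is.null(config$input$annotations) &&
             !is.null(config$input$obo)) {
    ann <- read_annotations(config$input$annotations)
    dag <- parse_obo(config$input$obo)
  }
  if (!is.null(ann) && !is.null(ks_table) && nrow(ks_table) > 0) {
    thr <- config$enrichment$study_ks_threshold
    low <- ks_table[ks_table$status == "ok" & !is.na(ks_table$ks) &
                      ks_table$ks <= thr, , drop = FALSE]
    study_genes <- sort(unique(c(low$gene_a, low$gene_b)))
    pop_genes <- sort(unique(unlist(lapply(sets, function(s) s$members))))
    if (length(study_genes) > 0) {
      enr <- enrich(study_genes, pop_genes, ann, dag,
                    alternative = config$enrichment$alternative)
      enrichment_skipped <- FALSE
    }
  }

  truth_report <- if (!is.null(truth))
    compare_to_truth(sets, ks_table, truth, go) else NULL

  manifest <- list(
    config_hash = config_hash(jsonlite::toJSON(unclass(config), force = TRUE,
                                         auto_unbox = TRUE, digits = NA)),
    seed = config$seed,
    package_version = as.character(utils::packageVersion("dupscan")),
    enrichment_skipped = enrichment_skipped,
    records = list(
      genes = n_genes(catalog),
      edges = nrow(edges),
      sets = length(sets),
      ks_pairs = if (is.null(ks_table)) 0L else nrow(ks_table),
      enrichment_terms = if (is.null(enr)) 0L else nrow(enr)),
    elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")))

  result <- structure(list(catalog = catalog, edges = edges, sets = sets,
                           ks_table = ks_table, summary = summary,
                           profiles = profiles, enrichment = enr,
                           truth = truth, truth_report = truth_report,
                           manifest = manifest),
                      class = "pipeline_result")
  if (!is.null(config$out_dir)) write_pipeline_result(result, config$out_dir)
  result
}

#' Compare recovered sets against planted truth
#'
#' @param sets Classified recovered sets.
#' @param ks_table Pairwise Ks table.
#' @param truth A `synthetic_truth`.
#' @param go Optional [make_go_annotations()] output (for enriched-term
#'   recovery).
#' @return List: `membership_ari` (adjusted Rand index over planted genes),
#'   `label_agreement` (fraction of truth sets recovered with exactly the
#'   expected label set), `background_in_sets` (fraction of background genes
#'   clustered), `ks_errors` (data.frame for pairs with a planted target:
#'   target_ks, ks, error), `n_truth_sets`, `n_recovered_sets`.
#' @export
compare_to_truth <- function(sets, ks_table, truth, go = NULL) {
  planted <- names(truth$membership)
  recovered <- stats::setNames(rep("unclustered", length(planted)), planted)
  for (s in sets) {
    hit <- intersect(s$members, planted)
    recovered[hit] <- s$set_id
  }
  ari <- adjusted_rand_index(unname(truth$membership), unname(recovered))

  # label agreement: a truth set counts as agreeing when it is recovered as
  # one set whose label set equals the expected labels
  set_by_members <- stats::setNames(
    lapply(sets, function(s) s),
    vapply(sets, function(s) paste(sort(s$members), collapse = ","), ""))
  agree <- vapply(seq_len(nrow(truth$sets)), function(i) {
    key <- paste(sort(strsplit(truth$sets$members[i], ",")[[1]]),
                 collapse = ",")
    s <- set_by_members[[key]]
    if (is.null(s)) return(FALSE)
    identical(paste(s$set_labels, collapse = ";"),
              truth$sets$expected_labels[i])
  }, TRUE)

  bg_clustered <- if (length(truth$background)) {
    clustered <- unique(unlist(lapply(sets, function(s) s$members)))
    mean(truth$background %in% clustered)
  } else NA_real_

  ks_errors <- NULL
  if (!is.null(ks_table)) {
    tp <- truth$pairs[!is.na(truth$pairs$target_ks), , drop = FALSE]
    key <- pair_key(ks_table$gene_a, ks_table$gene_b)
    idx <- match(pair_key(tp$gene_a, tp$gene_b), key)
    ks_errors <- data.frame(gene_a = tp$gene_a, gene_b = tp$gene_b,
                            target_ks = tp$target_ks,
                            ks = ks_table$ks[idx],
                            status = ks_table$status[idx],
                            stringsAsFactors = FALSE)
    ks_errors$error <- ks_errors$ks - ks_errors$target_ks
  }
  out <- list(membership_ari = ari,
              label_agreement = mean(agree),
              background_in_sets = bg_clustered,
              ks_errors = ks_errors,
              n_truth_sets = nrow(truth$sets),
              n_recovered_sets = length(sets))
  if (!is.null(go)) out$planted_enriched_terms <- go$enriched
  out
}

#' Write all pipeline result tables to a directory
#' @param result A `pipeline_result`.
#' @param dir Output directory.
#' @export
write_pipeline_result <- function(result, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_pair_list(result$edges, file.path(dir, "pairs.blast6.tsv"))
  write_sets(result$sets, file.path(dir, "sets.tsv"))
  write_tsv(set_type_table(result$sets), file.path(dir, "set_types.tsv"))
  if (length(result$sets))
    write_tsv(pair_type_table(result$sets), file.path(dir, "pair_types.tsv"))
  if (!is.null(result$ks_table))
    write_ks_table(result$ks_table, file.path(dir, "ks_pairs.tsv"))
  s <- result$summary
  write_tsv(data.frame(metric = names(unclass(s)),
                       value = unlist(unclass(s))),
            file.path(dir, "summary.tsv"))
  p <- result$profiles
  write_tsv(p$size_distribution, file.path(dir, "size_distribution.tsv"))
  if (!is.null(p$ks_histogram)) {
    h <- p$ks_histogram
    write_tsv(data.frame(bin_start = utils::head(h$bin_edges, -1),
                         bin_end = h$bin_edges[-1],
                         count = h$counts, fraction = h$fractions),
              file.path(dir, "ks_histogram.tsv"))
  }
  if (!is.null(p$mean_ks_by_size))
    write_tsv(p$mean_ks_by_size, file.path(dir, "mean_ks_by_size.tsv"))
  if (!is.null(p$mean_ks_by_size_and_type))
    write_tsv(p$mean_ks_by_size_and_type,
              file.path(dir, "mean_ks_by_size_and_type.tsv"))
  if (!is.null(result$enrichment))
    write_enrichment(result$enrichment, file.path(dir, "enrichment.tsv"))
  if (!is.null(result$truth_report)) {
    tr <- result$truth_report
    write_tsv(data.frame(metric = c("membership_ari", "label_agreement",
                                    "background_in_sets", "n_truth_sets",
                                    "n_recovered_sets"),
                         value = c(tr$membership_ari, tr$label_agreement,
                                   tr$background_in_sets, tr$n_truth_sets,
                                   tr$n_recovered_sets)),
              file.path(dir, "truth_report.tsv"))
    if (!is.null(tr$ks_errors))
      write_tsv(tr$ks_errors, file.path(dir, "ks_errors.tsv"))
  }
  jsonlite::write_json(result$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("dupscan pipeline result\n")
  print(x$summary)
  if (!is.null(x$profiles$fraction_ks_below))
    cat(sprintf("Fraction of ok pairs with Ks <= threshold: %.3f\n",
                x$profiles$fraction_ks_below))
  if (!is.null(x$truth_report))
    cat(sprintf("Truth: ARI %.3f, label agreement %.1f%%\n",
                x$truth_report$membership_ari,
                100 * x$truth_report$label_agreement))
  invisible(x)
}
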