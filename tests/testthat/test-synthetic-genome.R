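# The planted-duplication genome generator.

test_that("random coding sequences are valid and reproducible", {
  cds <- random_cds(100, 17)
  expect_equal(nchar(cds), 300L)
  expect_equal(substr(cds, 1, 3), "ATG")
  aa <- dupscan:::translate_cds(cds)
  expect_false(grepl("\\*", aa))
  expect_identical(random_cds(100, 17), cds)
  expect_false(identical(random_cds(100, 18), cds))
})

test_that("paralog evolution hits its divergence target", {
  cds <- random_cds(200, 19)
  # target zero: unchanged
  expect_equal(as.character(evolve_paralog(cds, 0, 0.2, 1)), cds)
  # determinism
  e1 <- evolve_paralog(cds, 0.4, 0.2, 5)
  e2 <- evolve_paralog(cds, 0.4, 0.2, 5)
  expect_identical(as.character(e1), as.character(e2))
  # realized divergence equals the stopping statistic, just above target
  expect_gte(attr(e1, "realized_ks"), 0.4)
  expect_lt(attr(e1, "realized_ks"), 0.46)
  # the mutant still translates cleanly (no stops ever accepted)
  expect_false(grepl("\\*", dupscan:::translate_cds(as.character(e1))))

  # omega 0: no nonsynonymous change is ever accepted -> ka = 0
  e0 <- evolve_paralog(cds, 0.3, 0, 3)
  expect_equal(dupscan:::translate_cds(as.character(e0)),
               dupscan:::translate_cds(cds))

  # targets at or beyond the length-dependent saturation bound are refused
  expect_error(evolve_paralog(cds, 10, 0.2, 1), "saturation bound")
})

test_that("simulated genomes honor spacing rules and carry a usable truth", {
  cfg <- small_sim_config(seed = 3)
  sim <- simulate_genome(cfg)
  cat1 <- sim$catalog
  truth <- sim$truth
  expect_s3_class(cat1, "gene_catalog")
  n_planted <- sum(truth$sets$size)
  expect_equal(n_genes(cat1), cfg$n_background_genes + n_planted)
  expect_equal(sort(names(truth$membership)),
               sort(setdiff(cat1$genes$gene_id, truth$background)))

  g <- cat1$genes
  # no overlapping genes anywhere (filter_catalog is a no-op)
  filt <- filter_catalog(cat1)
  expect_equal(n_genes(filt), n_genes(cat1))

  # planted tandem pairs: all pairwise gaps < 10 kb
  for (i in which(truth$sets$type == "tandem")) {
    m <- strsplit(truth$sets$members[i], ",")[[1]]
    for (a in seq_len(length(m) - 1)) for (b in (a + 1):length(m)) {
      d <- gene_distance(g[g$gene_id == m[a], ], g[g$gene_id == m[b], ])
      expect_lt(d, 10000)
    }
  }
  # intra members share a chromosome at > 10 kb
  for (i in which(truth$sets$type == "intra")) {
    m <- strsplit(truth$sets$members[i], ",")[[1]]
    chr <- g$chromosome[match(m, g$gene_id)]
    expect_equal(length(unique(chr)), 1L)
    d <- gene_distance(g[g$gene_id == m[1], ], g[g$gene_id == m[2], ])
    expect_gt(d, 10000)
  }
  # inter members sit on distinct chromosomes
  for (i in which(truth$sets$type == "inter")) {
    m <- strsplit(truth$sets$members[i], ",")[[1]]
    chr <- g$chromosome[match(m, g$gene_id)]
    expect_equal(length(unique(chr)), length(m))
  }

  # reproducibility: identical seed, identical genome
  sim2 <- simulate_genome(small_sim_config(seed = 3))
  expect_identical(sim2$catalog$cds, cat1$cds)
  expect_identical(sim2$catalog$genes, g)

  # a genome with no planted sets yields no duplication sets
  cfg0 <- sim_config(n_chromosomes = 2, n_background_genes = 20,
                     gene_length_mean = 100, gene_length_min = 80,
                     planted_sets = data.frame(size = integer(0),
                                               type = character(0),
                                               target_ks = numeric(0),
                                               omega = numeric(0)),
                     seed = 5)
  sim0 <- simulate_genome(cfg0)
  edges0 <- build_pair_list(sim0$catalog)
  expect_equal(length(clusters_to_sets(mcl(edges0))), 0L)
})

test_that("synthetic genomes round-trip through GFF3 + FASTA", {
  sim <- simulate_genome(small_sim_config(seed = 4))
  dir <- withr::local_tempdir()
  paths <- write_synthetic_genome(sim, dir)
  cat2 <- load_catalog(paths["gff"], paths["cds"], paths["protein"])
  expect_equal(cat2$genes, sim$catalog$genes)
  expect_equal(cat2$cds, sim$catalog$cds)
  expect_equal(cat2$protein, sim$catalog$protein)
})

test_that("planted GO enrichment is recovered; null stays null", {
  pop <- sprintf("g%03d", 1:300)
  lists <- list(study_genes = pop[1:40], pop_genes = pop)
  go <- make_go_annotations(lists, dag_size = 30,
                            enriched_terms = data.frame(study_freq = 0.9,
                                                        pop_freq = 0.05),
                            seed = 11)
  expect_true(all(go$study_genes %in% go$pop_genes))
  res <- enrich(go$study_genes, go$pop_genes, go$annotations, go$dag)
  hit <- res[res$term_id == go$enriched, ]
  expect_lt(hit$p_fdr_bh, 0.05)
  expect_equal(hit$direction, "over")

  # null configuration: planted term list empty, nothing should stand out
  go0 <- make_go_annotations(lists, dag_size = 30,
                             enriched_terms = NULL, seed = 12)
  expect_equal(go0$enriched, character(0))

  # with a synthetic_truth, the study set is the low-Ks planted cohort
  sim <- simulate_genome(small_sim_config(seed = 6))
  got <- make_go_annotations(sim$truth, dag_size = 20,
                             enriched_terms = NULL, seed = 13)
  low <- sim$truth$sets$set_key[sim$truth$sets$target_ks <= 1.0]
  expect_setequal(got$study_genes,
                  names(sim$truth$membership)[sim$truth$membership %in% low])
})
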