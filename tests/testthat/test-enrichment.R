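# OBO parsing, annotation propagation, Fisher's exact test, corrections.

tiny_obo <- function(lines) {
  path <- tempfile(fileext = ".obo")
  writeLines(c("format-version: 1.2", "", lines), path)
  path
}

chain_obo <- function() {
  tiny_obo(c(
    "[Term]", "id: GO:0000001", "name: a", "namespace: biological_process",
    "",
    "[Term]", "id: GO:0000002", "name: b", "namespace: biological_process",
    "is_a: GO:0000001 ! a", "",
    "[Term]", "id: GO:0000003", "name: c", "namespace: biological_process",
    "is_a: GO:0000002 ! b", "alt_id: GO:0000099", "",
    "[Term]", "id: GO:0000004", "name: dead",
    "namespace: biological_process", "is_obsolete: true", ""))
}

test_that("OBO stanzas parse into an ancestor-closed DAG", {
  dag <- parse_obo(chain_obo())
  expect_equal(sort(dag$terms$term_id),
               c("GO:0000001", "GO:0000002", "GO:0000003"))
  expect_equal(sort(go_ancestors(dag, "GO:0000003")),
               c("GO:0000001", "GO:0000002"))
  # alt_id aliases resolve to the primary id
  expect_equal(sort(go_ancestors(dag, "GO:0000099")),
               c("GO:0000001", "GO:0000002"))
  # obsolete terms are dropped
  expect_false("GO:0000004" %in% dag$terms$term_id)

  # a term with two parents has both in its closure (DAG diamond)
  diamond <- tiny_obo(c(
    "[Term]", "id: GO:1", "name: root", "",
    "[Term]", "id: GO:2", "name: l", "is_a: GO:1", "",
    "[Term]", "id: GO:3", "name: r", "is_a: GO:1", "",
    "[Term]", "id: GO:4", "name: leaf", "is_a: GO:2", "is_a: GO:3", ""))
  ddag <- parse_obo(diamond)
  expect_equal(sort(go_ancestors(ddag, "GO:4")), c("GO:1", "GO:2", "GO:3"))

  cyc <- tiny_obo(c(
    "[Term]", "id: GO:1", "name: a", "is_a: GO:2", "",
    "[Term]", "id: GO:2", "name: b", "is_a: GO:1", ""))
  expect_error(parse_obo(cyc), "cycle")
})

test_that("annotations propagate to ancestors with set semantics", {
  dag <- parse_obo(chain_obo())
  ann <- data.frame(gene_id = c("g1", "g2"),
                    term_id = c("GO:0000003", "GO:0000001"))
  closed <- propagate_annotations(ann, dag)
  expect_equal(closed$g1, c("GO:0000001", "GO:0000002", "GO:0000003"))
  expect_equal(closed$g2, "GO:0000001")
  # annotation to an obsolete term is dropped with a warning
  expect_warning(
    c2 <- propagate_annotations(
      data.frame(gene_id = "g1", term_id = "GO:0000004"), dag),
    "obsolete")
  expect_equal(c2$g1, character(0))
  expect_equal(propagate_annotations(list(), dag), stats::setNames(list(),
                                                                   NULL))
})

test_that("fisher_exact matches enumeration and stats::fisher.test", {
  # worked example: 3/3 in the study vs 5/10 in the population
  f <- fisher_exact(3, 3, 5, 10, alternative = "greater")
  expect_equal(f$p, choose(5, 3) / choose(10, 3), tolerance = 1e-12)
  expect_equal(f$direction, "over")

  # two-sided agrees with the enumeration oracle on a grid of tables
  for (pop_n in c(8, 13, 27)) {
    for (pop_count in c(2, pop_n %/% 2)) {
      for (study_n in c(3, pop_n %/% 3)) {
        lo <- max(0, study_n - (pop_n - pop_count))
        for (sc in lo:min(study_n, pop_count)) {
          expect_equal(
            fisher_exact(sc, study_n, pop_count, pop_n)$p,
            oracle_fisher_two_sided(sc, study_n, pop_count, pop_n),
            tolerance = 1e-12,
            info = sprintf("%d/%d vs %d/%d", sc, study_n, pop_count, pop_n))
        }
      }
    }
  }

  # and with R's own implementation on a 2x2 layout
  p_mine <- fisher_exact(7, 10, 12, 40)$p
  tab <- matrix(c(7, 3, 5, 25), 2)   # study in/out vs rest in/out
  expect_equal(p_mine, stats::fisher.test(tab)$p.value, tolerance = 1e-9)

  # equal frequencies give p = 1; degenerate zero counts too
  expect_equal(fisher_exact(5, 10, 10, 20)$p, 1)
  f0 <- fisher_exact(0, 3, 0, 10)
  expect_equal(f0$p, 1)
  expect_equal(f0$direction, "under")
  expect_error(fisher_exact(5, 3, 5, 10), "inconsistent")
})

test_that("enrichment ranks a planted term first and corrects p-values", {
  dag <- parse_obo(chain_obo())
  pop <- sprintf("g%03d", 1:120)
  study <- pop[1:30]
  # planted: GO:0000003 on most study genes, few others
  ann <- rbind(
    data.frame(gene_id = study[1:24], term_id = "GO:0000003"),
    data.frame(gene_id = pop[31:39], term_id = "GO:0000003"),
    data.frame(gene_id = pop[seq(1, 120, 3)], term_id = "GO:0000002"))
  res <- enrich(study, pop, ann, dag)
  expect_equal(res$term_id[1], "GO:0000003")
  expect_equal(res$direction[1], "over")
  expect_lt(res$p_fdr_bh[1], 0.05)
  # corrected p-values never fall below the raw p
  expect_true(all(res$p_bonferroni >= res$p - 1e-12))
  expect_true(all(res$p_sidak >= res$p - 1e-12))
  # BH is monotone after the step-up adjustment
  expect_true(all(diff(res$p_fdr_bh[order(res$p)]) >= -1e-12))
  # propagation never decreases a population count: ancestors cover at
  # least as many genes as the planted leaf
  anc_row <- res[res$term_id == "GO:0000001", ]
  leaf_row <- res[res$term_id == "GO:0000003", ]
  expect_gte(anc_row$pop_count, leaf_row$pop_count)

  # study == population: every p is 1
  res_same <- enrich(pop, pop, ann, dag)
  expect_true(all(res_same$p == 1))

  # a single tested term has all corrections equal to the raw p
  ann1 <- data.frame(gene_id = pop[1:10], term_id = "GO:0000001")
  res1 <- enrich(study, pop, ann1, dag)
  expect_equal(nrow(res1), 1L)
  expect_equal(res1$p_bonferroni, res1$p)
  expect_equal(res1$p_sidak, 1 - (1 - res1$p)^1)
})
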