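# Tandem / intra / inter classification and the set-level label union.

test_that("gene distance is the intergenic gap, floored at zero", {
  a <- gene_row("a", "chr1", 1000, 2000)
  b <- gene_row("b", "chr1", 5000, 6000)
  expect_equal(gene_distance(a, b), 2999)
  expect_equal(gene_distance(b, a), 2999)
  ov <- gene_row("c", "chr1", 1500, 2500)
  expect_equal(gene_distance(a, ov), 0)
  abut <- gene_row("d", "chr1", 2001, 2500)
  expect_equal(gene_distance(a, abut), 0)
  other <- gene_row("e", "chr2", 1000, 2000)
  expect_true(is.na(gene_distance(a, other)))
})

test_that("pair labels follow the 10 kb rule with a strict boundary", {
  g <- function(chr, s, e) gene_row("x", chr, s, e)
  near <- classify_pair(g("chr1", 1000, 2000), g("chr1", 5000, 6000))
  expect_equal(near$label, "tandem")
  far <- classify_pair(g("chr1", 1000, 2000), g("chr1", 52001, 53000))
  expect_equal(far$label, "intra")
  # boundary: distance exactly 10,000 is intra ("less than 10 kb" is strict)
  at <- classify_pair(g("chr1", 1000, 2000), g("chr1", 12001, 13000))
  expect_equal(at$distance, 10000)
  expect_equal(at$label, "intra")
  just_in <- classify_pair(g("chr1", 1000, 2000), g("chr1", 12000, 13000))
  expect_equal(just_in$distance, 9999)
  expect_equal(just_in$label, "tandem")
  x <- classify_pair(g("chr1", 1, 10), g("chr2", 1, 10))
  expect_equal(x$label, "inter")
  # invariance under argument swap and strand flips
  a <- gene_row("a", "chr1", 1000, 2000, "+")
  b <- gene_row("b", "chr1", 5000, 6000, "-")
  expect_equal(classify_pair(a, b)$label, classify_pair(b, a)$label)
  a$strand <- "-"
  expect_equal(classify_pair(a, b)$label, "tandem")
})

test_that("set labels are the union of pair labels; mixed flags multi-label sets", {
  genes <- rbind(gene_row("a", "chr1", 1000, 2000),
                 gene_row("b", "chr1", 4000, 5000),
                 gene_row("c", "chr2", 1000, 2000))
  cat1 <- make_catalog(genes)
  s3 <- structure(list(set_id = "DS0001", members = c("a", "b", "c"),
                       pair_labels = NULL, set_labels = NULL, mixed = NA),
                  class = "duplication_set")
  s3 <- classify_set(s3, cat1)
  expect_equal(s3$set_labels, c("inter", "tandem"))
  expect_true(s3$mixed)
  expect_equal(nrow(s3$pair_labels), 3L)

  s2 <- structure(list(set_id = "DS0002", members = c("a", "b"),
                       pair_labels = NULL, set_labels = NULL, mixed = NA),
                  class = "duplication_set")
  s2 <- classify_set(s2, cat1)
  expect_equal(s2$set_labels, "tandem")
  expect_false(s2$mixed)

  s_inter <- structure(list(set_id = "DS0003", members = c("a", "c"),
                            pair_labels = NULL, set_labels = NULL,
                            mixed = NA), class = "duplication_set")
  expect_equal(classify_set(s_inter, cat1)$set_labels, "inter")

  bad <- structure(list(set_id = "DS0004", members = c("a", "zz"),
                        pair_labels = NULL, set_labels = NULL, mixed = NA),
                   class = "duplication_set")
  expect_error(classify_set(bad, cat1), "zz")
})

test_that("adjacency mode downgrades tandem pairs with intervening genes", {
  genes <- rbind(gene_row("a", "chr1", 1000, 2000),
                 gene_row("mid", "chr1", 3000, 3500),
                 gene_row("b", "chr1", 4000, 5000))
  cat1 <- make_catalog(genes)
  s <- structure(list(set_id = "DS0001", members = c("a", "b"),
                      pair_labels = NULL, set_labels = NULL, mixed = NA),
                 class = "duplication_set")
  expect_equal(classify_set(s, cat1)$set_labels, "tandem")
  expect_equal(classify_set(s, cat1, require_adjacent = TRUE)$set_labels,
               "intra")
})

test_that("set counts satisfy the inclusion-exclusion identity", {
  # random sets over a random gene layout
  set.seed(41)
  genes <- do.call(rbind, lapply(1:30, function(i) {
    gene_row(sprintf("g%02d", i), sample(c("chr1", "chr2", "chr3"), 1),
             s <- sample.int(2e5, 1), s + 500)
  }))
  cat1 <- make_catalog(genes)
  ids <- genes$gene_id
  sets <- lapply(1:8, function(k) {
    structure(list(set_id = sprintf("DS%04d", k),
                   members = sort(sample(ids, sample(2:4, 1))),
                   pair_labels = NULL, set_labels = NULL, mixed = NA),
              class = "duplication_set")
  })
  sets <- classify_sets(sets, cat1)
  has <- function(lab) vapply(sets, function(s) lab %in% s$set_labels, TRUE)
  t_ <- has("tandem"); i_ <- has("intra"); e_ <- has("inter")
  lhs <- sum(t_) + sum(i_) + sum(e_) -
    sum(t_ & i_) - sum(t_ & e_) - sum(i_ & e_) + sum(t_ & i_ & e_)
  expect_equal(lhs, length(sets))
  # every pair exactly one label, every set at least one
  for (s in sets) {
    expect_true(all(s$pair_labels$label %in% c("tandem", "intra", "inter")))
    expect_gte(length(s$set_labels), 1L)
    expect_equal(s$mixed, length(s$set_labels) > 1L)
  }
})
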