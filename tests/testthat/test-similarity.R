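# Low-complexity masking, local alignment, E-values, pair list building.

test_that("low-complexity masking follows the windowed entropy rule", {
  # zero-entropy homopolymer: every window is below threshold
  expect_equal(mask_low_complexity(strrep("A", 12), 12, 2.2),
               strrep("X", 12))
  # 20 distinct residues: entropy log2(12) per window, above threshold
  all20 <- "ACDEFGHIKLMNPQRSTVWY"
  expect_equal(mask_low_complexity(all20, 12, 2.2), all20)
  # degenerate inputs
  expect_equal(mask_low_complexity("", 12, 2.2), "")
  expect_equal(mask_low_complexity("MKV", 12, 2.2), "MKV")
})

test_that("local alignment scores match a brute-force affine DP oracle", {
  mat <- dupscan:::get_blosum62()
  # textbook instance with linear gap costs
  o <- oracle_align("HEAGAWGHEE", "PAWHEAE", mat, 8, 8, local = TRUE)
  a <- align_pair("HEAGAWGHEE", "PAWHEAE", matrix = mat,
                  gap_open = 8, gap_extend = 8)
  expect_equal(a$score, o)

  # random short sequences, several gap regimes
  set.seed(5)
  aas <- rownames(mat)[1:20]
  for (i in 1:8) {
    s1 <- paste0(sample(aas, sample(5:18, 1), TRUE), collapse = "")
    s2 <- paste0(sample(aas, sample(5:18, 1), TRUE), collapse = "")
    for (gp in list(c(11, 1), c(5, 2))) {
      expect_equal(
        align_pair(s1, s2, matrix = mat,
                   gap_open = gp[1], gap_extend = gp[2])$score,
        oracle_align(s1, s2, mat, gp[1], gp[2], local = TRUE),
        info = paste(s1, s2, gp[1], gp[2]))
    }
    # symmetry
    expect_equal(align_pair(s1, s2, matrix = mat)$score,
                 align_pair(s2, s1, matrix = mat)$score)
  }

  # self alignment of identical sequences: sum of diagonal self scores
  s <- "MKVLAWGHE"
  expect_equal(align_pair(s, s, matrix = mat)$score,
               sum(diag(mat[strsplit(s, "")[[1]], strsplit(s, "")[[1]]])))

  # all-negative scoring floor: empty local alignment scores 0
  neg <- matrix(-1, 20, 20, dimnames = list(aas, aas))
  expect_equal(align_pair("AAAA", "WWWW", matrix = neg)$score, 0)
})

test_that("Karlin-Altschul E-values obey their closed-form identities", {
  expect_equal(estimate_evalue(0, 200, 1e5), 0.041 * 200 * 1e5)
  # E(2s) = E(s)^2 / (k m n)
  e1 <- estimate_evalue(50, 200, 1e5)
  e2 <- estimate_evalue(100, 200, 1e5)
  expect_equal(e2, e1^2 / (0.041 * 200 * 1e5))
  # lambda -> infinity drives E to zero for positive scores
  expect_lt(estimate_evalue(10, 200, 1e5, lambda = 500), 1e-300)
  expect_error(estimate_evalue(-1, 200, 1e5))
})

test_that("pair lists are non-redundant, sorted, and thresholded", {
  g1 <- random_cds(120, 21)
  genes <- rbind(gene_row("gB", "chr1", 100, 459),
                 gene_row("gA", "chr2", 100, 459))
  cat1 <- make_catalog(genes, c(gB = g1, gA = g1))  # identical pair
  edges <- build_pair_list(cat1)
  expect_equal(nrow(edges), 1L)
  expect_equal(edges$gene_a, "gA")   # lexicographic orientation
  expect_equal(edges$gene_b, "gB")
  expect_true(all(edges$weight <= 200))

  # single gene: no pairs
  cat2 <- make_catalog(gene_row("gA", "chr1", 100, 459),
                       c(gA = random_cds(120, 22)))
  expect_equal(nrow(build_pair_list(cat2)), 0L)

  # mutually dissimilar random genes at a strict cutoff: no edges
  genes3 <- rbind(gene_row("g1", "chr1", 100, 500),
                  gene_row("g2", "chr1", 5000, 5400),
                  gene_row("g3", "chr2", 100, 500))
  cat3 <- make_catalog(genes3, c(g1 = random_cds(130, 23),
                                 g2 = random_cds(130, 24),
                                 g3 = random_cds(130, 25)))
  expect_equal(nrow(build_pair_list(cat3, evalue_cutoff = 1e-10)), 0L)
})

test_that("pair list weight decreases with E-value and caps at the ceiling", {
  ev <- c(0, 1e-300, 1e-50, 1e-10, 1e-5, 1e-2, 1)
  w <- edge_weight(ev)
  expect_equal(w[1], 200)
  expect_true(all(diff(w) <= 0))
  expect_true(all(w >= 0 & w <= 200))
})

test_that("the 12-column pair list round-trips and collapses redundancy", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "pairs.tsv")
  # raw BLAST-like rows: self hit, duplicate orientations, multiple HSPs
  rows <- c("gA\tgA\t100\t50\t0\t0\t1\t50\t1\t50\t1e-60\t200",
            "gA\tgB\t90\t50\t5\t0\t1\t50\t1\t50\t1e-20\t100",
            "gB\tgA\t90\t50\t5\t0\t1\t50\t1\t50\t1e-18\t95",
            "gA\tgB\t80\t30\t6\t0\t1\t30\t1\t30\t1e-5\t40")
  writeLines(rows, path)
  edges <- read_pair_list(path)
  expect_equal(nrow(edges), 1L)
  expect_equal(edges$score, 100)     # best of the three gA/gB records
  expect_equal(edges$evalue, 1e-20)
  out <- file.path(dir, "out.tsv")
  write_pair_list(edges, out)
  edges2 <- read_pair_list(out)
  expect_equal(edges2$gene_a, edges$gene_a)
  expect_equal(edges2$evalue, edges$evalue)
})
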