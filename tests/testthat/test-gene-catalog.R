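# Catalog loading, validation and filtering.

write_tiny_genome <- function(dir, genes, cds, extra_gff = NULL) {
  prot <- vapply(cds, function(x) suppressWarnings(
    as.character(Biostrings::translate(Biostrings::DNAString(x),
                                       if.fuzzy.codon = "solve"))), "")
  lines <- c("##gff-version 3",
             sprintf("##sequence-region %s 1 200000",
                     unique(genes$chromosome)))
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    tid <- paste0(g$gene_id, ".t1")
    lines <- c(lines,
      sprintf("%s\tx\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
              g$chromosome, g$start, g$end, g$strand, g$gene_id),
      sprintf("%s\tx\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
              g$chromosome, g$start, g$end, g$strand, tid, g$gene_id),
      sprintf("%s\tx\tCDS\t%d\t%d\t.\t%s\t0\tID=%s.c;Parent=%s",
              g$chromosome, g$start,
              g$start + nchar(cds[[g$gene_id]]) - 1L, g$strand, tid, tid))
  }
  if (!is.null(extra_gff)) lines <- c(lines, extra_gff)
  gff <- file.path(dir, "g.gff3")
  writeLines(lines, gff)
  cds_named <- cds
  names(cds_named) <- paste0(names(cds), ".t1")
  prot_named <- prot
  names(prot_named) <- paste0(names(prot), ".t1")
  cfa <- file.path(dir, "c.fa"); pfa <- file.path(dir, "p.fa")
  dupscan:::write_fasta(cds_named, cfa)
  dupscan:::write_fasta(prot_named, pfa)
  list(gff = gff, cds = cfa, protein = pfa)
}

test_that("loading keeps one model per gene and all fields round-trip", {
  dir <- withr::local_tempdir()
  genes <- rbind(gene_row("gA", "chr1", 101, 400),
                 gene_row("gB", "chr1", 5000, 5299, strand = "-"),
                 gene_row("gC", "chr2", 1000, 1299))
  cds <- c(gA = random_cds(100, 1), gB = random_cds(100, 2),
           gC = random_cds(100, 3))
  p <- write_tiny_genome(dir, genes, cds)
  cat1 <- load_catalog(p$gff, p$cds, p$protein)
  expect_equal(n_genes(cat1), 3L)
  expect_equal(sort(cat1$genes$gene_id), c("gA", "gB", "gC"))
  expect_equal(unname(cat1$cds[["gB"]]), unname(cds[["gB"]]))
  expect_equal(cat1$genes$strand[cat1$genes$gene_id == "gB"], "-")

  # write -> load round-trip preserves every field
  dir2 <- withr::local_tempdir()
  paths <- write_catalog(cat1, dir2)
  cat2 <- load_catalog(paths["gff"], paths["cds"], paths["protein"])
  expect_equal(cat2$genes, cat1$genes)
  expect_equal(cat2$cds, cat1$cds)
  expect_equal(cat2$protein, cat1$protein)
  expect_equal(cat2$chromosome_lengths, cat1$chromosome_lengths)
})

test_that("the longest coding form is kept when a gene has two transcripts", {
  dir <- withr::local_tempdir()
  genes <- gene_row("gA", "chr1", 101, 600)
  cds_long <- random_cds(150, 4)   # 450 nt
  cds_short <- random_cds(100, 5)  # 300 nt
  extra <- c(
    "chr1\tx\tmRNA\t101\t600\t.\t+\t.\tID=gA.t2;Parent=gA",
    sprintf("chr1\tx\tCDS\t101\t%d\t.\t+\t0\tID=gA.t2.c;Parent=gA.t2",
            101 + nchar(cds_short) - 1L))
  p <- write_tiny_genome(dir, genes, c(gA = cds_long), extra_gff = extra)
  # add the short transcript's sequences
  prot_short <- as.character(Biostrings::translate(
    Biostrings::DNAString(cds_short)))
  cat(sprintf(">gA.t2\n%s\n", cds_short), file = p$cds, append = TRUE)
  cat(sprintf(">gA.t2\n%s\n", prot_short), file = p$protein, append = TRUE)
  cat1 <- load_catalog(p$gff, p$cds, p$protein)
  expect_equal(n_genes(cat1), 1L)
  expect_equal(nchar(cat1$cds[["gA"]]), 450L)
})

test_that("invalid CDS records are rejected with a warning, missing ones error", {
  dir <- withr::local_tempdir()
  genes <- rbind(gene_row("gA", "chr1", 101, 400),
                 gene_row("gB", "chr1", 5000, 5301))
  cds <- c(gA = random_cds(100, 6),
           gB = paste0(random_cds(100, 7), "A"))  # 301 nt
  p <- write_tiny_genome(dir, genes, cds)
  expect_warning(cat1 <- load_catalog(p$gff, p$cds, p$protein),
                 "not divisible by 3")
  expect_equal(n_genes(cat1), 1L)

  # a gene with no sequence at all is a hard error naming the gene
  lines <- readLines(p$gff)
  lines <- c(lines,
    "chr1\tx\tgene\t9000\t9300\t.\t+\t.\tID=gZ",
    "chr1\tx\tmRNA\t9000\t9300\t.\t+\t.\tID=gZ.t1;Parent=gZ",
    "chr1\tx\tCDS\t9000\t9299\t.\t+\t0\tID=gZ.c;Parent=gZ.t1")
  writeLines(lines, p$gff)
  expect_error(suppressWarnings(load_catalog(p$gff, p$cds, p$protein)), "gZ")
})

test_that("filtering drops unplaced chromosomes and overlapping genes", {
  genes <- rbind(gene_row("gA", "chr1", 100, 1000),
                 gene_row("gB", "chr1", 500, 800),
                 gene_row("gC", "chrUn_random", 100, 400))
  cds <- c(gA = random_cds(300, 8), gB = random_cds(90, 9),
           gC = random_cds(100, 10))
  cat1 <- make_catalog(genes, cds)
  filt <- filter_catalog(cat1)
  # chrUn gone, and of the overlapping pair only the longer CDS survives
  expect_equal(filt$genes$gene_id, "gA")

  # idempotence and the no-overlap postcondition
  expect_equal(filter_catalog(filt)$genes, filt$genes)

  # catalogs without overlaps or dropped chromosomes are unchanged
  genes2 <- rbind(gene_row("gA", "chr1", 100, 400),
                  gene_row("gB", "chr1", 5000, 5300))
  cat2 <- make_catalog(genes2,
                       c(gA = random_cds(100, 11), gB = random_cds(100, 12)))
  expect_equal(filter_catalog(cat2)$genes, cat2$genes)
})

test_that("after filtering no two same-chromosome spans overlap", {
  set.seed(31)
  n <- 40
  genes <- do.call(rbind, lapply(seq_len(n), function(i) {
    start <- sample.int(20000, 1)
    gene_row(sprintf("g%02d", i), sample(c("chr1", "chr2"), 1),
             start, start + sample.int(3000, 1))
  }))
  cds <- vapply(seq_len(n), function(i) random_cds(50 + i, 100 + i), "")
  names(cds) <- genes$gene_id
  filt <- filter_catalog(make_catalog(genes, cds))
  g <- filt$genes
  for (chr in unique(g$chromosome)) {
    gc <- g[g$chromosome == chr, ]
    if (nrow(gc) < 2) next
    gc <- gc[order(gc$start), ]
    expect_true(all(gc$start[-1] > gc$end[-nrow(gc)]))
  }
  expect_equal(filter_catalog(filt)$genes, filt$genes)
})
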