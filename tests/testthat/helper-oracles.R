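# Independent brute-force oracles used to verify the implementation.
# These deliberately share no code with the package internals.

# --- affine-gap alignment oracles -----------------------------------------
# Gap convention matches the implementation's: a gap of length k costs
# gap_open + k * gap_extend.

oracle_align <- function(a, b, mat, gap_open, gap_extend, local = TRUE) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)   # ends in match/mismatch
  X <- matrix(NEG, n + 1, m + 1)   # gap in b (up)
  Y <- matrix(NEG, n + 1, m + 1)   # gap in a (left)
  M[1, 1] <- 0
  if (!local) {
    for (i in 2:(n + 1)) X[i, 1] <- -(gap_open + (i - 1) * gap_extend)
    for (j in 2:(m + 1)) Y[1, j] <- -(gap_open + (j - 1) * gap_extend)
  }
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- mat[av[i - 1], bv[j - 1]]
      M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s
      if (local) M[i, j] <- max(M[i, j], s)
      X[i, j] <- max(M[i - 1, j] - gap_open - gap_extend,
                     X[i - 1, j] - gap_extend)
      Y[i, j] <- max(M[i, j - 1] - gap_open - gap_extend,
                     Y[i, j - 1] - gap_extend)
      if (local) best <- max(best, M[i, j])
    }
  }
  if (local) best else max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# --- NG86 oracles ----------------------------------------------------------

oracle_codon_table <- function() {
  # built from Biostrings' genetic code but structured independently
  gc <- Biostrings::GENETIC_CODE
  gc
}

oracle_neighbors <- function(codon) {
  out <- character(0)
  for (p in 1:3) for (nt in c("A", "C", "G", "T")) {
    if (substr(codon, p, p) == nt) next
    x <- codon
    substr(x, p, p) <- nt
    out <- c(out, x)
  }
  out
}

oracle_sites <- function(codon) {
  gc <- oracle_codon_table()
  stops <- names(gc)[gc == "*"]
  s <- 0
  for (p in 1:3) {
    nb <- character(0)
    for (nt in setdiff(c("A", "C", "G", "T"), substr(codon, p, p))) {
      x <- codon; substr(x, p, p) <- nt
      nb <- c(nb, x)
    }
    nb <- nb[!(nb %in% stops)]
    if (length(nb) > 0)
      s <- s + sum(gc[nb] == gc[codon]) / length(nb)
  }
  c(s = s, n = 3 - s)
}

# All orderings of positions via iterative insertion (distinct from the
# package's recursive generator).
oracle_orderings <- function(v) {
  out <- list(integer(0))
  for (x in v) {
    nxt <- list()
    for (p in out) {
      for (k in 0:length(p)) {
        nxt[[length(nxt) + 1L]] <- append(p, x, after = k)
      }
    }
    out <- nxt
  }
  out
}

oracle_pair_diffs <- function(c1, c2) {
  gc <- oracle_codon_table()
  stops <- names(gc)[gc == "*"]
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  if (length(pos) == 0) return(c(sd = 0, nd = 0))
  syn <- numeric(0)
  nsy <- numeric(0)
  for (ord in oracle_orderings(pos)) {
    cur <- c1
    s <- 0; ns <- 0
    blocked <- FALSE
    for (p in ord) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (nxt %in% stops) { blocked <- TRUE; break }
      if (gc[nxt] == gc[cur]) s <- s + 1 else ns <- ns + 1
      cur <- nxt
    }
    if (!blocked) { syn <- c(syn, s); nsy <- c(nsy, ns) }
  }
  if (length(syn) == 0) return(c(sd = NA_real_, nd = NA_real_))
  c(sd = mean(syn), nd = mean(nsy))
}

# Full NG86 for two codon vectors (complete-case), via the oracle pieces.
oracle_ng86 <- function(codons_a, codons_b) {
  sa <- sum(vapply(codons_a, function(x) oracle_sites(x)[["s"]], 0))
  sb <- sum(vapply(codons_b, function(x) oracle_sites(x)[["s"]], 0))
  dd <- mapply(function(x, y) oracle_pair_diffs(x, y)[["sd"]],
               codons_a, codons_b)
  nn <- mapply(function(x, y) oracle_pair_diffs(x, y)[["nd"]],
               codons_a, codons_b)
  keep <- !is.na(dd)
  n <- sum(keep)
  S <- (sum(vapply(codons_a[keep], function(x) oracle_sites(x)[["s"]], 0)) +
        sum(vapply(codons_b[keep], function(x) oracle_sites(x)[["s"]], 0))) / 2
  list(S = S, N = 3 * n - S, Sd = sum(dd[keep]), Nd = sum(nn[keep]),
       n_compared = n)
}

# --- hypergeometric / Fisher oracle ---------------------------------------

# Two-sided Fisher p by explicit enumeration with choose() ratios.
oracle_fisher_two_sided <- function(study_count, study_n, pop_count, pop_n) {
  support <- max(0, study_n - (pop_n - pop_count)):min(study_n, pop_count)
  pr <- vapply(support, function(x)
    choose(pop_count, x) * choose(pop_n - pop_count, study_n - x) /
      choose(pop_n, study_n), 0)
  obs <- pr[support == study_count]
  min(1, sum(pr[pr <= obs * (1 + 1e-7)]))
}

# --- small catalog builder -------------------------------------------------

make_catalog <- function(genes, cds = NULL) {
  if (is.null(cds)) {
    cds <- vapply(seq_len(nrow(genes)), function(i)
      random_cds(max(30L, (genes$end[i] - genes$start[i] + 1L) %/% 3L),
                 seed = 900 + i), "")
    names(cds) <- genes$gene_id
  }
  prot <- vapply(cds, function(x)
    as.character(Biostrings::translate(Biostrings::DNAString(x))), "")
  names(prot) <- names(cds)
  chrom <- tapply(genes$end, genes$chromosome, max) + 100000
  gene_catalog(genes, cds, prot, chrom)
}

gene_row <- function(id, chr, start, end, strand = "+") {
  data.frame(gene_id = id, chromosome = chr, start = start, end = end,
             strand = strand, stringsAsFactors = FALSE)
}

# A fast, tiny synthetic configuration for pipeline-level tests.
small_sim_config <- function(seed = 1L) {
  sim_config(
    n_chromosomes = 3L,
    n_background_genes = 30L,
    gene_length_mean = 120L,
    gene_length_min = 80L,
    planted_sets = rbind(
      data.frame(size = c(2L, 3L), type = "tandem", target_ks = 0.3,
                 omega = 0.2),
      data.frame(size = 2L, type = "intra", target_ks = 0.5, omega = 0.2),
      data.frame(size = c(2L, 3L), type = "inter", target_ks = 1.0,
                 omega = 0.2),
      data.frame(size = 3L, type = "mixed", target_ks = 0.4, omega = 0.2)),
    seed = seed)
}
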