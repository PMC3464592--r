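# Nei-Gojobori (NG86) site and difference counting with equal-weight
# pathway averaging and a Jukes-Cantor multiple-hit correction.
#
# Site and per-codon-pair difference counts are precomputed once into lookup
# tables (61 sense codons; 61 x 61 pairs) so that pairwise estimation and the
# mutation simulator both reduce to table lookups.

.ng86 <- new.env(parent = emptyenv())

NUCS <- c("A", "C", "G", "T")
STOP_CODONS <- c("TAA", "TAG", "TGA")

all_codons <- function() {
  g <- expand.grid(p3 = NUCS, p2 = NUCS, p1 = NUCS, stringsAsFactors = FALSE)
  paste0(g$p1, g$p2, g$p3)
}

sense_codons <- function() setdiff(all_codons(), STOP_CODONS)

codon_aa <- function(codon) unname(Biostrings::GENETIC_CODE[codon])

#' Synonymous and nonsynonymous site counts for one codon
#'
#' Counts NG86 synonymous sites by enumerating the nine single-nucleotide
#' neighbors of the codon under the standard genetic code. Neighbors that are
#' stop codons are excluded from the denominator at their position, so the
#' synonymous fraction at position i is (synonymous neighbors) / (non-stop
#' neighbors). The nonsynonymous count is `3 - s`.
#'
#' @param codon A three-letter string over A, C, G, T; must not be a stop codon.
#' @return Named numeric vector with elements `s` and `n`, `s + n == 3`.
#' @examples
#' ng86_codon_sites("TTT")  # s = 1/3: only TTT->TTC is synonymous
#' ng86_codon_sites("ATG")  # s = 0: methionine has no synonym
#' @export
ng86_codon_sites <- function(codon) {
  stopifnot(is.character(codon), length(codon) == 1L, nchar(codon) == 3L)
  if (codon %in% STOP_CODONS)
    stop("ng86_codon_sites: stop codon ", codon, " has no defined site counts")
  aa <- codon_aa(codon)
  if (is.na(aa)) stop("ng86_codon_sites: invalid codon ", codon)
  s <- 0
  for (pos in 1:3) {
    ref <- substr(codon, pos, pos)
    syn <- 0L
    valid <- 0L
    for (alt in setdiff(NUCS, ref)) {
      nb <- codon
      substr(nb, pos, pos) <- alt
      if (nb %in% STOP_CODONS) next
      valid <- valid + 1L
      if (codon_aa(nb) == aa) syn <- syn + 1L
    }
    if (valid > 0L) s <- s + syn / valid
  }
  c(s = s, n = 3 - s)
}

# All permutations of a vector (n <= 3 here).
perms <- function(v) {
  n <- length(v)
  if (n <= 1L) return(list(v))
  out <- list()
  for (i in seq_len(n)) {
    for (rest in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
  }
  out
}

# Pathway-averaged (sd, nd) for one codon pair. Paths passing through stop
# codons are excluded; if every path is blocked, returns c(NA, NA) and the
# column is skipped by ng86_pair().
codon_pair_diffs <- function(c1, c2) {
  a1 <- strsplit(c1, "")[[1]]
  a2 <- strsplit(c2, "")[[1]]
  d <- which(a1 != a2)
  k <- length(d)
  if (k == 0L) return(c(sd = 0, nd = 0))
  syn_counts <- numeric(0)
  for (ord in perms(d)) {
    cur <- c1
    syn <- 0
    ok <- TRUE
    for (pos in ord) {
      nxt <- cur
      substr(nxt, pos, pos) <- a2[pos]
      if (nxt %in% STOP_CODONS) { ok <- FALSE; break }
      if (codon_aa(nxt) == codon_aa(cur)) syn <- syn + 1
      cur <- nxt
    }
    if (ok) syn_counts <- c(syn_counts, syn)
  }
  if (length(syn_counts) == 0L) return(c(sd = NA_real_, nd = NA_real_))
  sd <- mean(syn_counts)
  c(sd = sd, nd = k - sd)
}

# Lazily build and cache the lookup tables.
ng86_tables <- function() {
  if (!is.null(.ng86$tables)) return(.ng86$tables)
  codons <- all_codons()
  nc <- length(codons)
  sense <- sense_codons()
  sites <- rep(NA_real_, nc)
  names(sites) <- codons
  for (cd in sense) sites[cd] <- ng86_codon_sites(cd)[["s"]]
  SD <- matrix(NA_real_, nc, nc, dimnames = list(codons, codons))
  ND <- SD
  for (c1 in sense) {
    for (c2 in sense) {
      dd <- codon_pair_diffs(c1, c2)
      SD[c1, c2] <- dd[[1]]
      ND[c1, c2] <- dd[[2]]
    }
  }
  idx <- seq_len(nc)
  names(idx) <- codons
  .ng86$tables <- list(codons = codons, index = idx, sites = sites,
                       SD = SD, ND = ND)
  .ng86$tables
}

#' Jukes-Cantor distance from an observed proportion of differences
#'
#' `d = -(3/4) ln(1 - (4/3) p)`; returns `NA` for `p >= 0.75` (saturation).
#' @param p Observed proportion of differences per site.
#' @export
jc_distance <- function(p) {
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p) & p < 0.75
  out[ok] <- -0.75 * log(1 - 4 * p[ok] / 3)
  out[!is.na(p) & p == 0] <- 0
  out
}

# Core NG86 computation on two equal-length codon vectors (gaps/ambiguous
# columns already removed). Returns the fields of a KsResult.
ng86_from_codons <- function(codons_a, codons_b, min_codons = 30L) {
  tb <- ng86_tables()
  stopifnot(length(codons_a) == length(codons_b))
  sd_col <- tb$SD[cbind(codons_a, codons_b)]
  keep <- !is.na(sd_col)     # drops all-stop-path columns (and stop codons)
  n_used <- sum(keep)
  if (n_used == 0L) {
    return(list(n_compared = 0L, S = 0, N = 0, Sd = 0, Nd = 0,
                ps = NA_real_, pn = NA_real_, ka = NA_real_, ks = NA_real_,
                status = "too_short"))
  }
  ca <- codons_a[keep]; cb <- codons_b[keep]
  Sa <- sum(tb$sites[ca]); Sb <- sum(tb$sites[cb])
  S <- (Sa + Sb) / 2
  N <- 3 * n_used - S
  Sd <- sum(tb$SD[cbind(ca, cb)])
  Nd <- sum(tb$ND[cbind(ca, cb)])
  if (n_used < min_codons || S <= 0) {
    return(list(n_compared = n_used, S = S, N = N, Sd = Sd, Nd = Nd,
                ps = if (S > 0) Sd / S else NA_real_,
                pn = if (N > 0) Nd / N else NA_real_,
                ka = NA_real_, ks = NA_real_, status = "too_short"))
  }
  ps <- Sd / S
  pn <- Nd / N
  ks <- jc_distance(ps)
  ka <- jc_distance(pn)
  status <- if (ps >= 0.75) "saturated" else "ok"
  list(n_compared = n_used, S = S, N = N, Sd = Sd, Nd = Nd,
       ps = ps, pn = pn, ka = ka, ks = ks, status = status)
}

#' NG86 Ks/Ka estimate for one codon alignment
#'
#' Computes synonymous (S) and nonsynonymous (N) site counts averaged over the
#' two sequences, pathway-averaged difference counts (Sd, Nd), the observed
#' proportions ps = Sd/S and pn = Nd/N, and Jukes-Cantor corrected distances
#' ks and ka. Columns whose minimal mutational pathways all pass through stop
#' codons are skipped entirely. `status` is `"saturated"` when ps >= 0.75
#' (ks unestimable) and `"too_short"` when fewer than `min_codons` codon
#' columns were compared.
#'
#' @param aln A `codon_alignment`, see [back_translate()].
#' @param min_codons Minimum number of compared codons for a stable estimate.
#' @return A one-row data frame of class `ks_result`.
#' @export
ng86_pair <- function(aln, min_codons = 30L) {
  stopifnot(inherits(aln, "codon_alignment"))
  keep <- !is.na(aln$codons_a) & !is.na(aln$codons_b) & !aln$excluded
  res <- ng86_from_codons(aln$codons_a[keep], aln$codons_b[keep],
                          min_codons = min_codons)
  out <- data.frame(gene_a = aln$pair[1], gene_b = aln$pair[2],
                    n_compared = res$n_compared, S = res$S, N = res$N,
                    Sd = res$Sd, Nd = res$Nd, ps = res$ps, pn = res$pn,
                    ka = res$ka, ks = res$ks, status = res$status,
                    stringsAsFactors = FALSE)
  class(out) <- c("ks_result", class(out))
  out
}
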