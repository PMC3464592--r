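---
title: "Profiling gene duplication sets with dupscan: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling gene duplication sets with dupscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Teleost fish genomes carry an unusually rich record of gene duplication:
tandem arrays produced by unequal crossing over, dispersed intra-chromosomal
copies, and inter-chromosomal duplicates left behind by large-scale and
whole-genome duplication events. Profiling that record for one genome means
answering four questions: which genes belong to a common duplicated family,
how are the copies arranged on the chromosomes, how old is each duplication
(measured as synonymous divergence, Ks), and are recent duplicates
functionally biased. `dupscan` implements that entire analysis as a tested R
pipeline, together with a synthetic-genome generator that plants duplication
sets of known size, arrangement and age so every stage can be validated
against ground truth.

# Pipeline stages and their models

## Gene catalog

Input is a standard annotation triple: gene coordinates in GFF3 (1-based,
inclusive, the GFF3 convention used throughout), CDS and protein FASTA. When
a gene has several transcripts, the longest coding form is kept; records
whose CDS length is not a multiple of three, or whose translation does not
reproduce the protein, are rejected with a warning. Filtering removes genes
on unplaced/random/mitochondrial sequences and resolves same-chromosome span
overlaps by keeping the gene with the longest CDS (CDS length, not genomic
span, because the catalog's unit of comparison is the coding form; ties go
to the lexicographically smallest gene id, which makes the filter
deterministic and idempotent). Strand is stored but ignored by every
distance computation — duplication-type distances are defined on spans, not
on orientation.

## Similarity graph

All-vs-all Smith–Waterman local alignment (BLOSUM62, affine gaps, defaults
gap open 11 / extend 1) replaces a BLAST search at desk scale; no heuristic
seeding is used, so scores are exact. Low-complexity segments are first
masked by a sliding-window Shannon-entropy filter (window 12 residues,
threshold 2.2 bits; masked residues score 0 against everything). This is a
deliberately simplified stand-in for SEG: its only job is to stop
low-complexity runs from creating spurious edges, and a single
window/threshold rule does that while remaining exactly testable.

Each alignment score is converted to a deterministic E-value by the
Karlin–Altschul formula `E = k · m · N · exp(-lambda · S)` with the
conventional gapped-BLOSUM62 parameters (lambda = 0.267, k = 0.041). We use
an analytic E-value rather than an empirical fit because the only consumer
is the clustering weight, which takes its logarithm; what matters is a
reproducible, monotone mapping from score to significance. Edges with E
above the cutoff (default 1e-5, the conventional paralog-screen value; a
config knob) are discarded; self matches and redundant orientations are
removed so each unordered pair appears once. Real BLAST tabular output
(`-outfmt 6`) can be substituted via `read_pair_list()`.

## Markov clustering

Duplicated families are read off the weighted similarity graph by Markov
clustering (MCL). Edge weights are `min(200, -0.4343 · ln E)` — i.e.
`-log10 E` capped at 200, the classic MCL input transform (0.4343 is
log10 e). The transition matrix gets a self-loop per node equal to its
maximum incident weight (standard regularization against period-2
oscillation), is column-normalized, and then alternates expansion (matrix
squaring) with inflation (element-wise power 2.0, the MCL convention,
followed by column renormalization), pruning entries below 1e-5, until the
matrix changes by less than 1e-6 or 100 iterations elapse (desk-scale
graphs converge in well under 50). Clusters are the connected components of
the non-zero structure of the limit matrix; overlapping attractor systems
are thereby merged, which guarantees a strict partition. Clusters of size
>= 2 become duplication sets; singletons are non-duplicated genes. Because
the graph decomposes into connected components first, clusters can never
span disconnected components.

## Duplication types

Every member pair of a set is classified from coordinates alone:

* **inter** — the two genes lie on different chromosomes;
* **tandem** — same chromosome and intergenic gap strictly below 10 kb;
* **intra** — same chromosome, gap >= 10 kb (the 10 kb boundary itself is
  intra).

Distance is the intergenic gap between the closest span boundaries
(`max(0, max(starts) - min(ends) - 1)`, zero for overlapping or abutting
spans). We chose the gap rather than midpoint distance because "within 10 kb
of one another" reads most naturally as the space between the genes and is
independent of gene length. Tandem status is pairwise and does not require
adjacency — intervening genes are allowed — but a strict-adjacency mode
(`require_adjacent = TRUE`) is exposed for users who prefer the narrower
reading. A set's labels are the union of its pair labels, and a set is
*mixed* when it carries more than one label; the union reading is the only
one under which the three non-exclusive categories plus a mixed count are
mutually consistent (the inclusion–exclusion identity over the three label
sets is asserted in the test suite on every pipeline run).

## Ks estimation (NG86)

For each member pair the proteins are globally aligned (Needleman–Wunsch,
BLOSUM62, gap open 10 / extend 0.5), the alignment is back-translated to
codons (residue i maps to codon i of its CDS, trailing stop codons stripped;
gap and ambiguous columns dropped pairwise), and synonymous/nonsynonymous
divergence is counted by the Nei–Gojobori method:

* per-codon synonymous sites: each of the nine single-nucleotide neighbors
  is classified under the standard genetic code; neighbors that are stop
  codons are excluded from the denominator at their position, so `s + n = 3`
  exactly per codon;
* per-column differences: codon pairs differing at d positions are averaged
  over all d! minimal mutational pathways with equal weights; pathways
  passing through stop codons are excluded, and the rare columns whose
  pathways are all blocked are skipped entirely (removed from `n_compared`
  and from the site totals, keeping `S + N = 3 · n_compared` exact);
* `ps = Sd/S` and `pn = Nd/N` are corrected for multiple hits by
  Jukes–Cantor, `d = -(3/4) ln(1 - (4/3) p)`, undefined at `p >= 0.75`
  (reported as status `saturated`, never as a number);
* alignments with fewer than 30 compared codons (config knob `min_codons`)
  are reported `too_short` — short alignments make the counting estimator
  unstable.

All site and difference counts are precomputed into 61- and 61×61-entry
lookup tables, verified in the test suite against independent brute-force
enumeration over all codons and codon pairs. Set-level Ks is the arithmetic
mean over pairs with status `ok`; saturated pairs are excluded from means
and histograms but always reported as a separate category. The mean (rather
than median or a representative pair) keeps grouped summaries exactly
recombinable: the weighted mean of the size-by-type groups equals the
per-size mean, which the tests assert.

## Profiles

The profiler reproduces the standard summary analyses: a genome summary
(gene count, set count, mean set size, per-type counts with percentages of
sets, mixed count), the set-size distribution with the fraction of
duplicated genes per size (sizes above a tail cap pooled), the pairwise-Ks
histogram (default bin width 0.25 over [0, 6]; binning is a config knob as
no canonical choice exists), the fraction of pairs at or below a Ks
threshold (default 1.0, the "recent duplicate" rule), and mean Ks grouped
by set size and by size × type. Histogram and fraction counts are in units
of gene *pairs*, not genes — pairwise comparisons are what the Ks
computation produces, and mixing units would make the grouped means
inconsistent.

## GO enrichment

Recent duplicates are tested for functional bias: the study set is every
gene belonging to at least one pair with Ks <= 1.0, the population is all
genes in duplication sets. Annotations are propagated leaf-to-root over the
is_a closure of an OBO 1.2 ontology (obsolete terms dropped, alt_ids
aliased, cycles a hard error). Each term annotated to at least one
population gene is tested with a two-sided Fisher's exact test computed by
hypergeometric point-probability summation (the two-sided form because both
over- and under-representation are of interest; one-sided available by
flag). Bonferroni, Šidák and Benjamini–Hochberg corrections are reported
side by side over the m tested terms (m = terms with >= 1 population
annotation after propagation, the goatools convention). All three GO
namespaces are tested together by default; a namespace filter is available.

## Assembly-collapse simulation

To ask whether shotgun assembly would merge near-identical paralogs into a
single locus, a reference is fragmented into error-free fixed-length reads
at uniformly random positions (default 500 bp at 10-fold coverage; exact
tiling available), reassembled by a deterministic greedy assembler that
repeatedly merges the pair with the longest exact suffix–prefix overlap
(>= 50 bp, ties lexicographic, contained reads absorbed), and the contigs
are mapped back (exact substring search first, seed-and-extend local
alignment as fallback; mapped = identity >= 0.98 over >= 90% of the contig).
For planted repeat families, a collapse event is counted when the repeat
unit occurs in fewer contigs than the genome has copies. Reads are
single-strand and error-free on purpose: the question under test is
repeat-driven collapse in an overlap assembler, and strand or error
modeling would only obscure that signal (a reverse-complement-aware mode
was considered and rejected as adding no discriminating power to the
collapse question).

# The synthetic genome generator

`sim_config()` defaults define the benchmark conditions used by the test
suite and the acceptance script:

* 8 chromosomes, 300 background genes. Background genes are mutually
  independent random coding sequences, so any background gene that lands in
  a duplication set is a false positive by construction. Eight chromosomes
  (not fewer) are required so that an inter-chromosomal set of up to six
  members can place every copy on a distinct chromosome, as the type
  definition demands.
* Gene lengths uniform on 150–450 codons (mean 300). Real teleost coding
  sequences average ~400+ codons; 300 keeps the benchmark representative
  while staying desk-scale. Lengths far below this are deliberately
  avoided: at ~60 codons a Ks = 2 pair drops to ~35% protein identity over
  a very short alignment and falls below any conventional similarity
  cutoff, which tests the detector's sensitivity limit rather than the
  pipeline logic.
* 40 planted sets of sizes 2–6: 10 tandem (Ks 0.3), 10 intra (alternating
  Ks 0.3/2.0), 10 inter (Ks 2.0), 4 mixed (Ks 1.0; a tandem pair plus
  copies on other chromosomes), and one whole-genome-duplication event
  contributing 6 size-2 cross-chromosome sets at a shared Ks 2.0. The two
  age cohorts (0.3 and 2.0) produce the bimodal Ks distribution the
  profiler must recover, and planting tandem young and inter old yields the
  tandem < intra < inter mean-Ks ordering the per-type profile must
  reproduce.
* Spacing: tandem arrays use 2 kb internal gaps, so even a four-member
  array keeps *all pairwise* gaps below 10 kb (3 gaps + 2 intervening genes
  ≈ 8–9 kb worst case); intra members are placed with at least 50 kb before
  them; ordinary intergenic gaps are exponential with mean 2 kb (floored at
  200 bp). Genes are laid out left to right in shuffled block order with no
  overlaps, so `filter_catalog()` is a no-op on clean synthetic data and
  tests isolate single stages.
* Divergence: each copy is evolved from the set's ancestor by proposing
  random single-nucleotide changes — stop-creating changes rejected,
  synonymous changes always accepted, nonsynonymous changes accepted with
  probability omega (default 0.2, a typical purifying-selection Ka/Ks) —
  until the NG86 estimate against the ancestor first reaches the target Ks.
  Targeting the estimator's own statistic makes the planted truth directly
  comparable to what the pipeline measures, with no rate-calibration
  bookkeeping. Divergence is applied to the copies only (the ancestor is
  emitted unchanged), so in sets larger than two the copy-copy pairs sit
  near twice the target; the recorded per-pair truth therefore carries a
  target only for ancestor-copy pairs. Targets at or beyond the
  length-dependent saturation bound (the Ks whose required synonymous
  proportion comes within 1/L of the 0.75 Jukes–Cantor limit; ≈ 4.3 for
  300 codons) are refused with an error.
* GO annotations: a small random is_a DAG is generated with the planted
  enriched terms as guaranteed leaves (they are generated last and never
  sampled as parents). Leaf status matters: an enriched internal node would
  accumulate background annotations through propagation and dilute its own
  signal. Enriched terms annotate the low-Ks study genes at `study_freq`
  (default 0.8) and the rest of the population at `pop_freq` (default 0.1);
  every gene also receives 1–3 random background terms.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: no insertions or deletions (every alignment gap in
the pipeline output is therefore spurious by construction), no codon-usage
bias or rate heterogeneity, no gene loss or fractionation after
whole-genome duplication, no transposable elements or segmental-duplication
mosaicism, no transcript-level complexity (one coding form per gene), and
background genes are entirely non-homologous rather than distantly related.
Real genomes violate all of these, so pipeline performance there is bounded
by, not equal to, the synthetic recovery rates.

# Numerical choices and degenerate inputs

* Alignment is delegated to Biostrings' pairwise aligner (a gap of length k
  costs `open + k · extend`); its traceback is deterministic, and scores are
  verified against brute-force affine-gap dynamic programming oracles in the
  tests. Score ties therefore never affect results.
* Fisher's two-sided p sums hypergeometric point probabilities not exceeding
  the observed one times (1 + 1e-7), the conventional tie tolerance; the
  tests verify agreement with exhaustive enumeration to 1e-12 for all
  tables with population up to 60.
* MCL: inflation 2.0, prune 1e-5, tolerance 1e-6, max 100 iterations;
  column sums are renormalized after pruning, and the per-iteration maximum
  column-sum deviation is recorded and asserted below 1e-9.
* Empty inputs degrade explicitly: an empty edge list yields an empty
  partition; a catalog of one gene yields no pairs; a Ks table with no ok
  pairs yields empty profile tables and an undefined set mean; an empty
  study set skips enrichment (recorded in the run manifest).
* Seeding: one global seed is fanned out to stages through a rolling-hash
  `child_seed()`, so a single integer reproduces a whole run; reruns with
  an identical configuration are byte-identical, which the tests assert.

# Known limitations

* **Spurious balanced gaps at high divergence.** Near Ks = 2 the global
  protein alignment occasionally inserts compensating gap pairs (the
  evolution model is indel-free, so any gap is an alignment artifact); the
  misaligned run between them inflates the estimate by up to ~0.5 in a few
  percent of pairs. Gapless pairs recover their target within ±0.15. We
  keep the standard gap penalties rather than suppressing gaps, since real
  data contain genuine indels.
* **Saturation reporting of the generator.** Because the mutation walk
  stops the first time the NG86 estimate reaches the target, any reachable
  target terminates with a defined (non-saturated) Ks just above target;
  pairs evolved to targets near 3 are reported saturated only when
  re-measurement noise pushes the observed synonymous proportion past 0.75
  (a minority of replicates). Genuinely saturated pairs arise in practice
  from copy-copy comparisons in old multi-member sets.
* **Greedy assembler.** The assembler is exact-overlap and greedy; it
  exhibits repeat collapse (its purpose) but is not a model of modern
  de Bruijn or string-graph assemblers.
* **E-values are analytic stand-ins.** Karlin–Altschul parameters are fixed
  constants, not fitted to the score distribution; absolute E-values should
  not be compared with BLAST output, though their ranking and thresholding
  behave equivalently.

# Problem sizes

The shipped test suite and acceptance script run the full pipeline on the
default 8-chromosome / 300-background / 40-set genome (~405 genes, ~82,000
pairwise comparisons), estimator-recovery batches of 50 replicate 300-codon
pairs per target, exhaustive NG86 and Fisher oracle comparisons (3,721
codon pairs; ~800,000 contingency tables), and 50 kb assembly simulations at
10-fold coverage — sizes chosen so the whole validation remains comfortably
reproducible on a single CPU.
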