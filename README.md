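# dupscan — gene duplication set detection and divergence profiling

`dupscan` profiles the gene-duplication landscape of an annotated genome.
Starting from a standard annotation triple (GFF3 coordinates, CDS FASTA,
protein FASTA) it:

1. builds a non-redundant all-vs-all protein similarity graph
   (Smith–Waterman / BLOSUM62 with entropy masking, Karlin–Altschul
   E-values; real `blastp -outfmt 6` output can be substituted);
2. clusters the graph into **duplication sets** with the Markov Cluster
   algorithm (edge weight `min(200, −log10 E)`, inflation 2.0);
3. classifies every set by chromosomal arrangement — **tandem** (same
   chromosome, gap < 10 kb), **intra-chromosomal** (same chromosome,
   gap ≥ 10 kb), **inter-chromosomal** — with non-exclusive set labels and
   a *mixed* flag;
4. estimates pairwise synonymous and nonsynonymous divergence by the
   **Nei–Gojobori (NG86)** method on protein-guided codon alignments:
   equal-weight pathway averaging with stop-codon exclusion, then the
   Jukes–Cantor correction `Ks = −(3/4)·ln(1 − (4/3)·ps)`, with explicit
   `saturated` (ps ≥ 0.75) and `too_short` statuses;
5. profiles the results: set-size distributions, Ks age histograms, the
   fraction of recent pairs (Ks ≤ 1), and mean Ks by set size and type;
6. tests **GO-term enrichment** of recent duplicates (Fisher's exact test
   on a propagated OBO DAG; Bonferroni, Šidák and BH-FDR side by side);
7. simulates **shotgun-assembly collapse** of near-identical paralogs with
   an error-free read fragmenter, a deterministic greedy overlap assembler,
   and contig-to-reference mapping.

A first-class synthetic-genome generator (`simulate_genome()`) plants
duplication sets of controlled size, arrangement and target Ks among
non-homologous background genes and emits GFF3/FASTA plus a machine-readable
truth, so every stage is validated against ground truth. The intended users
are comparative genomicists who want a transparent, fully testable
re-implementation of the classic duplication-profiling workflow at desk
scale.

Audience note: the methods vignette (`vignettes/dupscan-methods.Rmd`)
documents every model, default and known limitation.

## Worked example

Run the whole pipeline on the default synthetic benchmark genome
(8 chromosomes, 300 background genes, 40 planted sets at Ks cohorts
0.3 / 1.0 / 2.0):

```r
library(dupscan)
res <- run_pipeline(pipeline_config(seed = 1))
print(res)
```

```
dupscan pipeline result
Genes:                  405
Duplicated genes:       105
Duplication sets:       40
Mean set size:          2.62
Inter-chromosomal sets: 20 (50.0%)
Intra-chromosomal sets: 10 (25.0%)
Tandem sets:            14 (35.0%)
Mixed sets:             4 (10.0%)
Fraction of ok pairs with Ks <= threshold: 0.326
Truth: ARI 1.000, label agreement 100.0%
```

Reading the output: all 40 planted sets are recovered exactly (adjusted
Rand index 1.0 over planted genes, no background gene clustered), every set
carries its expected arrangement labels, and 32.6% of estimable pairs have
Ks ≤ 1.0 — the planted "recent" cohort. Percentages are of sets and exceed
100% in total because the three labels are non-exclusive. Per-type mean Ks
reflects the planted ages:

```r
res$profiles$mean_ks_by_type
#>    label   mean_ks n_pairs
#> 1  inter 2.1052709      49
#> 2  intra 0.9628957      14
#> 3 tandem 0.4912220      23
```

and the planted GO term (annotating 80% of the recent duplicates vs 10% of
the rest) tops the enrichment table:

```r
head(res$enrichment[, c("term_id", "study_count", "study_n", "pop_count",
                        "pop_n", "direction", "p_fdr_bh")], 1)
#>      term_id study_count study_n pop_count pop_n direction     p_fdr_bh
#> 1 GO:SYN0050          30      36        49   105      over 2.118089e-06
```

With `out_dir` set, every stage table (pair list, sets, types, Ks pairs,
summary, profiles, enrichment, truth report) is written as TSV alongside a
JSON run manifest; identical configurations reproduce identical bytes.

To analyze a real genome, point `pipeline_config(input = list(gff = ...,
cds_fasta = ..., protein_fasta = ..., obo = ..., annotations = ...))` at
your files; enrichment is skipped (and noted in the manifest) when no
annotations are supplied.

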