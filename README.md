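# tcmescan

Mining and structural classification of TnpB-containing mobile elements
(TCMEs) — the IS605, IS607 and IS1341 insertion-sequence groups — in
bacterial genome assemblies.

## The science

IS605-family insertion sequences are the evolutionary cradle of the
RNA-guided nuclease TnpB (the ancestor of Cas12).  They come in three
structural groups: **IS605** elements pair TnpB with a single-tyrosine
HuH transposase (Y1) — overlapping on the same strand (IS605a),
separated (IS605b), or on opposite strands (IS605c); **IS607** elements
pair it with a serine recombinase (SR; subgroups IS607a/b by overlap);
**IS1341** elements carry TnpB alone.  Elements are bounded by
subterminal palindromes (IS605/IS1341) or short direct repeats (IS607),
with a ~4-nt cleavage site (`TTAT` left; `TCAA`/`TTCA` right) immediately
outside the repeat; an element with both cleavage sites identifiable is
*full*, otherwise *truncated*.  IS1341 candidates that still carry more
than 20 bp of Y1/SR-derived flanking sequence are decayed IS605/IS607
copies, not genuine IS1341.

`tcmescan` implements the whole mining cascade as composable, seeded,
tested R functions:

* a log-odds PSSM of the TnpB RuvC domain, built from a curated seed set
  (length filter 200–600 aa, 80% pre-clustering, domain extraction, ≤20%
  gap filter), scored per column as
  `log2(((count + pc·bg)/(n + pc))/bg)`;
* a six-frame local scan (affine gaps, half-bit convention 11/1; stop
  codons are hard barriers; hits ≥ 50 aa) with a threshold calibrated as
  the 99.9th percentile over dinucleotide-preserving shuffles;
* locus extraction (±1.7 kb), ORF prediction (table 11, ATG/GTG/TTG
  starts), motif/homology role assignment, subgroup classification,
  palindrome/direct-repeat boundary detection with cleavage-tetramer
  anchoring, completeness calls, and the >20 bp decay filter;
* greedy identity clustering (80%/70%/90% stages), center-star consensus
  building, and known/new family naming against a reference library;
* neighbor-joining trees with Felsenstein bootstrap for the mined
  protein sets, and per-species invasion/copy-number summary tables with
  half-up rounding at printed precision;
* a synthetic-genome simulator with a ground-truth ledger that makes all
  of the above testable end to end.

## Worked example

Simulate two pseudo-species of four 0.2-Mb genomes with planted elements
at 2% divergence, mine them, and score the result against the truth
ledger:

```r
library(tcmescan)
ex <- tcme_experiment(n_species = 2, n_genomes = 4, genome_length = 2e5,
                      divergence = 0.02, seed = 1)
ex$result
#> <tcme_result> 40 elements in 8 genomes (12 families); scan threshold 27.9 bits
glance(ex$result)
#> # A tibble: 1 × 8
#>   n_genomes n_hits n_loci n_elements n_full n_decay n_families threshold_bits
#> 1         8     40     40         40     32       0         12           27.9
ex$metrics
#>   n_truth recall precision subgroup_accuracy completeness_accuracy boundary_within_tol
#> 1      40    100       100              97.5                  92.5                 100
ex$result$species_table[, c(1, 2, 4, 6, 7, 10)]
#>            species n_genomes n_tcmes pct_genomes_with_tcme mean_copies pct_full
#> 1 Synthetica alpha         4      14                   100         3.5       93
#> 2  Synthetica beta         4      26                   100         6.5       73
```

All 40 planted copies were recovered (recall/precision 100); the scan
threshold of 27.9 bits is the calibrated decoy percentile (genuine
domains score above 300 bits); 39/40 subgroup calls match the ledger,
boundary coordinates are all within ±5 nt, and every full-element family
is re-identified against the reference library built from the same
templates.  Larger runs (the package's validation survey uses 6 species
× 20 genomes × 0.5 Mb) push the per-call accuracies above 95%.

Individual stages are ordinary functions on tibbles — e.g.
`scan_genomes()`, `extract_loci()`, `annotate_elements()`,
`cluster_families()`, `species_summary()` — so any step can be run,
inspected or replaced in isolation; `autoplot(result, "invasion")` and
`autoplot(result, "copy_number")` draw the survey figures.  See the
`tcme-mining-methods` vignette for the models, parameter choices and
their rationale.

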