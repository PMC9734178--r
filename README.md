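# cistromediv

Cross-species analysis of transcription-factor cistrome conservation in R.

When the same transcription factor (TF) is profiled by ChIP-seq in several
related species, a set of linked questions follows: which genes are bound in
their promoters, which of those binding events are conserved across the
species, whether conserved binding sites are under stronger purifying
selection, and whether they matter more for gene regulation. `cistromediv`
implements this analysis chain for plant-style genomes — the motivating use
case is a photosynthesis-activating TF family bound at `RGATTYY`-type motifs
in five species — with every stage exercisable on a bundled synthetic-cohort
generator, so the whole pipeline is testable without any sequencing data.

## What it computes

- **Promoter target assignment** — narrowPeak summits are filtered on IDR
  and summit signal fold-change, resized to ±75 bp regions, and assigned to
  the gene whose species-specific upstream promoter window (e.g. 1.5–2.5 kb)
  contains the summit, nearest TSS first.
- **Conservation levels** — targets of a focal species are placed in
  orthogroups (OrthoFinder `Orthogroups.tsv` input) and each gene's
  conservation level is the number of species whose orthogroup members
  include a target, `1..S`. A category conservation score
  `sum(shared species pairs per orthogroup) / (N_og * C(S,2))` quantifies
  conservation of functional gene classes, and Fisher's exact test (BH
  corrected) measures category enrichment.
- **Selection on motifs** — IUPAC-consensus (or log-odds PWM, score > 6)
  motif hits are split into TF-bound versus open-chromatin-unbound
  background; per-site nucleotide diversity
  `pi = n/(n-1) * (1 - sum p_k^2)` is averaged over motif positions and the
  classes compared with a one-sided two-sample Kolmogorov–Smirnov test
  (`D+ = sup_x F_A(x) - F_B(x)`, `p = exp(-2 D+^2 mn/(m+n))`).
- **Sequence grammar** — a bag-of-k-mers classifier (canonical 7-mer counts,
  sparse logistic regression) separates bound summit windows from open
  chromatin and reports the top-weighted k-mers.
- **Regulatory potential** — a balanced-resampling random-forest predictor
  of differential-expression status from binding strength, summit–TSS
  distance, wild-type expression and binary TF co-binding features
  (point-biserial filter at |r| ≥ 0.1), with 500 resampled models, feature
  ablation and mean impurity importance.
- **Duplication retention** — duplicate gene pairs are classified by whether
  both / one / neither copy retains TF binding; binding concordance is
  Kendall's tau-b and expression correlation across tissues is compared
  between retention classes with a one-sided Welch t-test.

## Worked example

```r
library(cistromediv)

cfg <- cohort_config(n_orthogroups = 200, n_duplicate_pairs = 60, seed = 3)
co  <- generate_cohort(cfg, "cohort")           # writes the cohort files
pc  <- pipeline_config(co, n_models = 20, num_trees = 100, seed = 3)
res <- run_all(pc, "reports")

res$conservation$groups
#>  1  2  3  4  5
#> 39 28 11 11 12

res$integration$deg_overlap$pct_down
#> [1] 83.33

round(c(D = res$diversity_test$D, p = res$diversity_test$p), 4)
#>      D      p
#> 0.3854 0.0000

res$predictor$ablation
#>        group  mean_auc   delta_auc
#> 1     signal 0.7477811 -0.02680721
#> 2   distance 0.7511607 -0.03018684
#> 3 expression 0.6750942  0.04587963
#> 4  cobinding 0.5478753  0.17309854
```

Reading the output: of the 101 recovered promoter targets, 39 are
species-specific (level 1) and 12 are bound in all five species (level 5);
83.3% of the target DEGs are down-regulated in the TF mutant; bound motifs
have significantly lower nucleotide diversity than unbound open-chromatin
motifs (one-sided K–S, p < 1e-7), the planted signature of purifying
selection; and removing the co-binding features causes by far the largest
AUC drop in the DEG predictor (0.17), as planted — at this toy cohort size
the small positive/negative drifts of the other groups are resampling noise.

A shell front end with the same stages is installed as
`exec/cistrome-div` (subcommands `simulate`, `assign`, `scan`, `kmer-train`,
`conserve`, `diversity`, `run-all`).

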