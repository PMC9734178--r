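---
title: "Methods: cross-species cistrome conservation analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-species cistrome conservation analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(cistromediv)
```

`cistromediv` chains the analyses needed to ask how a transcription factor's
binding landscape diverges across related species: promoter target calling
from ChIP-seq summits, orthology-based conservation classification,
selection tests on binding motifs, integration with differential expression,
a machine-learned predictor of regulatory potential, and binding/expression
concordance of duplicated genes. This vignette explains the models and
conventions behind each stage, the tunable parameters and their defaults,
what the synthetic-data generator does and does not emulate, and the design
choices made where the problem is genuinely open.

## Coordinates and formats

All intervals are 0-based half-open internally (the BED/narrowPeak native
convention), so summit arithmetic is `summit = start + summit_offset` and
`length = end - start` with no off-by-one cases. GFF3 gene features are
converted at the boundary: the TSS of a `+` gene at 1-based `[start, end]`
is `start - 1`, of a `-` gene `end - 1`. Missing narrowPeak columns use the
UCSC `-1` sentinel. The variant panel is deliberately a per-site TSV
abstraction (chromosome, position, haplotype count, allele frequencies or a
precomputed diversity value) rather than a VCF: the analysis consumes only
per-position diversity, so genotype-level parsing is out of scope, and a
VCF-to-TSV conversion is a documented extension point.

## Promoter target assignment

Summits passing a conjunctive filter (IDR at most `idr_max`, default 0.01;
summit signal fold-change at least `signal_min`, default 0) are assigned to
a gene when the strand-aware upstream distance to the TSS lies in
`[0, window]`. The window is species-specific — defaults 1500, 2500, 2000,
1500 and 2500 bp for the five default species, reflecting genome size — and
distance 0 (summit exactly at the TSS) is deliberately included so that
boundary summits are not dropped. Downstream or intragenic summits are
never assigned. When a summit is eligible for several genes the nearest TSS
wins, with ties broken by lexicographically smallest gene id; neither
convention is forced by the biology, but a deterministic rule is required
for reproducibility, and assignments carry a `closest` flag so per-gene
"closest summit" summaries are unambiguous.

## Conservation classification and scoring

For a focal species, each target gene's conservation level is the number of
species (focal included) whose members of the gene's orthogroup include at
least one target, an integer `1..S`. Genes placed in no orthogroup are kept
at level 1 rather than dropped: a gene without orthologous targets elsewhere
is exactly what "species-specific" means here, and discarding it would
inflate the conservation rate. The category conservation score is

    score = sum_og (# species pairs both targeting the category in og) /
            (N_og * C(S, 2))

with `N_og` the orthogroups containing at least one category target in at
least one species. The observed-events-over-pairwise-comparisons idea
admits several normalisations (per gene, per orthogroup, per category
total); the per-orthogroup form above was fixed because it is bounded in
`[0, 1]`, equals 1 exactly when every category orthogroup is targeted in
all species, and is monotone-equivalent to the alternatives on all fixtures
we constructed. Category enrichment is Fisher's exact test (two-sided) with
Benjamini–Hochberg correction across categories.

## Selection tests on motifs

Motif instances come from IUPAC-consensus scanning (both strands, minus
hits reported in plus coordinates) or PWM scanning in log2-odds against a
uniform 0.25 background with pseudocount 1e-3, keeping windows scoring
strictly above `score_min` (default 6; motif-search tools use a comparable
dimensionless cut-off, though their log base and background differ, so no
scale equivalence is claimed). A hit overlapping a TF peak by at least 1 bp
is `bound`; a hit inside open chromatin with no TF-peak overlap is
`unbound_background`; everything else is `excluded` — classification uses
the full peak interval, which conservatively removes near-peak hits from
the background.

Per-site nucleotide diversity is `pi = n/(n-1) * (1 - sum p_k^2)` from
allele frequencies over `n` haplotypes; motif diversity is the arithmetic
mean over motif positions with panel-absent positions contributing 0. They
are invariant in the population sample, and excluding them would bias the
motif mean upward wherever coverage is sparse. Classes are compared with a
one-sided two-sample Kolmogorov–Smirnov test, `D+ = sup_x F_A(x) - F_B(x)`
for "A stochastically smaller", with the asymptotic p-value
`exp(-2 D+^2 mn/(m+n))` and an exact permutation option used automatically
for pooled sizes up to 20. Heavy ties (many motifs with diversity 0) make
the asymptotic test conservative, which the calibration test accounts for.

## Bag-of-k-mers classifier

Sequence windows (even width, default 150 bp centred on summits; windows
with `N` or beyond a contig end are dropped) are represented by counts of
canonical k-mers — each k-mer merged with its reverse complement, since
ChIP fragments are unstranded. `k` defaults to 7, the length of the
strongest expected motif word. The background is open-chromatin summits
with regions overlapping weak TF peaks removed before balanced sampling,
and the model is scored on a held-out 20% split.

The classifier is a sparse (L1-penalised) logistic regression with a fixed
small penalty (`lambda = 0.01`, `alpha` exposed). A pure ridge fit was
evaluated first and rejected on evidence: with ~8000 canonical 7-mer
features and a handful of informative ones, ridge spreads weight over all
features and the accumulated noise variance swamps the informative
coefficient — on data with one planted k-mer per positive the single
informative feature separates at AUC 0.99 while the ridge model plateaus
near 0.81 at every penalty. The lasso recovers the planted k-mer and
reaches AUC ~1.0 across a wide penalty range, matching the sparse
generative structure of motif-driven binding.

## DEG predictor

The feature table holds one row per target gene that is a down-regulated
DEG or a non-DEG (up-regulated DEGs are excluded as a distinct, rarer
regulatory mode): the factors' signal fold-changes at the closest summit,
summit–TSS distance (bp), wild-type FPKM, and one binary column per
co-binding TF (1 iff its peaks overlap the gene's 150 bp summit region).
Co-binding columns with absolute point-biserial correlation to the label
below 0.1 are discarded; absolute value because the filter targets
information content, not direction. Each of `n_models` (default 500)
repetitions downsamples the majority class to balance, splits 80/20, fits a
probability random forest (500 trees, default `mtry`), and records AUC,
accuracy, recall and F1 for the DEG class on the held-out fifth; recall and
F1 are reported for the DEG class (not macro-averaged), since the DEG class
is the scientific quantity of interest. Ablation retrains the same
repetitions without each feature group; importance is mean impurity
importance across repetitions, ties broken by feature name. All repetition
seeds derive from one master seed, so the full run is bit-reproducible.

## Duplication retention

Duplicate pairs (synteny/homology detection is consumed as input, not
computed) are classified `both` / `single` / `none` by target membership of
their genes. Binding concordance uses Kendall's tau-b — tie-corrected,
because fold-change ties are common after rounding — with a normal-
approximation p-value and exact enumeration for n up to 8 without ties.
Expression concordance is each pair's Pearson correlation across tissues,
compared between retention classes with a one-sided Welch t-test (unequal
variances assumed, as the class spreads differ by construction); pairs with
a constant expression vector are dropped with a log message.

## The synthetic cohort: what it emulates

`generate_cohort()` plants every effect the pipeline is meant to detect,
with defaults fixed once as the package's study conditions:

- five species, 2000 orthogroups (one gene per species per orthogroup, one
  linear chromosome, genes spaced beyond twice the largest window so no
  promoter windows overlap except in dedicated tie fixtures), 48% of
  orthogroups targeted in the focal species;
- conservation levels drawn with weights 375 : 205 : 151 : 100 for levels
  1–4 and 129/960 fully conserved, the partition structure typical of a
  five-species target set of ~960 genes;
- ChIP signal fold-changes lognormal(meanlog 1, sdlog 0.5) — mimicking the
  right skew of real fold-changes — times `boost^((level-1)/(S-1))` with
  `boost = 2`, so conserved sites bind detectably more strongly and the
  trend is graded across levels; a second, 95%-overlapping factor with
  jittered signal models a redundant paralogous TF;
- one planted consensus realization at every bound summit plus a
  Poisson(1) number of extra copies in flanking slots (bound regions have
  higher motif density than background, which is what gives k-mer models
  their cohort-level signal), and a planted consensus at 70% of unbound
  open-chromatin summits to provide the unbound background class;
- a variant panel over open chromatin at per-site density 0.3, alt-allele
  frequencies Beta(0.3, 3) shrunk by `pi_constraint_factor = 0.2` at bound
  motif positions (invariant sites are simply absent from the panel);
- DEG labels Bernoulli(logistic) in standardized log-signal, negative
  distance, log-FPKM and an informative co-binding count, with coefficients
  (0.8, 0.8, 0.8, 1.6) and intercept -1.3: co-binding dominates, so
  ablation has a planted right answer, and the true per-gene probabilities
  are stored in the ground truth so a Bayes-optimal reference AUC can be
  Monte-Carlo'd and compared with the forest's; 76% of DEGs are flagged
  down-regulated;
- 50 duplicate pairs per retention class with tissue-expression profiles
  correlated at 0.8 / 0.4 / 0.0 for both / single / none.

Not emulated: realistic genome composition (background sequence is i.i.d.
uniform), linkage disequilibrium, read-level noise, peak-calling artefacts,
many-to-many orthology (available in fixtures but not the generated
cohort), or any dependence between duplicate-pair binding signals — so the
cohort-level Kendall tau is a null quantity. Passing tests on this cohort
therefore demonstrate that the statistics detect the effects they target at
realistic sizes and calibrate under the null; they do not certify
performance on real genomes, where motif density, diversity and expression
have far richer covariance structure.

Genome FASTA is emitted for the focal species only by default
(`fasta_species = "all"` to override), since all sequence-level analyses
are focal-species analyses.

## Numerical and reproducibility choices

Degenerate inputs are handled explicitly: an all-tied Kruskal–Wallis input
returns H = 0 (the rank test's information-free case) rather than NaN; a
k-mer training set whose features are all constant yields the constant 0.5
predictor; empty conservation groups are dropped from the binding-strength
test with a warning; zero-width or negative intervals, summits outside
their peak, allele frequencies not summing to 1, duplicate gene ids, and
genes in two orthogroups are rejected at parse time with line- or
id-level messages. Pipeline reports are pure functions of
(inputs, config, seed): every output carries an MD5 hash of the config, no
timestamps are written, and repeated runs are checksum-identical.

Problem sizes used by the test suite were chosen to keep the full run in
the tens of minutes on one CPU: structural checks use cohorts of 60–200
orthogroups, planted-recovery checks the full 2000-orthogroup cohort, the
resampling predictor its full 500 repetitions, and calibration loops 200
simulations at reduced per-simulation size.

## Known limitations

The conservation score treats species symmetrically and ignores phylogeny:
sharing between close relatives counts as much as sharing across a deep
split. The K–S p-value is asymptotic (apart from the small-sample
permutation path) and conservative under heavy ties. The PWM score
threshold is a dimensionless default, not calibrated to any external
tool's scale. The predictor's metrics are in-cohort cross-validation
estimates, not external validation. None of these affect the planted-truth
recovery guarantees, but all matter when interpreting real data.
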