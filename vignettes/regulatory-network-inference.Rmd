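---
title: "Reverse-engineering a leaf transcriptional network: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reverse-engineering a leaf transcriptional network: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(leafnet)
```

# The problem

A leaf's transcriptional program can be read from two complementary data
sources: a compendium of expression profiles over many experimental
conditions, and the occurrence of transcription-factor binding motifs in gene
promoters. `leafnet` reverse-engineers a regulatory network from these in two
stages:

1. **Transcriptional module discovery.** A module is a set of co-expressed
   genes whose promoters share a combination of sequence motifs — rendered as
   an IF-THEN rule ("IF motif A AND motif B occur, THEN expression correlates
   with the center gene at \(\tau\) or better").
2. **Regulatory mechanism inference.** For every module, the set of
   transcription factors (TFs) whose expression best predicts the module's
   expression is found by growing a least-squares regression model with
   pairwise interaction terms:
   \[
   m_i \;=\; \beta_0 + \sum_{j \in R} \beta_j t_j
           + \sum_{j<k \in R} \beta_{jk}\, t_j t_k ,
   \]
   where \(m_i\) is the module profile, \(t_j\) the profile of TF \(j\), and
   \(R\) the regulator set. The sign of a cross term \(\beta_{jk}\) separates
   synergistic (\(\beta_{jk}>0\)) from competitive (\(\beta_{jk}<0\))
   regulation of the module by the TF pair.

The network (TFs and modules as nodes, an edge when a TF belongs to a
module's best mechanism) is then validated by bootstrap resampling of
conditions, leave-one-experiment-out prediction, and — through a homolog
map — by asking whether a mechanism trained in one species still predicts
expression of the homologous genes in another.

# Module discovery

For every gene in turn as *center*, and every correlation threshold
\(\tau \in \{0.50, 0.55, \dots, 0.95\}\), the co-expressed set is all genes
whose Spearman correlation with the center is at least \(\tau\). Two details
matter:

* **Pairwise-complete Spearman.** Correlations are computed only over
  conditions where both genes were measured, and ranks are assigned on that
  shared subset (column-wise ranking followed by pairwise deletion gives a
  different, biased statistic). A pair with fewer than `min_overlap = 10`
  shared conditions has no defined correlation and is treated as not
  co-expressed; the cut avoids spuriously perfect correlations from tiny
  overlaps.
* **The center belongs to its own co-expressed set** (its self-correlation is
  1), matching the reading of a module as a correlation neighborhood around a
  centroid gene.

Motif combinations of size 1–5 are searched level-wise, frequent-itemset
style: a combination is expanded only while at least `min_pos = 5` of its
carrier genes are co-expressed. This support pruning is anti-monotone —
adding a motif can only shrink the carrier set — so the search is exhaustive
over all combinations that could still produce a rule. A combination is
emitted as a rule when at least 5 carriers are co-expressed and at most
`max_neg = 50` carriers are not. Note that the negative count is *not*
anti-monotone (it can fall below 50 as motifs are added), which is why
expansion continues past combinations that fail only the negative cap.

Rule significance is the upper-tail hypergeometric probability of the
carrier/co-expressed overlap, with the *study genes* as universe — using the
leaf-specific gene set rather than a whole genome as background keeps
generically leaf-associated signals from dominating. The false discovery
rate is controlled at 0.05 by Benjamini–Hochberg, applied jointly across all
rules from all centers and thresholds (the FDR procedure is a design choice;
BH is the standard reading of "FDR-controlled").

Overlapping rules then compete for a representative library: rules are
ranked by p-value (ties broken by larger positive set, then center id,
threshold and motif ids, so selection is deterministic), and a rule becomes
a module only if the Jaccard index between its member set and every accepted
module's member set is at most `max_overlap = 0.5`. The competition
algorithm is intentionally simple and parameterized; greedy
selection-by-significance with a Jaccard cap is our choice where the
literature leaves the mechanism open.

Per-experiment co-expression (used to ask *where* a module is active) is a
permutation test: the mean pairwise Spearman correlation among members
within one experiment's conditions is compared against the same statistic
for random equal-sized gene sets (1000 draws by default, add-one empirical
p-value). Flags are descriptive; no correction is applied across
experiments.

# Mechanism inference

The module's response is the **concatenation** of its member genes' profiles,
with each TF's predictor tiled once per member. Concatenation makes all rows
of one condition statistically dependent, which drives two design choices:

* **Cross-validation folds split by condition**, never by concatenated row —
  otherwise copies of the same condition would appear in both training and
  test folds and leak.
* The significance test for order growth uses \(n\) = the number of
  concatenated rows, as the correlations themselves are computed over those
  rows.

A condition at which any candidate TF is unmeasured is dropped for all member
genes (predictor completeness), so every candidate TF set is evaluated on the
same rows; missing member-gene values are dropped row-wise.

Model order grows from 1: all TF sets of order \(n+1\) are evaluated by five
iterations of 5-fold cross-validation (the fold partitions are shared across
candidate sets, so comparisons are paired), and the best challenger replaces
the incumbent only if its pooled out-of-fold predictions correlate with the
observed profile *significantly* better. Significance is Williams' t-test
for the difference between two dependent Pearson correlations (both
predictions share the observed variable), with the p-value Bonferroni
multiplied by the number of TF sets tested at the challenger's order. Orders
1–3 are searched exhaustively; order 4 only extends the incumbent set one TF
at a time, keeping the search tractable at realistic TF counts (~35 TFs give
~6.5k triples but ~52k quadruples). TFs that are themselves module members
are excluded — no auto-regulation — because a gene trivially "predicts" a
module it belongs to.

Numerical edge cases: the Williams statistic is undefined at correlations of
exactly \(\pm 1\) (the package errors there, as the determinant of the
correlation matrix collapses). During order selection, noiseless data
produce exactly this situation; the selection loop therefore first requires
the challenger's correlation to be *strictly* larger (otherwise growth stops
without a test), and treats a strictly-better challenger whose test
denominator degenerates as decisively better (p = 0). Ties between TF sets
with identical cross-validated correlation are broken lexicographically.
Coefficients reported for the selected mechanism are refitted on all data;
T-statistics are coefficient over standard error from the ordinary
least-squares fit.

The final network's TF out-degree distribution can be summarized by a
power-law fit \(y = a x^b\) in log-log space over TF out-degrees, reported
with its log-space \(R^2\).

# Validation

**Bootstrap.** `B = 100` resamples of the conditions are drawn with
replacement (about \((1-1/n)^n \approx 36.8\%\) of conditions are absent
from each resample — the hold-out set). The module library stays fixed;
mechanism selection is re-run per resample. Re-discovering modules per
resample would answer a different question (stability of the library, not of
the network) and is computationally prohibitive. Each resample's mechanism
predicts the module profile at that resample's hold-out conditions — all
member genes share one predicted profile — and per gene, predictions are
averaged over the resamples in which the condition was held out before
correlating with the observed profile. Hold-out correlations therefore never
involve conditions used for fitting in the same resample. Edge support is
the fraction of bootstrap networks containing each full-data edge.

**Leave-one-experiment-out.** Mechanisms are re-selected (not merely
refitted) with an entire experiment removed, then predict the held-out
conditions; a gene or module counts as predicted when its
observed-vs-predicted Pearson correlation is significantly positive
(one-sided t-test on r at the held-out sample size — the significance
criterion is a design choice). A mechanism planted only inside the held-out
experiment is invisible to training and fails this test, which is exactly
the diagnostic the analysis is meant to provide.

**Theoretical optimum.** Any method predicting one profile per module is
bounded by the within-module expression coherence; the reference predictor
is the per-condition mean member profile, and each gene's correlation to it
is the ceiling for that gene.

# Cross-species transfer

Mechanisms are projected through a best-hit homolog map (a partial function;
many-to-one source mappings are resolved upstream to best hits): member
genes and TFs are replaced by homologs and the **coefficients are carried
over unchanged** — the question is whether the TF-to-module relationship is
conserved, not whether a new model can be fitted in the target species. A
module lacking any homolog or target expression for a member or regulator is
reported as unmapped rather than scored. Conservation is the Pearson
correlation between the concatenated homolog profile and the carried-over
prediction; the default cut of 0.40 is configurable, and a data-driven
alternative is the 95th percentile of a null built by randomly reassigning
target genes to modules (sizes preserved, 1000 runs).

# The synthetic benchmark

Real compendium data entangle every stage; the generator plants known
structure so each stage can be scored:

* TF profiles are i.i.d. standard normal per condition. This deliberately
  discards temporal/condition autocorrelation: independent predictors make
  the regression identifiable and give recovery tests a sharp target.
* Each planted module has a latent profile computed from its planted
  mechanism; members add independent Gaussian noise (`noise_sd`), carry the
  module's motif combination, and every gene additionally carries each motif
  at `background_motif_rate`. Entries are masked missing independently.
* Experiment labels are contiguous near-equal blocks, enabling
  leave-one-experiment-out tests.
* Defaults mirror a realistic compendium: ~35 TFs, modules of at least five
  genes sharing 1–5 motifs, mechanisms of 1–4 TFs, mostly positive linear
  coefficients (88%) and slightly more synergistic than competitive cross
  terms (56% / 44%).
* For cross-species data, a conserved module keeps its mechanism (same TFs
  and coefficients, fresh target-species TF profiles); a *rewired* module
  draws a fresh mechanism whose regulator set is disjoint from the source
  regulators. The disjointness is intentional: rewiring means the
  regulators changed, and overlapping redraws would leave residual
  predictability that is neither conservation nor rewiring.

What passing on this benchmark does **not** show: robustness to correlated
TF profiles, condition-dependent regulation, non-Gaussian noise,
heteroscedastic arrays, or motif occurrence errors from real promoter
scanning. The benchmark checks the machinery, not the biology.

Test and benchmark problem sizes (60 genes, 10 TFs, 200 conditions, 4
planted modules of mechanism orders 1, 2, 3, 3; 20 generator seeds for the
noisy recovery study; B = 20 for the noiseless bootstrap check) were chosen
as the smallest configuration at which every stage's behavior is
distinguishable from chance with comfortable margins.

# Parameters at a glance

| Parameter | Default | Meaning |
|---|---|---|
| `thresholds` | 0.50–0.95 step 0.05 | co-expression threshold grid |
| `min_pos` / `max_neg` | 5 / 50 | rule support constraints |
| `fdr` | 0.05 | BH false discovery rate for rules and annotations |
| `max_combination_size` | 5 | largest motif combination searched |
| `min_overlap` | 10 conditions | pairwise-complete correlation floor |
| `max_overlap` | 0.5 | Jaccard cap in library selection |
| `reps` × `folds` | 5 × 5 | cross-validation scheme |
| `alpha` | 0.05 | order-admission and classification significance |
| `max_order` | 4 | largest TF set |
| `B` | 100 | bootstrap resamples |
| `conservation_threshold` | 0.40 | conservation correlation cut |
| `motif_distance_threshold` | 0.3 | PFM redundancy cut |
| `n_perm`, `n_runs` | 1000 | permutation/randomization draws |

# Known limitations

* The motif distance is a column-correlation score over the best ungapped
  offset (both strands, `min_overlap = 4` columns); dedicated motif
  comparison tools use information-content weighting or p-value calibration.
  The distance function is pluggable for exactly this reason.
* Exhaustive search stops at order 3; a mechanism of four TFs is found only
  if three of them already win at order 3.
* Hold-out significance treats conditions as exchangeable; experiments with
  strong internal correlation will look more predictable than they are.
* GO-style annotation ancestors are not propagated; annotation tables are
  taken as flat sets.
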