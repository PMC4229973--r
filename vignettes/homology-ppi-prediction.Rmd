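---
title: "Predicting protein-protein interactions from homologous interactions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting protein-protein interactions from homologous interactions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(homppi)
```

## The problem and the model

Experimentally mapped interactomes are incomplete, so a long-standing
strategy is homology transfer: two query proteins are more likely to
interact if proteins homologous to them are already known to interact
(the interolog idea). `homppi` implements a probabilistic version of this
idea. For a query pair $(S_A, S_B)$ it computes three features against a
*training reference* (a set of known interacting pairs, their domain
assignments, and the interaction network they span) and feeds them to an
Averaged One-Dependence Estimator (AODE).

**Template similarity (F_Seq).** Among all combinations of a similarity
hit for $S_A$ and a hit for $S_B$ whose subjects form a known interacting
pair, the combination minimizing $\sqrt{e_A^2 + e_B^2}$ is selected, and
the four values $(e_A, \mathrm{mincov}_A, e_B, \mathrm{mincov}_B)$ become
features. The coverage of a hit is the number of positive-scoring
alignment positions divided by the longer sequence length. A permissive
e-value cutoff of $10^2$ keeps partial matches. When no interacting
template pair exists, the sentinel $(10^2, 0, 10^2, 0)$ is used. Ties in
the norm are broken by smaller $e_A$, then larger coverage sum, then
lexicographic template ids, so the selection is deterministic.

**Domain-pair propensity (F_Dom).** Every labeled training pair
contributes each *distinct unordered* domain pair formable between its
two proteins' domain sets once to a class-conditional frequency table
$F(c, d_x, d_y)$. The propensity of a domain pair is the natural-log
ratio of its class-relative frequencies. Because many pairs are never
seen in one class, an additive pseudocount $a$ (default 1) is applied to
every stored pair, with the class totals inflated by $Na$:
$$\mathrm{propensity}(d_x,d_y) =
 \ln\frac{(F(+,d_x,d_y)+a)/(S_+ + Na)}{(F(-,d_x,d_y)+a)/(S_- + Na)}.$$
The feature is the mean propensity over all domain pairs of the query
(unseen pairs contribute 0 but count in the denominator); a protein
without domain assignments yields 0. The log base only rescales the
feature and is immaterial after discretization.

**Network proximity (F_Net).** A network is built over the training
positives (constant edge weight, default 1.0). For every pair of
homologs $(p_A, p_B)$ of the two queries — hits at a stringent cutoff of
$10^{-3}$ — the shortest-path weight (SPW) is computed by Dijkstra's
algorithm, and the minimum over combinations is the feature. An SPW of 0
means a homolog of both queries is the same protein (the zero-length
path; no self-loop edge is required), 1.0 a directly interacting homolog
pair, and $n + 1$ a pair indirectly linked by $n$ proteins. The sentinel
$-1$ encodes "no path anywhere", which is itself informative.

## Order invariance and discretization

A pair is unordered, but F_Seq depends on which protein is called A. Of
the two encodings (a point and its coordinate swap), the package keeps
the one lying in a fixed half-space: with the reference point
$X_1 = (0, 1, 100, 0)$ and its swap $X_2$, the reference normal
$rn \propto (-100, 1, 100, -1)$ is anti-symmetric, the midpoint term
vanishes, and the kept orientation is the one with $rn \cdot F_{Seq} \ge 0$.
On the hyperplane itself both encodings are equivalent and the input
orientation is kept; together with canonical pair storage
($id_A \le id_B$) this is deterministic. Fixing $X_1$ as a constant (any
non-symmetric point works) makes fitted models serializable and
reproducible.

Canonicalized training vectors are then discretized per feature with the
Fayyad–Irani minimum-description-length method: recursive binary splits
at the entropy-minimizing midpoint between consecutive distinct values,
accepted only when the information gain exceeds
$(\log_2(n-1) + \Delta)/n$. Candidate cuts are evaluated at every
distinct-value midpoint; the classical restriction to class-boundary
points is an optimization that provably selects the same cut, so the
simpler candidate set is used. Values exactly on a split point fall in
the right bin. The sentinels ($100$, $0$, $-1$) are discretized as
ordinary reals — they are feature *values*, and the discretizer routinely
isolates them into their own bins. A feature with no accepted split
collapses to a single bin and becomes uninformative, which is the
desired behaviour for a feature carrying no class signal.

## The classifier

The AODE averages one-dependence estimators — Bayesian classifiers in
which every feature depends on the class and one shared parent feature:
$$\hat P(+\mid f_1,\dots,f_n) = \frac{\sum_i \hat P(+, f_i) \prod_{j \ne i}
\hat P(f_j \mid +, f_i)}{\sum_{c} \sum_i \hat P(c, f_i) \prod_{j \ne i}
\hat P(f_j \mid c, f_i)}.$$
The base estimates use Laplace smoothing,
$\hat P(c, f_i) = (F(c,f_i)+1)/(m_i + k v_i)$ and
$\hat P(c, f_i, f_j) = (F(c,f_i,f_j)+1)/(m_{ij} + k v_i v_j)$, where
$m_i$ ($m_{ij}$) counts training vectors with the feature(s) known, $k = 2$
classes and $v_i$ the number of bins. Conditionals are the quotient of
the two joints (and can exceed 1 because the two smoothing masses
differ — harmless, as only ratios across classes matter). Every known
feature serves as a parent: no minimum parent-frequency cutoff is
applied, staying literal to the averaged estimator. Products are
accumulated in log space. Missing features are skipped in both sums and
products; a vector with all features missing has no parent and is an
error. The Naive Bayes baseline reuses the same tables as
$\hat P(c)^{1-q}\prod_i \hat P(c, f_i)$ over the $q$ known features,
which makes it *exactly* equal to the AODE when a single feature is used
— a useful internal consistency check.

Note one subtlety of Laplace smoothing: duplicating the training set
doubles every count but does **not** leave posteriors invariant (the
+1 is not doubled); the package's tests assert the true behaviour.

## Evaluation protocol

Interaction data are extremely imbalanced; the package follows the
common construction of sampling non-interacting pairs uniformly from the
proteins of the positive set — 400 negatives per positive by default —
excluding positives and self-pairs. Performance is measured by ROC
AUC (tie-grouped trapezoid, equal to the Mann–Whitney statistic with
half-credit for ties), the normalized partial AUC up to a small FPR
(raw partial area divided by the cutoff, so a perfect model scores 1;
default cutoff 0.5%), MCC and the F-measure, with the conventions that a
zero denominator yields MCC 0 and $TP = 0$ yields F 0. A decision
threshold can be chosen as the score maximizing the F-measure over
pooled cross-validation scores (ties toward the smallest threshold).

Cross-validation is stratified by class and, crucially, *leakage-free*:
for every fold the whole feature context — template positives,
propensity table, network, half-space reference, discretization scheme
and classifier counts — is rebuilt from the training folds only.
Otherwise a test positive would trivially find itself as a template at
e-value 0 and SPW 1. The audit (`leak_templates` / `leak_edges` columns)
verifies programmatically that no test pair occurs among that fold's
templates or edges. Fold assignment sorts pairs by (label, canonical
key) before the seeded shuffle, so results are invariant to input row
order. The per-fold AUCs of two configurations can be compared with an
equal-variance two-sample t-test (`compare_auc_ttest`); with 10 folds per
run this is an unpaired test on the per-fold values.

An optional evaluation filter (`exclude_zero_evalue_templates`) drops
test pairs for which an interacting template is found with both e-values
exactly 0, i.e. pairs whose answer is already in the database — useful
when the question is true predictability of novel interactions rather
than retrieval.

## The synthetic generator

Real benchmarks derive from curated interaction databases that cannot be
bundled; the generator emulates their *structure* so every part of the
pipeline is testable self-contained. A latent template network
(Erdős–Rényi by default; preferential-attachment "scale-free" as an
option, since real interactomes are heavy-tailed and SPW distributions
depend on topology) is populated with query proteins, four per template
on average. Hits are simulated directly at the interface the package
consumes: a self-hit at e-value 0, family hits log-uniform in the
configured range (default $10^{-40}$–$10^{-5}$, comfortably inside the
$10^{-3}$ network cutoff), and occasional spurious hits at
$10^{-1}$–$10^{2}$ that pass only the permissive template-search cutoff,
adding realistic F_Seq noise. With probability `signal_strength` a
positive pair is drawn from a template-network edge (its family members
share domains, so domain pairs spanning template edges are automatically
enriched among positives); otherwise it is a uniformly random pair.
At `signal_strength = 0` positives are distributionally identical to the
sampled negatives, so any evaluation must return chance performance — a
null-calibration the acceptance checks exploit. Sequences are random
amino-acid strings generated only to satisfy FASTA round-trips and
length fields; e-values are simulated, not computed from alignments.
Defaults (2,000 proteins, 5,000 positives, ratio 400) mirror the scale
of the human benchmark this protocol is modeled on; tests use reduced
sizes (e.g. 200 proteins / 300 positives / ratio 50, and 10-fold CV),
which keeps the full planted-signal evaluation around a minute on one
CPU. What passing tests show is that the pipeline recovers a planted
homology/topology signal and is honest under a null; they do not show
calibration on real interactomes, whose degree distributions, homology
structure and annotation biases the generator does not attempt to match
quantitatively.

## A worked run

```{r example, eval = FALSE}
ds <- generate_synthetic(synthetic_config(
  n_proteins = 200, n_positive = 300, neg_ratio = 50,
  signal_strength = 1, seed = 11))
cv <- kfold_cv(ds$pairs, ds$domains, ds$hits, k = 10, seed = 3)
cv
spw_distribution(ds$pairs, ds$domains, ds$hits, k = 10, seed = 3)
```

On this configuration the AODE reaches a mean AUC around 0.93, and the
SPW table shows the planted pattern: positives mass at SPW $\le 1$,
negatives spread over larger weights and "NP".

## Numerical choices and limitations

* E-values are parsed as doubles; exact 0 is legal (identical-sequence
  self-hits) and is what the zero-e-value exclusion filter keys on.
* All hit rows are retained (no best-hit-per-subject collapse); the
  feature operations select their own minima, and self-hits are included
  — the exclusion filter handles the retrieval-leak case.
* Coverage is clipped to [0, 1]; gapped alignments can otherwise push
  positives past the longer sequence length.
* `spw` returns `Inf` for "no path" at the network layer; the feature
  layer maps it to the sentinel $-1$.
* MCC uses double arithmetic to avoid integer overflow at
  realistic negative counts ($\sim 10^6$ per fold).
* The propensity pseudocount, e-value cutoffs, edge weight, fold count
  and pAUC cutoff are all exposed as arguments with the defaults above.
* Only constant edge weights are implemented; interaction-type or
  annotation-similarity weighting is out of scope, though the weight
  field exists.
* Known limitation: with very few distinct feature values the MDL
  criterion can reject all splits, collapsing a feature to one bin; this
  is by design (no signal, no split) but means tiny datasets may yield
  constant posteriors.
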