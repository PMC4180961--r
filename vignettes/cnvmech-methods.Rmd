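---
title: "Methods: classifying deletion CNVs by boundary disruption and gene dosage"
author: "cnvmech maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: classifying deletion CNVs by boundary disruption and gene dosage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnvmech)
```

# Overview

`cnvmech` classifies pathogenic deletions by their most plausible effect
mechanism. The model has four ingredients: (i) a phenotype ontology with
information-content (IC) weighting, (ii) semantic similarity scores between a
patient's phenotype profile and individual genes, (iii) an interval model of
topological domains, their boundaries, genes and tissue-specific enhancers,
and (iv) a decision lattice combining them, with permutation null models to
judge cohort-level signal.

The package assumes deletions act through one of two mechanisms:
haploinsufficiency of deleted genes (gene-dosage effect, GDE), or enhancer
adoption after a topological domain boundary is deleted (TDBD), where an
enhancer and a phenotypically relevant gene that used to be insulated from
each other end up in one regulatory neighbourhood. Everything else is
reported as `unexplained`; patients whose phenotype cannot be pinned to one
tissue-linked target branch are `not_assessed`.

# Ontology and information content

The ontology is a rooted DAG of phenotype terms connected by `is_a` edges.
Annotations propagate upward: an entity annotated to a term is implicitly
annotated to all its ancestors, so every propagated set is ancestor-closed.
For a corpus of annotated entities, the frequency of term $t$ is
$p_t = (\text{entities with } t)/(\text{all entities})$ and
$IC(t) = -\ln p_t$.

Numerical choices:

* **Log base.** Natural log. The base uniformly rescales every score and can
  never change an argmax or a comparison; reported score magnitudes should
  not be compared against scores computed in another base.
* **Never-annotated terms.** $IC$ is undefined at $p_t = 0$; such terms
  carry no IC value and simply drop out of maxima and sums (they contribute
  no corpus evidence). They are *not* given infinite IC.
* **Ancestor convention.** Both `ancestors()` and `descendants()` include
  the query term itself. This makes an exact patient–gene term match score
  $IC(t)$, as it should.
* **Separate corpora.** IC tables are corpus-specific: the patient corpus
  drives target-term assignment, and a disease/gene corpus drives
  phenomatch scoring. A cross-species corpus can be swapped in by loading a
  different annotation table; nothing else changes.

# Patient-gene similarity

For gene $g$ with direct term set $T_g$ and a patient's propagated set
$\mathrm{annot}_j$, the common ancestors of a gene term are
$CA(t_g) = \mathrm{anc}(\mathrm{annot}_j) \cap \mathrm{anc}(t_g)$, and

$$S_g = \sum_{t_g \in T_g} \max\{IC(t) : t \in CA(t_g)\},$$

the phenomatch score. The phenogram score of a region is the *maximum*
$S_g$ over its genes — the analysis deliberately looks for a single best
explanatory gene rather than aggregating, because sparse clinical
annotation makes sums across genes noisy. An empty region scores 0, which
makes the "phenogram score above zero" GDE criterion automatically false
for gene-free regions.

**Open choice, resolved:** whether $T_g$ means the gene's direct terms or
its propagated closure. We sum over *direct* terms: summing over the
closure would count one biological match several times (once per ancestor).
The propagated variant is available behind `use_propagated = TRUE` and is
unit-tested, so the consequence of the choice is visible.

Target assignment intersects the patient's propagated set with each target
branch $desc(T_i)$ and assigns the branch with the strictly largest IC sum.
Tied maxima (detected with a $10^{-9}$ relative tolerance, since the sums
are floating-point) mark the patient `ambiguous`; no branch overlap marks
them `unassigned`; both are excluded from assessment, mirroring how such
cohorts are filtered in practice.

# Tissue-specific DHS ranking

Starting from read counts in fixed 200-bp windows, $X = \ln(c + 1)$, then
each sample's column is scaled by (grand mean raw count)/(sample mean raw
count). The usual prose description of this normalisation ("the logs of
the counts were normalised for depth") is ambiguous about whether scaling
applies to raw or logged values; we scale the *logged* values by default
and provide `mode = "scale-then-log"` for the other reading.

Per window, the pooled within-tissue sd is
$s = \sqrt{\sum_j \sum_{i \in C_j} (X_i - \bar X_j)^2 / \sum_j (n_j - 1)}$
and the specificity t-statistic for tissue $j$ is
$t_j = (\bar X_j - \bar X) / (\sqrt{1/m + 1/n_j}\,(s + s_0))$ with $s_0$
the mean of $s$ over windows (a regulariser against tiny variance
estimates, in the moderated-statistic tradition). Two details implemented
verbatim even though they are unusual: $\bar X$ is the
*unweighted mean of tissue means* (not the mean over samples — this matters
for unbalanced designs), and the scale factor uses $\sqrt{1/m + 1/n_j}$
with the tissue count $m$. Ties in $t_j$ break by genomic order so
rankings are deterministic.

Split-half reproducibility stratifies samples per tissue into two halves,
reruns the whole pipeline per half and reports the shared fraction of the
two top-$n$ lists over a grid of $n$. The curve maximum is located by
piecewise-linear interpolation over the grid, i.e. the argmax grid point;
with a strong planted signal of $k$ windows the curve peaks near $n = k$
(below $k$ the within-signal order is noise-dominated, above it the lists
dilute with noise windows). When a half ends up with single-sample tissues
(odd group sizes), those tissues contribute zero degrees of freedom to the
pooled sd; if *no* tissue has two samples in a half, rankings fall back to
scaled mean differences. RepeatMasker-style exclusions are modelled as an
optional window blacklist upstream of the matrix; read counting itself is
out of scope.

# Genome geometry

Coordinates are 0-based half-open (BED) everywhere. Boundaries are maximal
inter-domain gaps with $0 < \text{length} \le 400$ kb; larger gaps are
unorganized chromatin and never boundaries, and zero-length gaps (abutting
domains) are not boundaries either. "Completely overlaps" uses non-strict
inequalities, so shared endpoints count.

The adjacent regions of a deletion run from each breakpoint to the end of
the domain containing that breakpoint. A breakpoint in no domain falls back
to a fixed 400-kb flank — the same width as the boundary cap, and close to
the median observed breakpoint-to-boundary distance that motivates the
no-boundary control window. Genes and enhancers count as present in a
region on any ≥ 1 bp overlap; there is no principled overlap fraction for
membership of an element "between the breakpoint and the distal domain
end", and partial overlap is the permissive, convention-free reading.

Random placement is length-preserving and uniform over valid start
positions, with chromosomes weighted by $G - L + 1$. On a toy genome this
reproduces analytic complete-overlap probabilities exactly (tested at
$3\sigma$ of the binomial error).

# Classification lattice

Per assessed patient with target $T$ and tissue $\tau$:

* `tdbd_evidence`: the deletion completely covers ≥ 1 boundary, AND a
  $\tau$ enhancer overlaps one adjacent region AND a gene annotated
  (propagated) to $T$ overlaps the *other* adjacent region, in either
  orientation. The gene criterion is the discrete annotation to the target
  branch, not the continuous phenomatch score; the continuous score is used
  only for the split below and for GDE.
* `gde_evidence`: phenogram score over genes within the deletion > 0.
* Lattice: TDBD evidence with $S_{adjacent} > S_{within}$ (strict, "higher
  than") → `TDBD_only`; TDBD evidence otherwise with GDE evidence →
  `TDBD_GDE`; TDBD evidence otherwise without GDE evidence → `TDBD_only`
  (the vacuous-tie case the source leaves unspecified: without any
  within-deletion gene signal there is nothing to mix with); GDE evidence
  alone → `GDE`; otherwise `unexplained`.

The no-boundary control applies the same opposite-side signature within
fixed 400-kb flanks to deletions that cover no boundary, and refuses (by
error) to run on boundary-covering deletions.

# Null models and empirical P values

Two permutation schemes: (i) each patient receives the full annotation set
of a random patient from a *different* target group — sampling **with**
replacement, since the scheme is described as drawing "a randomly chosen
patient", not a matching; consequently only deletion coordinates are
invariant, not the multiset of annotation sets; (ii) gene identifiers are
permuted in the annotation table, holding the number of disease genes and
annotation depth constant. Empirical $P$ is the plain fraction
$\#\{null \ge observed\}/n$ with no $+1$ correction (a zero count is
reported as $< 1/n$), matching the reporting convention of a
$P < 10^{-4}$ floor at 10,000 replicates.

The replicate drivers recompute target assignment and classification per
replicate. Internally they use a precomputed cohort model in which each
(deletion, annotation-set) pair classifies in $O(1)$; the test suite
asserts this fast path is identical to the reference per-patient path, so
the optimisation cannot silently change semantics.

**Open choice, resolved:** the cohort rate can count `TDBD_only` or
`TDBD_only ∪ TDBD_GDE`; both are exposed (`rate =`). Sensitivity and power
statements in the acceptance tests use the union: both planted classes
carry the boundary-disruption signature, and the union is the statistic
with the full planted signal. The pure-TDBD rate remains available and is
reported alongside.

# The synthetic world

The generator emulates the four real inputs at reduced scale:

* **Ontology:** one root, 10 disjoint target branches (one per tissue),
  each a full 3-ary subtree of depth 3 (401 terms). Real phenotype
  ontologies are far larger and their branches share cross-links; the
  disjoint-branch simplification makes target assignment exact, which is
  what the recovery tests need.
* **Genes:** 3 per domain at fixed interior positions; 80% of genes carry
  1–5 phenotype terms drawn within a single target branch (emulating genes
  with a known monogenic disease); the unannotated fraction is honoured
  exactly.
* **Architecture:** 2 chromosomes × 200 domains of 0.6–1.4 Mb separated by
  gaps of 100–400 kb (boundaries), with 5% longer unorganized gaps; every
  domain carries one enhancer of each of the 10 tissues near its start —
  about the genome-wide density of 20,000 top sites per tissue spread over
  ~3,000 domains.
* **Cohort:** mechanism labels are allocated deterministically from the
  mixture fractions (exact counts, not multinomial draws, so recovery
  tests are exact). TDBD deletions cover exactly one boundary, contain no
  gene, and have the enhancer/target-gene signature across them with the
  patient's phenotype taken from the adjacent gene's own terms; mixed
  deletions additionally swallow a same-branch annotated gene and take the
  patient's terms from it (the generator verifies
  $S_{within} \ge S_{adjacent}$ at the candidate site and moves on
  otherwise); GDE deletions cover an annotated gene inside one domain;
  benign deletions sit in gene- and boundary-free territory with random
  single-branch phenotypes. Annotation noise — each planted term replaced
  by a uniformly random ontology term with the configured probability — is
  applied last. A `null_phenotypes` mode redraws every phenotype
  independently of geometry for calibration studies.
* **DNase counts:** Poisson background (mean 20) in 10,000 windows over
  4 tissues × 4 replicates; 200 planted windows per tissue have their mean
  multiplied by $e^2$ in that tissue's samples; per-sample depth factors
  (0.5–2×) exercise normalisation. Negative-binomial overdispersion is
  available via `dnase$size`.

What a green test does *not* establish: robustness to ontology
cross-links, to annotation sparsity at clinical scale, to domain calls that
disagree between cell types, or to enhancer maps with tissue-specific
absence; real cohorts also mix mechanisms within one patient in ways the
planted labels do not.

All randomness flows from one top-level seed through fixed per-module
offsets, so any component can be regenerated independently and runs are
reproducible byte for byte.

# Known limitations

* Domains are taken as given; deriving them from Hi-C contact matrices is
  upstream of this package, as is read alignment and window counting.
* Duplications are out of scope (the mechanism model is deletion-specific).
* The phenomatch corpus in the synthetic world is the gene-annotation
  corpus itself; with real data one would load disease-annotation
  frequencies instead.
* The discreteness of cohort rates makes empirical P values mildly
  conservative in small cohorts (ties count as extreme); the calibration
  test sizes its cohorts (120 patients) so the rate statistic takes enough
  distinct values for a meaningful uniformity check.
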