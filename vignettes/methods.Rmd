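---
title: "Scoring, calibrating and integrating tissue expression evidence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring, calibrating and integrating tissue expression evidence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tissuescore)
```

## The problem

High-throughput tissue expression surveys disagree on their units, their
error modes and even on what a "tissue" is. Microarray atlases report
normalized expression units per probe set; RNA-seq resources report
RPKM/FPKM; EST databases report sequence-tag counts per cDNA library;
mass-spectrometry maps report tryptic peptides per tissue sample; antibody
atlases report ordinal staining strengths. Comparing or combining them
requires (i) a common tissue vocabulary, (ii) a raw quality score per
(gene, tissue) within each platform, and (iii) a calibration of each raw
scale onto a common confidence scale. This package implements all three
steps plus the downstream analyses that the calibrated scores make
possible, and a synthetic-data generator rich enough to exercise every
stage.

## Tissue vocabulary

Tissue labels are resolved against an ontology structured as a directed
acyclic graph over is-a relations (the Brenda Tissue Ontology is the
canonical instance). Analyses are anchored on a configurable set of
*major tissues* — mutually non-ancestral terms (nominally 21) to which any
finer term is back-mapped through its ancestors, so a dataset probing six
brain sub-regions and a dataset probing whole brain land on the same
term. Matching is case-insensitive and exact, on names first and synonyms
second; no fuzzy matching is attempted, because an approximate match
invents a gene–tissue association rather than recovering one. Labels
naming more than one tissue ("retina and testis") are blacklisted. A term
inside a DAG can reach more than one major; its evidence is propagated to
every matched major, which is conservative and symmetric across datasets.
The major set is configuration, not a constant: the published selection of
21 terms is one choice among several defensible ones, and
`assert_non_overlapping()` verifies the only property the analyses rely
on.

## Per-dataset raw scores

Each platform has a scoring rule matching its measurement process:

| family | score | aggregation |
|---|---|---|
| expression units (3'-microarray) | normalized intensity | mean over a gene's probe sets, after removing `AFFX` controls and `_r/_i/_f/_x_at` multi-target probe sets |
| expression units (exon array) | normalized intensity | mean; no probe-suffix filter (the suffix convention is specific to the 3' arrays) |
| EST counts | tags per tissue | sum over a gene's clusters |
| RPKM / FPKM | length-normalized read density | used directly |
| peptide counts | distinct tryptic peptides per tissue | mean over samples sharing a tissue term (adult and fetal samples of one tissue) |
| IHC | consensus staining score | see below |

The in-silico digest cleaves after every lysine and arginine and
enumerates fragments spanning up to two missed cleavage sites. The
proline exception (no cleavage before P) is deliberately not applied: the
plain K/R rule is deterministic, and its fragment set is a superset of
the proline-aware one, so no observed peptide is missed by the matcher.
Peptides matching more than one gene are discarded — a unique-peptide
count is only evidence when the peptide is unambiguous.

## The IHC consensus score

A protein $p$ stained with $N_p$ antibodies over tissues $t$ receives

$$\mathrm{score}_{p,t} = \alpha \cdot \mathrm{quality}_p \cdot
\mathrm{level}_{p,t}, \qquad
\mathrm{quality}_p = e^{-\beta R_p^2 / N_p},$$

where $R_p^2 = \sum_{a,t} R_{a,t}^2$ with
$R_{a,t}^2 = (\mathrm{staining}_{a,t} - \overline{\mathrm{staining}}_{\cdot,t})^2$,
and the level is a disagreement-weighted average with weights
$1 - R_{a,t}^2 / R_p^2$. A single antibody keeps its raw staining values.
Numerical conventions: when $R_p^2 = 0$ the weights are the $0/0$ limit of
the definition, and uniform weights (the plain mean) are used — this is
the continuity limit of the weighted mean; a per-tissue zero weight sum
with $R_p^2 > 0$ is guarded by an unweighted-mean fallback with a
warning, although it cannot occur for $N_p \ge 2$ unless all disagreement
concentrates elsewhere. Multi-antibody scores are not clamped to the
single-antibody range: two agreeing antibodies at staining 6 score
$\alpha \cdot 6 = 18$ at the default $\alpha$, and the published IHC
cutoffs (1.1, 1.9) and star transform (score/5.5) presume this unclamped
scale.

### Choosing α and β

`fit_alpha_beta()` is an exhaustive grid search (default
$\alpha \in \{0.5, 1, \ldots, 5\}$, $\beta \in \{0, 0.1, \ldots, 2\}$);
the two-dimensional surface is cheap and a grid leaves no optimizer
tuning to document. The objective scores the staining data per candidate,
builds the fold-enrichment curve against the gold standard, and averages
the fold enrichment of the top quarter of windows. The restriction to the
top windows is load-bearing: for full windows the unrestricted mean over
windows equals the total gold-hit count divided by (window size ×
background), which does not depend on how the candidate parameters *rank*
a fixed association set — it is therefore constant across candidates and
cannot select anything. The top-window mean measures what the parameters
actually control, namely whether reliable evidence reaches the top of the
ranking. Ties are broken toward smaller β, then smaller α, preferring the
least aggressive correction among equivalent candidates.

## Calibration

Fold enrichment of an association set against a gold standard is the
fraction of its pairs found in the standard divided by the fraction
expected by chance, both computed after restricting to the genes and
tissues shared by the two sides. Sorting a dataset by score and
partitioning it into consecutive *disjoint* windows of 100 associations
traces fold enrichment as a function of score. Disjoint (rather than
sliding) windows give independent binomial errors and reproducible
points; each window is represented by its median score; a short final
window is kept only if it holds at least half a window, bounding the
variance of the last point without discarding the tail.

Four parametric forms map native scores to the unified 0–5 star scale:
$a \log_{10} s + b$, $A/(1 + B s^C) + D$, $a s + b$, and
$\min(a s, \mathrm{cap})$. The shipped defaults reproduce the published
per-dataset constants exactly; `fit_transform()` re-fits any form to a
user's curve (ordinary least squares for the linear forms,
Levenberg–Marquardt seeded by a logit-log regression for the sigmoid),
and `anchor_transform()` optionally rescales a fitted curve so that a
chosen anchor score maps to 2.5 stars — the published global
transformation onto stars is anchored on the text-mining evidence shared
with companion resources, and the anchoring choice is left explicit here
rather than hidden in constants. The text-mining transform is score/2.4
*capped at 4 stars*: the printed form is incomplete in the source table,
and 4 stars is the ceiling companion resources apply to text-mining
evidence, so the cap is the only reading that makes the entry a total
function. Confidence classes use boundary-inclusive cutoffs (a score
equal to a cutoff qualifies), so the published cutoffs themselves are
low/medium/high examples. Log-form transforms at non-positive scores
clamp to 0 stars with a warning.

## Integration analyses

All overlap analyses operate on association sets restricted to the
universe shared by the compared tables (their common genes and tissues);
the unrestricted variant is exposed for the coverage-complementarity
analysis, where the point is exactly what the restriction hides. Venn
patterns are exclusive bitstrings in declared set order, so counts
conserve mass. Percentages are rounded at a configurable precision (one
decimal by default) and the exact values are kept alongside, because a
summary that reports only rounded values cannot be composed further. The
mRNA reference set takes pairs classified high-confidence in at least
three datasets; the threshold is a parameter and the set shrinks
monotonically as it rises. The integrated-vs-single benchmark takes the
same number of top-scoring associations from the single dataset, breaking
ties at the cut rank lexicographically by gene then tissue so the
comparison is deterministic.

## The synthetic-data generator

The generator emulates the statistical structure the analyses assume,
not any particular dataset:

* **Truth.** Each of 20,000 genes is ubiquitous with probability 0.4
  (expressed in 19–21 of 21 tissues) or tissue-specific (1–3 tissues),
  tissues drawn uniformly — the bimodal breadth structure that the
  breadth analysis quantifies. The sizes match the scale of the real
  atlases while keeping a full pipeline run under half a minute.
* **Datasets.** Within each platform's gene/tissue coverage, expressed
  pairs escape dropout (2–5%) and draw from the expressed score
  distribution; unexpressed pairs emit background noise at rate 0.2–0.35.
  Continuous platforms use log-normal scores, count platforms
  negative-binomial (EST counts are strongly overdispersed; size 0.8).
  Two structural choices matter:
  the background shares the log-scale spread of the expressed
  distribution, making the likelihood ratio — and hence fold
  enrichment — monotone in the score; and tissue-specific genes carry a
  6–8× location lift, reflecting that specialized genes reach far higher
  expression in their target tissues than housekeeping genes do anywhere.
  The lift couples score to gold-standard membership (the gold standard
  is specificity-biased), which is what produces the steady rise of
  enrichment across the whole score range seen with real curated
  standards; without it, enrichment saturates as soon as windows are
  purely expressed records. Expressed-score locations are placed so the
  published medium cutoffs detect true expression with ~0.95–0.99
  sensitivity, mirroring the observation that the published cutoffs
  correspond to comparable quality across platforms.
* **Gold standard.** Each true pair enters with probability
  coverage × breadth^(−bias) (normalized so the most specific genes have
  weight 1; defaults 0.3 and 1). This reproduces both the incompleteness
  and the tissue-specificity skew of curated annotation.
* **Staining.** Antibody counts follow (0.5, 0.25, 0.15, 0.1) for 1–4
  antibodies. With probability `error_rate` a protein is a *difficult
  antigen*: all its antibodies report diffuse positive background
  staining (uniform over 1/3/6, independently per antibody and tissue).
  Correlating antibody failure within a protein is deliberate: the
  consensus quality factor can only be informative if between-antibody
  disagreement predicts that the consensus itself is unreliable. Under
  independent per-antibody or per-cell corruption, any surviving good
  antibody anchors the disagreement-weighted level, which is then already
  the better estimator, and the optimal β is 0; under the
  difficult-antigen model the disagreement flags precisely the proteins
  whose staining carries no signal, and a positive β wins the grid
  search — the behaviour reported for real multi-antibody data.
* **Determinism.** One global seed drives named substreams
  (`stream_seed(seed, "dataset:gnf")` etc.), so adding a dataset never
  perturbs the draws of another, and the full pipeline output is
  byte-identical across runs.

### What the generator does not emulate

Splice variants, probe-sequence effects, batch effects, correlated noise
beyond the shared truth (real platforms share systematic biases, so real
cross-dataset agreement overstates independent confirmation), and the
actual error structure of any specific atlas. Passing tests on this generator
demonstrate that the machinery is correct and that the analyses behave as
designed under the assumed structure — not that any particular biological
conclusion transfers to a given real dataset.

## Numerical and scale choices

* Window size 100 throughout; with per-window gold hits of order 5–20,
  the window fold-enrichment noise is 20–40%, which the curve-level
  statistics average out.
* The calibration check uses 6,000 genes, yielding ≈ 20,000
  gold-restricted associations (≈ 200 windows) for the continuous
  reference platform; the parameter-selection check stains 4,000
  proteins; the full-pipeline checks use the default 20,000 genes.
* For integer count scores, whole windows can fall inside blocks of tied
  scores whose internal ordering is arbitrary; the attainable window-rank
  correlation for the EST platform is therefore ≈ 0.87–0.89 rather than
  the > 0.9 the continuous platforms reach, and the tests assert the
  bound each family can meet.
* Sigmoid fits can in principle fail to converge on degenerate curves;
  the fitter reports the iteration count in its error. The logit-log
  seeding makes this rare in practice.
* `fold_enrichment` errors (rather than returning NaN) when either side
  of the restriction is empty, and `enrichment_curve` requires at least
  half a window of records, so silent division by zero cannot occur.

## Known limitations

The OBO parser covers the subset used for tissue mapping ([Term] stanzas
with id, name, synonym, is_a, is_obsolete), not full OBO 1.4 semantics.
Precision against an incomplete gold standard is unknowable; every
quality statement here is relative (fold enrichment), never absolute.
The statistical significance of pairwise overlaps is not computed — with
sets of this size any overlap test rejects, and the effect sizes (the
percentages) are the informative output.
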