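---
title: "Boolean implication discovery: model, parameters and design"
author: "BooleanImplications package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Boolean implication discovery: model, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(BooleanImplications)
```

## The problem

Large microarray compendia pool tens of thousands of arrays across tissues,
diseases and labs. Correlation across such heterogeneous collections is a
blunt instrument: many regulatory relationships are *asymmetric* ("whenever
VEGFA is low, gene X is low" says nothing about what happens when VEGFA is
high) and show up not as a linear trend but as one systematically empty
corner of a joint expression scatter. Boolean implication analysis
formalizes exactly that: discretize every probe into low/high, and test each
corner of the pairwise 2x2 contingency table for being far emptier than
independence predicts. This package implements the full discovery pipeline
around a known *seed* gene (the motivating use case is hypoxia biology with
VEGFA as the seed): discretization, pairwise implication statistics,
six-class relationship calling, a multilayer candidate filter cascade
(strength ranking, multi-probeset concordance, mouse conservation, novelty),
and a hypoxia-response-element (HRE, 5'-RCGTG-3') promoter scan, plus a
synthetic-compendium generator that makes every stage testable without any
external download.

## Step-function discretization (StepMiner)

For a probe with values $v_1 \le \dots \le v_n$ (sorted, missing removed),
we fit a one-step function: for each split $k \in \{1, \dots, n-1\}$ the fit
is the mean of the low segment $m_L(k)$ and of the high segment $m_H(k)$,
with total squared error
$\mathrm{SSE}(k) = \sum_{i \le k} (v_i - m_L)^2 + \sum_{i > k} (v_i - m_H)^2$.
The split minimizing SSE is chosen (computed in $O(n)$ after sorting via
prefix sums; among equal-SSE splits the smallest $k$ wins, for determinism)
and the threshold is the midpoint $t = (m_L + m_H)/2$.

States are then assigned per sample with an intermediate buffer zone of
half-width `margin` (default 0.5 log2 units): LOW if $v < t - \mathrm{margin}$,
HIGH if $v > t + \mathrm{margin}$, INTERMEDIATE otherwise. Values exactly at
$t \pm \mathrm{margin}$ are INTERMEDIATE — the boundary rule is strict and
fixed so that calls are reproducible to the bit. Missing values stay
missing. Intermediate and missing samples never enter the pair statistics.

A probe is *eligible* only when (i) it has at least `minN = 20` non-missing
values, (ii) its fitted dynamic range $m_H - m_L$ is at least 1.0 log2 units
(flat probes carry no usable on/off signal), and (iii) at least
`minSideFrac = 5%` of its samples land on each side after binarization (a
probe that is low in 2 samples out of 10,000 supports no implication worth
calling). Ineligible probes have all states set missing and are skipped by
discovery. Whether such a pre-filter was applied in any particular published
run is usually unstated; here it is configuration, with conservative
defaults.

## Sparse-quadrant implication statistics

For two committed probes, each sample with both states in {LOW, HIGH} falls
in one quadrant of a 2x2 table with counts $n_{ij}$ (first index: state of
A; 0 = low, 1 = high). With row totals $r_i$, column totals $c_j$ and total
$n$, each quadrant gets

$$e_{ij} = \frac{r_i\, c_j}{n}, \qquad
  S_{ij} = \frac{e_{ij} - n_{ij}}{\sqrt{e_{ij}}}, \qquad
  p_{ij} = \frac{1}{2}\left(\frac{n_{ij}}{r_i} + \frac{n_{ij}}{c_j}\right).$$

$S$ measures how far below its independence expectation the quadrant count
sits (in units of $\sqrt{e}$, so it grows as $\sqrt{n}$ for a fixed joint
distribution), and $p$ is the implication's error rate — the average of the
two conditional frequencies of landing in the supposedly forbidden corner.
A quadrant is *sparse* at thresholds (SThr, pThr) when $S > \mathrm{SThr}$
and $p < \mathrm{pThr}$. Quadrants with $e_{ij} = 0$ carry no evidence and
can never be sparse ($S$ is reported as 0, $p$ as 1).

The sparse pattern maps to a relationship class:

| sparse quadrant(s) | class | reading |
|---|---|---|
| (0,1) | `LOW_LOW` | A low $\Rightarrow$ B low |
| (1,0) | `HIGH_HIGH` | A high $\Rightarrow$ B high |
| (0,0) | `LOW_HIGH` | A low $\Rightarrow$ B high |
| (1,1) | `HIGH_LOW` | A high $\Rightarrow$ B low |
| (0,1) and (1,0) | `EQUIVALENT` | states agree |
| (0,0) and (1,1) | `OPPOSITE` | states disagree |

Three or four simultaneously sparse quadrants indicate a degenerate
marginal, not a relationship, and yield `NONE`, as does any pair supported
by fewer than `minPairs = 20` committed samples. For the symmetric classes
both quadrants must individually clear the thresholds (the stricter of the
two defensible conventions; `classifyPair` applies it uniformly).
Transposition is exact: the statistics of (A,B) at (i,j) equal those of
(B,A) at (j,i), so "A low ⇒ B low" and its contrapositive "B high ⇒ A high"
are the same evidence read in both directions.

## Operating points

The statistic scales as $\sqrt{n}$, so a threshold is meaningful only
relative to a compendium size. Two reference operating points are used
throughout the package and its tests:

* **SThr > 40, pThr < 0.2** — the stringent compendium-scale point
  (defaults of `discoverCandidates` and the `discover` subcommand),
  appropriate at $n \sim 10^4$ samples.
* **SThr = 10, pThr < 0.1** — a small-collection point used for
  dataset-level pair queries and in fast tests at $n \sim 10^3$.

When the two species' compendia differ in size, conservation calls use an
equal-stringency rescaling $\mathrm{SThr}_{mouse} =
\mathrm{SThr}\sqrt{n_{mouse}/n_{human}}$ (e.g. $40\sqrt{5000/10000} \approx
28.3$ for the default synthetic sizes); `conservationFilter` exposes the
mouse-side thresholds explicitly.

## The multilayer filter cascade

`discoverCandidates` pairs the seed probe against every eligible probe
(excluding the seed gene's own probesets) and keeps non-`NONE` calls with
the best sparse quadrant's $S$ and $p$. The cascade then annotates — it
never reclassifies, rescores or reorders:

1. **Strength** (`rankCandidates`): descending $S$, ties by ascending $p$,
   then probe id. "Strong relationship" is operationalized as rank order in
   $S$ since $S$ is the only strength quantity the method reports; a fixed
   shortlist is a rank cutoff.
2. **Concordance** (`concordanceFilter`): the same candidate re-classified
   against the seed gene's other probesets must share *directionality*
   (positive = low⇒low, high⇒high, equivalent; negative = the rest), under
   `mode = "all"` (default) or `"majority"`. Directionality rather than
   identical class is compared because the committed-sample mix differs per
   probeset; `strictClass = TRUE` restores exact-class matching.
3. **Conservation** (`conservationFilter`): each candidate's gene is mapped
   through a human/mouse ortholog table (case-insensitively — human symbols
   are uppercase, mouse mixed-case) to mouse probes; one eligible mouse
   probe sharing the candidate's directionality against the mouse seed
   suffices, and the best-$S$ supporting probe is recorded. A human
   "low ⇒ low" partner whose mouse ortholog shows "high ⇒ high" counts as
   conserved: the implication's direction, not its literal class, is the
   conserved object. Many-to-many orthology is resolved permissively (any
   one supporting probe) to mirror probe multiplicity on arrays.
4. **Novelty** (`noveltyAnnotate`): a user-supplied known-gene list;
   candidates none of whose symbols appear in it (case-insensitive) are
   flagged novel. The package only annotates membership; it does not try to
   mine literature.

Because the filters are pure annotations, any subset — the full candidate
superset, the conserved-novel shortlist (`selectSurvivors`), or a top-k
cut — can be reproduced from one annotated table, and `topKIntersection`
compares ranked tables across seed genes or compendia.

## The synthetic compendium

`simulateCompendium` emulates what the statistics need from a real
compendium and nothing more. Per sample a latent seed state is drawn
(HIGH with probability 0.5); each planted partner's state follows the joint
low/high distribution of its class, with the sparse quadrant(s) at mass
$\varepsilon$ (default 0.002). For the four asymmetric classes both
marginals cannot sit at 0.5 — that would force both off-diagonal quadrants
sparse, i.e. an equivalence — so the contrapositive corner receives mass
`crossFrac` (default 0.10) and the two implication-consistent corners share
the rest. At the defaults ($n = 10{,}000$, $\varepsilon = 0.002$) the
planted quadrant scores $S \approx (e - n\varepsilon)/\sqrt{e} \approx
44$–$50$ while the contrapositive corner stays near 36 with $p \approx
0.18$, so the stringent point SThr > 40, pThr < 0.2 separates planted
classes cleanly; this is also why the default sample count is 10,000 — the
stringent threshold is meaningless at small $n$.

Values are drawn from a two-component Gaussian (means 6 and 10 log2 units,
sd 0.5). The 4-unit gap at 0.5 sd keeps the intermediate zone nearly empty,
deliberately separating what recovery tests measure (the quadrant
statistics) from what the discretization tests measure; a noisier profile
(smaller gap, larger sd) can be configured to stress the margin logic
instead. The seed gene carries four probesets; alternates can be faithful,
inverted or independent, which is how discordant fixtures are planted —
a partner's state sequence is a single vector, so its directionality
against every *faithful* probeset of the seed is necessarily identical, and
discordance is a property of a probeset, not of a pair. The mouse matrix
(default 5,000 samples) replants conserved pairs with the
directionality-preserving LOW/HIGH-swapped class (mirroring the
human-low⇒low / mouse-high⇒high pattern), leaves non-conserved partners
independent, and uses mixed-case symbols to exercise ortholog matching.

What the generator does **not** emulate: probe-level Affymetrix noise,
batch and platform effects, duplicated or mislabeled GEO samples, non-Gaussian
expression tails and correlated background genes. Passing recovery tests
therefore demonstrates the correctness of the statistics, the classifier
and the cascade on data satisfying the model's assumptions — not robustness
of discovery on real heterogeneous compendia, where threshold choice and
sample provenance dominate.

`simulatePromoters` plants a configurable number of non-overlapping RCGTG
sites (random strand) in uniform-random sequence after scrubbing every
accidental occurrence on either strand, with flanking guard bases so each
planted site yields exactly one hit; plants are verified against an
independent regex-based scanner before the truth table is emitted, keeping
generator truth independent of `scanMotif`.

## Numerical and degenerate-input choices

* Equal-SSE step splits: smallest split index. Tiny negative SSE from
  floating-point cancellation is clamped to zero.
* Constant or near-flat probes: ineligible, never an error.
* Exactly-at-boundary values: INTERMEDIATE (strict inequalities).
* $e_{ij} = 0$: quadrant undefined, never sparse.
* Empty candidate tables, empty gene lists, zero-hit scans: valid empty
  results (with a warning where the input is suspicious, e.g. an empty
  mapping file).
* An `N` in a sequence never satisfies a non-N motif letter, so ambiguous
  bases cannot inflate HRE counts.
* All tabular output renders floats with 8 significant digits; write/read
  round trips are stable to at least 6.

## Problem sizes used by the tests

Unit tests run on compact compendia (2,000 human / 1,500 mouse samples, 2
planted pairs per class at $\varepsilon = 0.004$, SThr 10 / pThr 0.1); the
end-to-end recovery checks and the acceptance script use the full default
conditions (10,000 / 5,000 samples, 10 pairs per class at $\varepsilon =
0.002$, SThr 40 / pThr 0.2, 200 background probes), 500 bimodal probes of
1,000 samples for threshold recovery, 100 random 1-kb sequences for the
motif-scan oracle and 20 planted promoter sequences. These sizes keep a
full run in well under a minute on one core while exercising the stringent
operating point.

## Limitations

* Only seed-vs-all discovery is provided; genome-scale all-pairs network
  construction needs external edge stores and is out of scope.
* The pipeline starts from normalized log2 matrices; normalization (RMA),
  CEL parsing and GEO retrieval are upstream concerns.
* The novelty layer annotates membership in a supplied list; it neither
  mines literature nor computes a "fraction previously known" summary,
  whose denominator convention (genes vs probesets) is ambiguous in
  published uses.
* Region definitions for promoter/UTR/intron HRE counting are user inputs
  in 1-based inclusive sequence coordinates; no genome lift is attempted.
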