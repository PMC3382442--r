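---
title: "Ball histograms: spatial amino-acid descriptors for DNA-binding prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ball histograms: spatial amino-acid descriptors for DNA-binding prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

DNA-binding proteins tend to present spatially concentrated patches of
particular residues — most prominently the positively charged arginine and
lysine — that complement the charge of the DNA backbone. `ballhist`
implements a descriptor of protein structure built directly on that
observation: the **ball histogram**.

A protein is reduced to its alpha-carbon point cloud with residue types. A
**template** $\tau = (f_1, \dots, f_k)$ is an ordered list of Boolean
amino-acid properties — identities such as *Arg*, or classes such as
*Positive* = {Arg, Lys}. Given a sampling-ball radius $R$, the ball
histogram $H_\tau(t_1, \dots, t_k)$ is the joint probability that a ball of
radius $R$, centred uniformly at random inside the protein's *bounding
sphere* and containing at least one residue, contains exactly $t_i$
residues satisfying $f_i$ for every $i$. The bounding sphere is centred at
the geometric centre of the alpha-carbons with radius equal to the
farthest-residue distance plus $R$, so every ball that could contain a
residue is reachable. Balls containing no residue at all are discarded
rather than counted as $(0,\dots,0)$: otherwise the histogram would depend
on how much empty space the bounding sphere contains, i.e. on the
protein's overall shape rather than its local composition. The descriptor
is invariant to rotation and translation, and insensitive to enlarging the
bounding sphere.

The integral defining $H_\tau$ is intractable, so it is estimated by Monte
Carlo: `n_samples` ball centres are drawn uniformly from the bounding
sphere (isotropic Gaussian direction, radius scaled by $U^{1/3}$), empty
balls are dropped, and bin counts are normalized. One sample stream is
derived per (structure id, seed), shared by all templates: the histogram
for any sub-template is then obtained *exactly* by marginalizing the
"master" histogram over the full property pool, which is both the main
computational shortcut during template search and the reason
`marginalize()` reproduces direct construction bit-for-bit (weights are
pooled as integer numerators over the retained-sample denominator).

## Template discovery

Informative templates are found by maximizing the Bhattacharyya distance

$$D_B(h_a, h_b) = -\ln \sum_x \sqrt{h_a(x)\, h_b(x)}$$

between the *class-average* histograms of the binding and non-binding
training proteins (each protein weighted equally), marginalized to the
candidate template. The search is a deterministic best-first walk over the
lattice of property subsets up to length $L$: the highest-scoring open node
is popped (ties: shorter template first, then pool order), its
one-property extensions are scored and queued, and the best candidate by
*uncapped* distance that is not already discovered is retained. A greedy
search fails here — a classic worked example has two properties whose
single-property marginals are identical across classes (distance 0) but
whose joint supports are disjoint (distance $\infty$); greedy picks the
mildly informative third property first and never recovers. The test suite
keeps a greedy implementation as an oracle of exactly this failure, and an
exhaustive enumeration oracle confirming that on small lattices the search
attains the global optimum.

When several templates are requested, each search run penalizes candidates
that are subsets of already discovered templates (score multiplied by
$\lambda$) and seeds its open set with all pairwise intersections of the
discoveries, steering later runs toward diverse templates that share an
informative core.

Numerical choices worth stating:

* Infinite distances (disjoint supports) are replaced by the cap
  $D_{\text{cap}} = -\ln 10^{-12} \approx 27.6$ *inside scores*, so that
  the multiplicative $\lambda$-penalty still orders disjoint-support
  candidates; uncapped values are reported.
* $\lambda = 0.5$ by default: redundant subsets lose half their score but
  remain searchable. $\lambda = 1$ disables the penalty, $\lambda = 0$
  suppresses subsets entirely.
* $L = 3$ by default. Marginalizing can only shrink $D_B$, so the optimum
  is always a full-length template; more importantly the number of
  histogram bins grows exponentially in $L$ and the training-sample demand
  grows exponentially in *that*, which is the argument for several short
  templates instead of one long one.
* Ball membership is crisp and boundary-inclusive ($d \le R$), a
  measure-zero choice fixed for determinism. Fractional membership is
  deliberately not implemented.

## Classification

Histograms are propositionalized: every (template, radius, count vector)
with non-zero weight in at least one *training* histogram becomes a
numerical attribute whose value is the bin height; bins first seen at
prediction time are dropped, since the attribute space is frozen at
training. A random forest (500 trees by default, seeded) is fitted on these
vectors — chosen for its tolerance of very wide, sparse attribute spaces.
Evaluation is stratified k-fold cross-validation reporting rank-based AUC
and 0.5-threshold accuracy; the sampling-ball radius (grid 4, 8, 12 Å) and
the number of templates (1, 3, 5, 7) can be selected per outer fold by an
internal stratified 5-fold cross-validation on the training portion only.
Template discovery, attribute collection and hyperparameter selection all
run inside the outer training fold, so no information flows from held-out
structures into the model; per-protein master histograms *are* shared
across folds, which is safe because they are label-independent and
per-protein. Individual attributes can be ranked by a $\chi^2$ statistic
after discretizing each feature into 10 equal-width bins on $[0, 1]$
(empty bins dropped) — the binning is a package decision; the statistic is
otherwise standard.

## The synthetic generator

Real curated structure sets are large downloads, so the package ships a
generator that emulates the single feature of real data the method feeds
on: labelled point clouds whose residue-type composition is locally,
spatially structured. Chains are self-avoiding random walks with exact
3.8 Å CA–CA steps and a 3.5 Å minimum separation between non-consecutive
residues; types are uniform over the 20 amino acids. For the binding class
a sphere (default 10 Å) centred on a random residue has the planted
property's frequency multiplied by the enrichment factor (default 5, i.e.
*Positive* rises from 0.10 to 0.50 inside the cluster), the remaining mass
shared proportionally. Enrichment 1 makes the classes distributionally
identical — the null configuration used to check that the pipeline reports
chance-level AUC when there is nothing to find.

What the generator does *not* emulate: realistic secondary structure,
side chains, residue-composition differences between classes (the
background is uniform by design, isolating the spatial signal), realistic
packing density (a self-avoiding walk is looser than a folded protein), or
surface/electrostatics. Passing tests therefore demonstrate that the
implementation recovers planted spatial composition signal, not that it
reproduces published performance on curated PDB datasets.

## Problem sizes and defaults

* `n_samples` defaults to 10^4 per protein and radius; the Monte-Carlo
  error of a bin of weight $w$ is roughly $\sqrt{w/n}$. Convergence and
  invariance properties are tested at 2×10^5 samples where sub-0.05 L1
  agreement is required.
* The planted-cluster recovery experiment uses 40 + 40 structures of 150
  residues, 10-fold outer cross-validation at radius 8 Å (comparable to
  the 10 Å planted cluster) with 3 templates from the default 24-property
  pool, and checks: mean AUC at least 0.9, chance-level AUC on the null
  configuration, and that the discovered template set implicates the
  planted property (contains *Positive*, *Arg* or *Lys*) in at least 8 of
  10 sampling seeds.
* The tiny-structure oracle compares Monte-Carlo histograms against dense
  cubic-grid integration (0.25 Å step) on structures of up to 3 residues.

## Open choices made here

* **Polar membership.** Templates in the field mix identities with classes
  like *Polar* without a universal definition; the default table uses
  {Ser, Thr, Asn, Gln, Tyr, Cys, His} and is user-overridable via a YAML
  property table, so alternative conventions (e.g. His as positive) are a
  configuration, not a code change.
* **Neutral** is the complement of Positive ∪ Negative (16 types).
* **HeuristicScore** of the search is the capped class-average
  Bhattacharyya distance itself — the search's objective — rather than a
  separate heuristic.
* **Class averages** weight proteins equally regardless of size.
* **Per-fold template discovery.** Templates are re-discovered inside
  every outer training fold rather than once globally; the alternative
  leaks held-out information into feature construction.
* Modified residues with a standard parent (MSE→Met, SEC→Cys, ...) are
  mapped; others are skipped with a warning. Alternate locations keep the
  first conformer; the first model of multi-model files is used; all
  chains are pooled.

## Known limitations

* Monte-Carlo histograms of long templates at modest sample counts are
  sparse; feature vectors of distinct proteins can share few bins, which
  degrades forest performance well before the histogram itself stops being
  informative. Larger `n_samples` and shorter templates mitigate this.
* The bounding sphere of an elongated protein is mostly empty; sampling
  efficiency (retained fraction) falls with aspect ratio, though the
  estimate remains unbiased because empty balls are discarded.
* `read_structure()` keeps only residues with alpha-carbons and ignores
  occupancy; exotic chain identifiers are truncated to one character on
  PDB output.

## A worked call

```{r, eval = FALSE}
library(ballhist)

ds <- generate_dataset(10, 10, n_residues = 150, seed = 1)
cv <- cross_validate(ds, k = 5, radii = 8, n_templates_grid = 3L,
                     n_samples = 5000, seed = 1)
glance(cv)
autoplot(cv)
```
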