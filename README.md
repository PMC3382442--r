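# ballhist

Predicting whether a protein binds DNA, from nothing but its
three-dimensional structure — no evolutionary profiles, no surface or
electrostatics computation. `ballhist` is aimed at structural
bioinformaticians who need a structure-only propensity score (for example
for engineered proteins, where conservation information does not exist)
and at anyone who wants interpretable spatial features of residue
composition.

## The method

The descriptor is the **ball histogram**. Fix a *template*
τ = (f₁, …, f_k) of Boolean amino-acid properties (identities such as
*Arg*, or classes such as *Positive* = {Arg, Lys}) and a sampling-ball
radius R. Drop balls of radius R uniformly at random inside the protein's
bounding sphere; for every ball containing at least one alpha-carbon,
record the vector (t₁, …, t_k) of residue counts satisfying each property.
The normalized distribution

H_τ(t₁, …, t_k) = P(ball contains exactly tᵢ residues with property fᵢ, i = 1..k | ball non-empty)

is invariant to rotation and translation of the structure and captures how
strongly residues of chosen kinds cluster in space.

Templates are not hand-picked: a best-first search over the lattice of
property subsets maximizes the **Bhattacharyya distance**
D_B(h_a, h_b) = −ln Σ_x √(h_a(x)·h_b(x)) between the average histograms of
the binding and non-binding training proteins, with a subset penalty and
intersection seeding to keep multiple discovered templates diverse (greedy
selection provably fails here; the package's tests include the classic
counter-example). Histograms are then *propositionalized* — one numeric
attribute per observed bin — and a seeded random forest is trained, with
sampling radius and template count selectable per fold by internal
cross-validation. Because all templates share one Monte-Carlo sample
stream per protein, any sub-template histogram is obtained exactly by
marginalizing a single full-pool "master" histogram.

A synthetic-structure generator (self-avoiding 3.8 Å CA walks with a
planted, spatially clustered property enrichment) makes the entire
pipeline testable without downloading structure data.

## A worked example

```r
library(ballhist)

# 10 binding + 10 non-binding synthetic structures, 150 residues each,
# Positive residues enriched 5x inside a 10 A cluster in the binding class
ds <- generate_dataset(10, 10, n_residues = 150, seed = 1)

# one protein's ball histogram for the template (Arg, Lys) at R = 8 A
h <- build_histogram(ds$structure[[1]], c("Arg", "Lys"), R = 8,
                     n_samples = 10000, seed = 1)
print(h, n = 4)
#> # ball_histogram: template (Arg, Lys), R = 8 A, 7 bins, n_samples = 10000
#> # A tibble: 7 x 3
#>     Arg   Lys   weight
#>   <int> <int>    <dbl>
#> 1     0     0 0.704
#> 2     0     1 0.100
#> 3     0     2 0.000962
#> 4     1     0 0.144
#> # i 3 more rows

# discover the 3 most class-separating templates and cross-validate
cv <- cross_validate(ds, k = 5, radii = 8, n_templates_grid = 3L,
                     n_samples = 5000, seed = 1)
cv
#> 5-fold cross-validation (seed 1)
#>   AUC      0.850 +/- 0.224
#>   Accuracy 0.650 +/- 0.137
glance(cv)   # one-row summary; tidy(cv) gives per-fold metrics
```

The first histogram lines read: 70.4% of non-empty 8 Å balls in this
structure contain no arginine and no lysine, 10.0% contain exactly one
lysine and no arginine, and so on. Even at this deliberately small scale
(10 + 10 proteins) the forest separates the planted-cluster class from the
background well above chance; the test suite runs the same experiment at
40 + 40 proteins, where the planted signal is recovered at AUC ≥ 0.9
while a null configuration (`enrichment = 1`) stays at chance level.

There is also a command-line interface (`inst/cli/ballhist`) with verbs
`simulate`, `histogram`, `search`, `train`, `predict`, `evaluate`, a YAML
config file overridable by flags, and deterministic artifacts given a
seed.

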