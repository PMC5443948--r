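---
title: "Phenotypic partitioning of egg appearance: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phenotypic partitioning of egg appearance: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eggspace)
```

## The scientific question

Hosts of avian brood parasites defend themselves with egg "signatures":
distinctive combinations of colour, luminance and pattern that make a
mimetic foreign egg easier to detect. When one parasite species maintains
several sympatric host-races, each mimicking a different host, a host that
evolves its signature *towards* another host's phenotype becomes vulnerable
to that host's mimic. The community-level prediction is that sympatric host
species should *partition* egg-phenotype space — occupy more distinct
regions than comparable unparasitized species — and that each parasitic
host-race should match its own host better than other local hosts.

`eggspace` operationalises both predictions as classification problems on a
tidy egg-by-trait table and provides every stage from raw measurements to
the final tests, plus a synthetic-data generator that lets the whole
pipeline be validated without access to a physical egg collection.

## The phenotype space

Each egg is a 10-vector in a fixed order (`egg_traits()`):

* **luminance** — double-cone photon catch;
* **uv, sw, mw, lw** — single-cone photon catches, the colour channels of
  an avian visual model;
* **marking_size, main_contribution, contrast, coverage, dispersion** —
  granularity pattern metrics from an egg photograph.

A photon catch is the integral of reflectance × illuminant × receptor
sensitivity over wavelength, evaluated by trapezoidal quadrature on the
common grid of the spectrum and the visual system (linear interpolation at
the finer of the two steps). With `normalize = TRUE` (the default) a
perfect white reflector scores exactly 1 on every receptor, which makes
catches comparable across receptors and is the identity the tests pin
down. The packaged `ideal_visual_system()` uses Gaussian cone curves
(peaks 370/445/508/565 nm, a broad double cone at 560 nm) under a flat
illuminant. It is a synthetic stand-in, not a tabulated sensitivity set
for a real species: photon catches are used directly as indices of colour
and luminance, with no chromatic adaptation and no receptor-noise
modelling, so only the relative weighting of wavelengths matters
downstream.

Pattern metrics come from a granularity analysis: the image is mean-padded
outside the egg mask, Fourier transformed, and split into octave
frequency annuli. The band of scale *s* px is the half-open annulus
(1/(2*s*), 1/*s*] cycles/px, so it contains the spatial periods
[*s*, 2*s*); the largest scale is half the smaller image dimension and
scales halve per band. Band energy is the mean squared value of the
band-filtered image inside the mask. Two numerical details matter:

* band masks are built from integer frequency indices so that +f and −f
  fall on exactly the same side of a band edge — this keeps every annulus
  conjugate-symmetric (the filtered images are real) and makes the band
  energies tile the non-DC spectrum exactly (the Parseval identity the
  test suite checks on a full mask);
* the lowest band excludes DC, so all energies are invariant to adding a
  constant to the image.

The five metrics are then: the scale of the maximal-energy band
(predominant **marking size**; `NA` for a patternless egg), the maximal
band energy as a fraction of the total (**main contribution**), the square
root of total energy (**contrast**), the fraction of egg pixels darker
than an Otsu threshold computed on the egg region (**coverage**;
parameter-free and deterministic), and the coefficient of variation of
coverage across five equal-length zones along the egg's long axis
(**dispersion**: high when markings cluster, e.g. a blunt-pole ring).
These operationalisations are deliberately simple, individually
replaceable implementations of the five classic egg-pattern descriptors;
testability on synthetic images was weighted above fidelity to any
particular published parameterisation.

## Data hygiene

`preprocess_phenotypes()` reproduces the standard hygiene sequence:

1. **One egg per clutch**, chosen uniformly at random under an explicit
   seed (clutch mates are pseudoreplicates). Selection happens before
   outlier screening; the reverse order is equally defensible but must be
   one or the other, and selecting first means the outlier screen sees
   exactly the rows that enter the analysis.
2. **Mahalanobis outlier removal** against the pooled mean and covariance,
   flagging rows above the chi-square upper-`alpha` quantile with one df
   per trait. The default `alpha = 0.001` is deliberately conservative —
   the screen should only catch gross measurement errors — and is exposed
   because no universal cutoff exists. Screening is done on the pooled
   table (per family), not per species.
3. **Collinearity screening** of all trait pairs by Pearson correlation
   (threshold 0.8). Real photon catches make UV–MW and SW–LW highly
   correlated; when exactly those pairs trigger, the suggested drop set is
   MW and LW (keeping the shorter-wavelength member of each pair),
   otherwise the later trait of each flagged pair. Dropping is off by
   default: the headline analyses run on untransformed traits with
   correlated traits retained, and the transformed/reduced variants are
   sensitivity switches that should not change direction or significance
   of conclusions (the pipeline test asserts exactly this on the packaged
   preset).
4. **Arcsine-square-root transform** after min–max scaling to [0, 1]
   (the scaling is recorded so the transform inverts). Min–max scaling is
   this package's choice for mapping non-proportion traits onto the
   transform's domain.

## Classification and the chance null

The discriminant machinery is written from scratch (established
implementations serve as test oracles only). `fit_lda()` solves the
generalised eigenproblem `B v = θ W v` through a Cholesky whitening of the
pooled within-group covariance `W`, which keeps the eigenproblem symmetric
and the axes `W`-orthonormal; a ridge of `1e-8 · tr(W)/d` is added only if
`W` is singular, with a warning. Classification uses the Gaussian
equal-covariance rule with priors proportional to group sizes — the choice
consistent with a chance null driven by relative sample sizes — and ties
break toward the lowest group index so reruns are deterministic.

Validation schemes:

* **jack-knife** (`jackknife_accuracy()`): each row held out in turn and
  the model exactly refitted without it (rank-one downdates of the group
  sums and scatters; the test suite checks equality with a literal
  refit-per-row loop);
* **Monte-Carlo splitting** (`monte_carlo_split_accuracy()`): stratified
  random train/test splits, defaults `train_fraction = 0.75` and
  `n_reps = 100`, as a confirmation that should agree with the jack-knife
  in direction;
* **multinomial logistic regression** (`fit_multinomial_logistic()`):
  penalised Newton iteration with step halving, intercepts unpenalised,
  ridge default `1e-6 · n`. The ridge keeps the optimum finite on linearly
  separable groups (a group classified at 100% implies separability, where
  the unpenalised likelihood has no maximiser). Groupwise logistic
  accuracies are resubstitution accuracies; a jack-knifed logistic run is
  possible but not the default.

The chance null: assigning eggs to species in proportion to sample sizes
gives expected accuracy `Σ nᵢ²/N²` (exactly `1/k` for equal sizes, and
minimised by equal sizes for fixed `N` and `k`). Observed versus expected
correct counts are compared with Fisher's exact test on the 2×2 table
(rows = correct/incorrect, columns = expected/observed, expected correct
rounded to the nearest egg — the table construction is a package choice
and is configurable in spirit via `fisher_exact_2x2()`). Groupwise
accuracies carry Wald binomial CIs (`1.96·√(p(1−p)/n)`), pairwise accuracy
distributions are compared with Welch's t on pooled midranks (the
`statistic` column is the Welch t with Welch–Satterthwaite df), and no
multiple-testing correction is applied, since the pairwise discriminant
rates are not p-values. The pairwise analysis refits each two-species
model on the already-cleaned table, without redoing outlier or
collinearity screening per pair.

## Mimicry differentials

For each parasitic host-race, `mimicry_analysis()` runs a two-group
jack-knifed discriminant analysis against its own host and against every
other host of the same community, and reports own-host accuracy minus the
mean of the other-host accuracies. Low accuracy means the race's eggs sit
inside a host's cloud, so negative differentials indicate specialist
mimicry. The paired t-test pairs each race's own accuracy with its *mean*
other accuracy — one pair per race, df = races − 1 — which is the reading
consistent with small-df tests in this literature (an alternative pairing
of own against every single other comparison would inflate df). Races
below `min_race_n = 3` eggs are reported but excluded from the test; the
threshold is configurable and was chosen as the smallest size a two-group
jack-knife tolerates.

One behaviour worth knowing: when a synthetic race is generated at
fidelity 1, it is drawn from a distribution *fitted to the very host
sample* it is later compared against. Leave-one-out then shows a mild
below-chance artifact (holding out a host egg shifts the host mean away
from it while the mimic's cloud, fitted to the full sample, does not), so
own-host accuracies of perfect mimics can sit below 50%. This strengthens,
rather than weakens, the fidelity–differential monotonicity the tests
check, but it means "≈ chance" should be read as "no better than chance".

## Phylogenetic signal

`estimate_lambda()` implements Pagel's λ by profile maximum likelihood:
the λ-scaled tip covariance keeps root-to-tip path lengths on the diagonal
and multiplies shared path lengths by λ; for fixed λ the root state and
Brownian rate have GLS closed forms, and the profile likelihood is
maximised on [0, 1] by bounded scalar search (tolerance 1e-8) with both
boundaries evaluated explicitly and ties resolved toward the boundary.
Likelihood-ratio p-values against λ = 0 (`p0`, any signal) and λ = 1
(`p1`, departure from Brownian motion) use chi-square with 1 df even
though the null values lie on the parameter boundary — the convention of
the standard comparative-methods packages, conservative for the λ = 0 test
and anticonservative for λ = 1. Species-level trait values are per-species
means of the cleaned egg table (parasite rows excluded); the species-level
summary is a package choice. `summarize_over_trees()` propagates
phylogenetic uncertainty by averaging λ, `p0` and `p1` over a set of
candidate trees (100 by default in the pipeline), reporting means and SDs
and skipping (with a warning) trees that lack any species. λ estimates are
invariant to rescaling all branch lengths, which the rate parameter
absorbs — so the unit-depth rescaling of simulated trees is harmless.

## What the synthetic generator emulates — and what it does not

`generate_community()` draws each species as a multivariate normal cloud.
The dials:

* `trait_sd = 0.06` — within-species SD on every trait, on the [0, 1]
  scale the generator standardises pattern traits to (so the
  arcsine-square-root transform is always well defined; draws are clipped
  to [0, 1] for the five pattern traits, a negligible distortion at these
  SDs);
* `separation` — the ratio of between-species to within-species spread.
  Species mean offsets are drawn with the *same* correlation structure as
  the within-species covariance, so the UV–MW and SW–LW collinearity
  (r = 0.9 within species) survives in the pooled table, as it does in
  real photon catches. Because discriminability accumulates over 10
  traits, modest values already classify well: separations of about 0.8
  and 0.4 reproduce the magnitudes of groupwise accuracy reported for
  parasitized (~82%) and unparasitized (~55%) warblers, and those are the
  defaults of `warbler_community_spec()`;
* host-races are mixtures: each parasitic egg comes from the target
  host's fitted distribution with probability `fidelity`, otherwise from
  the pooled all-host distribution. The single fidelity dial spans the
  specialist–generalist continuum (1 = perfect specialist, 0 = pure
  generalist laying across all hosts);
* `warbler_community_spec()` matches the published group structure — 5
  parasitized species totalling 205 clutches, 6 unparasitized totalling
  219, five host-races of which two have n = 2 and n = 1 (exercising the
  low-n exclusion) — with per-species counts split 80/50/30/25/20 and
  60/45/40/30/24/20, an arbitrary allocation because per-species counts
  are not published;
* trees are pure-birth simulations rescaled to unit depth, and traits on
  them follow λ-scaled Brownian motion exactly (the tip covariance is
  constructed, then sampled).

The generator does **not** emulate: non-Gaussian trait distributions or
the discrete/bounded character of some real pattern metrics; real
reflectance spectra of particular taxa; within-species signature
polymorphism beyond a single Gaussian (real egg signatures are often
multimodal); egg three-dimensional geometry; or any phylogenetic
structure in the community trait means (species means are exchangeable
draws, so λ near 0 is the expected result for community traits). Passing
tests therefore demonstrate that the *machinery* is correct and that the
qualitative contrasts are recoverable under the stated conditions — not
that any particular real system satisfies those conditions.

## Validation design and problem sizes

The test suite checks every computational claim against an independent
route: discriminant fits against an established implementation and a
brute-force Gaussian-posterior rule; the jack-knife against a literal
refit-per-row loop on a 60-row fixture; Fisher's exact p against
exhaustive hypergeometric enumeration; the ranked Welch test against the
hand-written formula; λ estimates against an independent comparative-
methods implementation and closed-form limits; and photon catches against
fine-grid quadrature. End-to-end behaviour is validated with λ parameter
recovery (200-tip tree, 100 replicates per true λ, mean error under 0.1),
a host-race fidelity sweep (differentials strictly ordered across
fidelity 0/0.5/1, averaged over three seeds), and a sign-reproduction
experiment (50 seeded communities with parasitized separation 2.5 versus
unparasitized 0.8; the parasitized group shows higher mean pairwise
accuracy in at least 45). These sizes keep the full suite under a minute
on a single core while leaving the stochastic checks comfortable margins.

## Known limitations

* Real museum-collection accuracies cannot be reproduced here — the raw
  egg data exist only as a physical collection — so the published summary
  table enters only through its printed counts (`study_summary_counts()`),
  whose derived columns the package recomputes exactly.
* The granularity parameterisation (band count, energy definition) follows
  this package's conventions; published analyses defer theirs to earlier
  methodological work, so absolute pattern-metric values are not
  comparable across implementations, though relative structure is.
* Logistic "accuracy" is resubstitution accuracy and is optimistic
  relative to the jack-knifed discriminant rate; the two are reported side
  by side, never mixed.
* The λ boundary p-values inherit the chi-square(1) convention's boundary
  bias, and small trees give wide λ uncertainty — averaging over many
  candidate trees reports, but does not remove, that uncertainty.
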