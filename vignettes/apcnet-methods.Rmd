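---
title: "Methods: association scoring, null models and validation in apcnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: association scoring, null models and validation in apcnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apcnet)
```

## The inference problem

High-frequency GNSS tracking makes *every* dyad of a herd co-occur
eventually, so the presence or absence of proximity contacts cannot by
itself define a social bond. Two confounds dominate: shared background
(all animals are attracted to the same water, shade and resting places)
and meter-scale positioning error. `apcnet` treats association as an
information-theoretic excess — how much more often two animals are in
contact than their individual gregariousness predicts — and removes the
residual background with the average product correction (APC), a technique
originally developed to strip phylogenetic background from mutual
information scores between protein residues. The alternative, a null model
on the raw coordinates that preserves each animal's movement
autocorrelation, is notoriously hard to specify and expensive to compute;
the pre-network permutation model shipped here (see below) is the
practical compromise, and the APC route gives a null-model-free answer
that can be cross-checked against it.

## From fixes to contacts

GPS records are floored (never rounded) to the minute and deduplicated to
the first occurrence per animal-minute: both choices are deterministic and
stable under re-ordering of the input file. Distances are spherical
haversine distances (Earth radius 6 378 137 m, the conventional equatorial
value and the default of the geodesic routines practitioners use;
configurable in `haversine_m()`). A dyad-minute enters the distance table
only if *both* animals have a fix at that minute — no interpolation, so
missing data thin the table rather than bias it.

A contact is a dyad-minute with distance ≤ *d*, reading "did not exceed"
inclusively. The threshold is a study design parameter, not a fitted one;
1, 1.5, 2.5 and 5 m are the values the supported design compares. Each
minute is an independent contact event: contacts are deliberately not
chained into bouts, because the downstream counts are interpreted as
time-point frequencies. Contact locations (for the spatial grids) are the
dyad midpoint — symmetric and single-valued, where any other convention
would be arbitrary.

## PMI, PPMI and the average product correction

With contact counts $f(a,b)$, total $n$ and involvement $f(a)$, the
probabilities $p(a,b) = f(a,b)/n$ and $p(a) = f(a)/(2n)$ normalize exactly
(each contact contributes one dyad event and two animal participations),
and

$$\mathrm{PMI}(a,b) = \log_2 \frac{p(a,b)}{p(a)\,p(b)}$$

is positive when the dyad co-occurs more than independence predicts. PPMI
clamps PMI at zero from below, because the APC step assumes nonnegative
scores. Two boundary conventions matter:

* **Never-co-occurring dyads.** $f(a,b)=0$ makes PMI undefined
  ($\log 0$); the package carries a $-\infty$ sentinel through the PMI
  matrix and the PPMI clamp maps it to 0. The same sentinel is used when
  an animal has no contacts at all (the $0/0$ case). In a month of
  1-minute data every dyad co-occurs, so this convention only matters for
  very short or heavily stratified inputs.
* **Exact zeros.** PMI of exactly 0 is *not* positive and clamps to 0, and
  a corrected score of exactly 0 yields *no* edge — both inequalities are
  strict throughout.

The APC of a dyad is the product of the two animals' average PPMI with all
other animals, divided by the overall average PPMI. The averaging
denominator (should "average" divide by $N$ or by $N-1$ "others"?) cancels
algebraically as long as it is used consistently in both the per-animal
and the overall average, so the implementation uses the cancelled form

$$\mathrm{APC}(a,b) = \frac{S_a\,S_b}{S}, \qquad
S_a = \sum_{x \ne a} \mathrm{PPMI}(a,x), \quad
S = \sum_{x \ne y} \mathrm{PPMI}(x,y),$$

which is invariant to that choice; the test suite asserts the equality of
both readings against an explicit-loop oracle. APC needs at least three
animals (with two there are no "others") and is defined as identically
zero when all PPMI values are zero. The corrected score is
$\mathrm{PPMI_{APC}} = \mathrm{PPMI} - \mathrm{APC}$; the social network
takes an edge where it is strictly positive, weighted by the value. All
animals remain nodes, so network comparisons are always over a fixed node
set.

## Permutation null model

The null model shuffles the *distance column* of the dyad-minute table as
one global permutation per replicate, keeping dyad and minute labels in
place. This preserves the distance multiset exactly, so every replicate
has precisely the observed total number of contacts — a conservation the
tests assert — and destroys only the assignment of distances to dyads and
minutes. Per dyad, the one-sided upper-tail p-value is
$(1 + r)/(1 + n_\mathrm{perm})$ with $r$ the number of replicates whose
statistic (contact count or PMI) reaches the observed value. The add-one
convention avoids $p = 0$ and is standard for Monte-Carlo tests. No
multiple-testing correction is applied by default (an adjustment method
can be requested in `significant_network()`), keeping per-dyad
significance interpretable on its own.

Because the contact-count statistic is discrete, ties between replicate
and observed values make the test conservative: on fully exchangeable
(iid-distance) tables the expected fraction of dyads with $p < 0.05$ is
slightly *below* the nominal $5\%$ — about $5/(n_\mathrm{perm}+1)$ minus a
tie deficit that shrinks as counts grow. The calibration test therefore
accepts a band of $0.05 \pm 0.02$ around the nominal level.

## Robustness to missing data

`robustness_experiment()` deletes records uniformly at random (globally
across animals and minutes; a per-animal stratified option exists),
re-runs the entire pipeline and scores the result against the full-data
network with the graph Hamming distance

$$H = \frac{|E_1 \cup E_2| - |E_1 \cap E_2|}{N(N-1)/2}.$$

Note the arithmetic of "exchanged" edges: swapping one edge for another
changes *two* elements of the symmetric difference, so on 8 nodes a
two-edge exchange gives $4/28 \approx 0.14$ and a seven-edge exchange
$14/28 = 0.5$. The package reports both the normalized $H$ and the raw
symmetric-difference count (`edge_symmetric_difference()`), leaving the
"number of affected edges" interpretation to the caller. Replicate seeds
are derived deterministically from the base seed so any single replicate
is reproducible in isolation.

## GPS quality from lying bouts

Stationary accuracy is estimated from lying bouts: maximal runs of
consecutive minutes with `fraction_lying == 1.0` (the animal was *entirely*
lying), strictly longer than 60 minutes. Within each bout, fixes are
compared to the bout's geographic mean; deviations are converted to meters
by local equirectangular scaling at the bout latitude
(lat: $R\pi/180$; lon: $R\cos\bar\varphi\,\pi/180$ per degree) and pooled.
The summary radii use the standard planar approximations
$\mathrm{CEP} \approx 0.59(\sigma_\mathrm{lat} + \sigma_\mathrm{lon})$
(50 % radius) and
$\mathrm{2DRMS} = 2\sqrt{\sigma_\mathrm{lat}^2 + \sigma_\mathrm{lon}^2}$
(≈95 % radius). No filter for head movement during lying is applied: such
motion inflates the estimate slightly, making it a conservative accuracy
bound. DOP and satellite counts are carried through the data model but
never used to drop records.

## What the simulator emulates — and what it does not

`simulate_herd()` is the package's ground-truth harness, built to the
scale of the supported study design: 8 animals, 29 days at 1-minute
resolution (41 760 records per animal when complete), a 5-ha rectangular
pasture (250 m × 200 m), per-axis GPS noise of 1.04 m (lat) and 0.80 m
(lon), and two planted partner dyads.

* **Movement.** The herd center performs a boundary-reflected random walk
  (step SD 5 m/min); each animal adds a discrete-time mean-reverting
  (OU-style) offset with stationary per-axis SD 15 m and reversion 0.1 per
  minute. This is the simplest model that yields both herd cohesion and
  individually distinguishable space use. The spread and step values are
  chosen so that background dyads still make occasional sub-meter
  contacts over a month while partner dyads make many — the regime the
  association score is designed for.
* **Planted structure.** Partner dyads close a fixed fraction (strength
  0.3, i.e. 30 % of the gap per minute) of their offset difference
  whenever both are standing, and share their activity chain, so lying
  bouts are simultaneous and, through the attraction, adjacent.
* **Activity.** A two-state Markov chain per animal (lie-down 0.01,
  stand-up 0.012 per minute) gives a stationary lying fraction of ≈0.45
  and mean bout lengths of ≈83 minutes — realistic for cattle and long
  enough to qualify for the quality metrics. Lying animals do not move.
* **Noise and missingness.** Gaussian noise per axis is added after the
  true positions are recorded in the ground truth; records are then
  dropped uniformly at the configured missing fraction.

Not emulated: the two-part subdivision of the pasture and fence/gate or
watering-trough funneling (so simulated contact grids have no localized
hot spots), grazing-behavior realism, structured sensor dropout, and any
distance-dependence of GPS error. Passing the simulation-based tests
therefore demonstrates that the pipeline recovers *planted dyadic
preference under herd-cohesion background*, not that it is robust to every
artefact of real pastures.

## Problem sizes and seeds in the test suite

Unit tests run on 1–3 simulated days; the validation tests use the full
29-day design: planted-dyad recovery over ten independent seeds (all
planted dyads must rank in the top two corrected scores in at least nine),
a robustness experiment with kept fractions 0.9–0.4 and ten replicates
each (median Hamming distance at 90 % kept must not exceed that at 40 %,
and the median edge difference at 70 % kept must stay within four edges),
and permutation-null calibration over 200 exchangeable datasets × 100
permutations. All stochastic tests fix their seeds; the acceptance script
takes its seed from the command line and derives every random input from
it.

## Known limitations

* PMI is noisy for dyads with very few contacts: two rarely-contacting
  animals that meet a handful of times can reach large PMI because their
  marginals are tiny. APC absorbs much of this, but short observation
  windows (days rather than weeks) leave rank instability among background
  dyads — only the planted/true partner dyads are stable there.
* The APC edge rule ("corrected score strictly positive") has no
  significance interpretation; use the permutation null model when a
  per-dyad error rate is needed.
* The equirectangular degree-to-meter conversion and the CEP/2DRMS
  approximations are planar small-area approximations; at pasture scale
  (hundreds of meters, mid latitudes) the error is far below the GPS noise
  floor.
* `filter_by_activity()` requires whole-minute purity of the state, so
  minutes with mixed activity are discarded from both strata; the two
  stratified networks do not partition the full network's contacts.
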