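# apcnet

Social network inference for GPS-tracked animals via pointwise mutual
information with average product correction.

## The problem

Minute-resolution GNSS collars produce so much data that every pair of
animals in a herd co-occurs at least occasionally, so the mere presence of
proximity contacts says nothing about social preference. Part of the
contact signal is shared background — all animals visit the same watering
trough and resting areas — and part is measurement noise. `apcnet`
separates dyadic preference from that background without building a
coordinate-level null model:

1. **Contacts.** Pairwise haversine distances are computed for every dyad
   and minute where both animals have a fix; a *contact* is a dyad-minute
   whose distance does not exceed a threshold *d* (1, 1.5, 2.5 and 5 m are
   the supported study design).
2. **PMI.** With `f(a,b)` the contact count of dyad *(a,b)*,
   `n = Σ f(a,b)` the total and `f(a) = Σ_b f(a,b)`, contact probabilities
   are `p(a,b) = f(a,b)/n` and `p(a) = f(a)/(2n)` (both sets sum to one),
   and the association score is the pointwise mutual information

       PMI(a,b) = log2[ p(a,b) / (p(a) p(b)) ]

   clamped at zero from below (PPMI).
3. **APC.** The *average product correction*, a background-removal device
   from molecular coevolution analysis, estimates each dyad's expected
   association from the two animals' average PPMI with everyone else,
   relative to the overall average:
   `APC(a,b) = PPMI(a,·) PPMI(b,·) / mean(PPMI)`. The corrected score is
   `PPMI_APC(a,b) = PPMI(a,b) − APC(a,b)`, and the social network has an
   edge wherever this is strictly positive, weighted by the value.

Around that core the package provides the validation machinery such a
study needs: a pre-network permutation null model (shuffle the distance
column of the dyad-minute table, re-threshold, recompute), a missing-data
robustness experiment scored by the graph Hamming distance
`H = |E₁ Δ E₂| / (N(N−1)/2)`, lying/standing activity stratification,
stationary GPS accuracy metrics (CEP, 2DRMS) estimated from lying bouts,
and a herd simulator with planted partner dyads so the whole pipeline can
be exercised against a known ground truth.

## Worked example

```r
library(apcnet)

sim <- simulate_herd(sim_config(duration_days = 2, seed = 1))
fit <- apc_network(sim$tracks, threshold = 1)
fit
#> Social network fit (PPMI with average product correction)
#>   animals   : 8 (A, B, C, D, E, F, G, H)
#>   threshold : 1 m, stratum: all
#>   contacts  : n = 209
#>   edges     : 10 of 28 possible dyads

head(summary(fit)$dyads, 5)
#>   animal_a animal_b  f      pmi     ppmi       apc ppmi_apc edge
#> 1        A        B 83 3.082751 3.082751 0.2082919 2.874459 TRUE
#> 2        C        D 70 2.936530 2.936530 0.5679091 2.368621 TRUE
#> 3        F        H  3 3.722466 3.722466 1.5264909 2.195975 TRUE
#> 4        E        G  3 3.373458 3.373458 1.7378418 1.635617 TRUE
#> 5        F        G  2 2.925999 2.925999 1.5537725 1.372227 TRUE

recovery_report(sim, fit)$ranks
#> A--B C--D
#>    1    2
```

The two planted partner dyads (A–B and C–D) dominate both the contact
counts (`f`) and the corrected scores; the remaining dyads' PPMI is mostly
absorbed by their APC background estimate. GPS quality from the simulated
lying bouts recovers the configured per-axis noise:

```r
gps_quality(sim$tracks, sim$activity)
#> <gps_quality> 60 lying bout(s), 7534 fixes
#>   sd latitude : 1.03 m
#>   sd longitude: 0.80 m
#>   CEP (50%)   : 1.08 m
#>   2DRMS (95%) : 2.61 m
```

A command-line wrapper over the same functions lives in
`inst/cli/apcnet.R` (subcommands `simulate`, `distances`, `contacts`,
`network`, `nullmodel`, `robustness`, `quality`, `compare`).

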