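---
title: "Sexual conflict with a molecular decoy: model, simulator and rate-correlation analysis"
author: "decoysim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sexual conflict with a molecular decoy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(decoysim)
```

## The biological question

Gamete-recognition proteins are among the fastest-evolving genes known.  In
abalone, the sperm protein lysin dissolves the egg's vitelline envelope by
binding the giant receptor VERL, and branch-specific dN/dS estimates show
the two co-evolving: branches with rapid lysin evolution are branches with
rapid VERL evolution.  A VERL paralog, VEZP14, binds lysin with similar
affinity yet shows the *opposite* pattern — its lysin-binding motif evolves
rapidly exactly when lysin does not.  One hypothesis that reconciles both
patterns is molecular mimicry: VEZP14 may act as a *decoy* receptor, binding
excess sperm ligand without performing VERL's effector function, thereby
lowering the effective fertilization rate toward the female optimum.

`decoysim` implements an individual-based model of this hypothesis: sexual
conflict over mating rate between a male-expressed ligand locus and a
female-expressed receptor locus, extended with a female-expressed decoy
locus and a neutral control locus, plus the substitution-rate correlation
analysis used to compare simulated dynamics with branch-specific dN/dS
patterns.

## The model

Each of `N` diploid individuals carries two alleles (integers in
`0..allele_max`, default 50) at four loci: male-expressed ligand,
female-expressed receptor, female-expressed decoy, and a neutral control.
Alleles act additively: a phenotype is the mean of the two allelic values,
normalized by `allele_max` so that all distances live on [0, 1].

**Baseline mating rate.** For a male with phenotype $z_m$ and a female with
phenotype $z_f$, the phenotypic distance $D_{MF} = |z_m - z_f|$ sets the
per-encounter mating probability

$$P_{MF} = \exp\!\left[-\left(D_{MF}/s_p\right)^{x_p}\right],$$

which is 1 at zero distance and decays monotonically.  Males maximize
reproductive output at $P = 1$; females at an intermediate optimum
$P_{opt}$, because a female's expected offspring number is

$$W_f = B_{max} \exp\!\left[-\left(|P - P_{opt}|/s_w\right)^{x_w}\right].$$

The disagreement between the two optima is the engine of the co-evolutionary
chase: above $P_{opt}$ females are selected away from males, males are
selected after them.

**The decoy.** The decoy only acts when its phenotype lies strictly between
the male's and the female's ($\theta = 1$); ties give $\theta = 0$, since a
decoy indistinguishable from the receptor cannot divert ligand from it.
When active, the decoy pulls the pair's mating rate to the female optimum
minus two interference terms:

$$P' = \mathrm{clamp}\!\left(P_{opt} - P_t - P_i,\; 0,\; 1\right)$$

$$P_t = P_{opt}\,\min\!\left[1, \left(\frac{|D_{MF} - D_{opt}|}{s_d}\right)^{x_d}\right],
\qquad
P_i = P_{opt}\, c_0 \,\min\!\left[1, \left(\frac{d_{MD}}{s_i}\right)^{x_i}\right],$$

where $D_{opt}$ is the optimal male–female separation for decoy function and
$d_{MD}$ is the male–decoy distance.  $P_t$ penalizes pairs whose separation
deviates from $D_{opt}$ and deliberately does *not* depend on where the
decoy sits: if the decoy could cancel this penalty by tracking the male, the
decoy would simply join the chase as a third runner, and simulated
male–decoy rates become strongly *positively* correlated — the opposite of
the pattern the model exists to explain.  $P_i$ is the positional
interference of a decoy too similar to the true receptor; it fades as the
decoy approaches the male, which is what gives the decoy locus its own
selection gradient.  At $D_{MF} = D_{opt}$ with the decoy at the male the
rate equals $P_{opt}$ exactly; at a deviation of 0.5 the penalty reaches
$P_t \approx P_{opt}$ and the rate collapses to 0 regardless of decoy
position.

**The cycle.** These ingredients produce a recurrent four-phase dynamic:
(i) a two-locus chase with mating rate above $P_{opt}$; (ii) when the chase
sweeps across the decoy's phenotype at a separation near $D_{opt}$, the
decoy activates and the mating rate drops below $P_{opt}$, halting the
chase; (iii) the decoy evolves toward the male, shrinking $P_i$, and the
rate recovers toward $P_{opt}$; (iv) once the decoy sits at the male,
crossing it costs males nothing ($P_{MF}(D_{opt}) > P_{opt}$), the decoy is
left outside the interval, and the chase resumes.  The male and female move
together in phases (i)/(iv) while the decoy is still; the decoy moves in
phase (iii) while they are still.  Windowed substitution rates therefore
correlate positively between male and female and negatively between male
and decoy — unless a replicate happens to spend its time in transient
decoy–male chases, which removes the anti-correlation in that run.  Both
outcomes occur across replicates, matching the mixed replicate-level counts
the model is known for.

## Generation loop

Each generation: every female encounters `n_encounters` males drawn
uniformly with replacement and mates with each at probability $P'$ (her own
decoy genotype applies); mothers of the next generation are sampled among
mated females proportionally to $W_f$ of their *realized* mating rate
(matings/encounters); each offspring's sire is drawn uniformly from its
mother's mate multiset; each parent transmits one allele per locus
independently; transmitted alleles mutate with probability `mu` by a
single step up or down, reflecting at the allele-space boundaries; sex is
assigned uniformly.  Population size is exactly `N` every generation.
These choices fill gaps the verbal model description leaves open; they are
the simplest schemes consistent with it (fixed-size fecundity-proportional
regulation, uniform encounters, realized rather than expected rate, no
linkage).

The loop is implemented in C++ (Rcpp).  Because mating rates depend only on
the three integer allele sums, all pair rates are precomputed once into a
lookup table; the table is exported for testing and is verified against the
pure-R model functions.  Randomness comes from a xoshiro256++ generator
seeded per replicate by splitmix64 of (base seed, replicate index), so any
replicate is bit-reproducible in isolation, independent of R's RNG.

## Default parameter values

Simulation settings follow the published study conditions: `N = 10000`,
`15000` generations, `20` encounters per female, `mu = 5e-5` per locus per
gamete per generation, initial allelic values male 0 / female 5 / decoy 16 /
neutral 30, rate windows of `500` generations, `20` replicates.  The allele
space is widened to `0..50` so the male initial value 0 is representable.

The model-curve parameters are not printed in a machine-readable form in the
source material, so the package fixes its own defaults, chosen once as the
regime in which all four phases of the cycle occur at the published
population size and then frozen:

| parameter | default | meaning (units) |
|---|---|---|
| `P_opt` | 0.5 | optimal female mating rate (probability/encounter) |
| `B_max` | 10 | maximum offspring per female |
| `s_w`, `x_w` | 0.3, 2 | fecundity penalty scale (rate units) and exponent |
| `s_p`, `x_p` | 0.1, 2 | baseline rate decay scale (distance units) and exponent |
| `D_opt` | 0.08 | optimal separation for decoy function (distance units) |
| `sd`, `xd` | 0.04, 2 | deviation penalty scale (distance units) and exponent |
| `si`, `xi` | 0.05, 2 | positional interference scale (distance units) and exponent |
| `c0` | 0.25 | positional interference magnitude (fraction of `P_opt`) |

The decisive relationships, in order of importance: `D_opt` must sit at the
separation the chase naturally runs at (about 3–4 allele units at
`N = 10000` under `s_p = 0.1`), or the decoy never activates; `sd` must be
small enough that `P_t` reaches its cap within a couple of allele units of
deviation, or the decoy profitably tracks the chase as a third runner;
`c0 · P_opt` must stay below the decoy effectiveness `Pe = P_MF − P_opt`
typical of the chase band, or females whose decoy enters the interval are
purged and the decoy is pushed ahead of the sweep instead of being captured
by it; and `P_MF(D_opt) > P_opt` must hold, or phase (iv) never starts and
the system locks.  `validate_params()` enforces the feasibility conditions
that have a closed form: a nonempty functional band, fecundity
non-inferiority of the evolved decoy configuration over that band
(the `Pi < Pe` condition), and `P_t(0.5) ≥ 0.9 P_opt`.

## Rate analysis

`substitution_rates()` converts a trajectory of per-generation mean allelic
values into per-window absolute changes — a nonnegative rate proxy
comparable to branch-specific dN/dS (signed changes are kept as an
attribute).  `fit_rate_regression()` fits ordinary (or weighted) least
squares of one locus's rate series on another's with the two-sided t-test
of zero slope; `classify_correlation()` calls a pair positive/negative at
`p < alpha` (default 0.05), the criterion `p > 0.05` appearing in one place
in the source text being treated as a typographical slip for `p < 0.05`.
`summarize_replicates()` counts classifications across replicates and runs
Fisher's exact test on a configurable 2×2 contrast, by default
negative-significant vs not for the male–decoy pair against the
male–neutral control.  `fisher_exact_2x2()` enumerates the hypergeometric
support directly; the test suite verifies it against independent
enumeration for every 2×2 table with total ≤ 40 and against
`stats::fisher.test`.

The same regression applies unchanged to empirical branch-rate tables
(`read_branch_rates()`, `branch_rate_regression()`, with weights equal to
branch lengths when requested).  Estimating the per-branch dN/dS values
themselves is out of scope; tables are ingested in a documented
tab-separated format (`branch`, `length`, one column per gene).
`simulate_branch_rates()` generates fixture tables with a known linear
relationship (gamma-distributed predictor rates, Gaussian noise, gamma
branch lengths with mean 0.1 substitutions/codon) for testing and
calibration; it emulates the *shape* of codon branch-model output, not the
phylogenetic correlation structure of real trees, so passing recovery tests
says nothing about, e.g., shared-branch non-independence in real data.

## Problem sizes, determinism and degenerate inputs

The shipped test suite exercises the full published scale (20 replicates at
`N = 10000` for 15000 generations) once, in its replicate-level
reproduction test; all other tests use deliberately small populations
(N ≤ 500, ≤ 2000 generations) chosen to finish quickly while still showing
each behavior.  The packaged acceptance script runs a scaled-down version
of the study (20 replicates at `N = 1000`, 5000 generations, 250-generation
windows).  At that size the dynamics are mutation-limited (`2Nμ = 0.1` new
mutations per locus per generation) and the per-window rates are closer to
the drift floor, so per-replicate significance counts are noisier than at
full scale; the full-scale counts are the meaningful comparison to the
published replicate tallies.

Degenerate cases are handled explicitly: a rate series with zero variance
raises a typed degenerate-fit condition from `fit_rate_regression()` and is
reported as classification "none" by the per-trajectory analysis; a
constant response gives slope 0 with r² = 0; replicates in which no female
mates abort with a diagnostic and are reported alongside the successful
ones by `run_replicates()`.  Mutation reflects at the allele-space
boundaries, so allelic values can never leave `0..allele_max`.

## Known limitations

* One trait dimension; the decoy is between the sexes' phenotypes or it is
  not.  No spatial structure, no linkage, no explicit binding biochemistry.
* The exact functional forms are a faithful reconstruction of the described
  curve shapes, not a transcription of the original equations; the
  parameter table above is the package's own calibration, and replicate
  counts should be compared qualitatively (majorities, dominance,
  significance of the Fisher contrast), not digit-for-digit.
* The neutral control is only an α-level control: testing three neutral
  pairs per run at α = 0.05 yields a chance-level expectation of ~2.9 of
  20 runs with some significant neutral pair; strong selection episodes
  also modulate effective population size, which can nudge neutral windowed
  rates in either direction at small `N`.
* Empirical branch-rate regressions depend on upstream codon-model output
  that this package does not produce.
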