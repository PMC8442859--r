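---
title: "Models and methods behind cgpsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind cgpsim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`cgpsim` studies how sweepstakes reproductive success together with
collective larval dispersal produces chaotic genetic patchiness: cohorts of
close kin with depressed diversity appearing at single sites, below the
spatial scale of effective dispersal. This vignette documents the models,
the tunable parameters, the numerical choices, and the limits of what the
synthetic experiments can show.

## The spawning-stack model

Adults aggregate in "stacks" of up to `St = 20` individuals at a 1:1 sex
ratio. At the start of a generation the population is randomly partitioned
into balanced stacks of `St/2` females and `St/2` males; leftovers form one
final smaller balanced stack and any unpairable remainder stays unstacked.
`St` must be even, between 2 and 20 — an odd stack cannot hold a balanced
sex ratio, so it is a configuration error, not a silent adjustment.

Sweepstake reproduction picks one focal stack uniformly among complete
stacks and designates `F` of its females as breeders. Exactly `K` offspring
are then produced; each draws its mother uniformly from the `F` breeders
and its father uniformly, with replacement, from the focal stack's males.
Offspring are produced one at a time with independent parent draws — the
simplest scheme consistent with random mating up to a carrying capacity;
there is no clutch structure. With `F = 1` every offspring pair shares a
mother, so a sampled cohort can contain only full- and half-siblings — the
"success" criterion of the single-population experiments. With five males
per stack the expected full-sib pair fraction is 1/5.

The "relaxed" regime used for non-source demes (and for the multi-stack
control) lets every complete stack breed: each offspring's mother is drawn
uniformly from all stacked females and its father from the males of her
stack. The parameterisation of "less strict" reproduction is genuinely
open; we chose maximal contrast with the sweepstake mode and exposed the
pieces (stack size, eligibility) as arguments.

Genotypes are optional in the simulator. When present, transmission is
Mendelian over unlinked biallelic loci (free recombination): each parent
contributes one allele per locus, drawn uniformly from its two. Linkage
disequilibrium inside family cohorts therefore arises purely from
co-ancestry, which is the signal of interest, not from physical linkage.

## Metapopulation, collective dispersal, decay

Five demes form a linear stepping-stone chain; the sink sits at position 3
(so it has two neighbours, matching the idea of "populations adjacent to
the sink") and the source at position 5. The chain layout is a design
choice — only the source/sink/neighbour roles matter.

Each generation: the source reproduces by sweepstake (`F = 1`, `K = 1000`,
`St = 10` by default), the other demes in relaxed mode, `K` offspring per
deme. Collective dispersal then moves `round(CD·K)` uniformly chosen source
offspring into the sink. We implement this as an *exchange*: the displaced
sink-born offspring take the dispersers' place in the source. Removal would
leave the source below `K` at high CD (breaking fixed-`K` regulation), and
copying would leave the source holding the same family — the exchange keeps
every deme at exactly `K` while making the sink cohort the dispersed
family, which is the phenomenon under study. Finally, adjacent demes swap a
fraction `m` of their offspring (selections made simultaneously and
disjointly, sizes preserved).

Two further definitions deserve a note:

* **The CD sweep's diversity ratio** is π(sink offspring cohort) divided by
  π(the source's *parental* standing population). The source offspring
  cohort is itself always a single sweepstake family, so it cannot serve as
  the baseline for "how much diversity did the sink lose"; against the
  parental baseline the ratio is ≈ 1 at `CD = 0` and declines as CD grows.
* **The CD sweep defaults to `m = 0`**, isolating collective dispersal, so
  that `CD = 1` reduces exactly to the single-population sweepstake case
  (success probability 1). Any `m > 0` applied after dispersal would mix
  ~`2m` unrelated migrants into the sink and cap success at roughly
  `(1 − 2m)^10`. Stepping-stone mixing is switched on (default `m = 0.1`)
  in the decay experiment, where it is the mechanism that spreads
  low-diversity haplotypes and transient close kin to neighbouring demes.

The decay experiment runs one high-CD event generation and then three
generations with all demes relaxed and `CD = 0`. Close kin (one-generation
pedigree memory: full-sib if both parents shared, half-sib if one) vanish
from the sink within two generations because outcrossing produces offspring
whose parents are numerous, while π remains depressed because the
low-diversity haplotypes keep segregating — the same dissociation seen in
the decay trajectories the package reports (sampled cohorts of 10, π per
deme and generation).

## Kinship estimation

Two estimators are computed per pair, over loci non-missing in both
individuals:

* **Moment IBD**: expected identity-by-state class counts are linear in
  (Z0, Z1, Z2) with closed-form coefficients in the pooled allele
  frequencies; the triangular 3×3 system is solved, estimates are clamped
  to [0, 1] and renormalised to the simplex, and PI_HAT = Z2 + Z1/2. Allele
  frequencies come from the pooled analysis sample, never from a single
  cohort — inside a family cohort, cohort frequencies are badly biased.
  Loci with pooled MAF < 0.01 are dropped (they carry no IBS information
  and destabilise the system); pairs with fewer than 100 jointly genotyped
  loci are flagged unreliable. The classical small-sample bias correction
  is omitted; the uncorrected estimator is consistent at large L and is
  validated by parameter recovery on synthetic pedigrees.
* **Robust kinship** φ = (N_AaAa − 2·N_AAaa)/(N_Aa,i + N_Aa,j), requiring
  no allele frequencies. Expected values: 0.5 duplicates, 0.25 first
  degree, 0.125 second degree, ~0 unrelated.

Categories use the standard powers-of-two φ bounds (half-open on the right,
a convention the data cannot distinguish), with first degree split by
Z0 < 0.1 into parent-offspring (Z0 = 0 in expectation) versus full-sib
(Z0 = 0.25). Cohort summaries map onto the three reported classes
(full-sib, half-sib, unrelated); third/fourth degree and beyond count as
unrelated, duplicates are excluded with a warning. At realistic panel
sizes a couple of true half-sib pairs per 45 can fall just below the
second-degree bound — family cohorts are recovered as sib-*dominated*, not
always sib-perfect, which mirrors real cohorts.

## Cohort statistics

π is the mean of the unbiased per-site diversity (n/(n−1))·2p̂(1−p̂) over
the SNPs segregating in the *pooled* panel, so cohorts are compared on a
fixed denominator and only relative π is interpreted. LD is composite
(genotype-dosage correlation), avoiding phasing. Pairwise F_st is the
Weir–Cockerham θ, combined over loci as the ratio of summed variance
components, with negative estimates reported as computed; significance
comes from bootstrap resampling of loci (one-sided, proportion of
replicates with F_st ≤ 0), Bonferroni-corrected across cohort pairs.

The folded spectrum counts minor alleles, j = 1..⌊n/2⌋, over sites fully
genotyped and segregating within the cohort; the j = n/2 class for even n
is included as its own (unpaired) class. All spectra are normalized before
comparison.

## Coalescent models and the l₂ comparison

Under the Kingman coalescent the normalized expected unfolded spectrum is
(1/i)/H_{n−1}. The Xi-Beta(2−α, α) coalescent, 1 < α < 2, models diploid
sweepstakes: a reproduction event involves k of the b ancestral lineages at
rate proportional to C(b,k)·λ_{b,k}, λ_{b,k} = B(k−α, b−k+α)/B(2−α, α),
and the participants distribute uniformly over four parental groups
(the four genome copies of the parent pair), every group of two or more
merging simultaneously. Candidate events in which no group reaches size two
change nothing; their holding time still elapses, which is correct because
the superposed exponential clocks are memoryless. Time is measured on the
pair-coalescence scale (two lineages merge at rate 1); normalized spectra
are invariant to this choice.

Expected spectra are estimated by Monte Carlo (default 20,000 genealogies,
class standard errors below ~0.002 for n ≤ 40; delta-method SEs are
attached per class and cached per (n, α, replicates, seed)). An exact
first-step-analysis oracle enumerates the configuration space (integer
partitions of n) for n ≤ 5 and solves the linear occupation-time equations,
pinning down the process semantics independently of the simulator; the two
agree within Monte-Carlo error across α, and the α → 2 limit reproduces the
Kingman closed form to ~10⁻³ at α = 1.99.

Model choice minimises l₂ = Σ_j (x_j − y_j)² (no square root) between the
empirical and expected normalized folded spectra, over Kingman and an α
grid (default 1.05–1.95 in steps of 0.05). Ties within 10⁻¹² go to Kingman
on parsimony. The Monte-Carlo noise of the expected spectra is propagated
into a tolerance on the l₂ difference; a Xi-Beta preference smaller than
this tolerance is reported as not decisive.

## What the synthetic data can and cannot show

Founder pools draw per-locus frequencies from uniform, beta, or "neutral"
(log-uniform, density ∝ 1/p) distributions, monomorphic loci excluded at
creation; founders are Hardy–Weinberg draws. The neutral pool matters: a
sample on 1/p standing variation has an unfolded spectrum ∝ 1/j, i.e. the
Kingman expectation, making it the correct null for model-comparison
experiments (uniform pools give a flat sample spectrum that fits neither
family well — they emulate an ascertained SNP panel, which is what the
kinship and π analyses use).

One finding worth stating explicitly: a cohort sampled *one generation*
after a sweepstake event on neutral standing variation does **not** show
the multiple-merger spectrum signature. Mendelian segregation redistributes
the parents' variants to intermediate frequencies, producing a singleton
*deficit* (folded singleton ≈ 0.21 versus the Kingman 0.30 at n = 20), and
the Xi-Beta family — whose folded singleton class grows as α decreases —
fits such a spectrum *worse* than Kingman. The spectrum signature of
sweepstakes lives in standing variation shaped by *recurrent* sweepstakes
with mutation. `simulate_sweepstake_cohort()` therefore runs the forward
model for many generations (default 25, K = 200, L = 20,000) with a
symmetric per-transmission mutation probability (default 5·10⁻⁴) until
variation is at drift–mutation balance; its cohorts are star-like and
singleton-rich and decisively select Xi-Beta at small α. Everywhere else
the mutation rate defaults to zero.

The generator emulates cohort-labelled SNP-panel data: tens of cohorts of
~10 diploids, thousands of unlinked biallelic loci, one cohort a
single-mother family, optional uniform missingness (encoded ./. in VCF,
excluded pairwise in estimators). It does not emulate sequencing error,
linked loci, RAD locus dropout, or population structure among the
unrelated cohorts — so passing tests demonstrate estimator correctness and
the internal consistency of the simulated mechanism, not robustness to
those real-data artefacts.

## Problem sizes and reproducibility

Defaults were chosen so the full study-scale experiments run in minutes on
one core: L = 5,000 loci for the study-like dataset (kinship classification
error negligible), L = 1,000 for simulation experiments (π ratios stable),
100 replicates for the single-population and CD experiments, 50 for decay,
20,000 Monte-Carlo genealogies per expected spectrum. All randomness flows
from one master seed through named substreams (`substream_seed`), so
results are bit-reproducible and adding a stage never perturbs the streams
of existing stages; every experiment object records its seed.
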