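---
title: "Sweep definitions, mutation pressure, and null models: methods"
author: "sweepverdict"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sweep definitions, mutation pressure, and null models: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sweepverdict)
```

# What this package models

`sweepverdict` implements the computational machinery behind a methodological
argument in the soft-versus-hard selective sweep debate. It has three legs:

1. **A single-site Wright–Fisher model** of two beneficial nucleotides (C and
   T) competing against a wild-type background (A, with G as a selectively
   equivalent state) in a large population with recurrent mutation, together
   with frequency-threshold classifiers that call "sweep" and "soft sweep"
   from a mid-trajectory snapshot and then ask what the same replicate looks
   like a generation horizon later.
2. **A deterministic selection–mutation model** for the frequency of a
   beneficial allele, used to separate mutation-driven from selection-driven
   frequency change.
3. **A forward simulator of a 100-kb *Drosophila*-like genomic element** with
   exon/intron architecture, a discretized deleterious DFE, heterogeneous
   recombination, multi-deme non-equilibrium demography and Q-fold rescaling,
   summarized by H12 haplotype homozygosity in SNP-count windows — the
   ingredients of a purifying-selection-aware null model for haplotype scans.

Everything is simulation-based; the package analyses no empirical data.

# The single-site model

A diploid population of size $N$ (default $10^5$) evolves at one nucleotide
site under a finite-site model: each gamete mutates with probability $\mu$
(default $10^{-5}$ per site per generation) to one of the three other
nucleotides, chosen uniformly. We read the source model's "per replication"
rate as per generation, consistent with its own 1–2 day generation-time
framing. Fitness is semidominant with genotype values

$$w_{AA}=w_{GG}=w_{AG}=1,\quad w_{TT}=1+s_T,\quad w_{CC}=1+s_C,$$
$$w_{AT}=w_{GT}=1+\tfrac12 s_T,\quad w_{AC}=w_{GC}=1+\tfrac12 s_C,\quad
w_{TC}=1+\max(s_C,s_T).$$

The $\max$ rule for the C/T double heterozygote applies regardless of sign
ordering; no averaging variant is offered because the rule is explicit.
Simulations start fixed for A and record snapshots at generations 30 and 60.

**Life cycle.** `wf_generation()` forms Hardy–Weinberg genotype proportions
from the current allele frequencies, weights them by fitness, draws $2N$
gametes multinomially from the post-selection allele frequencies, then
mutates offspring gametes. This gamete-level formulation is
orders-of-magnitude faster than individual bookkeeping at $N=10^5$ and has
the same diffusion limit; deviations from an individual-based scheme are
$O(1/N)$ in the offspring-number distribution. Selection acts on parents and
mutation on offspring gametes, matching the default life cycle of forward
simulators; the source text does not state its order, so this is a
documented choice, not an inference.

**Seeding.** Grids derive one RNG stream per (cell, replicate) from the
master seed with a counter-based integer hash (`derive_seed`), so any cell
or replicate can be reproduced in isolation.

# Classification thresholds

`classifier_thresholds()` carries five numbers: combined beneficial
frequency for a "sweep" call (0.5 at generation 30), per-allele frequency
for a "soft" call (0.05, inclusive `>=`), and the horizon rules at
generation 60. Two phrasings of the soft rule circulate ("5% or greater"
vs. "greater than 5%"); the inclusive reading is the default and the
comparison operator is a flag. The soft call is defined *conditionally* on
the sweep call — `is_soft_feder()` refuses to answer otherwise, and
`grid_proportions()` uses the number of sweep calls, never the replicate
count, as the soft-call denominator. Cells with empty denominators report
`NA`, not 0. The "2 of the alleles" in the soft definition means the two
beneficial nucleotides specifically: the classification concerns competing
beneficial mutations, not the wild-type states.

**The horizon call.** No number is published for what "a single nucleotide
brought to high frequency" means, so both cutoffs are parameters:
`high_freq` (default 0.5) for the winner and `single_low_max` for the
loser. The default `single_low_max = soft_freq` demands that the losing
allele has dropped out of the soft-call range. Note a structural fact about
the equal-effects diagonal: when $s_C = s_T$, the two beneficial alleles are
selectively neutral *relative to each other* ($w_{TC}=w_{CC}=w_{TT}$), so at
$N=10^5$ the minor allele's share essentially cannot decline between
generations 30 and 60, and the strict default never fires there. For the
diagonal question — was only a *single* nucleotide brought to high
frequency? — the meaningful setting is `single_low_max = high_freq`, which
the package's own phase-diagram checks use and state.

# The deterministic model

With one-way recurrent mutation into a beneficial allele at frequency $x$,

$$\Delta x = \mu(1-x) + s\,x(1-x) = (\mu + s x)(1-x),$$

per generation; back mutation is neglected (the stochastic boundary phase is
brief and $x$ is small there). The scaled selection strength is
$\alpha = Ns$ (haploid) or $2Ns$ (diploid), and a strongly beneficial allele
behaves deterministically once past the establishment threshold
$x_0 = 5/\alpha$. Two printings of this threshold and of the
mutation-dominance condition are typographically garbled in the source
("$x_0 = 5\alpha$", "$\mu > s x_0 = 5N$"); we adopt $5/\alpha$ and $5/N$ on
dimensional grounds — $x_0$ must be a small frequency when $\alpha \gg 1$,
and $s \cdot 5/(Ns) = 5/N$ makes the two statements consistent. With
$\theta = N\mu$ (fixed by the model's own correspondence $\theta = 1$ at
$N = 10^5$, $\mu = 10^{-5}$), mutation dominates selection at the threshold
exactly when $\theta > 5$: at $\theta = 10$ observed frequency change is
primarily mutational input, at $\theta = 1$ it is not.

**Numerical behavior of the recursion.** `integrate_trajectory()` iterates
the printed difference equation (the discrete recursion is primary; the
continuous logistic serves only as a small-$s$ oracle). The recursion is a
forward-Euler step of the logistic flow, so its offset from
$x(t) = x_0 e^{st}/(1-x_0+x_0 e^{st})$ accumulates to roughly
$\tfrac{s}{2}\ln\frac{1-x_0}{x_0}$ in relative terms — about $3.45\,s$ for
$x_0 = 10^{-3}$. Agreement with the continuous form at 1% therefore holds
only for $s \lesssim 0.003$; at $s = 0.05$ the recursion instead matches the
logistic with discrete-time rate $\log(1+s)$ to within 2%. The test suite
freezes exactly these oracle-computed statements. Steps with
$\Delta x > 0.5$ (very large $s$) are flagged as outside the recursion's
validity regime rather than silently accepted.

**Connecting the two models.** The diploid semidominant simulator has exact
mean update $x' = x\,(1+\tfrac12 s_C(1+x))/(1+s_C x)$; at low frequency this
is the haploid recursion with coefficient $\tfrac12 s_C$. The
stochastic–deterministic consistency check therefore runs the recursion with
$s = s_C/2$ from $x_0 = 5/(2Ns_C)$ and compares it with Wright–Fisher means
conditioned on non-loss, over the first 30 generations where $x$ stays small
enough ($\lesssim 0.05$ at $s_C = 0.52$) that the $(1+s_C x)$ denominator is
negligible.

# The forward chromosome simulator

**Architecture.** The default 100-kb region carries 33 genes of 5 exons
(300 bp) and 4 introns (100 bp), each followed by a 1,068-bp intergenic
spacer: $33 \times 2968 = 97{,}944$ bp. The unspecified trailing 2,056 bp
are assigned intergenic, which makes the exonic fraction exactly the
published 49.5%. Placement of intergenic sequence after each gene is a
documented tiling choice.

**DFE.** New exonic mutations fall into four classes with weights
0.23/0.51/0.04/0.22: neutral, mild ($-10 \le 2N_{anc}s < -1$), moderate
($-100 \le 2N_{anc}s < -10$) and strong ($2N_{anc}s < -100$), with $s$
uniform within each class after descaling by $2N_{anc}$ (the ancestral
size). The strong class is unbounded below in its source, so $s$ is capped
at $-1$ (recessive-lethal scale) to keep fitness non-negative. Dominance is
fixed at $h = 0.5$ and fitness is multiplicative across sites. Mutations
outside exons are strictly neutral.

**Recombination.** Maps are per-10-kb-bin crossover rates in cM/Mb,
converted as $r = \text{cM/Mb} \times 10^{-8}$ per bp per generation.
`sample_recombination_map()` draws contiguous 10-bin runs from a
genome-scale table with replacement and resamples until the acceptance rule
passes. The published filter ("rates greater than 0.5 cM/Mb") is ambiguous
between per-bin and region-mean readings; the default is region mean with a
strict `>`, with per-bin and inclusive modes behind flags, and a bounded
resample budget that fails with a diagnostic rather than spinning. Whether
one map serves all replicates or each replicate redraws its own is equally
unstated; the package leaves this to the caller (a map is an argument, so
either policy is one line of user code) and its own checks redraw per
replicate.

**Demography.** Models are specified forward in time as named demes plus
scheduled events (size change, exponential growth, split, admixture pulse,
continuous migration). `compile_demography()` lowers this to a
per-generation plan: a deme-size matrix and one ancestry matrix per
generation, where row $d$ gives the probability that a parent of a deme-$d$
offspring comes from each deme. Splits and admixture pulses are one-
generation ancestry rows; migration edits the rows of all subsequent
generations. Each simulated individual draws the source deme of each parent
independently from its row. A burn-in of $10 N_{anc}$ generations at the
initial sizes precedes the scheduled span, which is the standard
equilibration horizon for forward simulation (diversity reaches its
stationary mean well within $10N$).

**Rescaling.** `rescale_model(base, Q)` divides sizes, times and durations
by $Q$ and multiplies mutation, recombination and migration rates — and
selection coefficients, via descaling the DFE's $N_{anc}$ by $Q$ — so that
$N\mu$, $Nr$, $Nm$ and $Ns$ are preserved to within rounding. The source
lists "all parameters" without naming $s$; multiplying $s$ is the only
reading that preserves $2Ns$, which the DFE is defined on. Rescaled models
refuse to build when a deme would round below 2 diploids or two event times
would collide into the same generation — the same degeneracy that motivated
holding the focal populations constant post-admixture in the originals.

**Mutation model.** Infinite sites on integer bp positions: positions in
use are never re-drawn; if the region begins to saturate (80% of positions
ever used), globally extinct positions are recycled, and the run aborts if
live variation truly saturates the region. This matches the coalescent
oracle's assumptions and keeps VCF output unambiguous.

**Sampling.** At the end of the run, 145 haploid genomes (the canonical
sample size here) are drawn without replacement from the focal deme's $2N$
gametes — "genomes", not diploid individuals, matching the input convention
of haplotype statistics — and monomorphic sites are dropped.

The per-generation engine is C++ (via Rcpp), the tier at which comparable
forward simulators operate; model construction, compilation and analysis are
R.

# Haplotype statistics

For descending window haplotype frequencies $p_1 \ge p_2 \ge \dots$:

$$H_1 = \sum_i p_i^2,\qquad H_{12} = (p_1+p_2)^2 + \sum_{i\ge3} p_i^2,\qquad
H_2 = H_1 - p_1^2,$$

with $H_2/H_1$ as the soft-vs-hard discriminator. Windows are SNP-count
windows (default 401 SNPs) advanced by a step (default 50 SNPs — the
convention of the scan this follows; "sliding" alone fixes no step, so the
step is a first-class parameter and every reported summary states it). The
final partial window is dropped; samples shorter than one window yield an
empty result with a warning. Haplotype strings are compared over raw allele
codes, so multi-allelic sites need no special-casing; ties in the spectrum
are broken lexicographically for determinism. Distribution summaries
(`summarize_distribution()`) support both pooled-across-windows and
per-replicate-mean modes because published "mean [SD] over replicates"
phrasing does not distinguish them; pooled is the default and both are one
flag apart. Truncating histograms at 0.05 is a plotting convention only and
is never applied to summaries.

# Synthetic data and oracles

The generator module exists so that every stage can be tested without
downloads:

- `make_toy_rate_table()` emulates a genome-scale 10-kb-bin rate table
  (uniform, lognormal, or hot/cold mosaic laws).
- `make_planted_sample()` realizes an exact haplotype spectrum by binary-
  encoding the distinct haplotypes, so H-statistic values are known by
  construction.
- `coalescent_sample()` is a standard neutral constant-size coalescent
  (exponential coalescence times at rate $k(k-1)/2$ on the $2N$ scale,
  Poisson mutations at $\theta/2$ per branch-length unit, infinite sites).
  It deliberately omits recombination and demography: it is a validation
  device, not a second simulator, so forward-vs-coalescent comparisons are
  restricted to neutral, constant-size, $r=0$ settings.
- `make_toy_demography()` provides constant, bottleneck-growth, and
  split-plus-admixture templates whose *structure* mirrors the published
  North American *D. melanogaster* histories (ancestral deme, split,
  admixture pulse forming the focal deme, constant size post-admixture) at
  desk-scale sizes. The numeric values are this package's own choices
  ($N = 500$, span $4N$, $\mu$ giving per-site $\theta = 5\times10^{-4}$ —
  a realistic per-site diversity scale); they are *not* the published
  posterior modes. The two fitted models themselves ship only as
  `inst/extdata` YAML templates whose numeric slots are explicit `EXTERNAL`
  placeholders: the package never asserts those values, and the printed
  H12 means/SDs under those demographies are reproducible only after a user
  fills the placeholders from the original publications.

**What passing tests do and do not show.** The generators plant known
spectra and known expectations; agreement shows the statistics and engines
are computed correctly and are mutually consistent at equilibrium. Real
data add linked selection at all scales, gene conversion, inversion
polymorphism, variable mutation rate and finite-sites homoplasy, none of
which the toy generators emulate — so green tests validate the machinery,
not any claim about *D. melanogaster* itself.

# Problem sizes and tolerances in the checks

Stochastic checks run at sizes chosen to give 3-standard-error resolution
well below the effect being asserted: the phase-diagram grid uses
$3\times3$ cells $\times$ 200 replicates at $N=10^5$; drift and
establishment checks use $10^4$–$2\times10^4$ absorbing runs at
$N \le 500$; forward-vs-coalescent comparisons use 150 replicates per arm at
$N = 200$, $\theta = 20$; rescaling comparisons use 60 replicates per arm at
$N = 300$ with $Q = 10$, 51-SNP windows. All statistical assertions are
3-SE bands (binomial or empirical); exact assertions (annotation
arithmetic, H-statistic enumeration, factorization identities) carry
tolerances at machine precision.

# Known limitations

- No within-host viral compartment structure, drug dynamics, or linked
  fitness variation in the single-site model; it is single-locus by design.
- The deterministic module is one-locus, no back mutation, no diffusion
  solver; its haploid recursion maps onto the diploid simulator only
  through the $s/2$ low-frequency correspondence described above.
- The forward simulator has no beneficial mutations (the null-model
  scenarios here are neutral and neutral-plus-purifying only), no X
  chromosome, no inversions, no gene conversion.
- The coalescent oracle has no recombination; whole-region comparisons at
  $r > 0$ would need an external coalescent-with-recombination simulator.
- H12 windows require at least one full SNP window; short regions return
  empty results rather than partial-window statistics.
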