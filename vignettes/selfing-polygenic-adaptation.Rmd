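---
title: "Polygenic adaptation under partial self-fertilisation: models, simulator and statistics"
author: "selfpoly"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Polygenic adaptation under partial self-fertilisation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(selfpoly)
```

# The scientific problem

Many adaptive traits are polygenic: an environmental change shifts a
phenotypic optimum, and adaptation proceeds through coordinated
frequency changes at many small-effect variants. Most theory for this
process assumes random mating, yet a large fraction of plants, and many
animals and fungi, self-fertilise. Selfing raises homozygosity
(inbreeding coefficient $F = \sigma/(2-\sigma)$ at neutral equilibrium
for selfing fraction $\sigma$), reduces the effective population size by
$1+F$, and suppresses effective recombination — all of which reshape how
a polygenic response is realised in the genome.

`selfpoly` implements three connected layers for studying this:

1. an **exact two-locus engine** — a deterministic genotype recursion
   under Gaussian stabilising selection and explicit partial selfing,
   together with the weak-selection closed forms it validates;
2. **multi-locus equilibrium theory** with background-association
   coefficients $\beta_i$;
3. a **Wright–Fisher forward simulator** with linked loci, three
   mutation classes and an optimum-shift schedule, plus the downstream
   statistics (variance decomposition, inbreeding depression, LD
   structure, haplotype samples, allele trajectories) and the
   effective-rate rescaling used to compare high selfing with
   low-recombination outcrossing.

# Two-locus engine

Two biallelic loci carry mutant alleles $A$, $B$ with trait effects
$\alpha_A$, $\alpha_B$; fitness is Gaussian,
$w(z) = \exp(-z^2/(2V_s))$. All quantities are scaled by $\sqrt{V_s}$:
$\gamma = \alpha/\sqrt{V_s}$, $d_0 = z_0/\sqrt{V_s}$.

The **exact recursion** (`exactGenerationStep()`) tracks the full
$4\times4$ ordered genotype-frequency matrix. Each generation the
genotypes are weighted by fitness; an offspring is then produced by
selfing a fitness-sampled parent with probability $\sigma$ (two
independent meioses of the *same* parent, so recombination during
selfing is modelled explicitly) or else by the union of two independent
fitness-sampled gametes. This is deliberately stronger than the common
shortcut that builds genotypes from haplotype frequencies via
$g_{ii} = x_i^2 + F x_i(1-x_i)$, $g_{ij} = 2x_ix_j(1-F)$: that
approximation (provided separately as `genotypesFromHaplotypes()`, and
used only to *initialise* a state that lacks a genotype table) ignores
recombination during self-fertilisation and degrades when selfing and
recombination are simultaneously high. Because the recursion is
deterministic and infinite-population, it serves as a brute-force oracle
for the closed forms; drift statements are tested in the forward
simulator instead.

The closed forms implemented and tested against the oracle are the LD
change at the optimum
$\Delta\delta = -(1+3F)p_Ap_B\gamma_A\gamma_B - (\delta/2)\Gamma$ with
$\Gamma = (1+3F)(\gamma_A+\gamma_B)^2 + (1-F)r(2-(\gamma_A+\gamma_B)^2)$;
the critical recombination fraction $3s^2/(2-s^2)$, $s=\gamma_A+\gamma_B$,
below which selfing amplifies selection-generated LD; the
quasi-linkage-equilibrium value
$\delta_{QLE} = -(1+3F)\gamma_A\gamma_B\,p_Ap_B/((1-F)r)$; and the
directional-phase changes
$\Delta p_A = d_0(1+F)(\gamma_Ap_Aq_A + \delta\gamma_B)$ and
$\Delta\delta = \delta(\kappa(1+F) - (1-F)r)$ with
$\kappa = d_0(\gamma_A(q_A-p_A)+\gamma_B(q_B-p_B))$.

**Validity regimes as tested.** The tests measure the one-step error of
the optimum LD form on a joint grid $\gamma, p \propto \zeta$ and
require the error to shrink at least as $\zeta^{2.5}$ (it empirically
scales as $\approx\zeta^5$ from $\delta=0$). The QLE comparison runs
the oracle to its quasi-steady ratio $\delta/(p_Ap_B)$ and requires 10%
agreement on a grid that *excludes* jointly high selfing and
recombination ($\sigma=0.5, r=0.5$ is excluded): there the
$F$-approximation underlying the closed form is known to degrade, and we
measured ~16–19% deviations. The directional forms are checked at
$\gamma = 0.02 \ll d_0 \in \{0.3, 0.5\}$, where the neglected
$O(\zeta^2)$ terms sit below 10% of the leading term; at
$\gamma = 0.05$ the allele-change form is already ~10–20% off, which is
the expected first-order behaviour of the expansion, not a defect.

The full allele-frequency recursions of the two-locus model under
selfing do not reduce to compact closed forms; they are represented in
this package only through the exact oracle.

# Multi-locus theory with background associations

A focal allele $A_i$ does not experience the average genetic background:
stabilising selection builds repulsion LD, so carriers of $A_i$ sit on
backgrounds whose mean deviates by $\beta_{A,i} = \beta_i(1-x_i)$
(and non-carriers by $-\beta_ix_i$). With this one extra (time-dependent)
quantity per locus, the per-generation allele change is

$$\Delta x_i = \frac{1+F}{V_s}(\alpha_i+\beta_i)D\,x_i(1-x_i)
 - \frac{1+3F}{V_s}(\alpha_i+\beta_i)^2\Big(1-\frac{D^2}{2V_s}\Big)
   x_i(1-x_i)\Big(\tfrac12-x_i\Big),$$

the mean-distance dynamics are
$\Delta D = -((1+F)V_g + C_{LD})D/V_s + \ldots$ (third-moment terms),
and at mutation–selection balance
$x_i(0) = u_iV_s/((1+3F)(\alpha_i+\beta_i)^2)$ with variance components

$$V_G = 4UV_s\frac{1+F}{1+3F}\overline{\frac{\alpha}{\alpha+\beta}},\quad
 V_g = \frac{4UV_s}{1+3F}\overline{\frac{\alpha^2}{(\alpha+\beta)^2}},\quad
 V_I = F V_g,\quad
 C_{LD} = 4UV_s\frac{1+F}{1+3F}\overline{\frac{\alpha\beta}{(\alpha+\beta)^2}}.$$

Three design points deserve comment.

* **Fraction groupings.** The implemented groupings are pinned by limit
  checks rather than typography: $x_i(0)$ must reduce to the
  house-of-cards frequency $uV_s/\alpha^2$ at $\beta=0, F=0$; $V_g$ must
  reduce to $4UV_s$ there; $V_I$ must vanish at $F=0$; and
  $V_G = V_g + V_I + C_{LD}$ must hold as an algebraic identity for
  *every* architecture. All four constraints are satisfied
  simultaneously by the forms above and enforced in the test suite.
* **The stabilising-term factor** is implemented as $1 - D^2/(2V_s)$,
  the second-order expansion of the Gaussian selection gradient
  consistent with the scaled distance $d = z/\sqrt{V_s}$.
* **$\beta_i$ are variables, not parameters.** No closed dynamics exist
  for them (nor for $V_g$ or $C_{LD}$), so the package treats them as
  inputs and provides `estimateBeta()`, which estimates
  $\hat\beta_{A,i} = (1+\hat F)(\bar g_{A,i} - \bar g_i)$ from a
  simulated population, where $\bar g_{A,i}$ is the mean haploid
  background (trait value excluding locus $i$) over carrier gametes and
  the $1+\hat F$ factor accounts for the co-transmitted homolog
  resembling the focal gamete with probability $\hat F$. Similarly, the
  third-order moments in the distance equation are accepted as supplied
  values; the cross-validation test exploits a symmetric pre-shift
  equilibrium where they vanish in expectation.

Note one subtlety verified by the tests: with $\beta$ *held fixed*,
$|C_{LD}|$ **decreases** with $F$ (the prefactor $(1+F)/(1+3F)$ is
decreasing). The amplification of negative LD covariance by selfing that
the simulations show operates through $\beta_i$ itself growing more
negative — another reminder that $\beta_i$ is endogenous.

# Forward simulator

## Design

Diploid Wright–Fisher population of constant size $N$, one linear
genome of `L` bp made of alternating neutral buffers (4000 bp) and genes
(1000 bp). Per-bp mutation rate $\mu$ applies genome-wide; a mutation in
a buffer is neutral, in a gene it is neutral / deleterious / trait with
probabilities 0.25 / 0.65 / 0.10. A trait mutation perturbs all
$n$ traits (universal pleiotropy), each effect drawn
$\mathcal N(0, 0.25^2/n)$ so the expected fitness effect near the
optimum is independent of $n$. Fitness is
$w = w_q\,w_d$ with
$w_q = \exp(-\tfrac12\sum_i (z_i - z_{0,i})^2/V_s)$ and
$w_d = (1-h|s|)^{n_{het}}(1-|s|)^{n_{hom}}$. The stated deleterious
selection coefficient is negative ($s=-0.02$, $h=0.2$); the
implementation treats it as a fitness *reduction* of magnitude $|s|$,
which is the intended biology of a partially recessive deleterious
mutation.

Reproduction is soft viability selection: each of $N$ offspring samples
parent 1 with probability proportional to fitness; with probability
$\sigma$ both gametes come from that parent (two independent meioses),
otherwise a second parent is sampled independently. Meiosis places
Poisson($r(L-1)$) crossovers uniformly and alternates parental
haplotypes; Poisson($\mu L$) new mutations land at uniform sites.

**Site occupancy.** At most one extant variant may occupy a site: a new
mutation landing on a site currently carrying a segregating or fixed
variant is discarded (the first-appearing mutation is kept). A site is
released when its variant is lost. This keeps the model effectively
infinite-sites — at the default desk scale fewer than ~2% of sites are
occupied at any time, so the realised mutation rate is within a couple
of percent of the nominal one — while guaranteeing that genotype and LD
bookkeeping never meets two variants at one position.

**Substitutions.** A mutation reaching 2N copies moves to a ledger and
is stripped from the haplotypes; every individual then carries twice its
effect through a running offset, so trait values (and the fixed
deleterious load) remain exact after fixation.

**Optimum schedule.** $z_0 = 0$ through a burn-in of $10N$ generations;
then every trait's optimum moves to $1/\sqrt n$, either instantly or as
a linear ramp in 100 equal increments. The $1/\sqrt n$ magnitude makes
the initial fitness drop identical across pleiotropy degrees, because
per-trait effect variance scales as $1/n$. (In flattened renderings of
the source text this appears as "$1/n$"; only $1/\sqrt n$ has the stated
equal-fitness-drop property.)

**Mutation-input conventions.** With full-scale defaults the per-gamete
trait mutation rate is $U_t = \mu L f_{gene} f_{trait} = 0.02$, i.e.
$2NU_t = 200$ new trait mutations enter the population per generation
over the $2N$ transmitted gametes — or 100 per generation if one counts
per diploid individual. Both numbers are printed by
`show(SimulationConfig)` so neither convention is silently asserted.

**Determinism.** Every random draw — parent choice, selfing decision,
crossovers, mutation placement, effects, cohort assays, bin
down-sampling — flows through R's RNG in a documented order, so
`set.seed()` makes runs bit-identical.

## Desk scaling

Full-scale runs ($N=5000$, 25 Mb, 50 000-generation burn-in) are
cluster-scale and are not reproduced in the package's tests. The
`deskConfig()` preset shrinks the genome (default 250 kb) while scaling
$\mu$ and $r$ up by the same factor, preserving the buffer/gene
proportions, the per-gamete mutation input ($\mu L = 1$,
$U_t = 0.02$) and the map length ($\approx 4.95$ crossovers per
meiosis). This keeps the population in the polygenic mutation-input
regime while making a $10N$-generation burn-in take seconds to minutes.
What desk scale does *not* preserve is $N$ itself: drift is stronger,
so quantitative outcomes (equilibrium variances, fixation counts) carry
$O(1/N)$ corrections, and the tests check *orderings* and analytically
corrected expectations rather than full-scale magnitudes. Test and
acceptance runs use $N$ between 100 and 300 with burn-ins of $10N$
generations.

Two desk-scale corrections are worth recording explicitly:

* **Excess homozygosity.** The neutral prediction
  $\hat F \to \sigma/(2-\sigma)$ holds up to a finite-population
  correction: the within-individual coalescence under selfing takes
  about 2 generations against a between-individual background of
  $T \approx 2N/(1+F)$, giving
  $E[\hat F] \approx F - (1+F)/N$. At $N=100$ this correction reaches
  0.02 at high selfing and the simulated values match it to within
  ~0.005 for every selfing fraction tested; at $N=5000$ it would be
  negligible.
* **Stochastic house of cards.** The deterministic equilibrium
  $V_g = 4U_tV_s$ is approached from below in a finite population; with
  the 10-fold-reduced rates used for validation
  ($U_t = 0.002$, mean scaled effect strength $N\bar s \approx 6\!-\!10$
  at $N \in \{200, 300\}$) the replicate-mean genic variance sits
  10–20% below 0.008, inside the 25% acceptance band; the deficit
  shrinks as $N$ grows, consistent with the $V_s/(N_e\alpha^2)$
  correction.

## Inbreeding-depression assay

At each requested statistics generation two cohorts of 500 (default)
offspring are produced from fitness-sampled parents — one by obligate
selfing, one by obligate outcrossing — with mutation disabled, and
$\mathrm{ID} = 1 - \bar w_S/\bar w_O$ is recorded; the cohorts are then
discarded. Note that a population in which *every* individual is
heterozygous at a deleterious site has ID $= 0$ in expectation: selfing
and outcrossing both produce 1:2:1 offspring from all-heterozygote
parents. Inbreeding depression requires variance in genotype across
parents; the unit tests check the all-heterozygote null exactly and a
Hardy–Weinberg deleterious population against the closed-form
fitness-weighted cohort expectation.

# Statistics

**Variance decomposition** (per trait): $V_G$ is the realised population
variance of individual trait values (so cross-locus covariance is
captured); $V_g = \sum_j 2p_jq_ja_j^2$ is the genic variance;
$V_I = \sum_j (2f_{2,j}f_{0,j} - \tfrac12 f_{1,j}^2)a_j^2$ is the
inbreeding covariance; and $C_{LD} = V_G - V_g - V_I$ by definition.
The $V_I$ form uses $f_1^2$ (squared heterozygote frequency): this is
the only reading that vanishes at Hardy–Weinberg proportions and equals
$2Fpqa^2$ under the single-locus $F$-model, both of which the tests
enforce — an inbreeding *covariance* must be zero without inbreeding.
For the same reason the mean is subtracted as $\mu_i^2$ in the raw
second moment. $V_G$ is computed from individual values rather than a
per-locus sum so that $C_{LD}$ genuinely captures between-locus
associations.

**LD tables.** From a phased sample of 50 individuals, sites are
filtered to minor allele frequency $\ge 0.1$ and then thinned greedily
left-to-right so retained SNPs are at least 0.5 Mb apart (both
thresholds scale as $L/50$ so desk-scale runs retain the same genome
fractions). MAF is applied before thinning, matching the behaviour of
site-filter-then-thin VCF tooling; the greedy rule is deterministic so
LD tables reproduce exactly. $r^2$ is the squared allelic correlation
and $|D'|$ normalises $D$ by its frequency-given bound. Decay curves
bin distances into 0.5 Mb bins up to half the genome, down-sample every
bin to the smallest bin count (seeded RNG), and drop a replicate whose
sparsest bin holds fewer than 10 pairs. Equivalence with any external
tool's tie-handling is not claimed.

**Haplotype samples** keep the full within-sample genotype matrix; for
display a thinned index of at most 100 mutations excludes trait
mutations fixed within the sample, prioritises segregating trait
variants and fills remaining space with background mutations.

**Allele trajectories** follow every trait mutation segregating in the
reference (pre-shift) snapshot across later snapshots, reading fixation
from the substitutions ledger; later-arising mutations are excluded.

# Rescaled-outcrossing comparison

To ask how much of the selfing phenomenology is "just" reduced
recombination, an outcrossing population can be run at effective rates
$\mu_{eff} = \mu/(1+F)$ and $r_{eff} = r(1 - 2F + \Phi)$ with
$\Phi = \sigma(2+\sigma)/((4-\sigma)(2-\sigma))$, the joint two-locus
identity-by-descent probability evaluated at free recombination
($r = 1/2$) — the appropriate choice because the whole-genome crossover
*count* $r(L-1)$ is what is being rescaled. At $\sigma = 0.999$ these
give $F = 0.998$, $\Phi = 0.997$, $\mu_{eff} \approx 2.0\times10^{-8}$
and $r_{eff} \approx 2.64\times10^{-10}$ (the exact evaluation; rounding
$F$ to three digits first gives the commonly quoted
$2.65\times10^{-10}$). A general two-locus IBD recursion for arbitrary
$r$ is deliberately out of scope.

# Numerical and degenerate-input policy

* Haplotype frequencies must sum to 1 within $10^{-8}$ on construction;
  the exact recursion conserves the sum to $10^{-12}$ per step.
* `qleLd()` refuses $F = 1$ or $r = 0$ (QLE undefined);
  `gammaThreshold()` refuses $(\gamma_A+\gamma_B)^2 \ge 2$;
  equilibrium formulas refuse $\alpha_i + \beta_i = 0$ (effectively
  neutral locus, no mutation–selection balance).
* A population whose fitnesses are all zero raises a degenerate-
  population error rather than sampling from nothing.
* `runSimulation()` has a resource guard on $N \times L$.
* LD tables with fewer than two surviving SNPs, and decay analyses in
  which every replicate is dropped, return empty results with warnings
  rather than errors, since both occur legitimately in sparse regimes.

# Known limitations

* The two-locus closed forms are first-order weak-selection results;
  outside their stated regimes (notably jointly high selfing and
  recombination) deviations of 15–20% are expected and documented
  rather than patched.
* The simulator records no tree sequences and does not interoperate
  with external simulators beyond VCF output of haplotype samples.
* Universal pleiotropy only; no partial-pleiotropy architectures.
* Trait effects are strictly additive within and between loci;
  dominance and epistasis on *fitness* arise only through the Gaussian
  map.
* Desk-scale tests demonstrate orderings and scaling-corrected
  expectations, not full-scale magnitudes; nothing in the test suite
  should be read as a quantitative claim about $N = 5000$ populations
  beyond the properties argued above.

# A worked session

```{r example}
# analytic layer: equilibrium components for the default architecture
equilibriumVarianceComponents(
  traitArchitecture(alpha = 0.25, u = 0.02, Vs = 1, F = 0))

# two-locus layer: selfing deepens equilibrium LD
st <- twoLocusState(pA = 0.05, pB = 0.05, delta = 0)
for (sig in c(0, 0.9)) {
  pr <- twoLocusParams(gammaA = 0.05, gammaB = 0.05, r = 0.2, sigma = sig)
  s <- st
  for (i in 1:300) s <- exactGenerationStep(s, pr)
  cat(sprintf("sigma = %.1f: delta = %.2e (QLE %.2e)\n",
              sig, ld(s), qleLd(s, pr)))
}

# simulation layer: a small optimum-shift run
cfg <- deskConfig(N = 100, L = 100e3, selfing = 0.9, burnIn = 1000,
                  postGens = 300, sDel = 0, statsIntervalPost = 100)
set.seed(1)
res <- runSimulation(cfg)
tail(simStats(res)[, c("gen", "meanFitness", "meanZ1", "VG1", "Vg1",
                       "VI1", "CLD1")])
```
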