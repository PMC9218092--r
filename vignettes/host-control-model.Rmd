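---
title: "Host control and the evolution of cooperation in the microbiome: model and methods"
author: "ecoleash"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Host control and the evolution of cooperation in the microbiome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecoleash)
```

# The model

`ecoleash` follows a focal symbiont species — equivalently, the members of
one niche in a host's microbiome — and its host, each able to invest in
cooperation that benefits the other. Hosts additionally evolve a control
(enforcement) trait that preferentially benefits more-cooperative
symbionts, as the innate and adaptive immune systems do when they target
traits such as flagella. The model is deliberately minimal: a large,
well-mixed population of hosts, every symbiont genotype experiencing every
host genotype each generation, and evolution acting on standing
discretized variation plus immigration from a fixed environmental pool.

Host fitness is

$$W_a = (1 - a) + x\, p_a\, \phi(\bar b(c)) - g\,\frac{c}{c_{\max}},
  \qquad p_a = a y,$$

so a host pays linearly for its own cooperation $a$ and for running the
control mechanism, and gains from the mean symbiont cooperation it
experiences after control, $\bar b(c)$, fed back through partner fidelity
($p_a$: helping symbionts increases their capacity to help back).
$\phi$ is the benefit curve (below; identity by default). Control acts
through a relative weight on each symbiont genotype,

$$q(b, c) = \frac{e^{bc}}{\int_0^1 e^{(1-R)\,b'c}\,S(b')\,db'}\; e^{-fc},$$

an exponential tilt toward high expression of the monitored trait,
normalized against the focal symbiont's competitors and scaled by the
genetic diversity $1-R$ among them — in a clonal population ($R = 1$)
there is nothing to discriminate and the denominator is exactly 1. The
factor $e^{-fc}$ is the indiscriminate collateral harm of control (e.g.
antimicrobial peptides shrinking all symbiont populations).

Symbiont fitness takes two forms. Between host generations (dispersal and
colonization),

$$W_b = (1 - b) + y \int\!\!\int H(a,c)\, q(b,c)\, p_b(c)\, a \; dc\, da,
 \qquad p_b(c) = R b x + (1-R)\,\bar b(c)\, x,$$

and within host generations (pure local competition on growth rate),

$$W_b = (1 - b) + \int q(b,c)\, h(c)\, dc,$$

where $h(c)$ is the marginal density of control in the host population.
Each host generation consists of `generationRatio` symbiont generations:
`generationRatio − 1` within-host cycles (each followed by immigration at
rate $m$) and one between-host cycle (followed by immigration at rate
$M$), so that a ratio of 1 reproduces the pure between-host model exactly.

## Parameters

| Parameter | Meaning | Default | Notes |
|---|---|---|---|
| `x`, `y` | benefit of received cooperation (host, symbiont) | 2, 2 | dimensionless; trait costs are 1, so these are benefit-to-cost ratios |
| `R` | symbiont relatedness | 0.5 | social-evolution sense: 1 = clonal, 0.1 ≈ ten equally abundant strains |
| `f` | symbiont-side cost of control | 0.02 | per unit control, in the exponent |
| `g` | host-side cost of control | 0.1 | the cost term is $g c/c_{\max}$, so g is the *maximal* direct cost regardless of `cMax` |
| `M`, `m` | immigration fractions | 0.05, 1e−6 | per host generation / per symbiont generation |
| `generationRatio` | symbiont generations per host generation | 1 | the key timescale parameter; ~hours vs ~decades for the human gut |
| `cMax` | upper bound of control | 10 | not a biological constant; see below |
| `nGrid` | grid points per trait axis | 11 | |
| `benefitForm` | cooperation-to-benefit curve | `"linear"` | |

`cMax` has no canonical value; because the host cost uses $c/c_{\max}$
and control strength enters as $e^{bc}$, raising `cMax` only extends the
range of achievable control strengths at the same maximal cost. The
default of 10 allows strong control ($e^{b\,c}$ spanning ~4 orders of
magnitude across the b grid at maximal c) without numerical overflow.

## Discretization

Trait distributions are probability masses at 11 evenly spaced grid
points per axis (endpoints inclusive): hosts an 11 × 11 matrix over
$(a, c)$, symbionts an 11-vector over $b$. All integrals are
probability-weighted sums over grid points with **no quadrature
weights** — the densities *are* proportions of the population at each
grid value, not samples of a continuous density, so cell-width weighting
would be wrong. Initial distributions evaluate a normal density at the
grid points and renormalize (truncated normal, mean 0: SD 0.5 for
cooperation in both species, SD 1 for control). The zero means give a
small but finite amount of standing cooperation and control variation,
without which neither trait can get off the ground; the model's outcomes
are initial-condition dependent, and this is the intended "small quantity
of cooperation at the start" regime.

## Update convention

Within a host generation the engine performs the within-host phase and
then a **simultaneous generational update**: host fitness and between-host
symbiont fitness are both evaluated on the same current state — the host
distribution and the symbiont distribution those hosts carried — and both
densities are then reweighted (and symbionts receive immigrants).
This is the standard convention for coupled discrete-time replicator
dynamics, and it matters here: the establishment of cooperation is a race
between hosts ratcheting up investment and within-host competition
eroding symbiont cooperation. A sequential update in which hosts evaluate
fitness against the *already updated* (post-dispersal, post-immigration)
symbiont distribution systematically handicaps the host side of that race
and shrinks the cooperative basin; at the reference parameters
(x = y = 2, R = 0.5, generation ratio 1) it turns an established
cooperative regime into a collapse. The engine's tests pin the
simultaneous order.

Within-host selection weights each control level by the host marginal
$h(c)$, so that competition reflects the hosts symbionts actually occupy;
this is the same mean-field assumption ("every genotype experiences every
host") as the between-host equation. An unweighted integral over $c$
would let empty regions of host trait space drive symbiont evolution.

## Benefit curves

The default relationship between mean symbiont cooperation and host
benefit is linear. Three non-linear named shapes are provided —
diminishing (concave), accelerating (convex) and sigmoidal — implemented
as smooth curves anchored at (0, 0) and (1, 1): scaled exponentials with
shape constant 3 for the concave/convex forms, a rescaled logistic with
steepness 10 centred at 0.5 for the sigmoidal form. Anchoring is the
essential property: the curve must map "no cooperation" to "no benefit"
and "full cooperation" to "full benefit" so that forms are comparable at
equal benefit scale x. An alternative set of published closed forms for
these shapes is exposed verbatim via
`benefitTransform(..., asPrinted = TRUE)` for inspection, but those
expressions are not anchored on [0, 1] (one diverges at b = 1/6, one
exceeds 1, and the "accelerating" one is concave), so the simulator never
uses them; the anchored curves are the package's defaults rather than a
guess at the intended algebra. The transform is applied only where the
host receives benefit — to $\bar b(c)$ inside $W_a$ — leaving the
symbiont-side equations untouched, since the curves describe how symbiont
cooperation translates into *host* benefit.

## The environmental pool

Immigrants are "largely uncooperative with a small baseline of
cooperation". The default pool equals the initial symbiont distribution
(truncated normal, mean 0, SD 0.5, mean cooperation ≈ 0.31), which
provides that baseline without introducing a new parameter; it is
configurable. The pool is fixed in time: it has not coevolved with the
host. Host-side variation is never replenished — there is no host
immigration and, by default, no mutation — so host selection can fix a
grid point. An optional nearest-neighbour mutation kernel
(`mutationRate`) exists for sensitivity analyses but is off by default,
matching the matrix formulation in which immigration is the source of
fresh symbiont variation.

# The escape extension

Symbionts in the linked representation carry expression $B$ of the
monitored trait and a linkage $\gamma$, with realized cooperation
$b = \gamma B$ on an 11 × 11 grid. Control targets expression — $q$ is
evaluated with $B$, and its denominator aggregates the joint density
through $B$ — while cooperation costs and partner-fidelity feedback use
$b$. That asymmetry is the point of the extension: when $\gamma$ can
evolve, selection favours genotypes that keep the trait the host rewards
while dropping the cooperation it is supposed to signal.

Two conventions the source material leaves open:

* **Immigrant linkage.** In "free" phases immigrants carry uniform
  $\gamma$: environmental strains have not coevolved the trait–cooperation
  linkage, and with no mutation operator, immigration is the only source
  of linkage variation — a pool with $\gamma$ pinned at 1 would make free
  phases inert. In "fixed" phases the linkage is hardwired for everyone,
  so immigrants enter at $\gamma = 1$.
* **Reinstating the linkage.** On entry to a "fixed" phase all mass is
  projected from $(B, \gamma)$ onto $(B, 1)$, preserving the B marginal —
  the simplest restoration consistent with hardwiring the relationship.
  With $\gamma$ pinned the extension embeds the base model exactly
  (trajectory equality is tested at 1e−10).

The default schedule — 100 generations fixed, 40 free, 160 fixed, at
generation ratio 10 — was chosen from the model's own timescales.
Escape is fast: once the linkage is free, cheater genotypes (high B, low
$\gamma$) sweep within a few host generations and realized cooperation
collapses. Loss of control is slower, driven by its direct cost at rate
$\sim g/c_{\max}$ per generation. If the free phase lasts long enough for
control to decay almost completely, re-fixing cannot rescue cooperation:
within-host competition crushes the symbionts before control can
re-evolve from the eroded tail of host variation. A 25–40 generation free
phase exhibits both halves of the phenomenon — clear collapse of
cooperation *and* control, followed by genuine restoration on re-fixing.

# The individual-based pathogen model

The IBM replaces densities with finite populations: `nHosts` hosts
(reference scale $10^4$) each carrying `microbesPerHost` microbes
(reference $10^3$). Traits take values **on the same grids** as the
deterministic model and each host's community is stored as counts per
genotype category (microbes within a host are exchangeable, so this is
equivalent to per-individual arrays). Keeping genotypes on the grid makes
the deterministic model the exact infinite-population limit, which is
what makes the consistency check between the two meaningful.

Each host generation: (1) a pathogen influx converts a binomially drawn
fraction (`pathogenInflux`, default 1e−3) of each host's microbes into
pathogens; (2) `generationRatio − 1` rounds of within-host competition,
each host's community multinomially resampled with probabilities
proportional to counts × max(within-host fitness, 0), computed against
that host's control level with its own community as the competitor pool;
(3) hosts are resampled proportional to max($W_a$, 0) × $p_f$; (4)
offspring hosts draw their microbes from the pooled parental microbe
population reweighted by between-host fitness and mixed with
environmental immigrants at rate M. Multinomial sampling with replacement
is used at every step — the simplest scheme consistent with
fitness-proportional random subsampling. Within-host immigration (m) is
omitted in the IBM: at the default m = 1e−6 it is far below one microbe
per host per cycle at any feasible population size.

Pathogens carry the non-cooperative phenotype (b = 0) and are subject to
host control exactly like non-cooperative symbionts; they differ only in
harming the host through the pathogenicity factor
$p_f = e^{vp(c/c_{\max})}e^{-vp}$, which multiplies host fitness. The
multiplicative insertion is chosen because a factor in (0, 1] scales
fitness naturally and vanishes smoothly as the pathogen proportion p
reaches 0 or control reaches $c_{\max}$. Neither the virulence nor the
influx has a stated canonical value; the package defaults to v = 100 with
influx 1e−3, and the pathogen-pressure scenario used in the acceptance
analysis (v = 100, influx 0.01) was fixed in advance by a gradient
argument: at p = 0.01, $p_f$ gives an uncontrolled host a fitness penalty
of $1 - e^{-1} \approx 63\%$, nullified at full control, making the
selection gradient on control from pathogens roughly an order of
magnitude steeper than the direct control cost $g/c_{\max}$ — "rare but
costly" without being immediately lethal.

# Outcome classification

The model's raw output is a continuous equilibrium, not a label.
`classifyOutcome()` applies a numeric convention: a run is
**cooperation** when the final mean symbiont cooperation exceeds the
environmental-pool mean by ≥ `margin` *and* the final mean host
cooperation exceeds its initial mean by ≥ `margin` (default 0.2, chosen
to separate the pool baseline ≈ 0.31 from near-full cooperation ≈ 0.9+;
both conditions, because mutualism requires both partners to have moved).
A non-cooperative run with control enabled whose final mean control fell
below 10% of its initial mean is **control_lost**; otherwise
**collapse**; a run whose selection weights all hit zero is **extinct**.
The rule is monotone in the margin: enlarging it can only demote
cooperation.

# Numerical choices

* **Clamping.** Fitnesses are clamped at 0 before use as replicator
  weights ($W_a$ can go slightly negative at extreme parameters); a
  population whose weights are all zero raises a typed extinction error
  rather than producing NaN densities.
* **Convergence.** Runs stop early when the L1 change of both densities
  in one host generation falls below 1e−10 (disable with
  `convergenceTol = 0`). Densities are renormalized after every
  multiplicative step; conservation is tested to 1e−12 over
  500-generation runs of every variant.
* **Degenerate inputs.** Point-mass distributions are legal everywhere
  ($\bar b(c)$ of a point mass is its location for any c); non-normalized
  densities are rejected by class validity at construction.
* **No RNG in the deterministic engine.** Identical parameters give
  bit-identical trajectories; all stochasticity lives in the IBM and is
  governed by its seed.

# What the tests do and do not show

The package's tests verify the implementation against independent
scalar-loop oracles (to 1e−12), analytic identities, exact enumeration of
the IBM's sampling scheme on tiny instances, and the qualitative regime
structure: cooperation at generation ratio 1, collapse at ratio ≥ 100,
rescue by host control and the broadening of the cooperative region it
brings, escape-driven collapse and restoration, loss of control without
immigration, and agreement of the IBM with its deterministic limit
(pathogen-free means within 3 Monte-Carlo SE over 10 seeds at 10³ hosts ×
10² microbes; problem sizes chosen so the full suite runs in minutes).
These are statements about the *model*, under its assumptions: one niche,
a well-mixed host population, mean-field interaction, a fixed
environmental pool, no spatial structure, no epidemiological transmission,
no host mortality dynamics, and no explicit multi-species community.
Passing tests show the equations are solved correctly and the published
regime structure is reproduced — not that any particular real microbiome
sits in a particular regime. Mapping real systems onto the parameter
space (relatedness estimates, generation ratios, benefit-to-cost ratios)
is the user's scientific judgement.

# Known limitations

* The 11-point grids are coarse; the regime boundaries shift slightly
  with `nGrid` (which is configurable, and the tests' fine-grained scans
  use denser grids where shape matters).
* Host variation is finite and unreplenished: once host selection fixes a
  grid point, nothing restores variation, which is realistic on the
  modelled timescale but means very long runs can freeze.
* The escape model's immigrant-linkage convention (uniform $\gamma$) is
  one reasonable choice among several; the qualitative collapse does not
  depend on it, but its speed does.
* The IBM's count representation assumes within-host exchangeability; it
  cannot express within-host spatial structure or microbe-level
  individuality beyond genotype.
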