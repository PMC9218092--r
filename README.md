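# ecoleash

Evolutionary dynamics of cooperation and host control in the microbiome.

## The problem

Diverse, long-lived microbiomes are hard places for cooperation to evolve.
A symbiont strain that invests in its host (producing a vitamin, staying
benign) grows more slowly than a cheater sharing the same niche, and when
many symbiont generations pass within a single host generation this
within-host competition is prolonged and chronic. `ecoleash` simulates the
coevolution of a host and the members of one niche of its microbiota to
ask when cooperation is stable, and in particular what *host control* —
enforcement mechanisms such as immune surveillance that preferentially
benefit more-cooperative symbionts — contributes, and when symbionts can
undermine it by decoupling cooperation from the trait the host monitors.
It is aimed at researchers in social evolution and microbiome science who
want a tested, scriptable implementation of this class of model.

## The model

Hosts carry two evolving traits, cooperation `a ∈ [0, 1]` and control
`c ∈ [0, c_max]`; symbionts carry cooperation `b ∈ [0, 1]`. Populations
are probability densities `H(a, c)` and `S(b)` on 11-point trait grids,
updated by replicator dynamics (frequencies reweighted by fitness each
generation). Fitnesses are

    W_a = (1 − a) + x p_a b̄(c) − g (c / c_max),        p_a = a y
    W_b = (1 − b) + y ∬ H(a, c) q(b, c) p_b(c) a dc da  (between host generations)
    W_b = (1 − b) + ∫ q(b, c) h(c) dc                    (within host generations)

where the effect of control on a focal symbiont is

    q(b, c) = e^{bc} / ∫ e^{(1−R) b'c} S(b') db' · e^{−fc}

with relatedness `R` (clonal populations, R = 1, offer control nothing to
discriminate), symbiont-side control cost `f`, host-side cost `g`, and
`b̄(c)` the control-weighted mean symbiont cooperation. Partner fidelity
feedback `p_b(c) = R b x + (1 − R) b̄(c) x` returns benefits to
cooperative symbionts. Each host generation comprises `generationRatio`
symbiont generations; immigrants arrive from a fixed, largely
uncooperative environmental pool at rates `M` (per host generation) and
`m` (per symbiont generation).

Two extensions:

* **Escape from control** — symbionts carry expression `B` of the
  monitored trait and a linkage `γ`, with realized cooperation `b = γB`.
  Control targets `B`; costs and feedback use `b`. When `γ` evolves
  freely, selection favours genotypes that keep the trait and drop the
  cooperation, and control collapses (`runEscapeSimulation()`).
* **Pathogens** — an individual-based version (`runIBM()`) adds an influx
  of non-cooperating pathogens whose within-host proportion `p` penalizes
  host fitness by `p_f = e^{vp(c/c_max)} e^{−vp}` at virulence `v`; full
  control nullifies the harm.

A sweep driver (`runSweep()`, `classifyOutcome()`) maps outcomes —
`cooperation`, `collapse`, `control_lost`, `extinct` — across relatedness
and benefit-to-cost gradients, and `cliMain()` (wrapped by
`inst/scripts/ecoleash`) exposes everything from the shell with YAML
configs.

## Worked example

Host control rescues cooperation at a high symbiont-to-host generation
ratio (benefits x = y = 2, relatedness R = 0.5, costs f = 0.02, g = 0.1,
immigration M = 0.05, m = 1e−6):

```r
library(ecoleash)
p <- modelParams(generationRatio = 100, controlEnabled = TRUE)
traj <- runSimulation(p)
traj
#> SimulationTrajectory (base model): 200 host generations
#>   final means: a = 1.0000, c = 0.9318, b = 0.9655
classifyOutcome(traj)
#> [1] "cooperation"
round(tail(trajectory(traj), 3), 4)
#>     generation meanA  meanC  meanB meanBControlled
#> 199        198     1 0.9325 0.9656          0.9801
#> 200        199     1 0.9321 0.9655          0.9800
#> 201        200     1 0.9318 0.9655          0.9800
```

Hosts evolve full cooperation (mean a = 1) and a stable level of control
(mean c ≈ 0.93, set by its cost), which keeps the symbionts cooperative
(mean b ≈ 0.97) despite 100 symbiont generations of within-host
competition per host generation. The same parameters with
`controlEnabled = FALSE` classify as `"collapse"`: without enforcement,
fast-growing cheats win and the host stops investing.

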