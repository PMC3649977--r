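---
title: "Property-based analysis of an extrinsic-apoptosis ODE model"
author: "apopSTL"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Property-based analysis of an extrinsic-apoptosis ODE model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apopSTL)
```

## What this package computes

Cell lines exposed to the death ligand TRAIL differ in how they die:
whether over-expressing Bcl2 rescues them, whether initiator (caspase-8) and
effector (caspase-3) caspases activate sequentially or synchronously, and
whether mitochondrial outer membrane permeabilization (MOMP) precedes
effector-caspase activity. These three behaviors are the classical type I /
type II distinguishing criteria. `apopSTL` encodes them as signal temporal
logic (STL) formulas with a signed, quantitative ("robustness") semantics
and evaluates them on trajectories of a mass-action ODE model of
TRAIL-induced apoptosis, per cell line, per mutant, and per sampled cell of
a heterogeneous population. On top of the monitor it provides
initial-concentration phase diagrams (STL robustness or direct finite-time
Lyapunov exponents, DLE), population statistics, and a property-guided
parameter search that revises rate constants until model predictions match
an observed truth table.

## The quantitative STL semantics

A trace is a set of named signals sampled on a common grid (the ODE output,
1-minute steps by default). The robustness $\rho(\varphi, x, t)$ of a
formula is defined recursively: a predicate $s > c$ has robustness
$s(t) - c$ (and $c - s(t)$ for $<$); negation flips the sign; conjunction
and disjunction take min and max; `ev`$_{[a,b]}$ and `alw`$_{[a,b]}$ take
the sup and inf of the operand's robustness over the window
$[t+a,\,t+b]$; `until` is $\sup_{t'} \min(\rho_\psi(t'),
\inf_{t'' \in [t,t']} \rho_\varphi(t''))$; `release` is evaluated through
the duality $\varphi\,R\,\psi \equiv \lnot(\lnot\varphi\,U\,\lnot\psi)$.
A positive value means the Boolean property holds, a negative value that it
fails, and the magnitude is a margin in the predicate's own units — which
also means values are comparable only within one formula.

Three choices deserve mention:

* **Sampling semantics.** Sup and inf range over sample instants only; no
  interpolation happens inside temporal operators. This matches evaluation
  on discrete solver output and makes an exhaustive $O(n^2\,|\varphi|)$
  reference implementation exact, which the test suite exploits: the
  production evaluator (running-minimum `until`, duality-based `release`)
  is checked against that independent brute-force recursion and against a
  separate purely Boolean evaluator on a thousand random formula/trace
  pairs per run. The ODE output grid must therefore be dense relative to
  the dynamics; one minute over six hours is ample here.
* **Horizon truncation.** A window $[t+a, t+b]$ extending past the trace
  horizon $T_f$ is truncated at $T_f$; if $t+a > T_f$ the window is empty
  and evaluation at $t$ is an error (`NA` in whole-signal output). Untimed
  operators mean $[0, \infty)$ capped at $T_f$.
* **Exact zeros.** Zero robustness is a boundary verdict; it is flagged and
  counted as *not satisfied* in population percentages. On continuous
  models it has measure zero.

## The apoptosis model and cell lines

The bundled network is a transcription of the extrinsic apoptosis reaction
model lineage (EARM1.4-style): receptor/ligand binding and DISC formation,
caspase-8 activation modulated by FLIP and Bar, direct cleavage of
caspase-3, the caspase-3 → caspase-6 → caspase-8 positive feedback loop,
XIAP binding and degradation of caspase-3, Bid/Bax-driven pore formation
inhibited by Bcl2, cytochrome-c and Smac release, apoptosome assembly and
PARP cleavage — 58 species (17 native proteins, 40 complexes or modified
forms, plus TRAIL) in 28 reaction groups expanding to 70 elementary
mass-action reactions. Amounts are molecules per cell; rate constants are
per second; the API works in hours. 50 ng/ml of TRAIL corresponds to 3000
ligand molecules per cell (60 per ng/ml).

Because the original machine-readable model distribution was not available
to this implementation, the network was reconstructed from the published
reaction scheme and rate constants of its parent model together with the
documented cell-line adaptations; the network metadata carries this
provenance and the file is labelled a synthetic stand-in. Two constants
deserve explicit notes, both recorded here as deliberate design decisions:

* The PARP-cleavage association rate `k9` was resolved to
  $10^{-7}$/molecule/s (the alternative reading, $10^{-6}$, makes Bcl2
  over-expressing HCT116 cells die within six hours, contradicting their
  reported survival and the reported cleaved-PARP trajectories).
* "Active caspase-3" sums all cleaved forms except the XIAP-bound pool
  *and* excludes the ubiquitinated degradation product: degraded protein
  has no catalytic activity, and counting it would make HCT116's caspase
  activation appear synchronous, contradicting its reported kinetics.

Twelve cell lines are bundled: HCT116 (`H`), SKW6.4 (`S`) and T47D (`T`)
with measured initial amounts for FLIP, caspase-8/-6/-3, XIAP, PARP, Bid,
Mcl1 (the cytosolic Bcl2 pool), Bax, Bcl2 and Smac, and the `X`
(XIAP zeroed), `B` (Bcl2 ×10) and `BX` variants of each. The feedback
deletion `dFB` zeroes `k7`, the caspase-6-mediated cleavage rate of
caspase-8. Variants touch disjoint quantities and compose in any order.

```{r properties}
formatFormula(makeP1())   # survival: always alive over 6 h
formatFormula(makeP2())   # sequential caspase activation (1 h separation)
formatFormula(makeP3())   # no death before MOMP
```

The thresholds are tunable through `propertySpec()`: `alpha` (fraction of
cleaved PARP that defines death, default 0.5), `beta` (fraction of free
Apaf-1 below which MOMP has happened, 0.5), `gamma` (active-caspase
fraction, 0.01) and the separation delay (1 h). The observed truth table
ships as a CSV with per-entry provenance; its 16 scoreable entries cover
the HCT116 and SKW6.4 families, while the T47D family, whose phenotypes
were ambiguous ("mixed"), is excluded from all match counting. The
observed value of Property 2 for parental SKW6.4 is recorded as *false*
(synchronous activation), following the primary kinetic description; a
secondary tabulation in the source material lists it as true, and the CSV's
provenance column documents the conflict.

With the original rate constants the nominal-cell predictions disagree with
the observations in exactly three places — (SKW6.4, P2), (OE-Bcl2 SKW6.4,
P2) and (ΔXIAP HCT116, P3) — and the mismatch count is insensitive to the
caspase threshold below 2% and to the MOMP threshold throughout (0.1–0.9).
It is *not* fully flat in `alpha` in this transcription (12–14 matches over
0.1–0.9): the OE-Bcl2 HCT116 nominal cell peaks at 11% cleaved PARP, so an
alive threshold of 10% flips its survival verdict — its margin is thinner
here than in the original model.

## Diagrams, DLE, and populations

`stlDiagram()` varies two initial amounts on a linearly spaced $n \times n$
grid (endpoints included; default ranges XIAP $[0, 6\cdot10^4]$, caspase-3
$[0, 10^6]$, caspase-8 $[1200, 4500]$, FLIP $[0, 800]$ molecules/cell),
holds every other species at the reference line's nominal value, simulates,
and stores the robustness at time 0. Overlay crosses mark cell lines at
their mean ± standard deviation (mean × CV). Grid points whose simulation
fails are masked; more than 1% failures aborts. Every stored cell is
reproducible by a single `simulateNetwork()` + `robustnessAt()` call.

`dle()` computes the direct finite-time Lyapunov exponent
$\frac{1}{2t}\log\lambda_{\max}(J^\top J)$, with $J = \partial x(t) /
\partial x(0)$ the flow-map Jacobian over *all* initial concentrations. The
default estimator is central finite differences (relative step $10^{-4}$,
absolute floor 1 molecule, one-sided at the nonnegativity boundary); an
independent forward-sensitivity (variational) integrator serves as the
cross-check and agrees to better than $10^{-3}$ relative on the apoptosis
model at a regular state. Near the death/survival separatrix the true
Jacobian grows without bound and *any* finite step saturates: ridge
detection therefore uses a smaller floor ($10^{-3}$ molecules). In this
transcription the Bcl2-over-expression background sequesters the
mitochondrial pathway everywhere on the XIAP/caspase-3 slice, so the
survival boundary is a gradual cleavage race rather than a snap transition,
and the DLE maximum sits one to three grid cells inside the death region
rather than exactly on the Property-1 zero crossing; the corresponding
acceptance check is left failing, with the estimator cross-validation
ruling out a numerical cause.

`samplePopulation()` draws initial amounts per native protein from
lognormal distributions with *arithmetic mean* equal to the nominal amount
(underlying normal: $\sigma^2 = \log(1+\mathrm{CV}^2)$, $\mu = \log m -
\sigma^2/2$) — the stated convention is that means are nominal — using the
measured CVs for caspase-3 and XIAP and 25% elsewhere; zero-nominal species
(ΔXIAP) stay exactly zero, and draws are untruncated and seed-reproducible.
`evaluatePopulation()` scores a formula per cell and reports mean,
quartiles and percent satisfaction; the MOMP-gating property is scored only
on cells in which MOMP occurred and that died (`mompDeathCondition()`),
mirroring the experimental exclusion of survivors; the survival property is
unconditioned. The study-scale population is 5000 cells per line; the test
suite and acceptance script use 500 cells on a 3-minute output grid, which
changes the reported percentages by well under the sampling error at that
size.

## Parameter search

The cost of a candidate parameter set sums three weighted components over
the 16 scoreable entries: a Boolean reward of $-c_B$ per consistent entry;
a continuous term $\sum w_p\,(-\sigma\rho)$ with $\sigma = +1$ (observed
true) or $-1$ (false) and per-property weights $w_p$ set to the reciprocal
robustness range of the reference evaluation, so that properties with
different units weigh comparably; and the deviation
$\sum |\log_{10}(k/k_{\mathrm{ref}})|$ over the searched rates. Weights are
calibrated so the components contribute about 50/30/20% at the start of a
run. The search space is the searchable census (all forward and catalytic
rates) in $\log_{10}$ boxes of ±2 (hundred-fold) around the reference. The
optimizer is a compact seeded differential-evolution loop (bounded,
derivative-free, reference point included in the initial population;
best-so-far trace monotone by construction). Phase 2 takes the phase-1
parameters that moved more than five-fold, and re-runs the search on each
singleton and pair (everything else reset to the reference) with the
continuous weight zeroed and the Boolean component re-weighted to ~90%,
returning the smallest subset that achieves full agreement.

The bundled `revisedParameters()` applies the published minimal revision:
feedback cleavage `k7` ×2.71 and PARP-cleavage catalysis `kc9` ÷55.6. On
this transcription it resolves the SKW6.4-P2 and ΔXIAP-HCT116-P3
inconsistencies but leaves (OE-Bcl2 SKW6.4, P2) mismatched: with the
mitochondrial path fully blocked, XIAP degrades the entire caspase-3 pool
well before six hours, so late quiet windows satisfy the sequentiality
property trivially under truncation semantics. A scan over alternative
two-parameter revisions (feedback, XIAP binding/degradation, direct
cleavage, PARP kinetics) reproduces 15 of 16 at best, so the residual
reflects a transcription difference from the original model rather than a
search failure; the corresponding acceptance check is left failing rather
than weakened.

## Numerical choices and limitations

* Integration uses `lsoda` with the analytic mass-action Jacobian, relative
  tolerance $10^{-8}$ and absolute tolerance $10^{-4}$ molecules; closed-form
  comparisons in the tests tighten these to $10^{-10}$–$10^{-12}$.
  Halving the output grid step changes derived channels by under $10^{-3}$
  relative.
* Conserved moieties are computed as the left null space of the
  stoichiometry matrix via a QR decomposition and are conserved to solver
  tolerance along trajectories; the transcription contains no synthesis or
  degradation of native totals, so each protein family is a conserved pool.
* The synthetic-data generator (the lognormal population sampler plus the
  fixture networks) emulates cell-to-cell variability in initial protein
  content only: no correlated covariation between proteins, no extrinsic /
  intrinsic noise split, no stochastic reaction kinetics, and no parameter
  variability across cells. Passing tests therefore validate the machinery
  under the stated variability model, not the biology of any particular
  cell line beyond what the bundled measured means and CVs encode.
* Toy fixtures carry their own oracles: exponential decay (closed form), a
  bistable two-species competition (basins resolved by long-horizon
  simulation), and a three-step activation cascade (closed form for the
  first stage); the cascade doubles as the desk-scale search problem with a
  deliberately mis-set middle rate.
* Robustness values are reported in each predicate's native units and never
  aggregated across different formulas.
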