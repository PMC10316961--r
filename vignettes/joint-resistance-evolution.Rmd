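---
title: "Joint evolution of general and specific host resistance: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint evolution of general and specific host resistance: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coresist)
```

## The biological question

Host populations defend themselves with qualitatively different kinds of
resistance. *General* resistance (thicker cuticles, inflammatory responses)
reduces infection by every pathogen and typically varies continuously;
*specific* resistance (R-gene recognition of a pathogen effector) is a
discrete allele that protects against one pathogen only. `coresist`
simulates their joint evolution in a host attacked by an endemic sterilizing
pathogen, and asks what the evolved resistance structure means for the
invasion and establishment of a *foreign* (host-shifted) pathogen that the
specific allele cannot see. The biology is modelled on anther-smut disease:
infection is permanent, sterilizes but does not kill, and transmission is
frequency dependent (pollinator-borne).

## The ecological model

Uninfected hosts are structured by background (S = no specific resistance,
R = carrying the specific allele) and by general-resistance strength
$q \in \{0, 0.01, \dots, 1\}$. With infected pools $I_e$ (endemic) and
$I_f$ (foreign) and total density $N$:

$$\frac{dS_i}{dt} = S_i\Big(b - c_{q_i} - \mu - \gamma N
  - \tfrac{1-q_i}{N}(\beta_e I_e + \beta_f I_f)\Big)$$
$$\frac{dR_i}{dt} = R_i\Big(b - c_{q_i} - c_r - \mu - \gamma N
  - \tfrac{1-q_i}{N}\big((1-r)\beta_e I_e + \beta_f I_f\big)\Big)$$
$$\frac{dI_e}{dt} = I_e\Big(\sum_i \beta_e(1-q_i)\tfrac{S_i+(1-r)R_i}{N}
  - \mu\Big), \qquad
\frac{dI_f}{dt} = I_f\Big(\sum_i \beta_f(1-q_i)\tfrac{S_i+R_i}{N} - \mu\Big)$$

Infected hosts are sterile (no birth term) but die at the same rate $\mu$
and occupy density-regulated space, so $N$ includes them everywhere it
appears — the single consistent reading of a shared $\gamma N$ term.
General and specific resistance multiply on transmission ($(1-q)(1-r)$,
which also keeps total resistance below 1); their fecundity costs add
($c_q + c_r$). The cost of general resistance is the power law
$c_q = 1 - (1-q)^\theta$; $\theta < 1$ (the default 0.5) makes costs
accelerating, which is what gives the continuous trait a single stable
attractor rather than branching. A density-dependent variant
(`transmission_mode = "density"`) drops the $1/N$ inside every
transmission term and is otherwise identical.

### Parameters and defaults

| parameter | meaning | default |
|---|---|---|
| `b` | host birth rate | 1.5 |
| `mu` | mortality rate (all hosts) | 0.2 |
| `gamma` | density-dependent regulation | 0.01 |
| `beta_e` | endemic transmission rate | 1 |
| `beta_f` | foreign transmission rate | scenario-specific (0–1) |
| `r` | strength of specific resistance | scenario-specific |
| `c_r` | fecundity cost of the R allele | scenario-specific |
| `theta` | cost-curve exponent | 0.5 |

All rates are per capita per unit model time; `q`, `r`, costs and
recombination rate `p` are dimensionless fractions. `beta_e >= beta_f` is
the standing biological assumption (a freshly host-shifted pathogen is
maladapted); the constructor only warns when it is violated so that
threshold-finding sweeps can cross the boundary.

## The evolutionary loop

General resistance evolves by deterministic adaptive dynamics
(`run_evolution()`): the ecology is integrated to $t = 1000$ by forward
Euler, then 5% of the density in every occupied $q$ bin is moved to the
adjacent bins (independently in the S and R backgrounds), and the cycle
repeats for up to 150 mutation iterations. The specific-resistance allele
and the foreign pathogen are seeded at density 1 on a configurable schedule
(`event_schedule()`); the standard two-pathogen protocol is R after 50
iterations and $I_f$ after 100. The end state is *stable* if the range of
each of $\sum S$, $\sum R$, $I_e$, $I_f$ over the last ten iterations is
below 0.001, otherwise *cyclic* ("variation" is read as the range, the
strictest simple choice; the protocol does not define it further).

Numerical choices, each of which is covered by a test:

* **Euler step `dt = 0.1`.** All rates are O(1); a halving-`dt`
  convergence gate asserts the equilibrated state moves by less than a
  relative $10^{-3}$.
* **Clamping.** Deterministic ODEs never reach zero, but losses and
  exclusions are reported as complete. Every compartment below $10^{-9}$
  is zeroed once, at the *end* of each equilibration phase — not every
  step — so an exponentially decaying lineage is genuinely removed and
  cannot be rescued by a later event. Within a step, forward-Euler
  overshoot below zero is projected back to 0.
* **Mutation boundary rule.** Interior bins split the moved 5% equally
  between their two neighbours; the bins at $q = 0$ and $q = 1$ send all
  of it to their single neighbour, conserving mass exactly. A
  consequence worth knowing: at a collapsed equilibrium the
  mutation–selection balance parks the modal bin at $q = 0.01$, one grid
  step above zero, so "general resistance lost" is asserted at one-grid-
  step resolution throughout.
* **R arrives naive.** The specific allele is seeded at $q = 0$: it is a
  new mutation at low frequency, not a recombinant of the evolved S
  background (seeding it at the evolved $q$ would presuppose exactly the
  linkage whose emergence is under study). This is exposed as
  `R_intro_q` for anyone who wants the other convention.
* **Fate classification.** R frequency among uninfected hosts below
  $\varepsilon = 0.01$ is loss, above $1 - \varepsilon$ fixation,
  otherwise polymorphism — well above the clamp threshold, well below any
  reported polymorphism. Evolved $q$ is summarised as both the
  density-weighted mean and the modal bin; headline comparisons use the
  mode (the attractor), which the mean approaches from below.
* **Iteration budgets.** Single runs and sweeps run 150 iterations, the
  protocol maximum: at exactly 50 + 50 a minority of polymorphism cells
  are still mid-collapse (modal $q_S$ of 0.05 on its way to the boundary
  bin), and the claims under test are about the equilibrium.

### What the simulation establishes — and what it does not

The "data" here are the model's own deterministic trajectories; there is no
sampling noise and re-running any scenario is bit-identical. A green test
therefore establishes that the *model as stated* has the claimed property at
the stated resolution (grid step 0.01, sweep steps of the coarse grids). It
says nothing about robustness to demographic stochasticity, spatial
structure, co-infection, recovery, mortality virulence or diploid genetics,
none of which are modelled.

## Invasion analytics

For a sterilizing pathogen with no recovery, $R_0 = \beta/\mu$. Because
only general resistance touches the foreign pathogen, its effective
transmission against residents at resistance $q$ is $\beta_f(1-q)$, giving
the invasion threshold $\beta_f > \mu/(1-q)$ (an $R_0$ condition against an
otherwise disease-free resident — the cross-checks in the test suite seed a
rare $I_f$ accordingly). Persistence alongside the more transmissible
endemic competitor additionally requires $\beta_f > (1-r)\beta_e$: the
foreign pathogen needs the specifically-resistant hosts as a refuge.

The evolved singular strategy has an independent closed-form oracle used by
the acceptance tests: a monomorphic resident at $q$ with the endemic
pathogen equilibrates at uninfected fraction $\mu/(\beta_e(1-q))$, a rare
mutant's growth rate is $b - c(q_m) - \mu - \gamma N^* -
(1-q_m)\beta_e I^*/N^*$, and the selection gradient at $q_m = q$ is
$g(q) = -c'(q) + \beta_e\big(1 - \mu/(\beta_e(1-q))\big)$. `singular_strategy()`
bisects $g$; at the default parameters the root is $q^* = 0.41883$, and the
grid simulation's modal bin lands one step away at 0.42 (mean 0.4188).
This package's honest reading of the published attractor "0.41" is that it
is the same singular point reported at the adjacent grid bin; both values
are within the one-grid-step tolerance used everywhere.

## The recombination model

To ask whether the evolved association (general resistance linked to S)
survives sex, the continuous trait is collapsed to two alleles, Q+ at the
strength evolved in S hosts and Q− at the strength evolved in R hosts,
giving four genotypes Q+S, Q+R, Q−S, Q−R. Births pass through a mating
matrix: for mother $m$ and father $f$ the offspring is maternal with
probability $1-p$ and each recombinant phase (maternal allele at one locus,
paternal at the other) with probability $p/2$. Fathers are drawn from the
uninfected pollen pool in proportion to genotype frequencies — infection
sterilizes both ovules and pollen — and the mother's fecundity
$b - c(\text{mother})$ prices the births, with the same additive costs as
the clonal model.

This construction is chosen over a symmetric Mendelian scheme (offspring =
either parent with probability 1/2) for one hard reason: at $p = 0$ it
reduces *exactly* to the clonal model, a reduction the four-genotype suite
asserts to $10^{-6}$ at equilibrium and term-by-term in the derivatives.
The exact published mating table was not available; maternal-by-default is
the construction that satisfies the stated constraint.

### A known irreproducibility, documented rather than patched

The published four-genotype demonstration pins $\mu = 0.2$, $\gamma =
0.001$, $r = 0.2$, $c_r = 0.1$, $q_+ = 0.091$, $\beta_f = 0.7$ (with the
standing $b = 1.5$, $\beta_e = 1$; $c_{q_+}$ is computed from $\theta=0.5$
as $1-(1-0.091)^{0.5} \approx 0.0466$, not hard-coded to the printed
0.0465). Those values are kept verbatim in the `fig5_*` presets — and they
cannot produce the advertised no-recombination outcome in this model.
Analytically: $\beta_f = 0.7 < (1-r)\beta_e = 0.8$, so the foreign pathogen
dies whatever the initial state; once it is gone, closed-form invasion
margins make exclusion one-way (Q−R invades a Q+S resident at +0.032,
Q+S invades a Q−R resident at −0.028), so Q+S is lost for *any*
recombination rate, initial abundance or introduction schedule — we checked
schedules, a range of unprinted $\beta_e$, and direct integration. The
parameter point also sits in the R-fixation region of the model's own
single-pathogen phase diagram, so no adaptive-dynamics run converges to the
claimed polymorphic source state ($q_S = 0.091$, $q_R = 0$, both pathogens
present). The corresponding acceptance expectation is left failing, with
this analysis as its justification.

The *phenomenon* — recombination erodes the evolved linkage disequilibrium
by creating the cheap double-susceptible genotype — is real in this model
and is demonstrated by the `ld_demo_*` presets at a self-consistent
polymorphic source state ($r = 0.8$, $c_r = 0.2$, $\beta_f = 0.7$,
$q_+ = 0.17$ taken from the package's own adaptive dynamics): at $p = 0$
only the coupled genotypes Q+S and Q−R exist ($D \approx 0.22$); at
$p = 0.05$ Q−S floods the population and $D$ collapses below 0.02. Complete
loss of the Q+ allele was not observed there and is not claimed.

## Worked example

```{r example, eval = FALSE}
library(coresist)

# evolve general resistance against a single endemic pathogen
pre <- scenario_preset("fig1b")
trace <- run_evolution(pre$params, pre$grid, pre$schedule, pre$config)
summarize_outcome(trace)$q_S_mode     # 0.42, one grid step from q* = 0.41883
singular_strategy(pre$params)         # 0.418826 (closed-form oracle)

# what that evolution means for a foreign pathogen
foreign_invasion_threshold(q = 0,    mu = 0.2)  # 0.2   (naive hosts)
foreign_invasion_threshold(q = 0.41, mu = 0.2)  # 0.339 (evolved hosts)
foreign_persistence_min_r(beta_e = 1, beta_f = 0.6)  # 0.4
```

## Limitations

Beyond the non-goals above: forward Euler at a fixed step is the protocol's
own integrator, kept for fidelity (with the convergence gate as guard)
rather than replaced by an adaptive stiff solver; sweep presets default to
26×26 grids with a 6×6 smoke tier, and region *topology* — not pixel-level
boundaries — is the reproducible object; the stability classifier applies
the protocol's absolute 0.001 range rule, so it is scale-sensitive for
very small $\gamma$ (large $N$) worlds.
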