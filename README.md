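# coresist

Deterministic eco-evolutionary simulator for the **joint evolution of
general and specific host resistance** against sterilizing pathogens, and
for what that evolution means for the invasion of foreign (host-shifted)
pathogens. The biology is modelled on anther-smut disease: infection is
permanent, sterilizes without killing, and transmission is frequency
dependent.

Who it is for: disease ecologists and evolutionary epidemiologists who want
a reproducible implementation of the two-resistance SI model — phase
diagrams over resistance strength and cost, invasion thresholds, and the
two-locus recombination follow-up — without re-deriving the plumbing.

## The model

Uninfected hosts carry a continuous general-resistance trait
q ∈ [0,1] (grid step 0.01) in two backgrounds, S and R, where the R allele
reduces endemic transmission by a factor r at fecundity cost c_r but is
invisible to the foreign pathogen. With infected pools I_e, I_f and
N the total density:

    dS_i/dt = S_i ( b − c_q − μ − γN − (1−q_i)(β_e I_e + β_f I_f)/N )
    dR_i/dt = R_i ( b − c_q − c_r − μ − γN − (1−q_i)((1−r)β_e I_e + β_f I_f)/N )
    dI_e/dt = I_e ( Σ_i β_e (1−q_i)(S_i + (1−r)R_i)/N − μ )
    dI_f/dt = I_f ( Σ_i β_f (1−q_i)(S_i + R_i)/N − μ )

with the power-law cost c_q = 1 − (1−q)^θ. General resistance evolves by
adaptive dynamics: equilibrate the ecology to t = 1000 (forward Euler,
compiled core), move 5% of every occupied q bin to adjacent bins, repeat up
to 150 times, with the R allele and the foreign pathogen seeded on a
schedule. Closed forms back the simulations: R0 = β/μ, the foreign
invasion threshold β_f > μ/(1−q), the persistence condition
β_f > (1−r)β_e, and a bisection oracle for the singular strategy of q.
A four-genotype model (Q±, S/R) with a mating matrix tests whether the
evolved linkage disequilibrium survives recombination at rate p.

## Worked example

```r
library(coresist)

# evolution of general resistance against a single endemic pathogen
pre   <- scenario_preset("fig1b")   # b=1.5, mu=0.2, gamma=0.01, beta_e=1, theta=0.5
trace <- run_evolution(pre$params, pre$grid, pre$schedule, pre$config)
oc    <- summarize_outcome(trace)
oc$q_S_mode                  # [1] 0.42      modal evolved resistance bin
oc$q_S_mean                  # [1] 0.4187978 density-weighted mean
singular_strategy(pre$params)# [1] 0.4188262 closed-form oracle, one bin away
classify_stability(trace)    # [1] "stable"

# consequences for a foreign pathogen
foreign_invasion_threshold(q = 0,    mu = 0.2)   # [1] 0.2
foreign_invasion_threshold(q = 0.41, mu = 0.2)   # [1] 0.3389831  (0.339)
foreign_persistence_min_r(beta_e = 1, beta_f = 0.6)  # [1] 0.4
```

The evolved trait raises the foreign-pathogen invasion threshold from 0.2
to 0.339; losing it (which stable S/R polymorphism causes — see the
vignette) hands that protection back.

Command line, same machinery:

```sh
exec/coresist run --scenario fig1b --out out/        # trace CSV + provenance
exec/coresist sweep --scenario fig2 --tier smoke --out out/
exec/coresist thresholds --q 0.41 --mu 0.2 --beta_e 1 --beta_f 0.6 --out out/
```

## Layout

- `R/`, `src/` — model core, integrator (Rcpp), adaptive dynamics,
  invasion analytics, recombination model, experiment presets, CLI
- `tests/testthat/` — unit, property and acceptance tests
- `vignettes/joint-resistance-evolution.Rmd` — model, assumptions,
  numerical choices, design decisions, known limitations (including one
  documented irreproducible published recombination preset)
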