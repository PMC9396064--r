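# pnaokin

Kinetic simulation and analysis of the catalytic cycle of
pseudooxynicotine amine oxidase (Pnao), the second enzyme of bacterial
nicotine catabolism in *Pseudomonas putida* S16. Despite its name and its
amine-oxidase fold, Pnao is a dehydrogenase: its reduced flavin is
reoxidized rapidly by the cytochrome c protein CycN and only very slowly by
O₂. This package is for enzymologists who want to simulate, fit, or
re-derive that characterization — stopped-flow transients, steady-state
turnover, and redox potentiometry — from a single parameterized model of
the cycle.

## The model

The catalytic cycle over the enzyme flavin states (E = Pnao, S =
pseudooxynicotine, C = CycN):

```
E_ox  --[ k_red·S/(Kd + S) ]-->  E_red·P  --[ k_rel ]-->  E_red (+ P)
E_red + C_ox  --[ k_cyc1 ]-->  E_sq  + C_red        (first 1e⁻ transfer)
E_sq  + C_ox  --[ k_cyc2 ]-->  E_ox  + C_red        (second 1e⁻ transfer)
E_red + O2    --[ k_ox_o2 ]-->  E_ox                (slow side reaction)
```

Observed stopped-flow traces are Beer–Lambert projections of the
mass-action trajectories; for pseudo-first-order conditions the observed
exponential rates are the eigenvalues of the first-order rate matrix, which
the package exposes (`eigenrates()`) as an analytic oracle for its own
fitters. Secondary analyses follow the standard forms: hyperbolic
k_obs = k_red·[S]/(K_d + [S]) for the reductive fast phase, linear
k_obs = k·[oxidant] for the bimolecular oxidations, Michaelis–Menten
v = k_cat·[C]/(K_M + [C]) for steady state (velocities divided by two
because two CycN are reduced per turnover), and the linearized Nernst plot
ln(red/ox)_enz vs ln(red/ox)_dye for the flavin midpoint potential.

Shipped defaults are the fitted constants: k_red = 74 s⁻¹, K_d = 64 μM,
k_rel = 6.3 s⁻¹, k_ox_o2 = 600 M⁻¹s⁻¹, k_cyc1 = 1.4×10⁵ M⁻¹s⁻¹,
k_cyc2 = 3.2×10⁴ M⁻¹s⁻¹, k_cat = 4.4 s⁻¹, K_M = 34 μM,
E_m(ox/sq) = −111 mV.

## Worked example

Simulate one reductive-half-reaction trace at 500 μM Pon with realistic
instrument noise and fit it to two exponentials:

```r
library(pnaokin)
p  <- pnao_params()
tr <- generate_reductive(p, 500e-6, instrument_model(seed = 1))[[1]]
fit_exponentials(tr, 2)
#> 2-phase exponential fit (converged), n = 400, residual sd = 0.00206 AU
#>   phase 1: k_obs = 65.665 +/- 0.95 1/s, dA = 0.117 AU
#>   phase 2: k_obs = 6.2724 +/- 0.18 1/s, dA = 0.06336 AU
#>   A_inf = 0.01716 AU
```

The fast phase sits at the expected 74·500/(64+500) = 65.6 s⁻¹ (hydride
transfer at this substrate concentration) and the slow phase at the
concentration-invariant 6.3 s⁻¹ product-release rate; the first phase
carries ~65% of the 450 nm amplitude.

An end-to-end run generates all four experiment classes at one seed, runs
the full fitting chain, and compares recovered to generating parameters:

```r
run_recovery(p, seed = 1)
#> Parameter-recovery report (seed 1 )
#>         generating  recovered rel_error
#> k_red     7.40e+01  7.357e+01 -5.82e-03
#> Kd_pon    6.40e-05  6.335e-05 -1.02e-02
#> k_rel     6.30e+00  6.215e+00 -1.35e-02
#> k_ox_o2   6.00e+02  5.961e+02 -6.46e-03
#> k_cyc1    1.40e+05  1.394e+05 -4.62e-03
#> k_cyc2    3.20e+04  3.244e+04  1.36e-02
#> k_art     5.00e-01  4.789e-01 -4.21e-02
#> kcat      4.40e+00  4.485e+00  1.94e-02
#> Km        3.40e-05  3.503e-05  3.04e-02
#> Em_enz   -1.11e+02 -1.110e+02  1.28e-16
#> all fits converged: TRUE
#> Rate-limiting-step consistency analysis
#>   fitted kcat: 4.485 1/s; k_rel: 6.3 1/s; k_red: 74 1/s
#>   predicted cycle kcat (1/k_red + 1/k_rel)^-1: 5.806 1/s
#>   predicted Km(CycN) from microscopic constants: 222.9 uM (open discrepancy vs empirical)
#>   oxidant preference: k_cyc1/k_ox_O2 = 230, k_cyc2/k_ox_O2 = 53
#>   verdict: product-release-limited
```

Read bottom-up, that is the whole scientific argument: turnover is limited
by product release (k_cat ≈ k_rel ≪ k_red), and CycN oxidizes the reduced
flavin 230 times faster than O₂ at equal oxidant concentration, so Pnao is
a CycN-dependent dehydrogenase.

See `vignettes/pnao-kinetics.Rmd` for the model assumptions, numerical
choices, and known limitations.

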