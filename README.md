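# pcaslsim

Simulation and model-based evaluation of pseudo-continuous arterial spin
labeling (pCASL) sampling protocols under macrovascular contamination,
flow dispersion and prolonged arterial transit times.

## What it does, and for whom

Multi-PLD pCASL protocols are optimized for cerebral blood flow (CBF)
and/or arterial transit time (ATT) accuracy under an idealized kinetic
model and a normal ATT range.  `pcaslsim` is for ASL methods researchers
who want to stress-test such schedules when those assumptions break: when
labeled blood lingers in large vessels (macrovascular contamination,
proportional to the arterial blood volume fraction aBV), when the bolus
disperses in transit, and when blood arrives later than the last sampled
post-labeling delay (PLD).

The forward model is the Buxton general kinetic model plus a
macrovascular compartment and a Gamma dispersion kernel.  The tissue
difference signal is

    ΔM_t(t) = 2 M0B f · (c ∗ (r·m))(t),   r(t) = e^(−f t/λ),  m(t) = e^(−t/T1t),

with the pCASL delivery c(t) a boxcar of height α·e^(−Δt/T1b) on
(Δt, Δt+τ); the macrovascular compartment is a boxcar of height
2αM0B·e^(−Δta/T1b)·aBV on (Δta, Δta+τ); dispersion convolves each
delivery with the unit-mass Gamma kernel

    k(t) = s^(1+sp)/Γ(1+sp) · t^(sp) · e^(−st),

whose sharpness s controls the degree of dispersion (reference
s0 = 1/0.13 s⁻¹, time-to-peak p = 0.17 s).  All signals are evaluated in
closed form (via regularized incomplete gamma functions in the dispersed
case).  Four nested model variants — `gkm`, `gkm+mvc`, `gkm+disp`,
`gkm+disp+mvc` — are fit by MAP estimation under truncated-Gaussian
priors, with curvature (inverse-Hessian) uncertainties; single-PLD data
are quantified by exact closed-form inversion at an assumed ATT.
Summaries include signed percent errors, the MVC-sensitivity slope
(% error per 1% aBV for aBV > 0.5%), dispersion-bias increases in peak
overestimation, quality-control exclusion filters, binned averages, and
one-tailed Welch protocol comparisons with Bonferroni correction.

See the methods vignette (`vignettes/pcasl-protocol-evaluation.Rmd`) for
the model conventions, priors, identifiability discussion and design
choices.

## Worked example

Macrovascular contamination masquerades as fast-arriving perfusion when
it is not modeled, and is corrected by the two-compartment variant:

```r
library(pcaslsim)

prot  <- builtin_protocol("cbf-opt")                 # 34-PLD optimized schedule
truth <- asl_state(cbf = 60, att = 1.4, abv = 0.01)  # 1% arterial blood volume
y     <- total_signal(protocol_times(prot), truth, include_mvc = TRUE)

fit(y, prot, model_spec("gkm"))
#> <asl_fit> gkm
#>             cbf    att
#> estimate 71.901 0.4982
#> sd        2.593 0.0835

fit(y, prot, model_spec("gkm+mvc"))
#> <asl_fit> gkm+mvc
#>              cbf    att    abv   datt att_macro
#> estimate 60.0000 1.4000 0.0098 0.5260    0.8740
#> sd        0.0028 0.0005 0.0000 0.0004    0.0009
```

The one-compartment fit misreads the contaminated curve as 72 ml/100 g/min
arriving at 0.5 s (CBF overestimated, ATT underestimated); the
two-compartment fit recovers the generating values and attributes ~1% of
the voxel to arterial blood.

A small Monte-Carlo sweep quantifies a protocol's sensitivity to
contamination (slope of mean CBF error vs aBV above 0.5%):

```r
grid <- condition_grid("abv", repeats = 50, seed = 1)   # aBV 0–2%, ATT 1.4 s
ens  <- simulate_ensemble(prot, grid, "D-M+")           # SNR 9.37 noise
fits <- fit_ensemble(ens, prot, model_spec("gkm"))
mvc_sensitivity(error_table(fits), "cbf_error_pct")
#>       parameter   slope intercept n_points abv_threshold
#> 1 cbf_error_pct 35.0472 -15.15468       30         0.005
```

i.e. every additional 1% of aBV inflates this protocol's CBF estimate by
about 35% when contamination is ignored.

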