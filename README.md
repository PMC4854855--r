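# tacfit

Compartmental kinetic modelling of dynamic PET time–activity curves, built
for quantifying receptor-targeted radiotracers — the motivating case is
PSMA-binding ligands in prostate-cancer tumor models, where uptake is a
two-step process: binding to the cell-surface target, then internalization
of the ligand–receptor complex.

## The model

`tacfit` implements the reversible two-tissue compartment (2TC) model. Blood
tracer concentration C<sub>p</sub>(t) drives a free/nonspecific tissue pool
C<sub>1</sub> and a specifically bound pool C<sub>2</sub>:

    dC1/dt = K1·Cp − (k2 + k3)·C1 + k4·C2
    dC2/dt = k3·C1 − k4·C2

with delivery K<sub>1</sub>, efflux k<sub>2</sub>, binding k<sub>3</sub> and
dissociation k<sub>4</sub> (all min⁻¹). The tissue impulse response is the
biexponential θ₁e^(−α₁t) + θ₂e^(−α₂t); predicted TACs are convolutions of
that response with the input function, time-averaged over the acquisition
frames exactly as scanner data are binned. On top of the micro-parameters
the package reports the standard trapping metrics: delivery ratio
K₁/k₂, binding fraction k₃/(k₂+k₃), retention ratio k₃/k₄ and total
distribution volume V<sub>T</sub> = (K₁/k₂)(1 + k₃/k₄).

Estimation is weighted nonlinear least squares (frame-duration weights,
bounded Levenberg–Marquardt, 20 deterministic log-spaced multi-starts),
with AICc selection between the one- and two-tissue models, Monte-Carlo
parameter-recovery studies, a synthetic-data generator with
count-statistics noise, and the scalar study metrics (SUV,
tumor-to-reference ratios, blocking reduction, internalization fractions,
summary-statistics t tests).

## Worked example

Simulate a noisy 60-min scan of a PSMA-positive tumor on the standard
53-frame protocol, refit the model, and compare compartment structures:

```r
library(tacfit)

sched <- parse_frame_spec("10x2,8x5,6x10,6x20,8x60,10x120,5x300")
cp    <- feng_input()                              # default bolus input
rc    <- rate_constants(0.12, 0.18, 0.08, 0.004)   # PSMA+ tumor kinetics

noisy <- add_noise(frame_average(rc, cp, sched), 0.05, seed = 1)
fit   <- fit_tac(noisy, cp)
summary(fit)
#> 2TC compartment-model fit (53 frames, duration weights)
#>   K1 = 0.127000 (0.00834) min^-1
#>   k2 = 0.208400 (0.03400) min^-1
#>   k3 = 0.091520 (0.01400) min^-1
#>   k4 = 0.005856 (0.00250) min^-1
#>   wrss = 0.0156241, AICc = -422
#> Derived kinetic metrics:
#>   delivery ratio  K1/k2      = 0.6092
#>   binding fraction k3/(k2+k3) = 0.3051
#>   retention ratio k3/k4      = 15.63
#>   distribution volume VT     = 10.13

select_model(fit_tac(noisy, cp, model = "1tc"), fit)$model
#> [1] "2tc"
```

The fitted constants land within one standard error of the generating
values at this noise level; the large retention ratio (k₃/k₄ in the tens)
is the kinetic signature of molecular trapping, and AICc correctly prefers
the two-tissue structure that generated the data. The scalar metrics work
the same way:

```r
tumor_to_reference(1.1, 0.1)        # 11   (tumor-to-reference SUV ratio)
blocking_reduction(1.1, 0.22)       # 80   (% uptake lost under blocking)
internalized_fraction(45.47, 35.05) # 43.53 -> reported as 44 %
```

See the vignette (`vignettes/tracer-kinetics.Rmd`) for the model
assumptions, numerical choices and the synthetic-data design.

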