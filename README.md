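# mechunfold

Trajectory-analysis toolkit for force-probe (steered) molecular dynamics
studies of mechanical protein unfolding, built around the plakin-domain
mechano-sensing problem: tandem spectrin repeats (SRs) with an inserted
SH3 domain are pulled apart at constant velocity, and the analysis must
decide *when* each structural feature unfolds, *how hard* it resists, and
*which* of two competing domains yields first.

The package implements the full analysis layer downstream of the MD
engine, plus a seeded synthetic-data generator that emulates every input,
so the pipeline is fully testable without trajectories:

- **Contact areas from structure.** Shrake–Rupley solvent-accessible
  surface areas with a deterministic golden-angle point set, and interface
  contact areas CA_{A↔B} = ½(SASA_A + SASA_B − SASA_{A+B}).
- **Unfolding-event detection.** Equilibrium baseline CA_low =
  Q1 − 1.5·(Q3 − Q1) over equilibrium frames; an event starts when the
  contact area first drops below ½·CA_low and ends below 0.002 nm²;
  display boxes narrower than 2 nm are widened symmetrically.
- **Rupture forces.** Channel combination F = ½(F1 − F2), Gaussian
  smoothing with σ fixed in elongation units (0.1 nm default), and the
  first-peak rupture force: the maximum of the smoothed profile within
  the first 20 nm of elongation.
- **Bell-model kinetics.** F_r = (k_B T/x_b)·ln(k v x_b/(k_B T k_off)) =
  A·ln(k v/B), fitted by unweighted least squares over all records across
  a pulling-velocity ladder; reports x_b = k_B T/A, k_off = B/A and the
  slope per decade of velocity A·ln 10.
- **Bayesian unfolding order.** From k-of-n first-unfolding counts, a
  uniform prior on the first-unfolding probability p and the logistic
  link p = 1/(1 + exp(ΔΔG/k_B T)) give a posterior over the barrier
  difference ΔΔG, with closed-form mode k_B T·ln((n−k+1)/(k+1)) and
  equal-tailed credible intervals mapped from Beta quantiles.
- **Significance and classification.** The Z-rule (difference of means
  at least 2·√(ε1² + ε2²), required at every one of the fastest three
  velocities), three-peak prominence labelling of force profiles, and a
  ROC of the maximum helix tilt angle (trapezoid AUC, equal to the
  Mann–Whitney statistic with ties counted ½).

I/O covers GROMACS-style pull-force XVG (with the 1.6605390 pN per
kJ/(mol·nm) conversion), fixed-column PDB/GRO structures, and TSV tables.

## Worked example

The Bayesian unfolding-order estimate from first-unfolding counts — 3 of
33 trajectories with SR5 unfolding before SR4:

```r
library(mechunfold)
post <- ddg_posterior(order_counts(3, 33, labels = c("SR5", "SR4")))
print(post)
#> ddg_posterior (SR5 first 3/33): mode 1.221 kcal/mol, 95% CI [0.698, 2.014]
```

The mode says the SR5 unfolding barrier sits about 1.2 kcal/mol above
SR4's; the interval is the 95% equal-tailed credible range given 33
trajectories. A Bell fit on noiseless records generated from known
parameters recovers them exactly:

```r
v <- c(1, 1/3, 1/10, 1/30)                       # nm/ns
rec <- data.frame(v_pull_nm_per_ns = v,
                  F_r_pN = 110 * log(830 * v / 1e-6))
print(fit_bell(rec, k_spring = 830))
#> bell_fit: A = 110 pN, B = 1e-06 pN/ns, x_b = 0.03765 nm, k_off = 9.091e-09 /ns
#>   slope 253.3 pN per decade of velocity, 4 velocities
```

## The analysis workflow

`analysis/` holds the numbered drivers of the full synthetic study (run
each from the repository root after installing; outputs land in
`results/`):

1. `01_simulate.R` — generate example raw inputs (pull traces,
   contact-area series) under the study conditions: two systems, four
   velocities (1, 1/3, 1/10, 1/30 nm/ns), 830 pN/nm spring, 300 K.
2. `02_events.R` — equilibrium baselines and unfolding-event catalogs
   for 33 trajectories per system.
3. `03_rupture_bell.R` — first-peak rupture extraction, Bell fits, and
   the Z-rule comparison of the two systems.
4. `04_ddg.R` — ΔΔG posteriors from the published first-unfolding counts
   and from the synthetic event catalogs.
5. `05_tilt_roc.R` — shearing/tearing peak-count labels and the
   tilt-angle ROC.

`run_full()` chains the same stages programmatically from one config
(see `default_config()`; YAML configs via `read_config()`).

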