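#!/usr/bin/env Rscript
# Stage 1: generate the synthetic force-probe study that stands in for the
# MD engine, and save example raw inputs for inspection.
#
# Two systems are emulated: a desmoplakin-like construct (x_b = 0.040 nm,
# k_off = 1e-6 /ns, first-unfolding preference ddG = 1.2 kcal/mol) and a
# plectin-like one (x_b = 0.048 nm, k_off = 1.2e-6 /ns, ddG = 0), pulled
# at 1, 1/3, 1/10, 1/30 nm/ns with a 830 pN/nm spring at 300 K.

suppressPackageStartupMessages(library(mechunfold))

cfg <- default_config(seed = 1)
dir.create("results", showWarnings = FALSE)

# one example pull-force trace per system at the fastest velocity
for (s in names(cfg$systems)) {
  sys <- cfg$systems[[s]]
  F_example <- gen_bell_ruptures(sys$x_b, sys$k_off, cfg$k_spring,
                                 velocities = 1, replicas = 1,
                                 seed = cfg$seed)$F_r_pN
  tr <- gen_force_trace(
    v_pull = 1, k_eff = F_example / cfg$trace$peak_x,
    events = data.frame(elong = seq(cfg$trace$peak_x, 30,
                                    by = cfg$trace$drop_spacing),
                        drop_frac = cfg$trace$drop_frac),
    noise_sd = cfg$trace$noise_sd, duration = 36, seed = cfg$seed,
    k_spring = cfg$k_spring, label = s)
  write_tsv(data.frame(time_ns = tr$time, f1_pN = tr$f1, f2_pN = tr$f2),
            file.path("results", paste0("01_example_trace_", s, ".tsv")))
  cat(sprintf("%s example trace: planted first-peak force %.0f pN, %d samples\n",
              s, F_example, length(tr$time)))
}

# one example contact-area series with a planted loss event at 40 nm
ca <- gen_ca_series(eq_mean = cfg$events$eq_mean, seed = cfg$seed,
                    events = data.frame(center = 40, width = 1),
                    pair = "SR4")
write_tsv(data.frame(elongation_nm = ca$series$elongation,
                     ca_nm2 = ca$series$ca),
          "results/01_example_ca_series.tsv")
cat(sprintf("example CA series: equilibrium mean %.2f nm^2, %d pulled frames\n",
            mean(ca$equilibrium), length(ca$series$ca)))
cat("stage 1 done: raw synthetic inputs in results/01_*.tsv\n")
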