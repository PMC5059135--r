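#!/usr/bin/env Rscript
# Visually evoked responses (100 ms flash every 30 s): split each trial into
# the primary (early-gamma) and secondary (spindle-burst) windows, compute
# window rates and induced spectra over 0.3 s evoked spectral windows, and
# contrast the immature two-phase response with the brief mature response.

suppressMessages(library(wavegate))
seed <- 1L

out_dir <- file.path("results", "evoked")
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
rows <- list()
for (age_name in c("P9_11", "P13_14")) {
  sess <- generate_evoked_trials(age_profile(age_name),
                                 stimulus_protocol("flash", n_trials = 20),
                                 seed = seed + match(age_name,
                                                     c("P9_11", "P13_14")))
  sp <- split_primary_secondary(sess)
  e1 <- evoked_spectrum(sp$primary$trial_counts)
  e2 <- evoked_spectrum(sp$secondary$trial_counts)
  p1 <- peak_frequency(e1, c(5, 55))
  p2 <- peak_frequency(e2, c(5, 55))
  for (w in c("primary", "secondary")) {
    es <- if (w == "primary") e1 else e2
    write.csv(data.frame(freq_hz = es$freq_hz, power = es$power),
              file.path(out_dir, sprintf("spectrum_%s_%s.csv", age_name, w)),
              row.names = FALSE)
  }
  rows[[age_name]] <- data.frame(
    age = age_name,
    primary_rate_hz = round(sp$primary$rate_hz, 1),
    secondary_rate_hz = round(sp$secondary$rate_hz, 1),
    primary_peak_hz = round(p1$f_peak_hz, 1),
    secondary_peak_hz = round(p2$f_peak_hz, 1),
    secondary_low_confidence = p2$low_confidence)
  cat(sprintf(
    "%-7s: primary %5.1f Hz (peak %4.1f Hz), secondary %5.1f Hz (peak %4.1f Hz%s)\n",
    age_name, sp$primary$rate_hz, p1$f_peak_hz, sp$secondary$rate_hz,
    p2$f_peak_hz, if (p2$low_confidence) ", low confidence" else ""))
}
write.csv(do.call(rbind, rows), file.path(out_dir, "summary.csv"),
          row.names = FALSE)
cat("\nAt P9-11 the flash evokes an early-gamma (30-50 Hz) primary response\n",
    "followed by a spindle-band (8-30 Hz) secondary response; by P13-14 the\n",
    "primary response is brief and non-oscillatory and the secondary\n",
    "response is largely gone.\n", sep = "")
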