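#' Experiment configuration
#'
#' Validated configuration for the end-to-end simulated experiments. The
#' default condition duration (1200 s) mirrors the standard design of a
#' 20 min control period and a 20 min period under manipulation; per-animal
#' seeds are derived from the master seed by a fixed offset so adding
#' animals never perturbs existing ones.
#'
#' @param kind `"silencing"` or `"stimulation"`.
#' @param seed master integer seed (mandatory).
#' @param n_animals simulated animals (default 6).
#' @param age age-profile name (silencing) or character vector of ages
#'   (stimulation).
#' @param target silenced structure for silencing experiments.
#' @param residual_fraction drive remaining under the manipulation.
#' @param duration_s per-condition duration (s).
#' @param wave list of overrides for [wave_params()].
#' @param spectral a [spectral_params()].
#' @param alpha significance level for all tests.
#' @param n_opto_trials,n_train_trials,n_flash_trials trial counts for the
#'   stimulation experiment.
#' @return an object of class `experiment_config`.
#' @export
experiment_config <- function(kind = c("silencing", "stimulation"), seed,
                              n_animals = 6, age = "P9_11",
                              target = "retina", residual_fraction = 0.1,
                              duration_s = 1200, wave = list(),
                              spectral = spectral_params(), alpha = 0.05,
                              n_opto_trials = 50, n_train_trials = 30,
                              n_flash_trials = 20) {
  kind <- match.arg(kind)
  if (missing(seed)) stop("config field 'seed' is mandatory")
  stopifnot(n_animals >= 1, duration_s > 0,
            residual_fraction >= 0, residual_fraction <= 1)
  if (kind == "silencing" && !target %in% c("retina", "lgn", "vc"))
    stop("config field 'target' must be one of retina, lgn, vc")
  structure(list(kind = kind, seed = as.integer(seed),
                 n_animals = as.integer(n_animals), age = age,
                 target = target, residual_fraction = residual_fraction,
                 duration_s = duration_s, wave = wave, spectral = spectral,
                 alpha = alpha, n_opto_trials = as.integer(n_opto_trials),
                 n_train_trials = as.integer(n_train_trials),
                 n_flash_trials = as.integer(n_flash_trials)),
            class = "experiment_config")
}

#' Load an experiment configuration from YAML
#'
#' @param path YAML file whose keys match [experiment_config()] arguments.
#' @return an `experiment_config`.
#' @export
read_experiment_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(formals(experiment_config))
  bad <- setdiff(names(y), known)
  if (length(bad))
    stop("unknown config field(s): ", paste(bad, collapse = ", "))
  if (!is.null(y$spectral)) y$spectral <- do.call(spectral_params, y$spectral)
  do.call(experiment_config, y)
}

animal_seed <- function(master, i, stream = 0L)
  (as.integer(master) + 7919L * as.integer(i) + 104729L * as.integer(stream)) %% .Machine$integer.max

wave_params_for <- function(config, seed) {
  args <- utils::modifyList(list(duration_s = config$duration_s, seed = seed),
                            config$wave)
  do.call(wave_params, args)
}

session_summary <- function(session, config, region = "LGN") {
  tr <- get_train(session, region = region)
  ev <- detect_events(tr)
  list(rate_hz = firing_rate(tr),
       continuity = compute_continuity(ev)$continuity,
       durations_s = ev$events$duration_s,
       spectrum = analyze_spectrum(bin_spike_train(tr), config$spectral))
}

#' Run a simulated silencing experiment
#'
#' Simulates `n_animals` paired control/manipulation sessions, analyses
#' each (rate, event continuity, event-duration distribution, normalized
#' spike spectrum), and applies the paired statistics: signed-rank tests on
#' rate and continuity percent change, a two-sample KS test on pooled event
#' durations, and the frequency-wise permutation test with max-statistic
#' correction on the spectra. Tables are written to `out_dir` (CSV/JSON plus
#' a markdown summary) and returned.
#'
#' @param config an [experiment_config()] of kind `"silencing"`.
#' @param out_dir output directory, or `NULL` to skip writing.
#' @param region analysed region (`"LGN"` for retina/VC silencing, `"VC"`
#'   for LGN silencing).
#' @return an object of class `silencing_report`.
#' @export
run_silencing_experiment <- function(config, out_dir = NULL,
                                     region = if (config$target == "lgn") "VC" else "LGN") {
  stopifnot(inherits(config, "experiment_config"),
            config$kind == "silencing")
  age <- age_profile(config$age)
  manip <- manipulation_spec(config$target,
                             residual_fraction = config$residual_fraction,
                             onset_s = 0)
  per <- data.frame(animal = seq_len(config$n_animals),
                    rate_pre = NA_real_, rate_post = NA_real_,
                    cont_pre = NA_real_, cont_post = NA_real_,
                    peak_pre_hz = NA_real_, peak_post_hz = NA_real_)
  dur_pre <- list(); dur_post <- list()
  spec_pre <- list(); spec_post <- list()
  for (i in seq_len(config$n_animals)) {
    ctl <- generate_wave_recording(age,
             wave_params_for(config, animal_seed(config$seed, i, 0L)),
             manipulation_spec("none"))
    man <- generate_wave_recording(age,
             wave_params_for(config, animal_seed(config$seed, i, 1L)), manip)
    a <- session_summary(ctl, config, region)
    b <- session_summary(man, config, region)
    per$rate_pre[i] <- a$rate_hz; per$rate_post[i] <- b$rate_hz
    per$cont_pre[i] <- a$continuity; per$cont_post[i] <- b$continuity
    if (!a$spectrum$flags$empty)
      per$peak_pre_hz[i] <- peak_frequency(a$spectrum)$f_peak_hz
    if (!b$spectrum$flags$empty)
      per$peak_post_hz[i] <- peak_frequency(b$spectrum)$f_peak_hz
    dur_pre[[i]] <- a$durations_s; dur_post[[i]] <- b$durations_s
    spec_pre[[i]] <- a$spectrum; spec_post[[i]] <- b$spectrum
  }
  per$rate_change_pct <- percent_change(per$rate_pre, per$rate_post)
  per$cont_change_pct <- percent_change(per$cont_pre, per$cont_post)

  w_rate <- wilcoxon_signed_rank(per$rate_pre, per$rate_post)
  w_cont <- wilcoxon_signed_rank(per$cont_pre, per$cont_post)
  cp <- stats::complete.cases(per$peak_pre_hz, per$peak_post_hz)
  w_peak <- if (any(cp))
    wilcoxon_signed_rank(per$peak_pre_hz[cp], per$peak_post_hz[cp])
  else list(statistic = NA_real_, p_value = NA_real_, n_nonzero = 0L,
            method = "degenerate", flag = "no-peaks")
  ks <- ks_two_sample_with_ci(unlist(dur_pre), unlist(dur_post),
                              alpha = config$alpha)
  ok <- !vapply(spec_pre, function(s) s$flags$empty, TRUE) &
    !vapply(spec_post, function(s) s$flags$empty, TRUE)
  perm <- if (sum(ok) >= 2)
    permutation_spectrum_test(spec_pre[ok], spec_post[ok],
                              alpha = config$alpha,
                              seed = animal_seed(config$seed, 0L, 2L))
  else NULL

  report <- structure(list(config = config, region = region,
                           per_animal = per,
                           durations = list(pre = unlist(dur_pre),
                                            post = unlist(dur_post)),
                           spectra = list(pre = spec_pre, post = spec_post),
                           stats = list(wilcoxon_rate = w_rate,
                                        wilcoxon_continuity = w_cont,
                                        wilcoxon_peak = w_peak, ks = ks,
                                        permutation = perm)),
                      class = "silencing_report")
  if (!is.null(out_dir)) write_silencing_report(report, out_dir)
  report
}

write_silencing_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  data.table::fwrite(report$per_animal, file.path(out_dir, "percent_change.csv"))
  dur <- data.table::data.table(
    condition = rep(c("control", "silenced"),
                    c(length(report$durations$pre),
                      length(report$durations$post))),
    duration_s = c(report$durations$pre, report$durations$post))
  data.table::fwrite(dur, file.path(out_dir, "event_durations.csv"))
  sp <- data.table::rbindlist(c(
    lapply(seq_along(report$spectra$pre), function(i)
      data.table::data.table(condition = "control", animal = i,
                             freq_hz = report$spectra$pre[[i]]$freq_hz,
                             power = report$spectra$pre[[i]]$power)),
    lapply(seq_along(report$spectra$post), function(i)
      data.table::data.table(condition = "silenced", animal = i,
                             freq_hz = report$spectra$post[[i]]$freq_hz,
                             power = report$spectra$post[[i]]$power))))
  data.table::fwrite(sp, file.path(out_dir, "spectra.csv"))
  st <- report$stats
  js <- list(
    target = report$config$target,
    residual_fraction = report$config$residual_fraction,
    region = report$region,
    n_animals = report$config$n_animals,
    mean_rate_change_pct = mean(report$per_animal$rate_change_pct),
    mean_continuity_change_pct = mean(report$per_animal$cont_change_pct),
    wilcoxon_rate_p = st$wilcoxon_rate$p_value,
    wilcoxon_continuity_p = st$wilcoxon_continuity$p_value,
    wilcoxon_peak_p = st$wilcoxon_peak$p_value,
    ks_D = st$ks$D, ks_p = st$ks$p_value,
    permutation = if (is.null(st$permutation)) NULL else list(
      threshold = st$permutation$corrected_threshold,
      n_permutations = st$permutation$n_permutations,
      significant_ranges_hz = st$permutation$significant_ranges_hz),
    seed = report$config$seed)
  jsonlite::write_json(js, file.path(out_dir, "stats.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       dataframe = "columns")
  md <- c(
    sprintf("# Silencing experiment: %s (residual %.2f), %s analysed",
            report$config$target, report$config$residual_fraction,
            report$region),
    "",
    sprintf("- n = %d simulated animals, %g s per condition",
            report$config$n_animals, report$config$duration_s),
    sprintf("- mean rate change: %+.1f%% (signed-rank p = %.4g)",
            js$mean_rate_change_pct, js$wilcoxon_rate_p),
    sprintf("- mean continuity change: %+.1f%% (signed-rank p = %.4g)",
            js$mean_continuity_change_pct, js$wilcoxon_continuity_p),
    sprintf("- event durations: KS D = %.3f, p = %.4g", js$ks_D, js$ks_p),
    if (!is.null(st$permutation) && nrow(st$permutation$significant_ranges_hz))
      sprintf("- spectra: p<%g between %s Hz", report$config$alpha,
              paste(sprintf("%.1f-%.1f",
                            st$permutation$significant_ranges_hz$lo_hz,
                            st$permutation$significant_ranges_hz$hi_hz),
                    collapse = ", "))
    else "- spectra: no significant frequency ranges")
  writeLines(md, file.path(out_dir, "summary.md"))
  invisible(out_dir)
}

#' Run a simulated stimulation experiment
#'
#' For each requested age mode: single-pulse optogenetic trials (PSTHs,
#' LGN and VC onset latencies and their difference, response reliability,
#' excitation 1-100 ms and inhibition 100-250 ms window changes), a 20 Hz
#' five-pulse train block (entrainment), and flash trials (primary/secondary
#' response rates and evoked spectra). Writes `responses.json`, per-age PSTH
#' tables and a markdown summary.
#'
#' @param config an [experiment_config()] of kind `"stimulation"`.
#' @param out_dir output directory, or `NULL` to skip writing.
#' @param ages character vector of age-profile names.
#' @return an object of class `stimulation_report`.
#' @export
run_stimulation_experiment <- function(config, out_dir = NULL,
                                       ages = c("P5_7", "P9_11", "P13_14")) {
  stopifnot(inherits(config, "experiment_config"),
            config$kind == "stimulation")
  single <- stimulus_protocol("opto_single", n_trials = config$n_opto_trials)
  train <- stimulus_protocol("opto_train", n_trials = config$n_train_trials,
                             train_freq_hz = 20, train_n_pulses = 5)
  flash <- stimulus_protocol("flash", n_trials = config$n_flash_trials)
  out <- list()
  for (a in seq_along(ages)) {
    age <- age_profile(ages[a])
    res <- list(age = ages[a])
    per_lat <- per_rel <- per_exc <- per_inh <- numeric(config$n_animals)
    per_vc <- numeric(config$n_animals)
    per_entr <- logical(config$n_animals)
    per_p1 <- per_p3 <- numeric(config$n_animals)
    per_prim <- per_sec <- numeric(config$n_animals)
    psth_acc <- NULL
    for (i in seq_len(config$n_animals)) {
      s1 <- generate_opto_trials(age, single,
                                 seed = animal_seed(config$seed, i, 10L + a))
      ps_lgn <- compute_psth(s1, "opto_single", region = "LGN",
                             window_s = c(-0.2, 0.3))
      ps_vc <- compute_psth(s1, "opto_single", region = "VC",
                            window_s = c(-0.2, 0.3))
      ol_l <- onset_latency(ps_lgn); ol_v <- onset_latency(ps_vc)
      per_lat[i] <- if (ol_l$responded) ol_l$latency_ms else NA
      per_vc[i] <- if (ol_v$responded) ol_v$latency_ms else NA
      per_rel[i] <- response_reliability(s1)$reliability_pct
      per_exc[i] <- window_rate_change(ps_lgn, c(0.001, 0.100))
      per_inh[i] <- window_rate_change(ps_lgn, c(0.100, 0.250))
      psth_acc <- if (is.null(psth_acc)) ps_lgn$rate_hz
                  else psth_acc + ps_lgn$rate_hz
      st <- generate_opto_trials(age, train,
                                 seed = animal_seed(config$seed, i, 20L + a))
      ei <- entrainment_index(st)
      per_entr[i] <- ei$entrained
      per_p1[i] <- ei$pulse_prob[1]
      per_p3[i] <- mean(ei$pulse_prob[3:5])
      sf <- generate_evoked_trials(age, flash,
                                   seed = animal_seed(config$seed, i, 30L + a))
      sp <- split_primary_secondary(sf)
      per_prim[i] <- sp$primary$rate_hz
      per_sec[i] <- sp$secondary$rate_hz
    }
    res$lgn_latency_ms <- mean(per_lat, na.rm = TRUE)
    res$vc_latency_ms <- mean(per_vc, na.rm = TRUE)
    res$lgn_vc_delay_ms <- mean(per_lat - per_vc, na.rm = TRUE)
    res$reliability_pct <- mean(per_rel)
    res$excitation_change_pct <- mean(per_exc)
    res$inhibition_change_pct <- mean(per_inh)
    res$entrained_fraction <- mean(per_entr)
    res$pulse1_prob <- mean(per_p1)
    res$pulse3plus_prob <- mean(per_p3)
    res$primary_rate_hz <- mean(per_prim)
    res$secondary_rate_hz <- mean(per_sec)
    res$psth <- data.frame(time_s = seq(-0.2 + 5e-4, 0.3 - 5e-4, by = 1e-3),
                           rate_hz = psth_acc / config$n_animals)
    out[[ages[a]]] <- res
  }
  report <- structure(list(config = config, ages = ages, results = out),
                      class = "stimulation_report")
  if (!is.null(out_dir)) write_stimulation_report(report, out_dir)
  report
}

write_stimulation_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  js <- lapply(report$results, function(r) r[setdiff(names(r), "psth")])
  jsonlite::write_json(js, file.path(out_dir, "responses.json"),
                       auto_unbox = TRUE, digits = NA)
  for (a in names(report$results))
    data.table::fwrite(report$results[[a]]$psth,
                       file.path(out_dir, sprintf("psth_%s.csv", a)))
  md <- c("# Stimulation experiment", "")
  for (a in names(report$results)) {
    r <- report$results[[a]]
    md <- c(md, sprintf("## %s", a),
            sprintf("- LGN onset %.1f ms, VC onset %.1f ms, delay %.1f ms",
                    r$lgn_latency_ms, r$vc_latency_ms, r$lgn_vc_delay_ms),
            sprintf("- reliability %.1f%%", r$reliability_pct),
            sprintf("- window change: 1-100 ms %+.1f%%, 100-250 ms %+.1f%%",
                    r$excitation_change_pct, r$inhibition_change_pct),
            sprintf("- 20 Hz train: entrained in %.0f%% of animals (pulse 1 prob %.2f, pulses 3-5 %.2f)",
                    100 * r$entrained_fraction, r$pulse1_prob, r$pulse3plus_prob),
            sprintf("- flash: primary %.1f Hz, secondary %.1f Hz",
                    r$primary_rate_hz, r$secondary_rate_hz), "")
  }
  writeLines(md, file.path(out_dir, "summary.md"))
  invisible(out_dir)
}
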