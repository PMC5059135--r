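short_cfg <- function(target = "retina", residual = 0.1, seed = 30,
                      age = "P9_11", dur = 400)
  experiment_config("silencing", seed = seed, target = target,
                    residual_fraction = residual, age = age,
                    duration_s = dur)

test_that("configuration is validated with informative errors", {
  expect_error(experiment_config("silencing"), "seed")
  expect_error(experiment_config("silencing", seed = 1, target = "cortex"),
               "target")
  expect_error(experiment_config("silencing", seed = 1,
                                 residual_fraction = 2))
  d <- withr::local_tempdir()
  yaml::write_yaml(list(kind = "silencing", seed = 3, banana = 1),
                   file.path(d, "cfg.yaml"))
  expect_error(read_experiment_config(file.path(d, "cfg.yaml")), "banana")
  yaml::write_yaml(list(kind = "silencing", seed = 3, n_animals = 2),
                   file.path(d, "ok.yaml"))
  cfg <- read_experiment_config(file.path(d, "ok.yaml"))
  expect_equal(cfg$n_animals, 2L)
})

test_that("sham manipulation produces a null comparison", {
  rep <- run_silencing_experiment(short_cfg(residual = 1, seed = 31))
  expect_lt(abs(mean(rep$per_animal$rate_change_pct)), 15)
  expect_lt(abs(mean(rep$per_animal$cont_change_pct)), 15)
  expect_equal(nrow(rep$stats$permutation$significant_ranges_hz), 0L)
})

test_that("retinal silencing reproduces the expected effect pattern", {
  rep <- run_silencing_experiment(short_cfg(seed = 32, dur = 600))
  expect_true(all(rep$per_animal$rate_change_pct < -50))
  expect_true(all(rep$per_animal$cont_change_pct < -50))
  expect_equal(rep$stats$wilcoxon_rate$p_value, 0.03125)
  # long-duration tail is lost
  expect_gt(max(rep$durations$pre), max(rep$durations$post))
  expect_lt(max(rep$durations$post), 5)
  # spindle-band power reduction flagged near the modulation frequency
  rg <- rep$stats$permutation$significant_ranges_hz
  expect_gt(nrow(rg), 0)
  expect_true(any(rg$lo_hz <= 28 & rg$hi_hz >= 18))
})

test_that("experiment reports are deterministic and regenerable from disk", {
  cfg <- short_cfg(seed = 33, dur = 300)
  cfg$n_animals <- 3L
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  run_silencing_experiment(cfg, out_dir = d1)
  run_silencing_experiment(cfg, out_dir = d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     info = f)
  }
  st <- jsonlite::read_json(file.path(d1, "stats.json"))
  expect_equal(st$wilcoxon_rate_p, 0.25)  # n = 3 exact signed-rank floor
  expect_true(file.exists(file.path(d1, "summary.md")))
})

test_that("stimulation experiment recovers the developmental sequence", {
  cfg <- experiment_config("stimulation", seed = 34, n_animals = 3,
                           n_opto_trials = 60, n_train_trials = 20,
                           n_flash_trials = 10)
  rep <- run_stimulation_experiment(cfg)
  r <- rep$results
  # latency ordering: P5-7 slowest, P9-11 and P13-14 similar
  expect_gt(r$P5_7$lgn_latency_ms, r$P9_11$lgn_latency_ms + 8)
  expect_lt(abs(r$P9_11$lgn_latency_ms - r$P13_14$lgn_latency_ms), 5)
  # reliability rises across development
  expect_lt(r$P5_7$reliability_pct, r$P13_14$reliability_pct - 20)
  # inhibition window clearly suppressed only after eye opening
  expect_lt(r$P13_14$inhibition_change_pct, -50)
  expect_gt(r$P5_7$inhibition_change_pct, -50)
  expect_gt(r$P9_11$inhibition_change_pct, -50)
  # 20 Hz trains entrain LGN only at P9-11
  expect_gt(r$P9_11$entrained_fraction, 0.5)
  expect_lt(r$P13_14$entrained_fraction, 0.5)
  # excitation window is elevated at all ages
  for (a in names(r)) expect_gt(r[[a]]$excitation_change_pct, 0)
})

test_that("silencing the thalamus is analysed in cortex", {
  rep <- run_silencing_experiment(short_cfg(target = "lgn", seed = 35,
                                            dur = 300))
  expect_equal(rep$region, "VC")
  expect_true(all(rep$per_animal$rate_change_pct < 0))
})
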