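# Synthetic AF-signal generator: determinism, spectral placement,
# additive structure, cohort construction.

test_that("generation is deterministic given the seed", {
  s <- aa_synth_spec(organization = 0.4, seed = 3, duration_s = 5)
  expect_identical(synthesize_aa(s)$samples, synthesize_aa(s)$samples)
  es <- ecg_synth_spec(aa = s, seed = 9)
  r1 <- synthesize_ecg(es); r2 <- synthesize_ecg(es)
  expect_identical(r1$samples, r2$samples)
  expect_identical(attr(r1, "r_peak_truth"), attr(r2, "r_peak_truth"))
})

test_that("fully organized f waves are deterministic and comb-like", {
  # different seeds, same organization = 1: identical signals
  a1 <- synthesize_aa(aa_synth_spec(organization = 1, seed = 1,
                                    duration_s = 10))
  a2 <- synthesize_aa(aa_synth_spec(organization = 1, seed = 99,
                                    duration_s = 10))
  expect_identical(a1$samples, a2$samples)
  # >= 95% of spectral energy inside the harmonic comb window
  a <- synthesize_aa(aa_synth_spec(organization = 1, n_harmonics = 3,
                                   duration_s = 30, seed = 1))
  expect_gt(band_energy_frac(a$samples, 1024, 4, 8 + 3 * 6), 0.95)
  # dominant periodogram peak within 0.5 Hz of the fundamental
  sp <- stats::spec.pgram(stats::ts(a$samples, frequency = 1024),
                          plot = FALSE, taper = 0)
  expect_lt(abs(sp$freq[which.max(sp$spec)] - 6), 0.5 + 1e-9)
})

test_that("fully disorganized signals decorrelate across seeds", {
  a1 <- synthesize_aa(aa_synth_spec(organization = 0, seed = 1))$samples
  a2 <- synthesize_aa(aa_synth_spec(organization = 0, seed = 2))$samples
  expect_lt(abs(cor(a1, a2)), 0.2)
})

test_that("zero amplitude forces a zero signal", {
  a <- synthesize_aa(aa_synth_spec(amp_mV = 0, duration_s = 2))
  expect_true(all(a$samples == 0))
})

test_that("the ECG is the exact sum of its components when others vanish", {
  aa <- aa_synth_spec(organization = 0.7, seed = 5, duration_s = 10)
  es <- ecg_synth_spec(aa = aa, qrs_amp_mV = 0, t_amp_mV = 0,
                       baseline_wander_amp_mV = 0, powerline_amp_mV = 0,
                       noise_std_mV = 0, seed = 6)
  rec <- synthesize_ecg(es)
  expect_equal(rec$samples, synthesize_aa(aa)$samples, tolerance = 1e-14)
})

test_that("beat count follows the RR renewal process", {
  rec <- synthesize_ecg(ecg_synth_spec(seed = 9))   # 30 s, mean RR 0.6
  nb <- length(attr(rec, "r_peak_truth"))
  expect_gte(nb, 30 / 0.6 - 3 * sqrt(30 / 0.6))
  expect_lte(nb, 30 / 0.6 + 3 * sqrt(30 / 0.6))
})

test_that("powerline interference shows as a sharp 50 Hz line", {
  rec <- synthesize_ecg(ecg_synth_spec(powerline_amp_mV = 0.05, seed = 3))
  sp <- stats::spec.pgram(stats::ts(rec$samples, frequency = 1024),
                          plot = FALSE, taper = 0)
  i50 <- which.min(abs(sp$freq - 50))
  neighbours <- sp$spec[c(i50 - 60, i50 + 60)]   # ~2 Hz away
  expect_gt(10 * log10(sp$spec[i50] / max(neighbours)), 20)
})

test_that("invalid generator settings are rejected by field name", {
  expect_error(aa_synth_spec(duration_s = -1), "duration_s")
  expect_error(aa_synth_spec(amp_mV = -0.1), "amp_mV")
  expect_error(aa_synth_spec(organization = 1.2), "organization")
  expect_error(ecg_synth_spec(rr_cv = 0.4), "refractory")
  expect_error(ecg_synth_spec(baseline_wander_freq_hz = 0.7),
               "baseline_wander_freq_hz")
})

test_that("cohorts are labeled, deterministic, and reject bad ranges", {
  empty <- synthesize_cohort(0, 0)
  expect_length(empty$records, 0)
  small1 <- synthesize_cohort(2, 2, seed = 1)
  small2 <- synthesize_cohort(2, 2, seed = 1)
  expect_identical(lapply(small1$records, `[[`, "samples"),
                   lapply(small2$records, `[[`, "samples"))
  expect_identical(small1$labels,
                   factor(rep(c("organized", "disorganized"), each = 2),
                          levels = c("organized", "disorganized")))
  expect_true(all(small1$organization[1:2] >= 0.85 &
                  small1$organization[1:2] <= 0.9))
  expect_true(all(small1$organization[3:4] >= 0.3 &
                  small1$organization[3:4] <= 0.35))
  expect_error(synthesize_cohort(2, 2, org_high = 0.5, org_low = 0.45),
               "overlap")
})

test_that("pipeline entropy rises monotonically as organization falls", {
  orgs <- c(1, 0.75, 0.5, 0.25, 0)
  mean_we <- vapply(orgs, function(o) {
    mean(vapply(1:20, function(s) {
      rec <- synthesize_ecg(ecg_synth_spec(
        aa = aa_synth_spec(organization = o, seed = 400 + s),
        seed = 600 + s))
      suppressMessages(we_score(rec))
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_we) >= -1e-9))
  # cohort-level direction: disorganized class scores higher
  ex <- cohort_experiment(seed = 7)
  sc <- ex$scores["bior4.4", ]
  expect_gt(mean(sc[ex$labels]), mean(sc[!ex$labels]))
})
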