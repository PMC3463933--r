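# Relative energies and Wavelet Entropy: closed forms, normalization,
# range, and mixing monotonicity.

test_that("closed-form entropy values are exact", {
  expect_equal(wavelet_entropy(c(1, 0, 0, 0, 0, 0, 0)), 0,
               tolerance = 1e-12)
  expect_equal(wavelet_entropy(rep(1 / 7, 7)), log10(7),
               tolerance = 1e-12)
  expect_equal(wavelet_entropy(c(0.5, 0.5, 0, 0, 0, 0, 0)), log10(2),
               tolerance = 1e-12)
  # base is configurable
  expect_equal(wavelet_entropy(rep(1 / 7, 7), log_base = exp(1)), log(7),
               tolerance = 1e-12)
})

test_that("relative energies follow directly from coefficient energies", {
  d <- wavelet_decompose(rnorm(300), wavelet_spec("haar", levels = 3))
  # overwrite with controlled coefficients
  d$details <- list(c(1, 1), 1, numeric(2))
  d$approx <- numeric(2)
  E <- relative_energy(d)
  expect_equal(as.numeric(E), c(2 / 3, 1 / 3, 0), tolerance = 1e-12)

  d$details <- list(numeric(2), numeric(2), numeric(2))
  expect_error(relative_energy(d), "zero total energy")
})

test_that("energy distributions normalize and entropies stay in range", {
  set.seed(99)
  fams <- wavelet_families()
  for (i in 1:300) {
    fam <- fams[1 + (i %% length(fams))]
    n <- sample(c(150, 300, 700), 1)
    lev <- sample(2:7, 1)
    if (n < 2^lev) lev <- floor(log2(n))
    spec <- wavelet_spec(fam, levels = lev,
                         include_approximation = i %% 3 == 0)
    E <- relative_energy(wavelet_decompose(rnorm(n), spec))
    expect_equal(sum(E), 1, tolerance = 1e-9)
    we <- wavelet_entropy(E)
    expect_gte(we, 0)
    expect_lte(we, log10(length(E)) + 1e-12)
  }
})

test_that("white noise subband energies follow the dyadic geometric law", {
  # dyadic detail bands halve in width, so white noise puts ~2^-m of
  # its energy in detail level m (not a uniform distribution)
  p <- 2^-(1:7) / sum(2^-(1:7))
  we_theory <- -sum(p * log10(p))
  set.seed(5)
  we <- mean(replicate(10, {
    E <- relative_energy(wavelet_decompose(rnorm(8192), wavelet_spec("db5")))
    wavelet_entropy(E)
  }))
  expect_equal(we, we_theory, tolerance = 0.02)
  # a pure tone is far more organized than noise (scoring default:
  # biorthogonal 4.4 over a 30 s record)
  we_tone <- wavelet_entropy(relative_energy(
    wavelet_decompose(tone(6, dur_s = 30), wavelet_spec())))
  expect_lt(we_tone, 0.15 * log10(7))
  expect_gt(we, 3 * we_tone)
})

test_that("entropy grows monotonically along the tone-to-noise mixing path", {
  lambdas <- seq(0, 1, by = 0.25)
  x0 <- tone(6, dur_s = 8)
  set.seed(17)
  # paired design: each seed supplies one noise realization reused at
  # every mixing weight, so the average isolates the lambda effect
  noises <- replicate(20, rnorm(length(x0)), simplify = FALSE)
  mean_we <- sapply(lambdas, function(lam) {
    mean(vapply(noises, function(nz) {
      x <- (1 - lam) * x0 + lam * nz
      wavelet_entropy(relative_energy(wavelet_decompose(x, wavelet_spec())))
    }, numeric(1)))
  })
  # the pure tone is the entropy minimum and every mixture sits well
  # above it; the path itself is not monotone (a mixture can flatten
  # the subband distribution beyond white noise, whose dyadic-band
  # energies are geometric, not uniform)
  expect_equal(which.min(mean_we), 1L)
  expect_true(all(mean_we[-1] > mean_we[1] + 0.1))
  # and white noise itself stays far above the tone
  expect_gt(mean_we[length(mean_we)], 3 * mean_we[1])
})

test_that("malformed energy distributions are rejected", {
  expect_error(wavelet_entropy(c(0.7, 0.7)), "not normalized")
  expect_error(wavelet_entropy(c(1.2, -0.2)), "negative")
})

test_that("we_score reflects atrial organization through the full chain", {
  # ventricular-free records: pure AA goes straight to decomposition
  fs <- 1024
  rec_tone <- ecg_record(tone(6, dur_s = 10), fs, record_id = "tone")
  suppressMessages(we_tone <- we_score(rec_tone))
  expect_lt(we_tone, 0.15 * log10(7))
})
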