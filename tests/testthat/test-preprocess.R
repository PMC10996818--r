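# Channel QC ------------------------------------------------------------------

test_that("flat-spectrum channels are flagged as white noise", {
  raw <- make_white_noise_raw(T = 4096, seed = 11)
  qc <- qc_channels(raw)
  expect_false(qc$usable[1])
  expect_identical(qc$reason[1], "white_noise")
  expect_lt(qc$qcod[1], 0.1)
})

test_that("a channel dominated by a slow oscillation keeps a dispersed spectrum", {
  T <- 4096; fs <- 7.8
  tt <- seq_len(T) / fs
  x <- sin(2 * pi * 0.1 * tt) + 0.05 * neurosync:::.with_seed(2, rnorm(T))
  qcod <- spectral_qcod(x, fs)
  expect_gte(qcod, 0.1)
  # through the full QC path: embed as an intensity modulation
  hb <- matrix(1e-4 * x, 1)
  raw <- simulate_raw_intensity(hb, -0.3 * hb, sampling_rate = fs)
  qc <- qc_channels(raw)
  expect_true(qc$usable[1])
  expect_identical(qc$reason[1], "ok")
})

test_that("the saturation rule is 'more than 2 seconds', boundary exact", {
  fs <- 8; T <- 4096  # at 8 Hz a 2.0 s run is exactly 16 samples
  tt <- seq_len(T) / fs
  hb <- matrix(1e-4 * sin(2 * pi * 0.1 * tt), 1)
  n2s <- 2 * fs
  raw_ok <- simulate_raw_intensity(hb, -0.3 * hb, sampling_rate = fs,
    artifacts = list(saturation = data.frame(channel = 1, onset_s = 10,
                                             duration_s = n2s / fs)))
  raw_bad <- simulate_raw_intensity(hb, -0.3 * hb, sampling_rate = fs,
    artifacts = list(saturation = data.frame(channel = 1, onset_s = 10,
                                             duration_s = (n2s + 1) / fs)))
  expect_true(qc_channels(raw_ok)$usable[1])
  qc <- qc_channels(raw_bad)
  expect_false(qc$usable[1])
  expect_identical(qc$reason[1], "saturation")
})

test_that("QC never modifies the data it inspects", {
  raw <- make_white_noise_raw(T = 1024, seed = 3)
  before <- raw$intensity
  qc_channels(raw)
  expect_identical(raw$intensity, before)
})

# Trim / concatenate -----------------------------------------------------------

test_that("segment lengths add and segments keep event order", {
  fs <- 10
  rec <- matrix(0, 2, 1000)
  rec[, 101:200] <- 7   # event 1: 100 samples of constant 7
  rec[, 501:650] <- 9   # event 2: 150 samples of constant 9
  ev <- data.frame(onset_s = c(10, 50), duration_s = c(10, 15),
                   condition = "political")
  out <- trim_concatenate(rec, ev, "political", fs)
  expect_identical(dim(out), c(2L, 250L))
  expect_true(all(out[, 1:100] == 7) && all(out[, 101:250] == 9))
})

test_that("missing conditions and out-of-bounds events are rejected", {
  rec <- matrix(rnorm(200), 1)
  ev <- data.frame(onset_s = 0, duration_s = 5, condition = "neutral")
  expect_error(trim_concatenate(rec, ev, "political", 10), "no events")
  ev2 <- data.frame(onset_s = 19, duration_s = 5, condition = "neutral")
  expect_error(trim_concatenate(rec, ev2, "neutral", 10), "outside")
})

# Bandpass ---------------------------------------------------------------------

test_that("DC is removed, passband preserved, stopband attenuated", {
  fs <- 7.8; T <- 4096
  tt <- seq_len(T) / fs
  # DC
  out <- bandpass(rep(5, T), sampling_rate = fs)
  expect_lt(abs(mean(out)) / 5, 1e-6)
  # 0.1 Hz is mid-band: amplitude gain within 5%
  mid <- 500:3500
  x <- sin(2 * pi * 0.1 * tt)
  g <- diff(range(bandpass(x, sampling_rate = fs)[mid])) / diff(range(x[mid]))
  expect_gt(g, 0.95); expect_lt(g, 1.05)
  # 2 Hz is deep in the stopband: >= 90% attenuation
  x2 <- sin(2 * pi * 2 * tt)
  g2 <- diff(range(bandpass(x2, sampling_rate = fs)[mid])) / diff(range(x2[mid]))
  expect_lt(g2, 0.1)
})

test_that("bands outside the Nyquist limits are rejected", {
  expect_error(bandpass(rnorm(100), low = 0.5, high = 0.1, sampling_rate = 7.8),
               "invalid band")
  expect_error(bandpass(rnorm(100), low = 0.005, high = 4, sampling_rate = 7.8),
               "invalid band")
})

# PCA motion correction --------------------------------------------------------

test_that("variance_fraction = 0 is the identity", {
  X <- matrix(rnorm(5 * 300), 5)
  expect_identical(pca_motion_correct(X, 0), X)
})

test_that("a shared spike artifact is strongly suppressed", {
  neurosync:::.with_seed(13, {
    X <- t(replicate(6, as.numeric(stats::filter(rnorm(600), rep(1, 8) / 8,
                                                 sides = 1))))
    X[is.na(X)] <- 0
  })
  spike <- numeric(600); spike[300:310] <- 10
  Xa <- X + matrix(rep(spike, each = 6), 6)
  corrected <- pca_motion_correct(Xa, 0.8)
  peak_before <- max(abs(Xa[, 300:310]))
  peak_after <- max(abs(corrected[, 300:310]))
  expect_lt(peak_after, 0.5 * peak_before)
})

test_that("removing more components never increases residual variance", {
  X <- matrix(rnorm(6 * 200), 6)
  res_var <- function(v) sum(pca_motion_correct(X, v)^2)
  vals <- vapply(c(0, 0.3, 0.6, 0.9, 0.999), res_var, numeric(1))
  expect_true(all(diff(vals) <= 1e-8))
})

test_that("single-channel input is a warned no-op", {
  X <- matrix(rnorm(100), 1)
  expect_warning(out <- pca_motion_correct(X, 0.8), "no-op")
  expect_identical(out, X)
})

# MBLL -------------------------------------------------------------------------

test_that("baseline intensity maps to zero concentration change", {
  hb0 <- matrix(0, 2, 40)
  raw <- simulate_raw_intensity(hb0, hb0)
  conc <- mbll(raw)
  expect_lt(max(abs(conc$hbo)), 1e-12)
  expect_lt(max(abs(conc$hbr)), 1e-12)
})

test_that("forward model then inversion round-trips concentrations", {
  neurosync:::.with_seed(17, {
    hbo <- matrix(rnorm(3 * 200, sd = 5e-4), 3)
    hbr <- matrix(rnorm(3 * 200, sd = 3e-4), 3)
  })
  hbo <- hbo - rowMeans(hbo)  # concentrations relative to baseline
  hbr <- hbr - rowMeans(hbr)
  raw <- simulate_raw_intensity(hbo, hbr)
  conc <- mbll(raw)
  expect_lt(max(abs(conc$hbo - hbo)), 1e-9)
  expect_lt(max(abs(conc$hbr - hbr)), 1e-9)
})

test_that("doubling the source-detector distance halves recovered concentrations", {
  neurosync:::.with_seed(18, hb <- matrix(rnorm(100, sd = 5e-4), 1))
  hb <- hb - rowMeans(hb)
  raw <- simulate_raw_intensity(hb, -0.5 * hb, distance = 3)
  c1 <- mbll(raw, distance = 3)
  c2 <- mbll(raw, distance = 6)
  expect_equal(c2$hbo, c1$hbo / 2, tolerance = 1e-12)
  expect_equal(c2$hbr, c1$hbr / 2, tolerance = 1e-12)
})

# Total haemoglobin ------------------------------------------------------------

test_that("total signal is an exact per-channel z-score, affine invariant", {
  neurosync:::.with_seed(19, {
    hbo <- matrix(rnorm(3 * 500), 3)
    hbr <- matrix(rnorm(3 * 500), 3)
  })
  tot <- total_hb_signal(hbo, hbr)$total
  expect_lt(max(abs(rowMeans(tot))), 1e-10)
  expect_lt(max(abs(sqrt(rowMeans(tot^2)) - 1)), 1e-10)
  # affine rescaling of the difference leaves the z-score unchanged
  tot2 <- total_hb_signal(3 * hbo + 2, 3 * hbr + 2)$total
  expect_equal(tot2, tot, tolerance = 1e-10)
})

test_that("hbo = hbr triggers degenerate-channel handling", {
  x <- matrix(rnorm(200), 2)
  expect_warning(expect_error(total_hb_signal(x, x), "no usable"),
                 "degenerate")
})

# Full chain -------------------------------------------------------------------

test_that("the preprocessing chain is deterministic and records stage order", {
  fs <- 7.8; T <- 2048
  neurosync:::.with_seed(23, {
    spec <- shared_response_spec(2, T, shared_weights = 1, noise_sd = 0.2,
                                 n_channels = 4, seed = 77)
    sig <- simulate_shared_response(spec)$data[[1]]
  })
  hbo <- 5e-4 * sig; hbr <- -2e-4 * sig
  raw <- simulate_raw_intensity(hbo, hbr, sampling_rate = fs)
  h1 <- preprocess_subject(raw)
  h2 <- preprocess_subject(raw)
  expect_identical(h1$total, h2$total)
  expect_identical(h1$provenance,
                   c("qc_channels", "bandpass(0.005-0.5 Hz)",
                     "pca_motion_correct(0.8)", "mbll",
                     "total_hb_signal(z-score)"))
})
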