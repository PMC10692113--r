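# Stimulus representations: Greenwood band edges, band-envelope
# spectrogram, envelope derivative, phonetic features, visual motion.

test_that("greenwood_band_edges matches the closed-form cochlear-map inversion", {
  edges <- greenwood_band_edges(250, 8000, 8)
  expect_length(edges, 9)
  expect_equal(edges[1], 250)
  expect_equal(edges[9], 8000)
  expect_true(all(diff(edges) > 0))

  # independent oracle: invert F(x) = A(10^(a x) - k) by hand and space x
  # uniformly between the endpoint positions
  A <- 165.4; a <- 2.1; k <- 0.88
  x <- seq(log10(250 / A + k) / a, log10(8000 / A + k) / a, length.out = 9)
  expect_equal(edges, A * (10^(a * x) - k), tolerance = 1e-10)

  expect_equal(greenwood_band_edges(250, 8000, 1), c(250, 8000))
  expect_error(greenwood_band_edges(8000, 250, 8), "fmin")
  expect_error(greenwood_band_edges(-10, 250, 4), "fmin")
})

test_that("greenwood_band_edges is increasing and bracketed for random ranges", {
  set.seed(11)
  for (i in 1:25) {
    fmin <- runif(1, 20, 1000)
    fmax <- fmin * runif(1, 1.5, 40)
    nb <- sample(1:12, 1)
    e <- greenwood_band_edges(fmin, fmax, nb)
    expect_length(e, nb + 1)
    expect_true(all(diff(e) > 0))
    expect_equal(e[c(1, nb + 1)], c(fmin, fmax))
  }
})

test_that("acoustic_spectrogram localises energy and tracks the envelope", {
  fs_audio <- 20000
  edges <- greenwood_band_edges(250, 8000, 8)
  t <- seq(0, 1, length.out = fs_audio)
  tone <- sin(2 * pi * 1000 * t)
  S <- acoustic_spectrogram(tone, fs_audio, edges, 50)
  expect_equal(dim(S), c(50, 8))
  expect_true(all(S >= 0))
  band_of_1k <- findInterval(1000, edges)
  expect_equal(which.max(colMeans(S)), band_of_1k)

  expect_true(all(acoustic_spectrogram(numeric(fs_audio), fs_audio,
                                       edges, 50) == 0))

  # broadband noise with a slow amplitude modulation: the summed band
  # envelopes must track a directly computed full-band envelope
  set.seed(2)
  tt <- seq(0, 2, length.out = 2 * fs_audio)
  am <- 1 + 0.8 * sin(2 * pi * 3 * tt)
  noise <- rnorm(2 * fs_audio) * am
  S2 <- acoustic_spectrogram(noise, fs_audio, edges, 50)
  # oracle: analytic-signal envelope of the band-limited waveform,
  # smoothed to the analysis bandwidth and decimated
  bf <- signal::butter(2, c(250, 8000) / (fs_audio / 2), type = "pass")
  wide <- signal::filtfilt(bf, noise)
  env_direct <- rhymetrf:::analytic_envelope(wide)
  lpf <- signal::butter(4, 20 / (fs_audio / 2), type = "low")
  env_direct <- signal::filtfilt(lpf, env_direct)
  idx <- round(seq(1, length(env_direct), length.out = nrow(S2)))
  r <- cor(rowSums(S2)[5:95], env_direct[idx][5:95])
  expect_gt(r, 0.95)

  expect_error(acoustic_spectrogram(tone, 12000, edges, 50), "Nyquist")
})

test_that("envelope_and_derivative sums bands and half-wave rectifies", {
  S <- matrix(runif(300), 100, 3)
  ed <- envelope_and_derivative(S)
  expect_equal(ed$env, rowSums(S))
  expect_true(all(ed$D >= 0))
  expect_equal(ed$D[1], 0)
  expect_true(all(ed$D[c(FALSE, diff(ed$env) <= 0)] == 0))

  const <- matrix(1, 50, 4)
  expect_true(all(envelope_and_derivative(const)$D == 0))
  rising <- matrix(seq(0, 9.8, by = 0.2), ncol = 1)
  expect_equal(envelope_and_derivative(rising)$D[-1],
               rep(0.2, 49), tolerance = 1e-12)
  falling <- matrix(seq(10, 0.2, by = -0.2), ncol = 1)
  expect_true(all(envelope_and_derivative(falling)$D == 0))
  expect_error(envelope_and_derivative(matrix(numeric(0), 0, 3)), "empty")
})

test_that("phoneme_to_features reproduces published articulatory vectors", {
  inv <- default_feature_inventory()
  on <- function(v) names(v)[v == 1]
  expect_setequal(on(phoneme_to_features("b", inv)),
                  c("voiced consonant", "plosive", "labial", "anterior"))
  expect_setequal(on(phoneme_to_features("s", inv)),
                  c("unvoiced consonant", "fricative", "strident",
                    "coronal", "anterior"))
  expect_setequal(on(phoneme_to_features("iy", inv)),
                  c("front", "high"))
  expect_error(phoneme_to_features("qq", inv), "qq")

  # purity: identical label -> identical vector across calls
  expect_identical(phoneme_to_features("ng", inv),
                   phoneme_to_features("ng", inv))

  # inventory invariants
  expect_true(all(rowSums(inv) >= 1))
  expect_true(all(inv[, "voiced consonant"] + inv[, "unvoiced consonant"] <= 1))
  expect_identical(colnames(inv), phonetic_feature_names)
})

test_that("phonetic_feature_matrix paints unit pulses at the analysis rate", {
  inv <- default_feature_inventory()
  al <- data.frame(label = "b", onset = 0, offset = 0.1)
  F1 <- phonetic_feature_matrix(al, inv, 50, 1)
  expect_equal(dim(F1), c(50, 14))
  expect_equal(sum(F1[, "plosive"]), 5)       # 0.1 s x 50 Hz
  expect_true(all(F1[1:5, "labial"] == 1))
  expect_true(all(F1[6:50, ] == 0))

  F0 <- phonetic_feature_matrix(al[0, ], inv, 50, 1)
  expect_equal(dim(F0), c(50, 14))
  expect_true(all(F0 == 0))

  # overlap resolves by OR: b and m share labial+anterior+voiced
  al2 <- data.frame(label = c("b", "m"), onset = c(0, 0.06),
                    offset = c(0.1, 0.2))
  expect_error(phonetic_feature_matrix(al2, inv, 50, 1),
               "non-overlapping")
  F2a <- phonetic_feature_matrix(data.frame(label = "b", onset = 0,
                                            offset = 0.1), inv, 50, 1)
  F2b <- phonetic_feature_matrix(data.frame(label = "m", onset = 0.06,
                                            offset = 0.2), inv, 50, 1)
  F2 <- pmax(F2a, F2b)
  expect_true(all(F2 %in% 0:1))
  expect_true(all(F2[4:5, "labial"] == 1))

  # zero-duration-after-rounding phonemes still occupy one sample
  F3 <- phonetic_feature_matrix(data.frame(label = "t", onset = 0.5,
                                           offset = 0.504), inv, 50, 1)
  expect_equal(sum(F3[, "plosive"]), 1)

  expect_error(phonetic_feature_matrix(data.frame(label = "b", onset = 0,
                                                  offset = 2), inv, 50, 1),
               "beyond")
})

test_that("visual_motion_regressor tracks frame-to-frame luminance change", {
  expect_true(all(visual_motion_regressor(rep(3, 100), 25, 50, 4) == 0))
  v <- visual_motion_regressor(rep(c(0, 1), 50), 25, 50, 4)
  expect_length(v, 200)
  expect_true(all(v[10:190] > 0))
  expect_error(visual_motion_regressor(1, 25, 50, 4), "2 frames")
})
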