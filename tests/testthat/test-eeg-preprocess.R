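# EEG conditioning chain: filters, resampling, bad channels, referencing,
# trial averaging, ground truth, ERP SNR.

test_that("zero_phase_bandpass matches the analytic Butterworth response", {
  fs <- 100
  t <- seq(0, 10, by = 1 / fs)

  # 2 Hz sine through a 1-4 Hz band: amplitude kept, zero delay
  x <- sin(2 * pi * 2 * t)
  y <- zero_phase_bandpass(x, 1, 4, order = 2, fs = fs)
  mid <- 200:800
  amp <- (max(y[mid]) - min(y[mid])) / 2
  expect_equal(amp, 1, tolerance = 0.1)
  cc <- stats::ccf(y[mid], x[mid], lag.max = 20, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)

  # 20 Hz sine through an 8 Hz low-pass: attenuation |H|^2 (two passes).
  # High sampling rate keeps the bilinear-transform frequency warp of the
  # digital design negligible, so the analog magnitude formula is the oracle.
  fs2 <- 1000
  t2 <- seq(0, 4, by = 1 / fs2)
  x2 <- sin(2 * pi * 20 * t2)
  y2 <- zero_phase_bandpass(x2, high = 8, order = 2, fs = fs2)
  H2 <- 1 / (1 + (20 / 8)^4)              # order-2 magnitude, squared freq ratio
  mid2 <- 1000:3000
  amp2 <- (max(y2[mid2]) - min(y2[mid2])) / 2
  expect_equal(amp2, H2, tolerance = 0.1)

  expect_true(all(zero_phase_bandpass(numeric(100), 1, 4, fs = fs) == 0))
  expect_error(zero_phase_bandpass(x, 0, 4, fs = fs), "Nyquist")
  expect_error(zero_phase_bandpass(x, 1, 60, fs = fs), "Nyquist")
})

test_that("resample_signal preserves band-limited content and length contract", {
  x <- rep(2.5, 10000)
  y <- resample_signal(x, 1000, 50)
  expect_length(y, 500)
  expect_equal(y[10:490], rep(2.5, 481), tolerance = 1e-6)

  t <- seq(0, 10 - 1 / 1000, by = 1 / 1000)
  s <- sin(2 * pi * 5 * t)
  y2 <- resample_signal(s, 1000, 50)
  ideal <- sin(2 * pi * 5 * (seq_along(y2) - 1) / 50)
  expect_gt(cor(y2[20:480], ideal[20:480]), 0.999)

  expect_error(resample_signal(s, 50, 1000), "upsampling")
})

test_that("bad channels are flagged by planted outliers and rebuilt from neighbours", {
  set.seed(5)
  layout <- rhymetrf:::channel_layout(20)
  montage <- rhymetrf:::synthetic_montage(layout)
  labels <- montage$label
  n <- 2000
  # smooth spatial field: common source with smooth loadings + small noise
  src <- as.numeric(signal::filtfilt(signal::butter(2, 0.2), rnorm(n)))
  load <- 1 + 0.3 * sin(seq_len(20))
  data <- outer(load, src) + 0.2 * matrix(rnorm(20 * n), 20)
  clean <- eeg_recording(data, fs = 50, channel_labels = labels,
                         mastoid_labels = layout$mastoid,
                         facial_labels = layout$facial, montage = montage)
  res <- interpolate_bad_channels(clean)
  expect_length(res$flagged, 0)
  expect_equal(res$eeg$data, clean$data)

  # plant a heavy-tailed outlier channel
  bad <- clean
  orig <- bad$data[7, ]
  bad$data[7, ] <- rt(n, df = 1.5)
  res2 <- interpolate_bad_channels(bad)
  expect_true(labels[7] %in% res2$flagged)
  expect_gt(cor(res2$eeg$data[7, ], orig), 0.8)

  # a threshold that flags most of the montage -> abort with diagnostic
  expect_error(interpolate_bad_channels(clean, z_threshold = 0.05), "half")
})

test_that("channel bookkeeping: 64 -> drop 4 facial -> reref -> 58", {
  layout <- rhymetrf:::channel_layout(64)
  eeg <- eeg_recording(matrix(rnorm(64 * 100), 64),
                       fs = 50,
                       channel_labels = c(layout$scalp, layout$mastoid,
                                          layout$facial),
                       mastoid_labels = layout$mastoid,
                       facial_labels = layout$facial)
  x <- drop_facial_channels(eeg)
  expect_equal(nrow(x$data), 60)
  x <- rereference_to_mastoids(x)
  expect_equal(nrow(x$data), 58)
  expect_false(any(c("M1", "M2") %in% x$channel_labels))

  # zero mastoids: re-referencing only removes channels
  z <- eeg_recording(rbind(matrix(rnorm(300), 3), 0, 0), fs = 50,
                     channel_labels = c("E1", "E2", "E3", "M1", "M2"),
                     mastoid_labels = c("M1", "M2"))
  zr <- rereference_to_mastoids(z)
  expect_equal(zr$data, z$data[1:3, ])

  # identical channels -> all zero after mastoid referencing
  same <- eeg_recording(matrix(rep(rnorm(100), each = 4), 4), fs = 50,
                        channel_labels = c("E1", "E2", "M1", "M2"),
                        mastoid_labels = c("M1", "M2"))
  expect_true(all(abs(rereference_to_mastoids(same)$data) < 1e-12))

  expect_error(rereference_to_mastoids(eeg_recording(matrix(0, 2, 5), 50)),
               "mastoid")
})

test_that("filtering and re-referencing commute (linear operations)", {
  set.seed(8)
  eeg <- eeg_recording(matrix(rnorm(6 * 500), 6), fs = 50,
                       channel_labels = c(paste0("E", 1:4), "M1", "M2"),
                       mastoid_labels = c("M1", "M2"))
  a <- rereference_to_mastoids(eeg)
  a$data <- zero_phase_bandpass(a$data, 1, 4, fs = 50)
  b <- eeg
  b$data <- zero_phase_bandpass(b$data, 1, 4, fs = 50)
  b <- rereference_to_mastoids(b)
  expect_equal(a$data, b$data, tolerance = 1e-9)
})

test_that("average_trials averages sample-wise and shrinks noise variance", {
  e1 <- eeg_recording(matrix(rnorm(200), 2), fs = 50)
  expect_equal(average_trials(list(e1))$data, e1$data)

  e2 <- e1; e2$data <- -e1$data
  expect_true(all(average_trials(list(e1, e2))$data == 0))

  set.seed(3)
  n <- 20000
  reps <- lapply(1:5, function(i)
    eeg_recording(matrix(rnorm(n), 1), fs = 50))
  avg <- average_trials(reps)
  expect_equal(avg$n_repetitions, 5)
  expect_equal(stats::var(avg$data[1, ]), 1 / 5, tolerance = 0.2)

  bad <- eeg_recording(matrix(rnorm(100), 2), fs = 50,
                       channel_labels = c("A", "B"))
  expect_error(average_trials(list(e1, bad)), "share")
})

test_that("ground_truth_average equals the brute-force grand mean", {
  set.seed(4)
  cohort <- lapply(1:5, function(i)
    eeg_recording(matrix(rnorm(4 * 300), 4), fs = 50))
  g <- ground_truth_average(cohort, band = NULL)
  brute <- Reduce(`+`, lapply(cohort, function(e) colMeans(e$data))) / 5
  expect_equal(g, brute, tolerance = 1e-12)

  # permutation invariance over participants
  expect_equal(ground_truth_average(rev(cohort), band = NULL), g)

  one <- cohort[1]
  expect_equal(ground_truth_average(one, band = c(1, 4)),
               zero_phase_bandpass(colMeans(one[[1]]$data), 1, 4, fs = 50))
  expect_error(ground_truth_average(list()), "empty")
})

test_that("snr_first_word measures post/pre ERP power", {
  set.seed(6)
  fs <- 50
  noise <- matrix(rnorm(3 * 200), 3)
  same <- eeg_recording(noise, fs = fs)
  expect_equal(snr_first_word(same, onset = 2), 1, tolerance = 0.35)

  # planted deflection of amplitude a on unit-variance noise: ratio ~ 1 + a^2
  a <- 2
  n_ch <- 20
  x <- matrix(rnorm(n_ch * 400), n_ch)
  x[, 101:125] <- x[, 101:125] + a       # 0.5 s deflection after onset at 2 s
  erp <- eeg_recording(x, fs = fs)
  expect_equal(snr_first_word(erp, onset = 2), 1 + a^2, tolerance = 0.25)

  silent <- eeg_recording(cbind(matrix(0, 2, 100), matrix(1, 2, 100)),
                          fs = fs)
  expect_error(snr_first_word(silent, onset = 2), "zero pre")
})

test_that("the preprocessing chain is deterministic", {
  sim <- function() simulate_longitudinal_cohort(do.call(
    sim_config, c(tiny_sim_block(n = 1, sessions = "4mo", gains = 0,
                                 trials = 1, dur = 4), seed = 12)))
  t1 <- sim()$data$participants[[1]]$sessions[[1]]$trials[[1]]
  t2 <- sim()$data$participants[[1]]$sessions[[1]]$trials[[1]]
  p1 <- preprocess_recording(t1$repetitions[[1]], fs_out = 25)
  p2 <- preprocess_recording(t2$repetitions[[1]], fs_out = 25)
  expect_identical(p1$eeg$data, p2$eeg$data)
})
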