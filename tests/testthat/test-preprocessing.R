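make_rec <- function(x, fs = 250, label = "resting") {
  if (is.vector(x)) x <- matrix(x, 1, dimnames = list("Fz", NULL))
  raw_recording(x, fs,
                data.frame(start_s = 0, end_s = ncol(x) / fs,
                           activity = label))
}

test_that("the 60 Hz band-stop attenuates a pure mains sinusoid by >= 20 dB", {
  fs <- 250; t <- seq_len(10 * fs) / fs
  rec <- make_rec(sin(2 * pi * 60 * t), fs)
  out <- apply_filter(rec, filter_spec("band_stop", 57, 63))
  expect_lt(sd(out$samples[1, ]) / sd(rec$samples[1, ]), 0.1)
})

test_that("filtering is linear and passes the band interior", {
  fs <- 250; t <- seq_len(10 * fs) / fs
  zero <- make_rec(rep(0, 10 * fs), fs)
  expect_equal(apply_filter(zero, filter_spec("band_pass", 0.5, 44))$samples,
               zero$samples)
  rec10 <- make_rec(sin(2 * pi * 10 * t), fs)
  out <- apply_filter(rec10, filter_spec("band_pass", 0.5, 44))
  expect_equal(sd(out$samples[1, ]) / sd(rec10$samples[1, ]), 1,
               tolerance = 0.05)
})

test_that("zero-phase filtering leaves the cross-correlation peak at lag 0", {
  fs <- 250; t <- seq_len(10 * fs) / fs
  x <- sin(2 * pi * 10 * t)
  out <- apply_filter(make_rec(x, fs),
                      filter_spec("band_pass", 0.5, 44))$samples[1, ]
  cc <- stats::ccf(out, x, lag.max = 10, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
})

test_that("band edges at or above Nyquist are rejected", {
  rec <- make_rec(rnorm(1000), 250)
  expect_error(apply_filter(rec, filter_spec("band_pass", 0.5, 125)),
               "Nyquist")
})

test_that("ICA removes a blink source shared with the EOG reference", {
  fs <- 250; n <- 60 * fs
  withr::with_seed(42, {
    blink <- numeric(n)
    starts <- sort(sample(seq_len(n - fs), 60))
    bump <- 300 * 0.5 * (1 - cos(2 * pi * seq_len(100) / 101))
    for (s in starts) blink[s:(s + 99)] <- blink[s:(s + 99)] + bump
    base <- matrix(rnorm(6 * n, sd = 30), 6,
                   dimnames = list(c("Fz", "C1", "C2", "T7", "T8", "Oz"),
                                   NULL))
    base["Fz", ] <- base["Fz", ] + blink
    x <- rbind(base, EOG = 2 * blink + rnorm(n, sd = 5))
  })
  rec <- make_rec(x, fs)
  out <- remove_artifact_components(rec, "EOG", 0.7)
  expect_gt(abs(cor(rec$samples["Fz", ], blink)), 0.8)
  expect_lt(abs(cor(out$samples["Fz", ], blink)), 0.2)
})

test_that("ICA with no reference channels is a warned no-op", {
  rec <- make_rec(matrix(rnorm(4 * 5000), 4,
                         dimnames = list(c("Fz", "C1", "C2", "Oz"), NULL)),
                  250)
  expect_warning(out <- remove_artifact_components(rec, character(0)),
                 "unchanged")
  expect_identical(out$samples, rec$samples)
})

test_that("ICA with threshold 1.0 is an identity round trip", {
  withr::with_seed(1, {
    x <- matrix(rnorm(4 * 5000, sd = 20), 4,
                dimnames = list(c("Fz", "C1", "C2", "Oz"), NULL))
    x <- rbind(x, EOG = rnorm(5000))
  })
  rec <- make_rec(x, 250)
  out <- remove_artifact_components(rec, "EOG", correlation_threshold = 1)
  expect_equal(out$samples, rec$samples, tolerance = 1e-6)
})

test_that("segmentation follows the exact-division and remainder rules", {
  fs <- 50
  rec100 <- make_rec(matrix(0, 1, 100 * fs, dimnames = list("Fz", NULL)),
                     fs)
  ep <- segment_epochs(rec100, 10)
  expect_length(ep$labels, 10)
  expect_true(all(ep$labels == "resting"))

  rec95 <- make_rec(matrix(0, 1, 95 * fs, dimnames = list("Fz", NULL)), fs)
  expect_length(segment_epochs(rec95, 10)$labels, 9)

  x <- matrix(0, 1, 50 * fs, dimnames = list("Fz", NULL))
  rec_mix <- raw_recording(x, fs, data.frame(
    start_s = c(0, 30), end_s = c(30, 50),
    activity = c("reading", "walking")))
  ep <- segment_epochs(rec_mix, 10)
  expect_equal(ep$labels, c("reading", "reading", "reading", "walking",
                            "walking"))
})

test_that("segmenting an unannotated recording warns and returns empty", {
  x <- matrix(0, 1, 1000, dimnames = list("Fz", NULL))
  rec <- raw_recording(x, 100, data.frame(start_s = numeric(0),
                                          end_s = numeric(0),
                                          activity = character(0)))
  expect_warning(ep <- segment_epochs(rec, 10), "no annotations")
  expect_length(ep$labels, 0)
})

test_that("SNR keeps pure in-band epochs and rejects equal-power epochs", {
  fs <- 250; t <- seq_len(10 * fs) / fs
  # brick-wall in-band signal: no out-of-band energy at all
  clean <- generate_recording(clean_config(n = 1))
  ep <- estimate_snr_and_reject(segment_epochs(clean, 10), 25)
  expect_true(all(ep$kept))

  # sinusoid pairs with equal in-band and out-of-band power: SNR 0 dB
  x <- sin(2 * pi * 10 * t) + sin(2 * pi * 50 * t)
  ep2 <- segment_epochs(make_rec(x, fs), 10)
  ep2 <- estimate_snr_and_reject(ep2, 25)
  expect_equal(ep2$snr_db[1], 0, tolerance = 1e-6)
  expect_false(ep2$kept[1])
})

test_that("the rejected-epoch fraction tracks the injected motion fraction", {
  cfg <- noisy_config(n = 10, motion_epoch_fraction = 0.2, seed = 9)
  rec <- generate_recording(cfg)
  ep <- suppressWarnings(preprocess_recording(rec))
  frac <- mean(!ep$kept)
  expect_lt(abs(frac - 0.2), 0.05)
  # and the rejected set matches the generator's ground truth
  expect_setequal(which(!ep$kept), rec$ground_truth$motion_epochs)
})

test_that("preprocessing preserves epoch labels and only rejection drops epochs", {
  rec <- generate_recording(noisy_config(n = 3, seed = 2))
  ep <- preprocess_recording(rec)
  expect_equal(table(ep$labels), table(rec$annotations$activity))
  expect_true(all(ep$kept == (ep$snr_db >= ep$snr_threshold_db)))
})
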