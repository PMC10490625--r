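test_that("the default bands tile 0.5-44 Hz without gaps or overlaps", {
  b <- eeg_bands()
  expect_equal(b$f_low, c(0.5, 4, 8, 13, 30))
  expect_equal(b$f_high, c(4, 8, 13, 30, 44))
  expect_equal(b$f_low[-1], b$f_high[-nrow(b)])
})

test_that("Welch PSD satisfies Parseval for a unit sinusoid", {
  fs <- 250; t <- seq_len(10 * fs) / fs
  x <- sin(2 * pi * 10 * t)
  spec <- welch_psd(x, fs)
  total <- sum(diff(spec$frequencies) *
                 (head(spec$psd[1, ], -1) + tail(spec$psd[1, ], -1)) / 2)
  expect_equal(total, 0.5, tolerance = 0.05)
  bp <- band_powers(spec)
  expect_gt(bp$power[1, "Alpha"] / sum(bp$power[1, ]), 0.95)
})

test_that("Welch PSD of the null signal is identically zero", {
  spec <- welch_psd(rep(0, 2500), 250)
  expect_true(all(spec$psd == 0))
})

test_that("Welch PSD integrates to the variance of white noise", {
  fs <- 250
  sigma2 <- 4
  totals <- withr::with_seed(11, replicate(30, {
    spec <- welch_psd(rnorm(10 * fs, sd = sqrt(sigma2)), fs)
    sum(diff(spec$frequencies) *
          (head(spec$psd[1, ], -1) + tail(spec$psd[1, ], -1)) / 2)
  }))
  expect_equal(mean(totals), sigma2, tolerance = 0.1)
})

test_that("a Welch segment longer than the epoch is a parameter error", {
  expect_error(welch_psd(rep(0, 100), 250, welch_params(2)), "longer")
})

test_that("band powers of a flat unit PSD are proportional to band widths", {
  bp <- band_powers(flat_spectrum(1))
  expect_equal(as.numeric(bp$power[1, ]), c(3.5, 4, 5, 17, 14))
  expect_true(all(band_powers(flat_spectrum(0))$power == 0))
})

test_that("bands outside the frequency grid raise a parameter error", {
  spec <- welch_psd(rnorm(2500), 250)
  bad <- data.frame(name = "X", f_low = 100, f_high = 200)
  expect_error(band_powers(spec, bad), "grid")
})

test_that("relative power reproduces hand-computed fractions", {
  rp_from <- function(powers) {
    bp <- structure(list(region_power = matrix(
      powers, 1, 5, dimnames = list("F", c("Delta", "Theta", "Alpha",
                                           "Beta", "Gamma")))),
      class = "band_power_set")
    relative_power(bp)
  }
  rp <- rp_from(c(2, 1, 4, 2, 1))
  expect_equal(rp["F", "Alpha"], 0.4)
  expect_equal(sum(rp["F", ]), 1)
  expect_equal(as.numeric(rp_from(rep(3, 5))["F", ]), rep(0.2, 5))
  rp1 <- rp_from(c(0, 0, 7, 0, 0))
  expect_equal(as.numeric(rp1["F", ]), c(0, 0, 1, 0, 0))
  expect_true(all(is.na(rp_from(rep(0, 5))["F", ])))
})

test_that("pdBSI matches its analytic bounds and a hand-computed case", {
  expect_identical(pdbsi(rep(2, 10), rep(2, 10)), 0)
  expect_identical(pdbsi(rep(3, 10), rep(0, 10)), 1)
  expect_equal(pdbsi(3, 1), 0.5)
  expect_true(is.na(pdbsi(rep(0, 4), rep(0, 4))))
  # zero-sum bins are skipped, not counted
  expect_equal(pdbsi(c(3, 0), c(1, 0)), 0.5)
})

test_that("pdBSI is monotone in one-sided PSD scaling", {
  withr::with_seed(5, {
    r <- runif(20, 0.5, 2); l <- runif(20, 0.5, 2)
  })
  vals <- vapply(c(1, 1.5, 2, 4, 8, 16), function(lam)
    pdbsi(lam * r, l), numeric(1))
  expect_true(all(diff(vals) >= -1e-12))
  expect_true(all(vals >= 0 & vals <= 1))
})

test_that("spectral ratios match their definitions and flag zero denominators", {
  pw <- c(Delta = 4, Theta = 1, Alpha = 2, Beta = 2, Gamma = 1)
  expect_equal(spectral_ratios(pw)[["DAR"]], 2)
  expect_equal(spectral_ratios(c(Delta = 2, Theta = 4, Alpha = 1, Beta = 1,
                                 Gamma = 0))[["DTR"]], 0.5)
  expect_equal(spectral_ratios(c(Delta = 3, Theta = 1, Alpha = 2, Beta = 2,
                                 Gamma = 0))[["DTABR"]], 1)
  expect_true(is.na(spectral_ratios(c(Delta = 1, Theta = 0, Alpha = 1,
                                      Beta = 1, Gamma = 0))[["DTR"]]))
})

test_that("pdBSI and RP match hand-computed values on a 4-bin toy spectrum", {
  # toy: right = (4, 2, 2, 0), left = (2, 2, 0, 0) on 4 bins
  r <- c(4, 2, 2, 0); l <- c(2, 2, 0, 0)
  # per-bin terms: 2/6, 0/4, 2/2, skip -> mean = (1/3 + 0 + 1) / 3
  expect_equal(pdbsi(r, l), (1 / 3 + 0 + 1) / 3)
})

test_that("the feature table has the documented shape and invariants", {
  rec <- generate_recording(clean_config(n = 4, seed = 3))
  ep <- preprocess_recording(rec)
  ft <- build_feature_table(ep)
  expect_equal(names(ft), c(feature_names(), "label"))
  expect_equal(nrow(ft), 16)
  # per-region RP normalization, exact
  for (reg in c("F", "C", "T", "O", "G")) {
    sums <- rowSums(ft[, paste("RP", c("Delta", "Theta", "Alpha", "Beta",
                                       "Gamma"), reg, sep = "_")])
    expect_true(all(abs(sums - 1) < 1e-9))
  }
  pd_cols <- grep("^pdBSI", names(ft), value = TRUE)
  expect_true(all(ft[, pd_cols] >= 0 & ft[, pd_cols] <= 1))
  ratio_cols <- grep("^(DAR|DTR|DTABR)_", names(ft), value = TRUE)
  expect_true(all(ft[, ratio_cols] >= 0))
})

test_that("symmetric simulation keeps mean pdBSI low", {
  rec <- generate_recording(clean_config(n = 8, seed = 4))
  ft <- build_feature_table(preprocess_recording(rec))
  expect_lte(mean(ft$pdBSI_C), 0.15)
  expect_lte(mean(ft$pdBSI_T), 0.15)
})

test_that("an epoch set with zero kept epochs yields an empty table", {
  rec <- generate_recording(clean_config(n = 1))
  ep <- segment_epochs(rec, 10)
  ep$kept <- rep(FALSE, length(ep$kept))
  ft <- build_feature_table(ep)
  expect_equal(nrow(ft), 0)
})

test_that("feature CSV export round-trips with its provenance sidecar", {
  rec <- generate_recording(clean_config(n = 1))
  ft <- build_feature_table(preprocess_recording(rec))
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(ft, path)
  back <- utils::read.csv(path)
  expect_equal(names(back), names(ft))
  side <- jsonlite::read_json(sub("csv$", "json", path))
  expect_equal(side$welch_params$segment_length_s, 2)
  expect_equal(side$n_rows, nrow(ft))
})
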