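test_that("the wavelet pyramid is invertible and energy-conserving", {
  set.seed(11)
  for (n in c(4096, 5000, 30000)) {     # dyadic and non-dyadic lengths
    x <- rnorm(n)
    p <- dwt_decompose(x, levels = 9)
    xr <- dwt_reconstruct(p)
    expect_lt(max(abs(xr - x)) / max(abs(x)), 1e-8)
    coef_energy <- sum(p$approx^2) +
      sum(vapply(p$details, function(d) sum(d^2), 0))
    expect_lt(abs(coef_energy - sum(x^2)) / sum(x^2), 1e-8)
  }
})

test_that("pyramid structure follows the requested depth", {
  p <- dwt_decompose(rnorm(2^12), levels = 9)
  expect_length(p$details, 9L)
  expect_length(p$approx, 2^12 / 2^9)
  expect_equal(vapply(p$details, length, 0L), 2^12 / 2^(1:9))
  expect_error(dwt_decompose(rnorm(100), levels = 9), "too short")
})

test_that("a constant signal has no detail energy", {
  p <- dwt_decompose(rep(3.7, 2048), levels = 9)
  expect_lt(max(abs(unlist(p$details))), 1e-10)
})

test_that("alpha level selection follows the dyadic band containing 10 Hz", {
  expect_identical(alpha_band_level(500), 5L)
  expect_identical(alpha_band_level(250), 4L)
  expect_identical(alpha_band_level(128), 3L)
  expect_error(alpha_band_level(500, levels = 3), "no dyadic")
  expect_error(alpha_band_level(15), "no dyadic")
})

test_that("alpha extraction keeps in-band energy and rejects out-of-band", {
  rec <- sine_recording(c(10, 40), fs = 500, seconds = 60)
  out <- extract_alpha(rec)
  expect_equal(out$band, c(7.8125, 15.625))
  expect_identical(ncol(out$data), ncol(rec$data))
  expect_gte(band_power_fraction(out$data[1, ], 500, 7.8125, 15.625), 0.9)
  rms_out <- sqrt(mean(out$data[2, ]^2))
  rms_in <- sqrt(mean(rec$data[2, ]^2))
  expect_lt(rms_out / rms_in, 0.1)
})

test_that("alpha extraction is linear", {
  set.seed(5)
  x <- rnorm(4000)
  y <- rnorm(4000)
  ex <- function(v) extract_alpha(eeg_recording(rbind(v), 500, "Cz"))$data[1, ]
  lhs <- ex(2.5 * x - 1.25 * y)
  rhs <- 2.5 * ex(x) - 1.25 * ex(y)
  expect_lt(max(abs(lhs - rhs)), 1e-9)
})

test_that("universal soft thresholding behaves as specified", {
  p <- dwt_decompose(rnorm(2048), levels = 5)
  expect_identical(threshold_denoise(p, "none"), p)
  zero <- dwt_decompose(rep(0, 2048), levels = 5)
  thr <- threshold_denoise(zero)
  expect_true(all(vapply(thr$details, function(d) all(d == 0), TRUE)))
  # denoising a noisy sine must reduce reconstruction MSE vs the clean sine
  set.seed(21)
  t <- (0:8191) / 500
  clean <- sin(2 * pi * 10 * t)
  noisy <- clean + rnorm(length(t), sd = 0.8)
  pn <- dwt_decompose(noisy, levels = 9)
  mse_raw <- mean((dwt_reconstruct(pn) - clean)^2)
  mse_den <- mean((dwt_reconstruct(threshold_denoise(pn)) - clean)^2)
  expect_lt(mse_den, mse_raw)
})

test_that("segmentation floors to whole segments and errors when short", {
  rec <- eeg_recording(matrix(rnorm(2 * 36000), 2, 36000), fs = 10,
                       labels = c("C3", "C4"))    # 60 min at 10 Hz
  segs <- segment_recording(rec, seconds = 600)
  expect_length(segs$segments, 6L)
  expect_true(all(vapply(segs$segments,
                         function(s) ncol(s$data) == 6000L, TRUE)))
  # contiguity: concatenated segments reproduce the kept samples
  expect_equal(do.call(cbind, lapply(segs$segments, function(s) s$data)),
               rec$data, ignore_attr = TRUE)
  rec25 <- eeg_recording(matrix(rnorm(15000), 1, 15000), fs = 10, "Cz")
  expect_length(segment_recording(rec25, 600)$segments, 2L)
  expect_error(segment_recording(rec25, 2000), "shorter")
})

test_that("alpha ratio separates in-band from out-of-band signals", {
  rec <- sine_recording(c(10, 40), fs = 500, seconds = 60,
                        labels = c("Pz", "Cz"))
  r <- alpha_ratio(rec)
  expect_gt(r$per_channel[["Pz"]], 0.9)
  expect_lt(r$per_channel[["Cz"]], 0.1)
  expect_true(all(r$per_channel >= 0 & r$per_channel <= 1))
})

test_that("per-level energy ratios sum to one", {
  set.seed(9)
  x <- rnorm(5000)
  p <- dwt_decompose(x, levels = 9)
  total <- sum(x^2)
  ratios <- c(vapply(p$details, function(d) sum(d^2), 0),
              sum(p$approx^2)) / total
  expect_equal(sum(ratios), 1, tolerance = 1e-10)
})

test_that("zero-energy input yields ratio 0 with a warning", {
  rec <- eeg_recording(matrix(0, 1, 2048), 500, "Cz")
  expect_warning(r <- alpha_ratio(rec), "zero-energy")
  expect_identical(r$value, 0)
})
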