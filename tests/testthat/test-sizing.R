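test_that("detect_peaks handles degenerate signals", {
  expect_equal(nrow(detect_peaks(rep(0, 1000), 100, 10)), 0L)
  expect_error(detect_peaks(numeric(0), 100, 10), "empty")
  expect_error(detect_peaks(c(1, NA, 3), 100, 10), "finite")
  expect_error(detect_peaks(rep(1, 10), 0, 10), "positive")
})

test_that("detect_peaks finds isolated Gaussian apexes", {
  x <- seq_len(2000)
  one <- 10000 * exp(-((x - 700)^2) / 72)
  pk <- detect_peaks(one, 500, 12)
  expect_equal(pk$scan, 700)
  expect_equal(pk$height, 10000)
  two <- one + 8000 * exp(-((x - 800)^2) / 72)
  pk2 <- detect_peaks(two, 500, 20)
  expect_equal(pk2$scan, c(700, 800))
})

test_that("detect_peaks agrees with a brute-force oracle on noisy signals", {
  set.seed(11)
  for (k in 1:8) {
    y <- pmax(0, stats::rnorm(600, 50, 30)) +
      200 * (stats::runif(600) < 0.02)
    min_sep <- sample(c(3, 8, 15), 1)
    got <- detect_peaks(y, 120, min_sep)
    expect_equal(got$scan, oracle_peaks(y, 120, min_sep))
  }
})

test_that("calibration is exact at all 23 knots and monotone between them", {
  lad <- default_ladder()
  tr <- synth_trace(fragment_record(300), noise_sd = 0, seed = 1)
  pk <- detect_peaks(tr$ladder_signal, 500, 12)
  cal <- calibrate(pk, lad)
  expect_equal(nrow(cal$knots), 23L)
  expect_equal(cal$fun(cal$knots$scan), as.numeric(sort(lad)))
  grid <- seq(min(cal$knots$scan), max(cal$knots$scan), length.out = 5000)
  expect_true(all(diff(cal$fun(grid)) > 0))
  # no extrapolation beyond the knots
  expect_true(is.na(predict_size(cal, min(cal$knots$scan) - 10)))
})

test_that("calibration fails closed with too few ladder peaks", {
  lad <- default_ladder()
  tr <- synth_trace(fragment_record(300), noise_sd = 0, seed = 1)
  pk <- detect_peaks(tr$ladder_signal, 500, 12)
  expect_error(calibrate(pk[1:10, ], lad), class = "isr_calibration_error")
})

test_that("size_and_classify splits major and minor peaks by height", {
  tr <- synth_trace(fragment_record(300), noise_sd = 0, seed = 1)
  cal <- calibrate(detect_peaks(tr$ladder_signal, 500, 12), tr$ladder)
  sc <- function(size) size_to_scan(size)
  peaks <- data.frame(scan = c(sc(289), sc(490)), height = c(12000, 4000))
  pr <- size_and_classify(peaks, cal, 0.10, "ex")
  expect_equal(pr$major_bp, 289L)
  expect_equal(pr$minors_bp, "490")
  # exact height tie: smaller size becomes the major
  tie <- data.frame(scan = c(sc(490), sc(289)), height = c(7000, 7000))
  expect_equal(size_and_classify(tie, cal)$major_bp, 289L)
  # single peak: no minors
  one <- size_and_classify(peaks[1, ], cal)
  expect_equal(one$major_bp, 289L)
  expect_equal(one$minors_bp, "")
  # sub-threshold peak dropped as noise
  weak <- data.frame(scan = c(sc(289), sc(490)), height = c(12000, 500))
  expect_equal(size_and_classify(weak, cal)$minors_bp, "")
  # peak outside the calibrated range dropped with a warning
  outside <- data.frame(scan = c(sc(289), 100), height = c(12000, 9000))
  expect_warning(pr2 <- size_and_classify(outside, cal, isolate_id = "x"),
                 "outside")
  expect_equal(pr2$major_bp, 289L)
})

test_that("interspacer length is the amplicon minus the 121 bp of flanking rDNA", {
  expect_equal(amplicon_to_isr(289), 168L)
  expect_equal(amplicon_to_isr(122), 1L)
  expect_error(amplicon_to_isr(121), "121")
})

test_that("noise-free round trip recovers every fragment size exactly", {
  sizes <- c(50L, 61L, 137L, 289L, 293L, 455L, 546L, 777L, 999L, 1000L)
  for (s in sizes) {
    tr <- synth_trace(fragment_record(s), noise_sd = 0, seed = 1)
    pr <- profile_trace(tr)
    expect_equal(pr$major_bp, s)
    expect_equal(pr$quality, "ok")
  }
})

test_that("peaks outside the ladder range are refused as unsizable", {
  expect_error(synth_trace(fragment_record(1005), noise_sd = 0), "unsizable")
})

test_that("sizing error stays within 1 bp for at least 99% of noisy fragments", {
  set.seed(13)
  sizes <- sample(60:990, 1000, replace = TRUE)
  err <- vapply(seq_along(sizes), function(i) {
    tr <- synth_trace(fragment_record(sizes[i]), noise_sd = 25,
                      seed = 20000 + i)
    abs(profile_trace(tr)$major_bp - sizes[i])
  }, numeric(1))
  expect_gte(mean(err <= 1), 0.99)
})

test_that("peak tables classify without calibration", {
  pt <- data.frame(isolate_id = c("a", "a", "b"),
                   size_bp = c(293, 546, 360), height = c(9000, 3000, 8000))
  pr <- classify_peak_table(pt)
  expect_equal(pr$major_bp, c(293L, 360L))
  expect_equal(pr$minors_bp, c("546", ""))
})
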