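make_rec <- function(signal, fs = 1000, labels = NULL, events = NULL) {
  if (is.null(labels)) labels <- paste0("ch", seq_len(nrow(signal)))
  if (is.null(events)) {
    events <- data.frame(sample = integer(0), attended = logical(0))
  }
  eeg_recording(signal, fs, labels, events)
}

test_that("re-referencing subtracts the mastoid mean and drops the refs", {
  set.seed(10)
  sig <- matrix(rnorm(5 * 200), 5)
  rec <- make_rec(sig, labels = c("a", "b", "c", "M1", "M2"))
  out <- rereference(rec)
  expect_identical(out$labels, c("a", "b", "c"))
  ref <- colMeans(sig[4:5, ])
  for (i in 1:3) expect_equal(out$signal[i, ], sig[i, ] - ref)
  # common-mode rejection: adding a constant to all channels changes nothing
  rec2 <- make_rec(sig + 7.5, labels = rec$labels)
  expect_equal(rereference(rec2)$signal, out$signal)
  # a channel equal to the mastoid mean becomes zero
  sig3 <- rbind(ref, sig[4:5, ])
  rec3 <- make_rec(sig3, labels = c("x", "M1", "M2"))
  expect_equal(max(abs(rereference(rec3)$signal)), 0)
  expect_error(rereference(make_rec(sig[1:3, ])), "not found")
})

test_that("band-pass keeps 10 Hz, rejects 100 Hz, and is zero-phase", {
  fs <- 1000
  t <- seq(0, 10, by = 1 / fs)
  probe <- function(f) {
    rec <- make_rec(matrix(sin(2 * pi * f * t), 1), fs)
    y <- bandpass(rec)$signal[1, ]
    core <- seq(2 * fs, length(t) - 2 * fs)
    stats::sd(y[core]) / stats::sd(sin(2 * pi * f * t)[core])
  }
  expect_equal(probe(10), 1, tolerance = 0.05)
  expect_lt(probe(100), 10^(-20 / 20))  # > 20 dB attenuation
  # zero phase: an in-band Gaussian burst keeps its peak latency
  burst <- exp(-(t - 5)^2 / (2 * 0.05^2)) * sin(2 * pi * 10 * (t - 5))
  rec <- make_rec(matrix(burst, 1), fs)
  y <- bandpass(rec)$signal[1, ]
  expect_lte(abs(which.max(abs(y)) - which.max(abs(burst))), 1L)
  expect_error(bandpass(make_rec(matrix(rnorm(50), 1), fs = 50)), "too low")
})

test_that("decimation keeps every 5th sample and remaps events", {
  set.seed(3)
  sig <- matrix(rnorm(2 * 1000), 2)
  rec <- make_rec(sig, 1000,
                  events = data.frame(sample = c(1L, 501L, 1000L),
                                      attended = c(TRUE, FALSE, TRUE)))
  out <- downsample(rec, 200)
  expect_identical(ncol(out$signal), 200L)
  expect_equal(out$signal, sig[, seq(1, 1000, by = 5)])
  # 0-based: 0 -> 0, 500 -> 100, 999 -> 200 clamped to the last sample (199)
  expect_identical(out$events$sample, c(1L, 101L, 200L))
  expect_identical(out$fs, 200)
  # an event exactly at 0-based sample 1000 maps to 0-based sample 200
  rec_long <- make_rec(matrix(rnorm(1200), 1), 1000,
                       events = data.frame(sample = 1001L, attended = TRUE))
  expect_identical(downsample(rec_long, 200)$events$sample, 201L)
  # an in-band sinusoid survives the filter + decimation chain
  fs <- 1000
  t <- seq(0, 6, by = 1 / fs)
  rec2 <- make_rec(matrix(sin(2 * pi * 10 * t), 1), fs)
  y <- downsample(bandpass(rec2), 200)$signal[1, ]
  core <- seq(400, length(y) - 400)
  expect_equal(stats::sd(y[core]) * sqrt(2), 1, tolerance = 0.05)
  expect_error(downsample(rec, 300), "integer multiple")
})

test_that("epochs are 62x100, baseline-corrected, and edge-safe", {
  ses <- small_session()
  rec <- downsample(bandpass(rereference(as_recording(ses))), 200)
  ep <- extract_epochs(rec)
  expect_identical(dim(ep$data)[1:2], c(62L, 100L))
  expect_identical(dim(ep$data)[3], nrow(ses$events))
  expect_identical(as.character(ep$labels),
                   ifelse(ses$events$attended, "target", "nontarget"))
  # constant channels vanish under baseline correction
  const <- make_rec(matrix(5, 3, 400), 200,
                    events = data.frame(sample = c(50L, 200L),
                                        attended = c(TRUE, FALSE)))
  epc <- extract_epochs(const)
  expect_equal(max(abs(epc$data)), 0)
  # events too close to the edges are skipped and counted
  edgy <- make_rec(matrix(rnorm(400), 1), 200,
                   events = data.frame(sample = c(5L, 100L, 395L),
                                       attended = c(TRUE, TRUE, FALSE)))
  expect_warning(epe <- extract_epochs(edgy), "skipped")
  expect_identical(dim(epe$data)[3], 1L)
  expect_identical(epe$n_skipped, 2L)
})

test_that("the full pipeline recovers template latencies at high SNR", {
  ses <- small_session()  # noise 2 uV, snr_scale 3
  ep <- preprocess_pipeline(as_recording(ses))
  expect_identical(dim(ep$data)[1:2], c(62L, 100L))
  expect_identical(ep$fs, 200)
  # determinism
  ep2 <- preprocess_pipeline(as_recording(ses))
  expect_identical(ep$data, ep2$data)
  # stage-1 target grand average peaks near 90/130/195 ms on the peak channel
  ga <- grand_average(ep, label = "target", stage = 1)
  ch <- which.max(vapply(seq_len(62), function(i) max(abs(ga[i, ])), 0))
  times <- ep$times
  for (expected in c(90, 130, 195)) {
    win <- abs(times - expected) <= 10
    # |waveform| has a local dominance at each component latency
    expect_gt(max(abs(ga[ch, win])), 0.5 * max(abs(ga[ch, ])))
  }
  # P300 at 350 ms in stage-2 targets
  ga2 <- grand_average(ep, label = "target", stage = 2)
  expect_gt(max(ga2[ch, abs(times - 350) <= 15]),
            0.5 * max(abs(ga2[ch, ])))
  # grand average of identical epochs equals the epoch
  one <- subset_epochs(ep, 1L)
  both <- bind_epochs(one, one)
  expect_equal(grand_average(both), ep$data[, , 1], ignore_attr = TRUE)
  expect_error(grand_average(ep, label = "target", stage = 99), "no epochs")
})
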