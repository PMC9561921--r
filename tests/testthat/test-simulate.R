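test_that("default templates carry the stage-specific ERP components", {
  t1 <- default_templates(1)
  lat1 <- vapply(t1$target$components, `[[`, 0, "latency_ms")
  expect_identical(lat1, c(90, 130, 195))
  signs1 <- sign(vapply(t1$target$components, `[[`, 0, "amplitude"))
  expect_identical(signs1, c(1, -1, 1))  # P1, N2, P2 polarities
  expect_length(t1$nontarget$components, 0L)

  t2 <- default_templates(2)
  lat2 <- vapply(t2$target$components, `[[`, 0, "latency_ms")
  expect_identical(lat2, c(50, 90, 180, 350))
  p300 <- t2$target$components[[4]]
  expect_identical(p300$name, "P300")
  expect_gt(p300$amplitude, 0)
  expect_error(default_templates(3), "stage")
})

test_that("template rendering is an exact superposition of components", {
  mont <- default_montage()
  fs <- 200
  tpl <- default_templates(1, mont)$target
  w <- render_template(tpl, fs, 0.5)
  expect_identical(dim(w), c(62L, 100L))
  # single component: peak at its latency, peak value = amplitude * weight
  single <- tpl
  single$components <- tpl$components[1]
  w1 <- render_template(single, fs, 0.5)
  ch <- which.max(tpl$components[[1]]$topography)
  expect_identical(which.max(w1[ch, ]),
                   as.integer(round(90 * fs / 1000)) + 1L)
  expect_equal(max(w1[ch, ]), tpl$components[[1]]$amplitude, tolerance = 1e-3)
  # superposition: rendering all components = sum of individual renders
  parts <- lapply(seq_along(tpl$components), function(i) {
    s <- tpl
    s$components <- tpl$components[i]
    render_template(s, fs, 0.5)
  })
  expect_equal(w, Reduce(`+`, parts), tolerance = 1e-12)
  # empty template renders to zeros
  expect_true(all(render_template(default_templates(1)$nontarget, fs, 0.5)
                  == 0))
  # components must fit inside the window
  late <- tpl
  late$components <- list(erp_component("X", 480, 30, 1,
                                        gaussian_topography(mont)))
  expect_error(render_template(late, fs, 0.5), "window")
})

test_that("1/f noise has the configured spectral exponent and is seeded", {
  cfg <- sim_config(noise_amplitude = 10, spectral_exponent = 1, seed = 5)
  x <- simulate_noise(cfg, 2, 50000)
  expect_equal(dim(x), c(2L, 50000L))
  expect_equal(stats::sd(x[1, ]), 10, tolerance = 0.01)
  expect_identical(x, simulate_noise(cfg, 2, 50000))
  expect_true(all(simulate_noise(sim_config(noise_amplitude = 0), 3, 100)
                  == 0))
  # periodogram log-log slope ~ -alpha
  for (alpha in c(0.8, 1.2)) {
    cfg_a <- sim_config(noise_amplitude = 5, spectral_exponent = alpha,
                        seed = 9)
    y <- simulate_noise(cfg_a, 1, 2^19)[1, ]
    sp <- stats::spec.pgram(stats::ts(y, frequency = cfg_a$fs), plot = FALSE,
                            taper = 0)
    keep <- sp$freq > 0.5 & sp$freq < 100
    fit <- stats::lm(log(sp$spec[keep]) ~ log(sp$freq[keep]))
    expect_equal(unname(stats::coef(fit)[2]), -alpha, tolerance = 0.1)
  }
})

test_that("simulated sessions have the full two-stage marker structure", {
  ses <- small_session()
  n_char <- nrow(ses$truth)
  ev <- ses$events
  # 8 markers per character: 3 stage-1 sub-trials + 5 stage-2 slots
  expect_identical(nrow(ev), 8L * n_char)
  expect_identical(sum(ev$stage == 1), 3L * n_char)
  expect_identical(sum(ev$stage == 2), 5L * n_char)
  expect_true(all(diff(ev$sample) > 0))
  # stage 2: exactly one attended slot per character
  expect_identical(sum(ev$attended[ev$stage == 2]), n_char)
  # stage-1 attended sub-trials = popcount of each character's group code
  expected <- sum(vapply(ses$truth$code,
                         function(cd) sum(code_bits(cd)), integer(1)))
  expect_identical(sum(ev$attended[ev$stage == 1]), expected)
  expect_error(simulate_session("a@", default_cb), "not in charset")
})

test_that("sessions are reproducible and average to the template", {
  cfg <- sim_config(noise_amplitude = 2, snr_scale = 3, seed = 12)
  s1 <- simulate_session("ABC", default_cb, cfg)
  s2 <- simulate_session("ABC", default_cb, cfg)
  expect_identical(s1$signal, s2$signal)
  # grand average of many noisy target insertions converges to the template
  set.seed(31)
  text <- paste(sample(default_cb$charset, 60, replace = TRUE), collapse = "")
  ses <- simulate_session(text, default_cb,
                          sim_config(noise_amplitude = 0.5, snr_scale = 1,
                                     seed = 77))
  tgt2 <- ses$events[ses$events$stage == 2 & ses$events$attended, ]
  tpl <- render_template(ses$templates$stage2$target, ses$fs, 0.5)
  acc <- 0
  for (s in tgt2$sample) {
    acc <- acc + ses$signal[seq_len(62), s:(s + ncol(tpl) - 1L)]
  }
  avg <- acc / nrow(tgt2)
  rel_rms <- sqrt(mean((avg - tpl)^2)) / sqrt(mean(tpl^2))
  expect_lt(rel_rms, 0.1)
})
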