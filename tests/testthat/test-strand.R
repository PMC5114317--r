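test_that("a drug-free strand propagates, is deterministic, and yields an upright T wave", {
  cfg <- test_strand()
  f1 <- simulate_strand(cfg)
  act <- activation_times(f1$time, f1$V)
  expect_true(all(is.finite(act)))
  # wave travels endo -> epi; the first cells share the stimulus
  expect_true(all(diff(act[-(1:3)]) > 0))

  f2 <- simulate_strand(cfg)
  expect_identical(f1$V, f2$V)        # identical config -> identical field

  ecg <- compute_pseudoecg(f1)
  m <- measure_qt(ecg)
  # T wave deflection is positive (M-cell gradient), QT in physiologic range
  expect_gt(ecg$phi[which.min(abs(ecg$time_ms - m$tpeak_ms))], 0)
  expect_gt(m$qt_ms, 250); expect_lt(m$qt_ms, 450)

  # doubling the electrode distance scales amplitude but not QT
  far <- cfg; far$electrode_mm <- cfg$electrode_mm * 2
  ecg_far <- compute_pseudoecg(f1, far)
  expect_lt(max(abs(ecg_far$phi)), max(abs(ecg$phi)))
  expect_lt(abs(measure_qt(ecg_far)$qt_ms - m$qt_ms), 2)
})

test_that("zero diffusion decouples the cable: only stimulated cells fire", {
  cfg <- test_strand(diff_coef = 0, prepace_beats = 5,
                     protocol = pacing_protocol(beats = 1))
  f <- simulate_strand(cfg)
  peak <- apply(f$V, 2, max)
  expect_gt(max(peak[1:3]), 0)               # stimulated end fires
  expect_true(all(peak[10:ncol(f$V)] < -60)) # distal cells stay at rest
})

test_that("a spatially uniform field produces an identically zero trace", {
  cfg <- test_strand()
  fake <- structure(list(time = 0:500,
                         V = matrix(rep(sin(0:500 / 50) * 50 - 40, 50),
                                    nrow = 501),
                         x = (0:49) * cfg$dx, config = cfg),
                    class = "strand_field")
  ecg <- compute_pseudoecg(fake)
  expect_equal(max(abs(ecg$phi)), 0)
})

test_that("QT detection finds constructed landmarks and is invariant to shift and scale", {
  tr <- synthetic_ecg()   # QRS at 10 ms, T limb hits baseline at 400 ms
  m <- measure_qt(tr)
  expect_lt(abs(m$qt_ms - 390), 2)

  shifted <- tr; shifted$time_ms <- tr$time_ms + 50
  expect_equal(measure_qt(shifted)$qt_ms, m$qt_ms)

  scaled <- tr; scaled$phi <- tr$phi * 3
  expect_equal(measure_qt(scaled)$qt_ms, m$qt_ms)

  flat <- tr; flat$phi[flat$time_ms > 100] <- 0   # no T wave at all
  expect_error(measure_qt(flat), "T wave")
})

test_that("Bazett correction matches its closed form and rejects bad input", {
  expect_equal(bazett(400, 1000), 400)
  expect_equal(bazett(400, 640), 500)
  expect_equal(bazett(350, 810), 350 / 0.9)
  expect_error(bazett(-1, 1000), "positive")
  expect_error(bazett(400, 0), "positive")
})

test_that("IKr block prolongs strand QTcB and baseline is reproducible", {
  cfg <- test_strand()
  q0 <- strand_qtcb(cfg)
  q0b <- strand_qtcb(cfg)
  expect_lt(abs(q0$qtcb_ms - q0b$qtcb_ms), 0.5)
  q1 <- strand_qtcb(cfg, channel_block(IKr = 0.25))
  expect_gte(q1$qtcb_ms, q0$qtcb_ms)
  # RR = pacing cycle length of 1000 ms, so QTcB = QT at default pacing
  expect_equal(q0$qtcb_ms, q0$qt_ms)
})

test_that("strand configuration enforces its invariants", {
  expect_error(strand_config(n_endo = 2, n_m = 2, n_epi = 2), "at least 20")
  expect_error(strand_config(dx = 0), "positive")
  expect_error(strand_config(electrode_mm = -1), "off the strand")
  expect_error(strand_config(diff_coef = -1), ">= 0")
})
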