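# Trials here are deliberately tiny (1-2 subjects, 1 replicate, scaled-down
# strand); identical block vectors are memoized inside run_trial, so the
# degenerate designs below cost only a handful of strand simulations.

test_that("zero exposure gives exactly zero ΔQTcB in every arm and model", {
  design <- trial_design("null", n_subjects = 2, n_replicates = 2,
                         seed = 1, cv = 0.3, conc_scale = 0,
                         strand = test_strand())
  tr <- run_trial(design, victim = drug_spec("drugA", mid_exposure_pk(),
                                             ikr_blocker_table()),
                  perpetrator = drug_spec("drugB", mid_exposure_pk(),
                                          ikr_blocker_table()))
  expect_true(all(tr$results$dqtcb_ms == 0))
  s <- summarize_trial(tr)
  expect_true(all(s$mean_dqtcb_ms == 0))
})

test_that("an inert perpetrator makes the combination arm identical to the victim arm", {
  inert <- data.frame(drug = character(), channel = character(),
                      ic50_uM = numeric(), hill_n = numeric())
  design <- trial_design("inert", n_subjects = 2, n_replicates = 1,
                         seed = 3, cv = 0.2, strand = test_strand())
  tr <- run_trial(design,
                  victim = drug_spec("drugA", mid_exposure_pk(),
                                     ikr_blocker_table()),
                  perpetrator = drug_spec("inertB", mid_exposure_pk(), inert),
                  modifier = exposure_modifier(1, 1))
  res <- tr$results
  for (subj in unique(res$subject)) {
    t_arm <- res$qtcb_ms[res$arm == "T" & res$subject == subj]
    ti <- res$qtcb_ms[res$arm == "T+I" & res$subject == subj]
    expect_true(all(ti == t_arm))       # subject-by-subject, all models
  }
  # and the inhibitor-alone arm sits at baseline
  expect_true(all(res$dqtcb_ms[res$arm == "I"] == 0))
})

test_that("per-subject ΔQTcB ordering follows the interaction models", {
  design <- trial_design("order", n_subjects = 2, n_replicates = 1,
                         seed = 5, cv = 0.3, strand = test_strand())
  tr <- run_trial(design,
                  victim = drug_spec("drugA", mid_exposure_pk(),
                                     ikr_blocker_table()),
                  perpetrator = drug_spec("drugB", mid_exposure_pk(),
                                          ikr_blocker_table()))
  m <- per_subject_deltas(tr)
  expect_true(all(m[, "sum"] >= m[, "bliss"] - 1e-9))
  expect_true(all(m[, "bliss"] >= m[, "loewe"] - 1e-9))
  expect_gt(min(m), 0)   # two mid-curve IKr blockers must prolong QTc
  # determinism under the master seed
  tr2 <- run_trial(design,
                   victim = drug_spec("drugA", mid_exposure_pk(),
                                      ikr_blocker_table()),
                   perpetrator = drug_spec("drugB", mid_exposure_pk(),
                                           ikr_blocker_table()))
  expect_identical(tr$results, tr2$results)
})

test_that("summaries reduce constructed results correctly", {
  fake <- structure(list(
    results = data.frame(
      replicate = c(1, 1, 1, 2, 2, 2), subject = rep(1:3, 2),
      arm = "T+I", model = "sum", conc_uM = 1,
      qtcb_ms = c(401, 402, 403, 401, 402, 403),
      dqtcb_ms = c(1, 2, 3, 1, 2, 3)),
    design = trial_design("fake", seed = 1)), class = "qt_trial")
  s <- summarize_trial(fake)
  expect_equal(s$mean_dqtcb_ms, 2)
  expect_equal(s$ci_lo, s$ci_hi)          # identical replicates: zero width
  expect_equal(s$ci_lo, 2)

  single <- fake
  single$results <- fake$results[1, ]
  s1 <- summarize_trial(single)
  expect_equal(s1$mean_dqtcb_ms, 1)
  expect_true(is.na(s1$ci_lo))
})

test_that("trial design validates its invariants", {
  expect_error(trial_design("x", n_subjects = 0, seed = 1), "at least one")
  expect_error(trial_design("x", n_subjects = 2), "seed")
  d <- trial_design("x", seed = 1, arms = "T")
  expect_true(all(c("BL", "T+I") %in% d$arms))  # BL and T+I always present
})
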