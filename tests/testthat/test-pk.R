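test_that("one-compartment profile matches its closed forms and unit chain", {
  p <- pk_params(dose_mg = 60, f_bio = 1, ka = 1, ke = 0.1, v_L = 600)
  expect_equal(pk_auc(p), 1000)                   # F*D/(ke*V) in ng.h/ml
  prof <- pk_profile(p, seq(0, 80, by = 0.02))
  expect_equal(prof$conc_ngml[1], 0)              # nothing absorbed at t=0
  expect_true(all(prof$conc_ngml >= 0))
  # trapezoid AUC on a fine grid approaches the closed form
  p2 <- pk_params(60, 1, ka = 2, ke = 0.3, v_L = 100)
  prof2 <- pk_profile(p2, seq(0, 60, by = 0.02))
  expect_lt(abs(profile_auc(prof2) / pk_auc(p2) - 1), 0.005)
  # very fast absorption approaches the bolus Cmax F*D/V
  pb <- pk_params(60, 1, ka = 500, ke = 0.1, v_L = 100)
  expect_lt(abs(pk_cmax(pb) / (1000 * 60 / 100) - 1), 0.05)
})

test_that("the ka = ke limit is continuous", {
  pa <- pk_params(60, 1, ka = 0.5, ke = 0.5, v_L = 100)       # exact limit
  pb <- pk_params(60, 1, ka = 0.5, ke = 0.5 * (1 - 1e-10), v_L = 100)
  t <- c(0.5, 1, 2, 5, 10)
  expect_equal(qtddi:::pk_conc(pa, t), qtddi:::pk_conc(pb, t),
               tolerance = 1e-6)
})

test_that("ng/ml to uM conversion round-trips exactly", {
  x <- c(0, 2.31, 19.67, 500)
  expect_equal(uM_to_ngml(ngml_to_uM(x, 471.7), 471.7), x,
               tolerance = 1e-12)
})

test_that("calibration round-trips every printed exposure pair within 1 %", {
  tab1 <- qtddi_table("table1")
  both <- tab1[is.finite(tab1$auc_pred), ]
  expect_gte(nrow(both), 4)
  for (k in seq_len(nrow(both))) {
    p <- calibrate_pk(both$cmax_pred[k], both$auc_pred[k], dose_mg = 60)
    expect_lt(abs(pk_cmax(p) / both$cmax_pred[k] - 1), 0.01)
    expect_lt(abs(pk_auc(p) / both$auc_pred[k] - 1), 0.01)
  }
  # Cmax-only rows still calibrate once a profile shape is assumed
  cmax_only <- tab1[!is.finite(tab1$auc_pred), ]
  p <- calibrate_pk(cmax_only$cmax_pred[1],
                    cmax_only$cmax_pred[1] / qtddi:::DEFAULT_KE)
  expect_lt(abs(pk_cmax(p) / cmax_only$cmax_pred[1] - 1), 0.01)
})

test_that("calibration is deterministic, linear in dose, and rejects infeasible targets", {
  p1 <- calibrate_pk(2.31, 20.5)
  p2 <- calibrate_pk(2.31, 20.5)
  expect_identical(p1, p2)
  doubled <- pk_params(p1$dose_mg * 2, p1$f_bio, p1$ka, p1$ke, p1$v_L)
  expect_equal(pk_auc(doubled), 2 * pk_auc(p1))
  expect_error(calibrate_pk(1e6, 1), "infeasible")
  expect_error(calibrate_pk(-1, 10), "positive")
})

test_that("population sampling is seeded, honors cv = 0, and recovers the CV", {
  base <- mid_exposure_pk()
  expect_identical(sample_population(base, 5, cv = 0, seed = 1),
                   rep(list(base), 5))
  a <- sample_population(base, 20, cv = 0.3, seed = 42)
  b <- sample_population(base, 20, cv = 0.3, seed = 42)
  expect_identical(a, b)
  c_ <- sample_population(base, 20, cv = 0.3, seed = 43)
  expect_false(identical(a, c_))
  big <- sample_population(base, 10000, cv = 0.3, seed = 7)
  kes <- sapply(big, function(p) p$ke)
  expect_lt(abs(sd(kes) / mean(kes) - 0.3), 0.02)
  expect_error(sample_population(base, 10, cv = -0.1), ">= 0")
})

test_that("exposure modifiers rescale Cmax and AUC exactly", {
  prof <- pk_profile(mid_exposure_pk(), seq(0, 120, by = 0.02))
  same <- apply_interaction(prof, exposure_modifier(1, 1))
  expect_equal(same$conc_ngml, prof$conc_ngml)
  # equal multipliers reduce to pure amplitude scaling
  dbl <- apply_interaction(prof, exposure_modifier(2, 2))
  expect_equal(dbl$conc_ngml, 2 * prof$conc_ngml, tolerance = 1e-10)
  # ketoconazole-study victim Cmax ratio from the exposure table
  tab1 <- qtddi_table("table1")
  keto <- tab1[tab1$study == "ketoconazole", ]
  ratio <- keto$cmax_pred[keto$arm == "T+I"] / keto$cmax_pred[keto$arm == "T"]
  mod <- exposure_modifier(auc_mult = ratio, cmax_mult = ratio)
  out <- apply_interaction(prof, mod)
  expect_lt(abs(max(out$conc_ngml) / max(prof$conc_ngml) / ratio - 1), 0.01)
  # uneven multipliers hit both targets through time rescaling
  p <- attr(prof, "pk_params")
  mod2 <- exposure_modifier(auc_mult = 3, cmax_mult = 1.5)
  out2 <- apply_interaction(prof, mod2)
  p2 <- attr(out2, "pk_params")
  expect_equal(pk_auc(p2) / pk_auc(p), 3, tolerance = 1e-10)
  expect_equal(pk_cmax(p2) / pk_cmax(p), 1.5, tolerance = 1e-10)
  expect_error(exposure_modifier(0.5, 1), ">= 1")
})
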