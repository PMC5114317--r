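test_that("the distance metric matches printed worked examples", {
  expect_equal(qt_distance(obs = c(408, 416, 490),
                           pred = c(394.5, 395, 439)), 48.61,
               tolerance = 0.005 / 48.61)
  expect_equal(qt_distance(obs = c(381, 387, 386),
                           pred = c(392.0, 394.5, 396.6)), 4.69,
               tolerance = 0.005 / 4.69)
  expect_equal(qt_distance(obs = c(400, 410, 420), pred = c(400, 410, 420)),
               0)
})

test_that("distance is baseline-shift invariant and agrees with a brute-force path", {
  set.seed(11)
  for (k in 1:50) {
    obs <- runif(3, 350, 500); pred <- runif(3, 350, 500)
    shift <- runif(1, -40, 40)
    # independent re-derivation straight from the three delta terms
    dto <- obs[2] - obs[1]; dio <- obs[3] - obs[1]
    dtp <- pred[2] - pred[1]; dip <- pred[3] - pred[1]
    brute <- sqrt((dtp - dto)^2 + (dip - dio)^2 +
                    ((dip - dtp) - (dio - dto))^2)
    expect_equal(qt_distance(obs, pred), brute, tolerance = 1e-12)
    expect_equal(qt_distance(obs + shift, pred), qt_distance(obs, pred),
                 tolerance = 1e-9)
    expect_equal(qt_distance(obs, pred + shift), qt_distance(obs, pred),
                 tolerance = 1e-9)
  }
})

test_that("delta-only studies feed reported changes straight into the distance", {
  d1 <- qt_distance(obs_deltas = c(8, 39), pred = c(392.8, 398.5, 418.2))
  d2 <- qt_distance(obs_deltas = c(8, 39), pred_deltas = c(5.7, 25.4))
  expect_equal(d1, d2, tolerance = 1e-12)
})

test_that("the full comparison table reproduces the recomputable printed distances", {
  d <- table2_distances()
  printed <- qtddi_table("table2_distances")
  exact <- c("paroxetine", "ketoconazole", "clarithromycin",
             "erythromycin_cr19", "itraconazole")
  for (st in exact) {
    got <- d$distance[d$study == st & d$model == "sum"]
    want <- printed$distance[printed$study == st & printed$model == "sum"]
    expect_equal(round(got, 2), want)
  }
  # Bliss/Loewe residuals stay within the rounding of the printed triplets
  for (case in list(c("ketoconazole", "bliss"), c("ketoconazole", "loewe"),
                    c("erythromycin_cr19", "bliss"))) {
    got <- d$distance[d$study == case[1] & d$model == case[2]]
    want <- printed$distance[printed$study == case[1] &
                               printed$model == case[2]]
    expect_lt(abs(got / want - 1), 0.002)
  }
})

test_that("Welch t test matches the closed form and rejects degenerate input", {
  x <- c(1, 2, 3); y <- x + 10
  w <- welch_t(x, y)
  # closed-form Welch statistic and Welch-Satterthwaite df
  se <- sqrt(var(x) / 3 + var(y) / 3)
  t_manual <- (mean(x) - mean(y)) / se
  df_manual <- se^4 / ((var(x) / 3)^2 / 2 + (var(y) / 3)^2 / 2)
  expect_equal(w$t, t_manual)
  expect_equal(w$df, df_manual)
  expect_lt(w$p, 0.01)
  same <- welch_t(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(same$t, 0); expect_equal(same$p, 1)
  expect_error(welch_t(c(0, 0), c(0, 0)), "zero variance")
  expect_error(welch_t(1, c(1, 2)), "at least 2")
})

test_that("flip counting matches hand counts and its invariances", {
  all3 <- matrix(3, nrow = 6, ncol = 3)
  expect_equal(count_flips(all3)$pct_cases, 0)
  one <- rbind(c(4.9, 5.1, 5.0))
  expect_equal(count_flips(one)$n_cases, 1)
  ten <- rbind(matrix(2, 8, 3), c(4, 6, 5), c(4.9, 5.2, 5.1))
  expect_equal(count_flips(ten)$pct_cases, 20)
  # order invariance and duplication scaling
  perm <- ten[sample(nrow(ten)), ]
  expect_equal(count_flips(perm)$pct_cases, 20)
  expect_equal(count_flips(rbind(ten, ten))$pct_cases, 20)
  # exactly-at-threshold prediction counts as reaching it
  expect_equal(count_flips(rbind(c(4.9, 5.0, 4.95)))$n_cases, 1)
  expect_equal(count_flips(rbind(c(5.0, 5.1, 5.3)))$n_cases, 0)
  expect_error(count_flips(rbind(c(1, NA, 2))), "missing")
})

test_that("model ranking sorts by distance with the declared tie-break", {
  expect_equal(best_model(c(sum = 1, bliss = 2, loewe = 3)),
               c("sum", "bliss", "loewe"))
  expect_equal(best_model(c(loewe = 1, bliss = 2, sum = 3)),
               c("loewe", "bliss", "sum"))
  expect_equal(best_model(c(loewe = 2, bliss = 2, sum = 2)),
               c("sum", "bliss", "loewe"))
  expect_equal(best_model(c(bliss = 7)), "bliss")
})
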