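test_that("Hill block has the right midpoint, endpoints and slope", {
  expect_equal(hill_inhibition(1, ic50 = 1, hill_n = 1), 0.5)
  expect_equal(hill_inhibition(0, ic50 = 3.7, hill_n = 2.2), 0)
  expect_equal(hill_inhibition(3, ic50 = 1, hill_n = 2), 9 / 10)
  # strictly increasing in concentration, bounded by 1
  cc <- seq(0, 50, by = 0.5)
  e <- hill_inhibition(cc, ic50 = 2, hill_n = 1.5)
  expect_true(all(diff(e) > 0))
  expect_true(all(e >= 0 & e < 1))
  expect_error(hill_inhibition(-1, 1, 1), "non-negative")
  expect_error(hill_inhibition(Inf, 1, 1), "finite")
  expect_error(hill_inhibition(1, 0, 1), "positive")
})

test_that("the three interaction models match their closed forms", {
  expect_equal(combine_sum(0.2, 0.3), 0.5)
  expect_equal(combine_sum(0.7, 0.6), 1.0)
  expect_equal(combine_bliss(0.5, 0.5), 0.75)
  expect_equal(combine_bliss(1.0, 0.37), 1.0)
  expect_equal(combine_loewe(0.5, 0.5), 0.5 / 0.75)
  expect_equal(combine_loewe(0.9, 0.9), 0.18 / 0.19)
  # Loewe continuity point at complete block of both drugs
  expect_equal(combine_loewe(1, 1), 1)
  expect_error(combine_sum(-0.1, 0.5), "\\[0, 1\\]")
  expect_error(combine_bliss(0.5, 1.2), "\\[0, 1\\]")
})

test_that("models are symmetric, have identity at zero, and are ordered", {
  g <- seq(0.05, 0.95, by = 0.05)
  grid <- expand.grid(ea = g, eb = g)
  s <- combine_sum(grid$ea, grid$eb)
  b <- combine_bliss(grid$ea, grid$eb)
  l <- combine_loewe(grid$ea, grid$eb)
  expect_true(all(l <= b + 1e-12))
  expect_true(all(b <= s + 1e-12))
  expect_true(all(s >= 0 & s <= 1 & b >= 0 & b <= 1 & l >= 0 & l <= 1))
  # symmetry
  expect_equal(s, combine_sum(grid$eb, grid$ea))
  expect_equal(b, combine_bliss(grid$eb, grid$ea))
  expect_equal(l, combine_loewe(grid$eb, grid$ea))
  # identity at eb = 0, exactly
  expect_identical(combine_sum(g, 0), g)
  expect_identical(combine_bliss(g, 0), g)
  expect_equal(combine_loewe(g, 0), g, tolerance = 1e-15)
  # monotone in each argument
  for (f in list(combine_sum, combine_bliss, combine_loewe)) {
    for (eb in c(0.2, 0.6, 0.9))
      expect_true(all(diff(f(g, eb)) >= -1e-12))
  }
})

test_that("Loewe on same-IC50 Hill curves is exact dose addition", {
  conc <- c(0.01, 0.1, 0.3, 1, 2, 5, 10)
  for (a in conc) for (b in conc) {
    ea <- hill_inhibition(a, 1, 1)
    eb <- hill_inhibition(b, 1, 1)
    expect_equal(combine_loewe(ea, eb), hill_inhibition(a + b, 1, 1),
                 tolerance = 1e-12)
  }
})

test_that("channel vectors combine element-wise and validate their channels", {
  zero <- channel_block()
  b <- channel_block(IKr = 0.4, INa = 0.1)
  for (m in c("sum", "bliss", "loewe"))
    expect_equal(unclass(combine_channels(zero, b, m)), unclass(b))
  two <- combine_channels(channel_block(IKr = 0.5), channel_block(IKr = 0.5),
                          "bliss")
  expect_equal(unname(unclass(two)), c(0.75, 0, 0, 0))
  all6 <- channel_block(0.6, 0.6, 0.6, 0.6)
  expect_equal(unname(unclass(combine_channels(all6, all6, "sum"))),
               rep(1, 4))
  expect_error(channel_block(IKr = 1.2), "\\[0, 1\\]")
  bad <- c(IKr = 0.1, IKs = 0, INa = 0, ICa = 0)  # wrong channel name
  expect_error(combine_channels(bad, zero, "sum"), "channel set")
})

test_that("drug block tables evaluate per-channel Hill curves", {
  tab <- data.frame(drug = c("d1", "d1", "d2"),
                    channel = c("IKr", "ICaL", "IKr"),
                    ic50_uM = c(1, 10, 2), hill_n = c(1, 1, 2))
  e <- drug_block_at(1, "d1", tab)
  expect_equal(unname(e[["IKr"]]), 0.5)
  expect_equal(unname(e[["ICaL"]]), 1 / 11)
  expect_equal(unname(e[["IKs"]]), 0)   # missing row means no block
  expect_equal(unname(unclass(drug_block_at(0.5, "absent", tab))),
               rep(0, 4))
  path <- tempfile(fileext = ".csv")
  write.csv(tab, path, row.names = FALSE)
  expect_equal(read_drug_blocks(path)$ic50_uM, tab$ic50_uM)
  tab$channel[1] <- "IKr2"
  write.csv(tab, path, row.names = FALSE)
  expect_error(read_drug_blocks(path), "unknown channels")
  expect_error(read_drug_blocks(tempfile()), "not found")
})
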