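# Threshold ladder, solubilized-mass estimates, ensemble prediction and
# screening.

test_that("ladder estimates follow the two-consecutive-failures rule", {
  le <- c(20, 40, 60, 80)
  lc <- c(10, 20, 30, 40)
  expect_equal(as.numeric(ladder_estimate(c(TRUE, FALSE, FALSE, FALSE), le)), 39)
  expect_equal(as.numeric(ladder_estimate(c(FALSE, FALSE, FALSE, FALSE), le)), 0)
  expect_equal(as.numeric(ladder_estimate(c(TRUE, FALSE, FALSE, TRUE), lc)), 19)
  expect_equal(as.numeric(ladder_estimate(c(TRUE, TRUE, FALSE, FALSE), lc)), 29)
  expect_equal(as.numeric(ladder_estimate(c(FALSE, TRUE, TRUE, FALSE), lc)), 39)
  top <- ladder_estimate(c(TRUE, TRUE, TRUE, TRUE), lc)
  expect_equal(as.numeric(top), 40)
  expect_true(isTRUE(attr(top, "lower_bound")))
})

test_that("adding a pass at a higher rung never lowers the estimate", {
  lc <- c(10, 20, 30, 40)
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), 4))
  for (r in seq_len(nrow(combos))) {
    base <- as.logical(combos[r, ])
    e0 <- as.numeric(ladder_estimate(base, lc))
    for (i in which(!base)) {
      up <- base; up[i] <- TRUE
      expect_gte(as.numeric(ladder_estimate(up, lc)), e0)
    }
  }
})

test_that("solubilized-mass conversion inverts the loading formulas", {
  est <- estimate_solubilized(0, 39, polymer_feed = 10, df = 6)
  expect_equal(est$m_le, 2.34, tolerance = 1e-12)
  expect_equal(est$m_lc, 0)
  # inversion identity: plugging m_lc back into the LC formula returns LC
  for (lc in c(9, 19, 29, 39)) {
    m <- estimate_solubilized(lc, 0, polymer_feed = 10, df = 6)$m_lc[1]
    expect_equal(100 * m / (m + 10), lc, tolerance = 1e-9)
  }
  # combined estimate lies between the two
  est <- estimate_solubilized(19, 39, polymer_feed = 10, df = c(2, 6, 10))
  expect_true(all(est$m_combined >= pmin(est$m_lc, est$m_le) &
                    est$m_combined <= pmax(est$m_lc, est$m_le)))
  expect_warning(estimate_solubilized(100, 39, 10, 6), "cannot invert")
})

test_that("the ensemble predicts all eight thresholds with AD flags", {
  ens <- tiny_ensemble()
  expect_named(ens$models, c("LC10", "LC20", "LC30", "LC40",
                             "LE20", "LE40", "LE60", "LE80"))
  f <- make_worked_example()
  thr <- predict_thresholds(f, ens)
  expect_equal(nrow(thr), 8)
  expect_true(all(thr$threshold == names(ens$models)))
  expect_true(is.logical(thr$pass) && is.logical(thr$in_ad))
  # out-of-AD thresholds are treated as failed
  rep <- prediction_report(f, ens)
  failed_by_ad <- !rep$thresholds$in_ad
  expect_true(all(!rep$thresholds$pass[failed_by_ad]))
  expect_true(all(rep$estimates$m_combined >=
                    pmin(rep$estimates$m_lc, rep$estimates$m_le) - 1e-12))
})

test_that("coformulation predictions are invariant to drug order", {
  ens <- tiny_ensemble()
  pool <- drug_pool()
  d1 <- drug_spec("curcumin", pool$smiles[pool$name == "curcumin"])
  d2 <- drug_spec("ibuprofen", pool$smiles[pool$name == "ibuprofen"])
  pol <- polymer_spec("MeOx", "nPrOzi", c(35, 20, 35))
  f12 <- formulation(pol, list(d1, d2), c(4, 4), 10)
  f21 <- formulation(pol, list(d2, d1), c(4, 4), 10)
  t12 <- predict_thresholds(f12, ens)
  t21 <- predict_thresholds(f21, ens)
  expect_equal(t12$score, t21$score, tolerance = 1e-9)
})

test_that("screening returns one ranked row per drug x polymer", {
  ens <- tiny_ensemble()
  pool <- drug_pool()
  drugs <- stats::setNames(pool$smiles[1:2], pool$name[1:2])
  res <- screen_library(drugs, polymers = c("nPrOzi", "nBuOx", "BzOx"),
                        ensemble = ens)
  expect_equal(nrow(res), 6)
  expect_true(all(res$n_passed == sort(res$n_passed, decreasing = TRUE)))
  expect_true(all(c("LC10", "LE80", "n_passed", "lc_estimate") %in% names(res)))
  # unparsable SMILES rows are skipped with a message
  expect_message(
    res2 <- screen_library(c(good = pool$smiles[1], bad = "not_a_smiles((("),
                           polymers = c("nPrOzi"), ensemble = ens),
    "skipping")
  expect_equal(nrow(res2), 1)
})
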