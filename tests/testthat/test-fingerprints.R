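# Count fingerprints and count-weighted mixing.

test_that("mixing scales a single component by its multiplicity", {
  fp <- count_fingerprint("CCN(C)C(C)=O", "rdk5", 2048L)
  mixed <- mix_count_fingerprints(list(fp), 35)
  expect_equal(mixed$bit, fp$bit)
  expect_equal(mixed$count, 35 * fp$count)
})

test_that("mixing adds counts bitwise and is order-invariant", {
  f1 <- count_fingerprint("CCN(C)C(C)=O", "ecfp4", 2048L)
  f2 <- count_fingerprint("c1ccccc1O", "ecfp4", 2048L)
  f3 <- count_fingerprint("CCCCCC", "ecfp4", 2048L)
  m123 <- mix_count_fingerprints(list(f1, f2, f3), c(70, 20, 2.5))
  m321 <- mix_count_fingerprints(list(f3, f2, f1), c(2.5, 20, 70))
  expect_equal(m123$bit, m321$bit)
  expect_equal(m123$count, m321$count)
  # additivity on the dense vector
  dense <- function(f, w) { v <- numeric(f$width); v[f$bit] <- w * f$count; v }
  expect_equal({ v <- numeric(2048); v[m123$bit] <- m123$count; v },
               dense(f1, 70) + dense(f2, 20) + dense(f3, 2.5))
})

test_that("fractional drug multiplicities are kept unless rounding is requested", {
  fp <- count_fingerprint("c1ccccc1O", "rdk7", 2048L)
  frac <- mix_count_fingerprints(list(fp), 2.4)
  expect_equal(frac$count, 2.4 * fp$count)
  rounded <- mix_count_fingerprints(list(fp), 2.4, round_drug_count = TRUE)
  expect_equal(rounded$count, 2 * fp$count)
})

test_that("family and width mismatches are configuration errors", {
  f1 <- count_fingerprint("CCO", "rdk5", 1024L)
  f2 <- count_fingerprint("CCO", "ecfp4", 1024L)
  f3 <- count_fingerprint("CCO", "rdk5", 2048L)
  expect_error(mix_count_fingerprints(list(f1, f2), c(1, 1)), "configuration")
  expect_error(mix_count_fingerprints(list(f1, f3), c(1, 1)), "configuration")
  expect_error(count_fingerprint("CCO", "avalon"), "configuration")
})

test_that("path fingerprints count the expected number of subpaths", {
  # pentane: paths of 1..4 bonds along a chain of 5 atoms: 4+3+2+1
  fp <- count_fingerprint("CCCCC", "rdk5", 4096L)
  expect_equal(sum(fp$count), 10)
  # morgan counts one environment per atom and radius
  fe <- count_fingerprint("CCCCC", "ecfp4", 4096L)
  expect_equal(sum(fe$count), 5 * 3)
  fe6 <- count_fingerprint("CCCCC", "ecfp6", 4096L)
  expect_equal(sum(fe6$count), 5 * 4)
})
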