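# SiRMS simplex descriptors: binning, labelling, enumeration against a
# brute-force oracle, mixture weighting.

test_that("property binning uses inclusive upper bounds", {
  logp <- property_bin_scheme("logp")
  expect_equal(bin_atomic_property(-0.5, logp), "A")
  expect_equal(bin_atomic_property(c(0.3, 0.6), logp), c("C", "D"))
  expect_equal(bin_atomic_property(0, logp), "B")
  eeq <- property_bin_scheme("eeq")
  expect_equal(bin_atomic_property(0, eeq), "B")
  expect_equal(bin_atomic_property(-0.281, eeq), "A")
  expect_error(bin_atomic_property(NaN, logp), "input error")
  expect_error(property_bin_scheme("logp", c(1, 1, 2)), "ascending")
})

test_that("atom labelling is total and types benzene as 6>sp2", {
  benz <- parse_smiles("c1ccccc1")
  lb <- label_atoms(benz, schemes = "atom")
  expect_equal(nrow(lb$labels), 6)
  expect_true(all(lb$labels$atom == "6>sp2"))
  # explicit hydrogens get their own vertices
  lbh <- label_atoms(benz, schemes = "atom", explicit_h = TRUE)
  expect_equal(nrow(lbh$labels), 12)
  expect_equal(sum(lbh$labels$atom == "1>s"), 6)
  # unavailable plug-in schemes are configuration errors without values
  expect_error(label_atoms(benz, schemes = "eeq"), "configuration error")
  ok <- label_atoms(benz, schemes = "eeq", external = list(eeq = rep(0.1, 6)))
  expect_true(all(ok$labels$eeq == "C"))
})

test_that("ethanol Crippen-style labels match the contribution table by hand", {
  eth <- parse_smiles("CCO")
  contrib <- crippen_atomic(eth)
  # C bonded only to C/H; C bonded to O; hydroxyl O - from the shipped table
  expect_equal(contrib$logp, c(0.1441, -0.2035, -0.2893), tolerance = 1e-9)
  lb <- label_atoms(eth, schemes = "logp")
  expect_equal(lb$labels$logp, c("C", "B", "B"))
})

test_that("simplex enumeration matches the brute-force oracle on small molecules", {
  mols <- list(parse_smiles("CCCC"), parse_smiles("CCCCC"),
               parse_smiles("CCO"), parse_smiles("c1ccccc1"),
               parse_smiles("CC(C)C=O"), parse_smiles("C1CC1CO"))
  for (m in mols) {
    for (sc in c("atom", "logp")) {
      fast <- enumerate_simplexes(m, sc)
      oracle <- brute_simplexes(m, sc)
      fast <- fast[order(fast$key), ]
      oracle <- oracle[order(oracle$key), ]
      expect_equal(fast$key, oracle$key)
      expect_equal(fast$count, oracle$count)
      expect_equal(sum(fast$count), choose(n_heavy(m), 4))
    }
  }
})

test_that("simplex totals are C(n,4) also with explicit hydrogens", {
  m <- parse_smiles("CC(C)O")
  s <- enumerate_simplexes(m, "atom", explicit_h = TRUE)
  n_all <- nrow(m$atoms_all)
  expect_equal(sum(s$count), choose(n_all, 4))
  # fewer-than-4-atom structures give an empty, valid vector
  expect_equal(nrow(enumerate_simplexes(parse_smiles("CCO"), "atom")), 0)
})

test_that("noH simplexes equal the explicit-H set restricted to heavy labels", {
  m <- parse_smiles("CCCC")
  noh <- enumerate_simplexes(m, "atom", explicit_h = FALSE)
  h <- enumerate_simplexes(m, "atom", explicit_h = TRUE)
  h_heavy <- h[!grepl("1>s", h$key), ]
  expect_equal(noh$key, h_heavy$key)
  expect_equal(noh$count, h_heavy$count)
})

test_that("mixture weighting follows the doubled-minor rule", {
  a <- parse_smiles("CCC"); b <- parse_smiles("CO")
  # equimolar: cross-component weight 2 * 0.5 = 1 per simplex
  eq <- mixture_simplexes(list(a, b), c(0.5, 0.5), scheme = "atom")
  expect_equal(sum(eq$count), 5)  # 5 cross subsets, unit weight
  # skewed: cross weight 2 * 0.1
  sk <- mixture_simplexes(list(a, b), c(0.9, 0.1), scheme = "atom")
  expect_equal(sum(sk$count), 5 * 0.2, tolerance = 1e-12)
  expect_true(all(grepl("D1", sk$key)))
  # single-component simplexes carry the component's own fraction
  big <- parse_smiles("CCCCC")
  mix <- mixture_simplexes(list(big, b), c(0.8, 0.2), scheme = "atom")
  own <- mix[!grepl("D1", mix$key), ]
  expect_equal(sum(own$count), 0.8 * choose(5, 4), tolerance = 1e-12)
})

test_that("uniform fraction scaling leaves relative single-molecule weights unchanged", {
  a <- parse_smiles("CCCCC"); b <- parse_smiles("CCCCO")
  m1 <- mixture_simplexes(list(a, b), c(0.6, 0.4), scheme = "atom")
  m2 <- mixture_simplexes(list(a, b), c(0.3, 0.2), scheme = "atom")
  expect_equal(m1$key, m2$key)
  expect_equal(m1$count / sum(m1$count), m2$count / sum(m2$count),
               tolerance = 1e-12)
})

test_that("ternary mixtures produce three-origin simplexes under the fragment cap", {
  a <- parse_smiles("CCC"); b <- parse_smiles("CC"); d <- parse_smiles("O")
  mx <- mixture_simplexes(list(a, b, d), c(0.6, 0.3, 0.1), scheme = "atom")
  three <- mx[grepl("P", mx$key) & grepl("D1", mx$key) & grepl("D2", mx$key), ]
  expect_true(nrow(three) > 0)
  # hand count: (2,1,1) gives 3 pairs x 2 = 6 subsets, of which the
  # disconnected CCC pair {1,3} (x2) has 4 fragments and is capped away;
  # (1,2,1) gives 3; kept = 4 + 3 = 7, each weighted 2 * min fraction = 0.2
  expect_equal(sum(three$count), 7 * 0.2, tolerance = 1e-12)
  expect_error(mixture_simplexes(list(a, b, d, d), c(.4, .3, .2, .1)),
               "unsupported")
})
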