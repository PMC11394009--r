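# Descriptor backend: chi indices against independent oracles, mixture
# weighting, determinism.

test_that("chi path indices match hand-computed Kier-Hall values", {
  but <- parse_smiles("CCCC")
  d <- poxload:::chi_descriptors(but)
  expect_equal(d[["Xp-1d"]], 2 / sqrt(2) + 1 / 2, tolerance = 1e-12)
  expect_equal(d[["Xp-3d"]], 1 / sqrt(1 * 2 * 2 * 1), tolerance = 1e-12)
  expect_equal(d[["Xp-0d"]], 2 / sqrt(1) + 2 / sqrt(2), tolerance = 1e-12)
  # isobutane: one order-3 cluster (star), no order-3 path
  iso <- parse_smiles("CC(C)C")
  di <- poxload:::chi_descriptors(iso)
  expect_equal(di[["Xc-3d"]], 1 / sqrt(3 * 1 * 1 * 1), tolerance = 1e-12)
  expect_equal(di[["Xp-3d"]], 0)
  # benzene: valence delta 3 on all aromatic CH; ring chi of order 6
  benz <- parse_smiles("c1ccccc1")
  db <- poxload:::chi_descriptors(benz)
  expect_equal(db[["Xch-6dv"]], 3^-3, tolerance = 1e-12)
})

test_that("order-7 chi subgraph values reproduce frozen reference values", {
  # frozen from an independent brute-force subgraph enumeration over the
  # same structures (RDKit graph, exhaustive edge-subset enumeration)
  cur <- parse_smiles("COc1cc(/C=C/C(=O)CC(=O)/C=C/c2ccc(O)c(OC)c2)ccc1O")
  dc <- poxload:::chi_descriptors(cur)
  expect_equal(dc[["Xp-7dv"]], 0.3848020, tolerance = 1e-6)
  expect_equal(dc[["Xch-7dv"]], 0.0689362, tolerance = 1e-5)
  expect_equal(dc[["Xpc-7dv"]], 0.9266935, tolerance = 1e-6)
  ta <- parse_smiles(paste0("CC1(C)O[C@@H]2C[C@H]3[C@@H]4CCC5=CC(=O)C=C[C@]5",
                            "(C)[C@@]4(F)[C@@H](O)C[C@]3(C)[C@@]2(O1)C(=O)CO"))
  dt <- poxload:::chi_descriptors(ta)
  expect_equal(dt[["Xp-7dv"]], 3.3106977, tolerance = 1e-6)
  expect_equal(dt[["Xch-7dv"]], 0.9530061, tolerance = 1e-6)
})

test_that("autocorrelation and size descriptors agree with direct sums", {
  eth <- parse_smiles("CCO")
  d <- component_descriptors(eth, include_3d = FALSE)
  expect_equal(d[["ATS1Z"]], 6 * 6 + 6 * 8)
  expect_equal(d[["ATS0Z"]], 6^2 + 6^2 + 8^2)
  expect_equal(d[["MW"]], 46.069, tolerance = 1e-3)
  expect_equal(d[["nRot"]], 0)
  but <- component_descriptors(parse_smiles("CCCC"), include_3d = FALSE)
  expect_equal(but[["nRot"]], 1)
  meth <- component_descriptors(parse_smiles("C"), include_3d = FALSE)
  expect_equal(meth[["nRot"]], 0)
})

test_that("descriptor computation is deterministic across runs", {
  a <- component_descriptors("CC(=O)Nc1ccc(O)cc1", include_3d = TRUE)
  b <- component_descriptors("CC(=O)Nc1ccc(O)cc1", include_3d = TRUE)
  expect_identical(a, b)
})

test_that("mixture weighting is the molar-fraction linear combination", {
  v1 <- c(a = 1, b = 10); v2 <- c(a = 3, b = -2)
  expect_equal(mix_descriptors(list(v1, v2), c(0.75, 0.25)),
               c(a = 1.5, b = 7))
  # identical components reproduce themselves
  expect_equal(mix_descriptors(list(v1, v1, v1), c(0.2, 0.3, 0.5)), v1)
  # zero-weight components do not matter
  expect_equal(mix_descriptors(list(v1, v2, c(a = 99, b = 99)), c(0.7, 0.3, 0)),
               mix_descriptors(list(v1, v2), c(0.7, 0.3)))
  # renormalisation linearity: scaling all fractions changes nothing
  expect_equal(mix_descriptors(list(v1, v2), c(3, 1)),
               mix_descriptors(list(v1, v2), c(0.75, 0.25)))
  expect_error(mix_descriptors(list(v1, c(a = 1, z = 2)), c(0.5, 0.5)),
               "configuration error")
})
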