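# Polymer domain model: capping, pseudotrimers, stoichiometry, LC/LE.

test_that("capping follows the one-hydrogen/one-methyl rule with methyl on nitrogen", {
  meox <- build_capped_monomer("[*]N(C(C)=O)CC[*]", role = "A")
  expect_equal(mol_formula(meox), "C5H11NO")  # N-methyl-N-ethylacetamide
  # nitrogen side takes the methyl: N has three heavy neighbours, no N-H
  nN <- which(meox$atoms$elem == "N")
  expect_equal(meox$atoms$nH[nN], 0L)
  expect_equal(meox$atoms$degree[nN], 3L)

  # both attachments on carbons: one H cap, one methyl -> +1 heavy atom
  unit <- parse_smiles("[*]CCO[*]")
  capped <- build_capped_monomer("[*]CCO[*]", role = "A")
  expect_equal(n_heavy(capped), n_heavy(unit) - 2 + 1)
})

test_that("capping validates attachment-point counts", {
  expect_error(build_capped_monomer("[*]C([*])C[*]", role = "A"), "structural")
  expect_error(build_capped_monomer("CCC", role = "A"), "structural")
  expect_error(build_capped_monomer("[*]CC[*]", role = "terminus_start"),
               "structural")
})

test_that("monomer registry units are mass-consistent", {
  reg <- monomer_registry()
  expect_true(all(c("MeOx", "nPrOzi", "nBuOx", "BzOx", "PentOx") %in%
                    names(reg$monomers)))
  meox <- monomer_spec("MeOx")
  expect_equal(meox$mw_repeat, 85.106, tolerance = 1e-6)  # C4H7NO
  nbuozi <- monomer_spec("nBuOzi")
  expect_equal(nbuozi$mw_repeat, 141.21, tolerance = 1e-3)  # C8H15NO
})

test_that("polymer mass equals the block sum and validates overrides", {
  pol <- polymer_spec("MeOx", "nPrOzi", c(35, 20, 35))
  expected <- 70 * 85.106 + 20 * 127.185 + 15.035 + 84.141
  expect_equal(pol$mw_polymer, expected, tolerance = 0.1)
  expect_error(polymer_spec("MeOx", "nPrOzi", c(35, 20, 35),
                            mw_polymer = expected + 5), "inconsistent")
  expect_error(polymer_spec("MeOx", "nPrOzi", c(0, 20, 35)), "block_lengths")
})

test_that("pseudotrimer contains each building block once and conserves atoms", {
  pol <- polymer_spec("MeOx", "nPrOzi", c(35, 20, 35))
  tri <- build_pseudotrimer(pol)
  expect_true(mol_is_connected(tri))
  units <- list(pol$termini[[1]], pol$a_monomer, pol$b_monomer,
                pol$a_monomer, pol$termini[[2]])
  expected_heavy <- sum(vapply(units, function(u)
    n_heavy(parse_smiles(u$repeat_smiles)) - count_attachments(u$repeat_smiles),
    numeric(1)))
  expect_equal(n_heavy(tri), expected_heavy)
  # amide nitrogens: T2 piperidide + 3 interior units
  expect_equal(sum(tri$atoms$elem == "N"), 4L)

  # degenerate homopolymer: A and B identical
  hom <- polymer_spec("MeOx", "MeOx", c(1, 1, 1))
  tri2 <- build_pseudotrimer(hom)
  expect_equal(sum(tri2$atoms$elem == "N"), 4L)
  expect_true(mol_is_connected(tri2))
})

test_that("drugs per chain follows the mass-ratio formula", {
  d <- drug_spec("probe", "c1ccccc1O")  # phenol 94.11
  pol <- polymer_spec("MeOx", "nPrOzi", c(35, 20, 35))
  f <- formulation(pol, d, drug_feed = 2, polymer_feed = 10, t_days = 0)
  expect_equal(drugs_per_chain(f), 0.2 * pol$mw_polymer / d$mw_drug,
               tolerance = 1e-12)
  # worked numbers: m_added 2, polymer 10, MWp 10000, MWd 500 -> 4.0
  expect_equal((2 / 10) * (10000 / 500), 4.0)
})

test_that("molar fractions are counts over N_total and sum to one", {
  d <- drug_spec("probe", "c1ccccc1O")
  pol <- polymer_spec("MeOx", "nPrOzi", c(35, 20, 35))
  # pick a feed giving exactly N_drug = 10
  feed <- 10 * 10 * d$mw_drug / pol$mw_polymer
  f <- formulation(pol, d, drug_feed = feed, polymer_feed = 10)
  st <- molar_fractions(f)
  expect_equal(sum(st$N), 102, tolerance = 1e-9)
  expect_equal(st$n[st$class == "B"], 20 / 102, tolerance = 1e-9)
  expect_equal(sum(st$n), 1, tolerance = 1e-12)
})

test_that("molar fractions sum to one over many random formulations", {
  set.seed(404)
  sums <- replicate(1000, {
    bl <- c(sample(5:60, 1), sample(5:40, 1), sample(5:60, 1))
    mwp <- sum(bl * c(85.1, 127.2, 85.1)) + 99.2
    nd <- runif(1, 0, 40)
    n <- c(1, bl[1] + bl[3], bl[2], 1, nd)
    sum(n / sum(n))
  })
  expect_true(all(abs(sums - 1) < 1e-12))
})

test_that("loading metrics match the printed formulas and their identity", {
  pol <- polymer_spec("MeOx", "nBuOx", c(35, 20, 35))
  d <- drug_spec("probe", "c1ccccc1O")
  f <- formulation(pol, d, drug_feed = 8, polymer_feed = 10, m_solubilized = 3.2)
  lm <- loading_metrics(f)
  expect_equal(lm$LC, 24.2424, tolerance = 1e-4)
  expect_equal(lm$LE, 40.0, tolerance = 1e-9)
  # algebraic identity LC/(100-LC) = (LE/100) * m_added / m_polymer_feed
  set.seed(11)
  for (r in 1:50) {
    df <- runif(1, 0.5, 12); p <- runif(1, 2, 25); ms <- runif(1, 0, df)
    ff <- formulation(pol, d, df, p, m_solubilized = ms)
    met <- loading_metrics(ff)
    expect_equal(met$LC / (100 - met$LC), (met$LE / 100) * df / p,
                 tolerance = 1e-9)
  }
  # monotonicity in m_sol
  ms <- seq(0, 8, by = 0.5)
  lcs <- vapply(ms, function(m)
    loading_metrics(formulation(pol, d, 8, 10, m_solubilized = m))$LC, 0)
  les <- vapply(ms, function(m)
    loading_metrics(formulation(pol, d, 8, 10, m_solubilized = m))$LE, 0)
  expect_true(all(diff(lcs) > 0) && all(diff(les) > 0))
  # zero solubilization
  z <- loading_metrics(formulation(pol, d, 8, 10, m_solubilized = 0))
  expect_equal(c(z$LC, z$LE), c(0, 0))
})

test_that("formulation validation rejects bad rows", {
  pol <- polymer_spec("MeOx", "nBuOx", c(35, 20, 35))
  d <- drug_spec("probe", "c1ccccc1O")
  expect_error(formulation(pol, d, 0, 10), "positive")
  expect_error(formulation(pol, d, 2, 10, m_solubilized = 3), "\\[0, drug feed\\]")
  expect_error(formulation(pol, list(d, d, d), c(1, 1, 1), 10), "1-2 drugs")
})
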