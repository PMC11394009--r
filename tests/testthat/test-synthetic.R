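# Synthetic-data generator: reproducibility, planted correlations, worked
# example.

test_that("the generator is byte-reproducible under a fixed seed", {
  t1 <- generate_formulation_dataset(generator_config(n_formulations = 60, seed = 5))
  t2 <- generate_formulation_dataset(generator_config(n_formulations = 60, seed = 5))
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_formulation_table(t1, f1); write_formulation_table(t2, f2)
  expect_identical(readLines(f1), readLines(f2))
  t3 <- generate_formulation_dataset(generator_config(n_formulations = 60, seed = 6))
  expect_false(identical(t1$data, t3$data))
})

test_that("generated tables respect the physical bounds and validate", {
  tab <- tiny_table()
  sol <- tab$data$drug1_solubilized
  expect_true(all(sol >= 0 & sol <= tab$data$drug1_feed))
  expect_s3_class(tab, "pox_formulation_table")
})

test_that("the planted rule anticorrelates drug feed and loading efficiency", {
  tab <- generate_formulation_dataset(generator_config(n_formulations = 400,
                                                       seed = 3))
  le <- 100 * tab$data$drug1_solubilized / tab$data$drug1_feed
  expect_lt(stats::cor(tab$data$drug1_feed, le), 0)
  # storage time decays loading
  t0 <- le[tab$data$t_days == 0]
  tlong <- le[tab$data$t_days == 180]
  expect_lt(mean(tlong), mean(t0))
})

test_that("the noiseless limit is a deterministic function of the inputs", {
  cfg <- generator_config(n_formulations = 300, seed = 12, noise_sd = 0,
                          decay = 0)
  tab <- generate_formulation_dataset(cfg)
  le <- 100 * tab$data$drug1_solubilized / tab$data$drug1_feed
  key <- paste(tab$data$drug1, tab$data$b_monomer, tab$data$nB,
               tab$data$drug1_feed)
  spread <- tapply(le, key, function(v) diff(range(v)))
  expect_true(all(spread < 1e-9))
})

test_that("the worked example is the paclitaxel / A-nPrOzi-A 10:2 case", {
  f <- make_worked_example()
  expect_equal(f$polymer_feed, 10)
  expect_equal(f$drug_feed, 2)
  expect_equal(f$t_days, 0)
  expect_equal(group_key(f), "MeOx|nPrOzi|paclitaxel")
  # descriptor assembly succeeds on every supported subset
  for (s in c("mordred", "rdk5", "ecfp4", "maccs", "sirms-noH")) {
    row <- assemble_feature_row(f, subset = s, fp_width = 2048L,
                                include_3d = FALSE)
    expect_true(all(c("DF", "polymer_feed", "t_measure", "nA1", "nB", "nA2")
                    %in% names(row)))
    expect_false(any(is.na(row[c("DF", "polymer_feed", "t_measure")])))
  }
})

test_that("feature rows separate structure from experimental settings", {
  pool <- drug_pool()
  d <- drug_spec("curcumin", pool$smiles[pool$name == "curcumin"])
  pol <- polymer_spec("MeOx", "nPrOzi", c(35, 20, 35))
  f2 <- formulation(pol, d, 2, 10)
  f8 <- formulation(pol, d, 8, 10)
  r2 <- assemble_feature_row(f2, "rdk5", fp_width = 2048L)
  r8 <- assemble_feature_row(f8, "rdk5", fp_width = 2048L)
  expect_equal(attr(r2, "group_key"), attr(r8, "group_key"))
  expect_false(isTRUE(all.equal(r2[["DF"]], r8[["DF"]])))
  # fingerprint bits differ only through the drug multiplicity
  drug_bits <- grep("^DRUG_", names(r2), value = TRUE)
  ratio <- r8[drug_bits] / r2[drug_bits]
  expect_equal(unname(ratio), rep(4, length(drug_bits)), tolerance = 1e-9)
})
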