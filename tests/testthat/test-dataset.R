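# Table IO, threshold labels and mixtures-out splitting.

test_that("the shipped example table loads and round-trips", {
  path <- system.file("extdata", "example_formulations.csv", package = "poxload")
  tab <- read_formulation_table(path)
  expect_length(tab$rows, 3)
  tf <- tempfile(fileext = ".csv")
  write_formulation_table(tab, tf)
  tab2 <- read_formulation_table(tf)
  expect_equal(tab2$data, tab$data)
  expect_equal(table_group_keys(tab2), table_group_keys(tab))
})

test_that("malformed tables are rejected with row context", {
  path <- system.file("extdata", "example_formulations.csv", package = "poxload")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  bad <- df
  bad$drug1_solubilized[2] <- bad$drug1_feed[2] + 1
  expect_error(formulation_table(bad), "row 2")
  expect_error(formulation_table(df[, setdiff(names(df), "drug1_feed")]),
               "format error")
  extra <- df; extra$mystery <- 1
  expect_warning(formulation_table(extra), "unknown columns")
  # prediction-only rows are kept
  noy <- df; noy$drug1_solubilized <- NA
  tab <- formulation_table(noy)
  expect_length(tab$rows, 3)
  expect_error(label_thresholds(tab, "LC", 10), NA)
  expect_true(all(is.na(label_thresholds(tab, "LC", 10))))
})

test_that("threshold labels are inclusive and nested across the ladder", {
  path <- system.file("extdata", "example_formulations.csv", package = "poxload")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  # engineer LC exactly 40%: m_sol such that m/(m+10) = 0.4 -> m = 20/3
  df$drug1_feed[1] <- 8; df$drug1_solubilized[1] <- 20 / 3
  tab <- formulation_table(df)
  expect_equal(as.character(label_thresholds(tab, "LC", 40))[1], "pos")
  df$drug1_solubilized[1] <- 0.999 * 10 / 9  # LC just below 10
  df$drug1_feed[1] <- 10
  tab <- formulation_table(df)
  expect_equal(as.character(label_thresholds(tab, "LC", 10))[1], "neg")
  # nesting over a synthetic table
  tab <- tiny_table()
  npos <- vapply(c(10, 20, 30, 40), function(t)
    sum(label_thresholds(tab, "LC", t) == "pos"), 0)
  expect_true(all(diff(npos) <= 0))
  npos_le <- vapply(c(20, 40, 60, 80), function(t)
    sum(label_thresholds(tab, "LE", t) == "pos"), 0)
  expect_true(all(diff(npos_le) <= 0))
})

test_that("mixtures-out split partitions rows, keeps groups intact and is reproducible", {
  tab <- tiny_table()
  y <- label_thresholds(tab, "LE", 40)
  sp <- mixtures_out_split(tab, 0.8, seed = 13, labels = y)
  n <- length(tab$rows)
  expect_setequal(c(sp$ts, sp$hs), seq_len(n))
  expect_length(intersect(sp$ts, sp$hs), 0)
  keys <- table_group_keys(tab)
  expect_length(intersect(unique(keys[sp$ts]), unique(keys[sp$hs])), 0)
  sp2 <- mixtures_out_split(tab, 0.8, seed = 13, labels = y)
  expect_identical(sp, sp2)
  sp3 <- mixtures_out_split(tab, 0.8, seed = 14, labels = y)
  expect_false(identical(sp$assignment, sp3$assignment))
})

test_that("exactly divisible equal groups split to the target fraction", {
  pool <- drug_pool()[1:10, ]
  df <- do.call(rbind, lapply(1:10, function(i) {
    data.frame(a_monomer = "MeOx", b_monomer = "nBuOx", nA1 = 35, nB = 20,
               nA2 = 35, terminus_start = "Me", terminus_end = "Pip",
               polymer_feed = 10, drug1 = pool$name[i],
               drug1_smiles = pool$smiles[i],
               drug1_feed = c(2, 6), drug1_solubilized = c(1, 2),
               t_days = 0, stringsAsFactors = FALSE)
  }))
  tab <- formulation_table(df)
  for (seed in c(1, 7, 99)) {
    sp <- mixtures_out_split(tab, 0.8, seed = seed)
    expect_length(sp$ts, 16)
    expect_length(sp$hs, 4)
  }
})

test_that("holdout prevalence stays near the full-set prevalence", {
  tab <- tiny_table(200, seed = 21)
  y <- label_thresholds(tab, "LE", 40)
  p_all <- mean(y == "pos")
  devs <- vapply(1:30, function(s) {
    sp <- mixtures_out_split(tab, 0.8, seed = s, labels = y)
    mean(y[sp$hs] == "pos") - p_all
  }, numeric(1))
  expect_lt(mean(abs(devs)), 0.06)
})
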