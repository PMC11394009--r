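# Shared fixtures, built lazily and cached for the test session.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

tiny_table <- function(n = 120, seed = 7) {
  fixture(paste0("table", n, "_", seed), function() {
    generate_formulation_dataset(generator_config(n_formulations = n, seed = seed))
  })
}

tiny_features <- function(n = 120, seed = 7) {
  fixture(paste0("feat", n, "_", seed), function() {
    assemble_feature_matrix(tiny_table(n, seed), subset = "mordred",
                            include_3d = FALSE)
  })
}

fast_config <- function(seed = 1) {
  pox_config(repeats = 2, tune_length = 3, seed = seed,
             boruta_runs = 12, num_trees = 150)
}

tiny_ensemble <- function() {
  fixture("ensemble", function() {
    tab <- tiny_table(160, seed = 5)
    pox_ensemble(tab, subset = "mordred", family = "RF",
                 config = pox_config(repeats = 1, tune_length = 2,
                                     boruta = FALSE, seed = 5,
                                     num_trees = 120),
                 include_3d = FALSE)
  })
}

# independent brute-force simplex enumerator (combn over atom subsets,
# canonical key by exhaustive permutation) used as the oracle for the
# Rcpp engine
brute_simplexes <- function(mol, scheme = "atom", explicit_h = FALSE) {
  lb <- label_atoms(mol, schemes = scheme, explicit_h = explicit_h)
  n <- lb$natoms
  if (n < 4) return(data.frame(key = character(0), count = numeric(0)))
  A <- matrix(FALSE, n, n)
  b <- lb$bonds
  for (e in seq_len(nrow(b))) A[b[e, 1], b[e, 2]] <- A[b[e, 2], b[e, 1]] <- TRUE
  labs <- lb$labels[[1]]
  perms <- as.matrix(expand.grid(rep(list(1:4), 4)))
  perms <- perms[apply(perms, 1, function(p) length(unique(p)) == 4), ]
  pair_idx <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  keys <- apply(utils::combn(n, 4), 2, function(ix) {
    cand <- apply(perms, 1, function(p) {
      q <- ix[p]
      bits <- paste(as.integer(A[cbind(q[pair_idx[, 1]], q[pair_idx[, 2]])]),
                    collapse = "")
      paste0(paste(labs[q], collapse = ","), "|", bits)
    })
    min(cand)
  })
  agg <- table(keys)
  data.frame(key = names(agg), count = as.numeric(agg), stringsAsFactors = FALSE)
}

random_formulation <- function() {
  pool <- drug_pool()
  i <- sample(nrow(pool), 1)
  d <- poxload:::cached_drug(pool$name[i], pool$smiles[i])
  pol <- poxload:::cached_polymer("MeOx", sample(c("nPrOzi", "nBuOx", "BzOx"), 1),
                                  c(sample(20:50, 1), sample(10:30, 1),
                                    sample(20:50, 1)), "Me", "Pip")
  formulation(pol, d, drug_feed = stats::runif(1, 1, 10),
              polymer_feed = stats::runif(1, 5, 20),
              t_days = sample(c(0, 7, 30), 1),
              m_solubilized = NA)
}
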