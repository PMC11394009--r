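# Synthetic formulation tables with a planted structure-loading relationship.
#
# The generator emulates the schema of an experimental solubilization table
# (one row per formulation x time point) and plants an additive-logistic rule
# in interpretable properties: more hydrogen-bond donors on the drug help
# loading, a mid-range drug logP window helps, longer hydrophobic B blocks
# help, higher drug feed lowers the achievable loading efficiency, and
# storage time decays it exponentially. Noise is Gaussian on the efficiency
# scale and the solubilized mass is clamped to [0, drug feed], so generated
# tables always pass the table validation.

#' Built-in hydrophobic drug pool
#'
#' @return data.frame with `name` and `smiles` of the shipped drug library
#' @export
drug_pool <- function() {
  utils::read.delim(system.file("extdata", "drug_smiles.tsv", package = "poxload"),
                    stringsAsFactors = FALSE)
}

#' Generator configuration
#'
#' @param n_formulations number of rows
#' @param seed integer seed; a fixed seed reproduces the table byte for byte
#' @param drugs drug pool data.frame (name, smiles)
#' @param b_monomers B-block monomer names sampled for polymers
#' @param block_lengths list of `(nA1, nB, nA2)` candidates
#' @param polymer_feed fixed polymer feed (g/L)
#' @param df_levels drug-feed grid (g/L)
#' @param t_levels measurement time points (days)
#' @param coef planted-rule coefficients: intercept, per hydrogen-bond donor,
#'   logP window indicator, per B-block monomer, per g/L drug feed
#' @param logp_window drug logP window considered favourable
#' @param decay storage-time decay rate (1/day)
#' @param noise_sd Gaussian noise on the loading-efficiency fraction
#' @export
generator_config <- function(n_formulations = 500, seed = 42,
                             drugs = drug_pool(),
                             b_monomers = c("nPrOx", "nPrOzi", "nBuOx",
                                            "nBuOzi", "BzOx"),
                             block_lengths = list(c(35, 20, 35), c(25, 15, 25),
                                                  c(50, 30, 50)),
                             polymer_feed = 10,
                             df_levels = c(2, 4, 6, 8, 10),
                             t_levels = c(0, 1, 7, 30, 180),
                             coef = c(intercept = -6, hbd = 2.2,
                                      logp_window = 4.5, b_length = 0.18,
                                      df = -0.7),
                             logp_window = c(2, 5),
                             decay = 0.008, noise_sd = 0.05) {
  if (!nrow(drugs) || !length(b_monomers)) {
    stop("configuration error: empty drug or polymer pool", call. = FALSE)
  }
  list(n_formulations = n_formulations, seed = seed, drugs = drugs,
       b_monomers = b_monomers, block_lengths = block_lengths,
       polymer_feed = polymer_feed, df_levels = df_levels,
       t_levels = t_levels, coef = coef, logp_window = logp_window,
       decay = decay, noise_sd = noise_sd)
}

#' @keywords internal
drug_pool_properties <- function(drugs) {
  key <- paste0("pool|", paste(drugs$smiles, collapse = ";"))
  hit <- .spec_cache[[key]]
  if (!is.null(hit)) return(hit)
  props <- do.call(rbind, lapply(drugs$smiles, ob_properties))
  props$name <- drugs$name
  .spec_cache[[key]] <- props
  props
}

#' Generate a synthetic formulation table
#'
#' @param config a [generator_config()]
#' @return a `pox_formulation_table`
#' @export
generate_formulation_dataset <- function(config = generator_config()) {
  props <- drug_pool_properties(config$drugs)
  n <- config$n_formulations
  co <- config$coef
  df <- with_seed(config$seed, {
    di <- sample(nrow(config$drugs), n, replace = TRUE)
    bi <- sample(config$b_monomers, n, replace = TRUE)
    bl <- config$block_lengths[sample(length(config$block_lengths), n,
                                      replace = TRUE)]
    dfv <- sample(config$df_levels, n, replace = TRUE)
    tv <- sample(config$t_levels, n, replace = TRUE)
    eps <- stats::rnorm(n, 0, config$noise_sd)
    inwin <- props$logP[di] >= config$logp_window[1] &
      props$logP[di] <= config$logp_window[2]
    lin <- co[["intercept"]] + co[["hbd"]] * props$HBD[di] +
      co[["logp_window"]] * as.numeric(inwin) +
      co[["b_length"]] * vapply(bl, `[`, numeric(1), 2) +
      co[["df"]] * dfv
    le_frac <- stats::plogis(lin) * exp(-config$decay * tv) + eps
    msol <- round(pmin(pmax(le_frac * dfv, 0), dfv), 4)
    data.frame(
      a_monomer = "MeOx", b_monomer = bi,
      nA1 = vapply(bl, `[`, numeric(1), 1),
      nB = vapply(bl, `[`, numeric(1), 2),
      nA2 = vapply(bl, `[`, numeric(1), 3),
      terminus_start = "Me", terminus_end = "Pip",
      polymer_feed = config$polymer_feed,
      drug1 = config$drugs$name[di],
      drug1_smiles = config$drugs$smiles[di],
      drug1_feed = dfv, drug1_solubilized = msol,
      t_days = tv, stringsAsFactors = FALSE)
  })
  formulation_table(df, provenance = sprintf("synthetic(seed=%d)", config$seed))
}

#' The worked-example formulation
#'
#' Paclitaxel loaded into A-nPrOzi-A micelles at a 10/2 polymer-drug mass
#' ratio, measured immediately; used in the documentation and as a descriptor
#' smoke-test input.
#' @return a `pox_formulation`
#' @export
make_worked_example <- function() {
  pool <- drug_pool()
  ptx <- cached_drug("paclitaxel", pool$smiles[pool$name == "paclitaxel"])
  pol <- cached_polymer("MeOx", "nPrOzi", c(35, 20, 35), "Me", "Pip")
  formulation(pol, ptx, drug_feed = 2, polymer_feed = 10, t_days = 0)
}
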