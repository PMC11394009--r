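# Drugs, formulations, stoichiometry and the LC/LE loading metrics.

#' Construct a drug specification
#'
#' @param name drug name
#' @param smiles structure SMILES; must parse to a single connected molecule
#' @param mw optional molar mass override (g/mol)
#' @return object of class `pox_drug`
#' @export
drug_spec <- function(name, smiles, mw = NULL) {
  mol <- parse_smiles(smiles, name = name)
  if (!mol_is_connected(mol)) {
    stop("drug structure must be a single connected molecule: ", name, call. = FALSE)
  }
  mw <- if (is.null(mw)) mol_weight(mol) else mw
  if (mw <= 0) stop("mw_drug must be positive", call. = FALSE)
  structure(list(name = name, smiles = smiles, mol = mol, mw_drug = mw),
            class = "pox_drug")
}

#' @export
print.pox_drug <- function(x, ...) {
  cat(sprintf("<pox_drug> %s (%.2f g/mol) %s\n", x$name, x$mw_drug, x$smiles))
  invisible(x)
}

#' Construct a formulation
#'
#' One solubilization experiment: a polymer, one or two drugs with their feeds,
#' the polymer feed, the measurement time point and (when measured) the
#' solubilized drug mass.
#'
#' @param polymer a `pox_polymer`
#' @param drugs a `pox_drug` or list of up to two
#' @param drug_feed numeric vector of drug feeds (g/L), one per drug
#' @param polymer_feed polymer feed (g/L)
#' @param t_days measurement time point (days, >= 0)
#' @param m_solubilized solubilized drug mass per drug (g/L); NA for
#'   prediction-only rows
#' @param settings optional free-form list of experimental metadata
#' @return object of class `pox_formulation`
#' @export
formulation <- function(polymer, drugs, drug_feed, polymer_feed,
                        t_days = 0, m_solubilized = NA_real_, settings = list()) {
  if (inherits(drugs, "pox_drug")) drugs <- list(drugs)
  if (!length(drugs) || length(drugs) > 2) {
    stop("a formulation carries 1-2 drugs", call. = FALSE)
  }
  drug_feed <- as.numeric(drug_feed)
  m_solubilized <- rep_len(as.numeric(m_solubilized), length(drugs))
  if (length(drug_feed) != length(drugs)) {
    stop("drug_feed must match the number of drugs", call. = FALSE)
  }
  if (any(drug_feed <= 0) || polymer_feed <= 0) {
    stop("all feeds must be positive", call. = FALSE)
  }
  if (t_days < 0) stop("t_days must be >= 0", call. = FALSE)
  meas <- !is.na(m_solubilized)
  if (any(m_solubilized[meas] < 0) ||
      any(m_solubilized[meas] > drug_feed[meas] + 1e-9)) {
    stop("m_solubilized must lie in [0, drug feed]", call. = FALSE)
  }
  structure(list(polymer = polymer, drugs = drugs, drug_feed = drug_feed,
                 polymer_feed = polymer_feed, t_days = t_days,
                 m_solubilized = m_solubilized, settings = settings),
            class = "pox_formulation")
}

#' @export
print.pox_formulation <- function(x, ...) {
  cat(sprintf("<pox_formulation> %s + %s | feeds %s / %.1f g/L, t = %g d\n",
              x$polymer$name,
              paste(vapply(x$drugs, `[[`, "", "name"), collapse = "+"),
              paste(sprintf("%.2g", x$drug_feed), collapse = "+"),
              x$polymer_feed, x$t_days))
  invisible(x)
}

#' Mixture identity used for mixtures-out splitting
#'
#' The key joins the A monomer, the B monomer and the sorted drug names;
#' formulations differing only in feeds, block lengths or time points share it.
#' @param x a `pox_formulation`
#' @export
group_key <- function(x) {
  paste(x$polymer$a_monomer$name, x$polymer$b_monomer$name,
        paste(sort(vapply(x$drugs, `[[`, "", "name")), collapse = "+"),
        sep = "|")
}

#' Number of drug molecules per polymer chain
#'
#' `N_drug = (m_added / m_polymer_feed) * (MW_polymer / MW_drug)`; kept
#' fractional.
#' @param x a `pox_formulation`
#' @return numeric vector, one value per drug
#' @export
drugs_per_chain <- function(x) {
  if (x$polymer_feed <= 0) stop("polymer feed must be positive", call. = FALSE)
  vapply(seq_along(x$drugs), function(d) {
    (x$drug_feed[d] / x$polymer_feed) *
      (x$polymer$mw_polymer / x$drugs[[d]]$mw_drug)
  }, numeric(1))
}

#' Molar fractions of all micellar components
#'
#' Counts per chain are the block lengths, the two termini and the (fractional)
#' drugs per chain; fractions are counts over the total.
#'
#' @param x a `pox_formulation`
#' @return data.frame (class `pox_stoichiometry`) with columns `component`
#'   (T1, A, B, T2, drug names), `class`, `N` (count per chain) and `n`
#'   (molar fraction); `sum(n) == 1`.
#' @export
molar_fractions <- function(x) {
  bl <- x$polymer$block_lengths
  nd <- drugs_per_chain(x)
  comp <- data.frame(
    component = c(x$polymer$termini[[1]]$name, x$polymer$a_monomer$name,
                  x$polymer$b_monomer$name, x$polymer$termini[[2]]$name,
                  vapply(x$drugs, `[[`, "", "name")),
    class = c("T1", "A", "B", "T2", paste0("drug", seq_along(x$drugs))),
    N = c(1, bl[1] + bl[3], bl[2], 1, nd),
    stringsAsFactors = FALSE)
  comp$n <- comp$N / sum(comp$N)
  class(comp) <- c("pox_stoichiometry", "data.frame")
  comp
}

#' Loading capacity and loading efficiency
#'
#' `LC = 100 * m_sol / (m_sol + m_polymer_feed)` (complete polymer dissolution
#' assumed) and `LE = 100 * m_sol / m_added`, both in percent. For
#' coformulations the LC drug term defaults to the drug's own solubilized mass;
#' `coformulation_lc = "total"` uses the total solubilized cargo instead.
#'
#' @param x a `pox_formulation` with measured solubilization
#' @param coformulation_lc `"per_drug"` (default) or `"total"`
#' @return data.frame with one row per drug: `drug`, `LC`, `LE`; the formula
#'   convention is recorded in the `"lc_formula"`/`"le_formula"` attributes.
#' @export
loading_metrics <- function(x, coformulation_lc = c("per_drug", "total")) {
  coformulation_lc <- match.arg(coformulation_lc)
  if (any(is.na(x$m_solubilized))) {
    stop("m_solubilized missing: metrics undefined", call. = FALSE)
  }
  if (any(x$drug_feed <= 0)) stop("domain error: m_added must be > 0", call. = FALSE)
  msol <- x$m_solubilized
  lc_drug_term <- if (coformulation_lc == "total") rep(sum(msol), length(msol)) else msol
  out <- data.frame(
    drug = vapply(x$drugs, `[[`, "", "name"),
    LC = 100 * msol / (lc_drug_term + x$polymer_feed),
    LE = 100 * msol / x$drug_feed,
    stringsAsFactors = FALSE)
  attr(out, "lc_formula") <- "LC = 100 * m_sol / (m_sol + m_polymer_feed)"
  attr(out, "le_formula") <- "LE = 100 * m_sol / m_added"
  attr(out, "coformulation_lc") <- coformulation_lc
  out
}
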