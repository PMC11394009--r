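# Physicochemical descriptor backend and molar-fraction mixture weighting.
#
# The backend computes, for a capped building block or a drug molecule:
#  * molecular-connectivity chi indices of orders 0-7 in the four subgraph
#    classes (path Xp, chain/ring Xch, cluster Xc, path-cluster Xpc), each with
#    sigma-electron (d) and valence-electron (dv) vertex weighting,
#  * Moreau-Broto autocorrelations ATS/ATSC over lags 0-6 for atomic number,
#    mass, van der Waals volume, polarizability and electronegativity,
#  * the detour-matrix spectral descriptor SpMAD_Dt,
#  * an ESOL-style group/property-contribution logS,
#  * rotatable-bond counts, OpenBabel logP/MR/TPSA/HBD/HBA and size terms,
#  * optionally 3D-MoRSE signals from a single deterministic conformer.

.descriptor_cache <- new.env(parent = emptyenv())

#' @keywords internal
chi_descriptors <- function(mol) {
  w <- mol_deltas(mol)
  res <- cpp_chi_subgraphs(n_heavy(mol), mol$bonds, w, 7L)
  out <- c()
  orders <- list(p = 0:7, ch = 3:7, c = 3:7, pc = 4:7)
  for (wi in 1:2) {
    wname <- c("d", "dv")[wi]
    s <- res$sums[[wi]]
    # order 0: vertex sum, path class by convention
    d0 <- w[, wi]
    s["p", 1] <- sum(1 / sqrt(d0[d0 > 0]))
    for (ty in names(orders)) {
      for (k in orders[[ty]]) {
        out[sprintf("X%s-%d%s", ty, k, wname)] <- s[ty, k + 1]
      }
    }
  }
  out
}

#' @keywords internal
autocorrelation_descriptors <- function(mol, max_lag = 6L) {
  a <- mol$atoms
  props <- list(
    Z = a$Z,
    m = .elem_lookup(a$elem, "mass"),
    v = (4 / 3) * pi * .elem_lookup(a$elem, "vdw")^3,
    p = .elem_lookup(a$elem, "pol"),
    e = .elem_lookup(a$elem, "en"))
  D <- mol_distances(mol)
  out <- c()
  for (pn in names(props)) {
    w <- props[[pn]]
    wc <- w - mean(w)
    for (k in 0:max_lag) {
      if (k == 0) {
        ats <- sum(w^2); atsc <- sum(wc^2)
      } else {
        sel <- D == k & upper.tri(D)
        ats <- sum(outer(w, w)[sel])
        atsc <- sum(outer(wc, wc)[sel])
      }
      out[sprintf("ATS%d%s", k, pn)] <- ats
      out[sprintf("ATSC%d%s", k, pn)] <- atsc
    }
  }
  out
}

#' @keywords internal
spmad_detour <- function(mol) {
  n <- n_heavy(mol)
  if (n < 2) return(0)
  D <- cpp_detour_matrix(n, mol$bonds)
  if (D[1, 1] < 0) return(NA_real_)
  ev <- eigen(D, symmetric = TRUE, only.values = TRUE)$values
  mean(abs(ev - mean(ev)))
}

#' @keywords internal
morse_descriptors <- function(smiles, weights_pol, n_s = 8L) {
  xyz <- mol_coords_3d(smiles)
  out <- stats::setNames(rep(NA_real_, 2L * n_s),
                         c(sprintf("Mor%02du", seq_len(n_s)),
                           sprintf("Mor%02dp", seq_len(n_s))))
  if (is.null(xyz) || nrow(xyz) != length(weights_pol)) return(out)
  r <- as.matrix(stats::dist(xyz))
  ut <- upper.tri(r)
  rr <- r[ut]
  wu <- rep(1, length(weights_pol))
  wp <- weights_pol / .ELEMENTS$pol[.ELEMENTS$elem == "C"]
  for (s in seq_len(n_s)) {
    sc <- s - 1L
    kern <- if (sc == 0) rep(1, length(rr)) else sin(sc * rr) / (sc * rr)
    out[sprintf("Mor%02du", s)] <- sum(outer(wu, wu)[ut] * kern)
    out[sprintf("Mor%02dp", s)] <- sum(outer(wp, wp)[ut] * kern)
  }
  out
}

#' Compute the descriptor vector of a single component
#'
#' @param x a `pox_mol`, `pox_drug`, `pox_monomer` or SMILES string (monomers
#'   are represented by their capped structures).
#' @param include_3d compute 3D-MoRSE terms from a generated conformer
#'   (deterministic builder + force-field clean-up); slightly slower.
#' @return named numeric vector; the `"backend_id"` attribute records the
#'   engine configuration. Failed descriptors are NA (filtered later in the
#'   preprocessing stage).
#' @export
component_descriptors <- function(x, include_3d = TRUE) {
  if (inherits(x, "pox_drug")) x <- x$mol
  if (inherits(x, "pox_monomer")) x <- x$capped
  if (is.character(x)) x <- parse_smiles(x)
  stopifnot(inherits(x, "pox_mol"))
  key <- paste0(x$smiles, "|3d=", include_3d)
  hit <- .descriptor_cache[[key]]
  if (!is.null(hit)) return(hit)

  a <- x$atoms
  nb <- nrow(x$bonds)
  nrot <- count_rotatable_bonds(x)
  obp <- tryCatch(ob_properties(x$smiles),
                  error = function(e) data.frame(logP = NA, MR = NA, MW = NA,
                                                 TPSA = NA, HBD = NA, HBA = NA))
  arom_prop <- if (nrow(a)) mean(a$aromatic) else 0
  logS <- 0.16 - 0.63 * obp$logP - 0.0062 * mol_weight(x) +
    0.066 * nrot - 0.74 * arom_prop
  base <- c(
    MW = mol_weight(x), nHeavy = nrow(a), nBonds = nb,
    nRing = sum(a$in_ring), nAromAtom = sum(a$aromatic),
    nRot = nrot, RotRatio = if (nb > 0) nrot / nb else 0,
    nHBDon = obp$HBD, nHBAcc = obp$HBA, TPSA = obp$TPSA,
    SLogP = obp$logP, SMR = obp$MR, FilterItLogS = logS,
    SpMAD_Dt = spmad_detour(x))
  out <- c(base, chi_descriptors(x), autocorrelation_descriptors(x))
  if (include_3d) {
    out <- c(out, morse_descriptors(x$smiles, .elem_lookup(a$elem, "pol")))
  }
  attr(out, "backend_id") <-
    paste0("poxload-graph-backend/0.1; openbabel-props; crippen-style-atomic; ",
           "conformer=obbuilder+ff-cleanup; 3d=", include_3d,
           "; eeq/alp/H-bond-strength schemes omitted")
  .descriptor_cache[[key]] <- out
  out
}

#' Molar-fraction weighted mixture descriptors
#'
#' `DESC_MIX[d] = sum_i n_i * DESC_i[d]` over the mixture components.
#'
#' @param components list of descriptor vectors from
#'   [component_descriptors()]; all must share one descriptor name set.
#' @param fractions numeric vector of molar fractions, one per component
#'   (renormalised to sum to one).
#' @return named numeric vector of the same length as each input.
#' @export
mix_descriptors <- function(components, fractions) {
  stopifnot(length(components) == length(fractions))
  if (!length(components)) stop("no components", call. = FALSE)
  nm <- names(components[[1]])
  for (v in components) {
    if (!identical(names(v), nm)) {
      stop("configuration error: descriptor name sets differ between components",
           call. = FALSE)
    }
  }
  if (any(fractions < 0)) stop("negative molar fraction", call. = FALSE)
  tot <- sum(fractions)
  if (tot <= 0) stop("fractions sum to zero", call. = FALSE)
  w <- fractions / tot
  out <- stats::setNames(numeric(length(nm)), nm)
  for (i in seq_along(components)) {
    out <- out + w[i] * unclass(components[[i]])[nm]
  }
  out
}
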