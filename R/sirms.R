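# SiRMS-style simplex descriptors: atoms are labelled by binned atomic
# properties, every tetraatomic subset of a structure (bound = connected,
# unbound = split into up to three fragments) is counted under labelled-graph
# isomorphism, and mixture simplexes combine fragments of the polymer
# (represented by its pseudotrimer) and the drug(s), weighted by molar
# fractions (doubled minor-component fraction for cross-component simplexes).

.BIN_SCHEMES <- list(
  logp = c(-0.5, 0, 0.5),
  mr   = c(1.5, 3, 8),
  eeq  = c(-0.28, 0, 0.28),
  alp  = c(6, 9, 12),
  sa   = c(0.5, 0.75, 1),
  sdx  = c(0.5, 0.75, 1),
  sdc  = c(0.5, 0.75, 1)
)

#' Property-binning scheme for SiRMS atom labelling
#'
#' Numeric schemes map a per-atom property value to labels A-D through three
#' ascending cutpoints with inclusive upper bounds (`A <= c1 < B <= c2 < C <=
#' c3 < D`); the `atom` scheme labels by atomic number and hybridisation
#' (e.g. `6>sp2`).
#'
#' @param property_id one of `"logp"`, `"mr"`, `"eeq"`, `"alp"`, `"sa"`,
#'   `"sdx"`, `"sdc"`, `"atom"`
#' @param cutpoints optional override of the three cutpoints
#' @export
property_bin_scheme <- function(property_id, cutpoints = NULL) {
  if (property_id == "atom") {
    return(structure(list(property_id = "atom", cutpoints = NULL),
                     class = "pox_bin_scheme"))
  }
  if (is.null(cutpoints)) cutpoints <- .BIN_SCHEMES[[property_id]]
  if (is.null(cutpoints)) stop("unknown property scheme: ", property_id, call. = FALSE)
  if (length(cutpoints) != 3 || any(diff(cutpoints) <= 0)) {
    stop("cutpoints must be three strictly ascending values", call. = FALSE)
  }
  structure(list(property_id = property_id, cutpoints = cutpoints),
            class = "pox_bin_scheme")
}

#' Bin an atomic property value into a label
#'
#' Inclusive upper bounds: a value equal to a cutpoint takes the lower label.
#' @param value numeric value(s)
#' @param scheme a `pox_bin_scheme`
#' @return character vector of labels in `A`-`D`
#' @export
bin_atomic_property <- function(value, scheme) {
  if (scheme$property_id == "atom") {
    stop("the atom scheme is categorical; use label_atoms()", call. = FALSE)
  }
  if (any(is.na(value))) stop("input error: NaN property value", call. = FALSE)
  cp <- scheme$cutpoints
  ifelse(value <= cp[1], "A",
         ifelse(value <= cp[2], "B", ifelse(value <= cp[3], "C", "D")))
}

#' Label every atom of a structure under one or more schemes
#'
#' The default backend supplies the `atom` (atomic number + hybridisation)
#' and Crippen-style `logp`/`mr` schemes. Schemes relying on externally
#' computed per-atom values (`eeq`, `alp`, `sa`, `sdx`, `sdc`) accept those
#' values through `external`; requesting one without values is a
#' configuration error.
#'
#' @param mol a `pox_mol`
#' @param schemes character vector of scheme ids
#' @param explicit_h include explicit hydrogens as labelled vertices
#' @param external named list of per-atom numeric vectors for plug-in schemes
#' @return list with `labels` (data.frame, one column per scheme), `bonds`
#'   (bond matrix of the labelled graph) and `natoms`.
#' @export
label_atoms <- function(mol, schemes = c("atom", "logp", "mr"),
                        explicit_h = FALSE, external = list()) {
  stopifnot(inherits(mol, "pox_mol"))
  n_hv <- n_heavy(mol)
  if (explicit_h) {
    elem <- mol$atoms_all$elem
    natoms <- length(elem)
    bonds <- mol$bonds_all
    heavy_idx <- which(elem != "H")
  } else {
    elem <- mol$atoms$elem
    natoms <- n_hv
    bonds <- mol$bonds
    heavy_idx <- seq_len(n_hv)
  }
  crip <- NULL
  labels <- list()
  for (sc in schemes) {
    if (sc == "atom") {
      hyb <- rep("s", natoms)
      hyb[heavy_idx] <- mol$atoms$hyb
      z <- rep(1L, natoms)
      z[heavy_idx] <- mol$atoms$Z
      labels[[sc]] <- paste0(z, ">", hyb)
    } else if (sc %in% c("logp", "mr")) {
      if (is.null(crip)) crip <- crippen_atomic(mol, hydrogens = explicit_h)
      v <- crip[[if (sc == "logp") "logp" else "mr"]]
      labels[[sc]] <- bin_atomic_property(v, property_bin_scheme(sc))
    } else {
      v <- external[[sc]]
      if (is.null(v)) {
        stop("configuration error: no backend for scheme '", sc,
             "'; supply per-atom values via `external`", call. = FALSE)
      }
      if (length(v) != natoms) stop("external values length mismatch", call. = FALSE)
      labels[[sc]] <- bin_atomic_property(v, property_bin_scheme(sc))
    }
  }
  list(labels = as.data.frame(labels, stringsAsFactors = FALSE),
       bonds = bonds, natoms = natoms)
}

#' @keywords internal
decode_simplex_keys <- function(df, levels, origins = NULL) {
  if (!nrow(df)) return(character(0))
  vapply(seq_len(nrow(df)), function(r) {
    parts <- strsplit(df$key[r], "|", fixed = TRUE)[[1]]
    lab <- paste(levels[as.integer(strsplit(parts[1], ".", fixed = TRUE)[[1]]) + 1L],
                 collapse = ",")
    key <- paste0(lab, "|", parts[2])
    if (!is.null(origins)) {
      o <- as.integer(strsplit(parts[3], "")[[1]]) + 1L
      key <- paste0(key, "|", paste(origins[o], collapse = "."))
    }
    key
  }, character(1))
}

#' Enumerate the simplexes of one labelled structure
#'
#' Counts every 4-atom subset keyed by its label multiset and induced bond
#' topology (up to isomorphism of the labelled subgraph). Connected patterns
#' are bound simplexes; disconnected ones are unbound.
#'
#' @param mol a `pox_mol`
#' @param scheme scheme id passed to [label_atoms()]
#' @param explicit_h include explicit hydrogens
#' @param external see [label_atoms()]
#' @return data.frame (class `pox_simplex_vector`) with `key`, `count`,
#'   `nfrag` (fragments = connected components of the simplex).
#' @export
enumerate_simplexes <- function(mol, scheme = "atom", explicit_h = FALSE,
                                external = list()) {
  lb <- label_atoms(mol, schemes = scheme, explicit_h = explicit_h,
                    external = external)
  if (lb$natoms < 4) {
    out <- data.frame(key = character(0), count = numeric(0), nfrag = integer(0))
    class(out) <- c("pox_simplex_vector", "data.frame")
    return(out)
  }
  f <- factor(lb$labels[[1]])
  raw <- cpp_simplexes(lb$natoms, lb$bonds, as.integer(f) - 1L,
                       integer(lb$natoms), 1.0, 0L)
  out <- data.frame(key = decode_simplex_keys(raw, levels(f)),
                    count = raw$count, nfrag = raw$nfrag,
                    stringsAsFactors = FALSE)
  out <- out[order(out$key), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("pox_simplex_vector", "data.frame")
  out
}

#' Mixture simplex descriptors
#'
#' Single-component simplexes (SiRMS-S) are weighted by the component's molar
#' fraction; simplexes combining fragments of 2-3 distinct components
#' (SiRMS-M) are weighted by twice the smallest molar fraction among the
#' involved components. Simplexes with more than `frag_cap` unbound fragments
#' are dropped. Components are tagged `P` (polymer pseudotrimer), `D1`, `D2`.
#'
#' @param components list of `pox_mol` (first the polymer pseudotrimer, then
#'   1-2 drugs)
#' @param fractions molar fraction per component (polymer fraction = sum of
#'   its monomer/termini fractions)
#' @param scheme,explicit_h,external see [label_atoms()]
#' @param frag_cap maximum number of unbound fragments per simplex (default 3)
#' @param cap_single also apply the fragment cap to single-component simplexes
#' @return `pox_simplex_vector` data.frame with origin-tagged keys
#' @export
mixture_simplexes <- function(components, fractions, scheme = "atom",
                              explicit_h = FALSE, external = list(),
                              frag_cap = 3L, cap_single = TRUE) {
  if (length(components) > 3) {
    stop("unsupported: more than 3 mixture components", call. = FALSE)
  }
  stopifnot(length(fractions) == length(components))
  labs <- list(); bonds <- list(); origin <- integer(0); natoms <- 0L
  for (i in seq_along(components)) {
    ext_i <- if (length(external)) external[[i]] else list()
    lb <- label_atoms(components[[i]], schemes = scheme,
                      explicit_h = explicit_h, external = ext_i)
    labs[[i]] <- lb$labels[[1]]
    b <- lb$bonds
    if (nrow(b)) b[, 1:2] <- b[, 1:2] + natoms
    bonds[[i]] <- b
    origin <- c(origin, rep(i - 1L, lb$natoms))
    natoms <- natoms + lb$natoms
  }
  all_lab <- factor(unlist(labs))
  bmat <- do.call(rbind, bonds)
  raw <- cpp_simplexes(natoms, bmat, as.integer(all_lab) - 1L, origin,
                       as.numeric(fractions), 1L, as.integer(frag_cap),
                       cap_single)
  onames <- c("P", "D1", "D2")[seq_along(components)]
  out <- data.frame(key = decode_simplex_keys(raw, levels(all_lab), onames),
                    count = raw$count, nfrag = raw$nfrag,
                    stringsAsFactors = FALSE)
  out <- stats::aggregate(cbind(count = out$count) ~ key, data = out, FUN = sum)
  out$nfrag <- NA_integer_
  out <- out[order(out$key), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("pox_simplex_vector", "data.frame")
  out
}
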