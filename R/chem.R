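# Molecule parsing and light-weight graph chemistry on top of OpenBabel
# (ChemmineOB) and ChemmineR. A parsed molecule ("pox_mol") keeps the full
# hydrogen-explicit graph plus a heavy-atom view; all graph descriptors work on
# these tables.

# element data: atomic number, monoisotopic-ish average mass, valence electrons,
# van der Waals radius (A), static polarizability (A^3), Pauling electronegativity
.ELEMENTS <- data.frame(
  elem = c("H",  "B",   "C",   "N",   "O",   "F",   "Si",  "P",   "S",   "Cl",  "Br",  "I"),
  Z    = c(1,    5,     6,     7,     8,     9,     14,    15,    16,    17,    35,    53),
  mass = c(1.008, 10.811, 12.011, 14.007, 15.999, 18.998, 28.086, 30.974, 32.06, 35.453, 79.904, 126.904),
  Zv   = c(1,    3,     4,     5,     6,     7,     4,     5,     6,     7,     7,     7),
  vdw  = c(1.20, 1.92,  1.70,  1.55,  1.52,  1.47,  2.10,  1.80,  1.80,  1.75,  1.85,  1.98),
  pol  = c(0.67, 3.03,  1.76,  1.10,  0.80,  0.56,  5.38,  3.63,  2.90,  2.18,  3.05,  5.35),
  en   = c(2.20, 2.04,  2.55,  3.04,  3.44,  3.98,  1.90,  2.19,  2.58,  3.16,  2.96,  2.66),
  stringsAsFactors = FALSE
)

.elem_lookup <- function(elem, what) {
  idx <- match(elem, .ELEMENTS$elem)
  out <- .ELEMENTS[[what]][idx]
  out[elem == "*"] <- 0
  out
}

#' Parse a SMILES string into a molecular graph
#'
#' Converts the SMILES through OpenBabel into an SDF block with explicit
#' hydrogens, reads it back with ChemmineR and assembles atom and bond tables.
#' Attachment points for polymer repeat units are written as the dummy atom
#' `[*]`; dummies carry zero mass and are preserved in the graph.
#'
#' @param smiles single SMILES string (may contain `[*]` attachment markers).
#' @param name optional molecule name stored on the object.
#' @return an object of class `pox_mol` with elements `atoms` (element, Z,
#'   charge, nH, degree, aromatic flag, hybridisation), `bonds` (heavy-atom
#'   bond matrix `i, j, order`), `atoms_all`/`bonds_all` (hydrogen-explicit
#'   graph), `name` and `smiles`.
#' @export
parse_smiles <- function(smiles, name = NULL) {
  stopifnot(is.character(smiles), length(smiles) == 1L, nzchar(smiles))
  sdf <- tryCatch(
    suppressWarnings(ChemmineOB::convertFormat(
      "SMI", "SDF", paste0(smiles, "\n"),
      options = data.frame(names = "h", args = "", stringsAsFactors = FALSE))),
    error = function(e) stop("SMILES parse failure: ", smiles, call. = FALSE))
  if (!nzchar(sdf) || !grepl("V2000", sdf, fixed = TRUE))
    stop("SMILES parse failure: ", smiles, call. = FALSE)
  tf <- tempfile(fileext = ".sdf")
  on.exit(unlink(tf), add = TRUE)
  writeLines(sdf, tf)
  set <- suppressWarnings(ChemmineR::read.SDFset(tf))
  mol <- set[[1]]
  ab <- ChemmineR::atomblock(mol)
  bb <- ChemmineR::bondblock(mol)
  elem <- sub("_.*$", "", rownames(ab))
  n_all <- length(elem)
  bonds_all <- if (is.null(dim(bb)) || nrow(bb) == 0) {
    matrix(integer(0), ncol = 3)
  } else {
    cbind(as.integer(bb[, 1]), as.integer(bb[, 2]), as.integer(bb[, 3]))
  }
  charge <- integer(n_all)
  for (ln in grep("^M  CHG", strsplit(sdf, "\n", fixed = TRUE)[[1]], value = TRUE)) {
    f <- as.integer(strsplit(trimws(sub("^M  CHG", "", ln)), "\\s+")[[1]])
    k <- f[1]
    for (q in seq_len(k)) charge[f[2 * q]] <- f[2 * q + 1]
  }

  heavy <- which(elem != "H")
  hmap <- integer(n_all); hmap[heavy] <- seq_along(heavy)
  keep <- bonds_all[, 1] %in% heavy & bonds_all[, 2] %in% heavy
  bonds <- bonds_all[keep, , drop = FALSE]
  if (nrow(bonds)) {
    bonds[, 1] <- hmap[bonds[, 1]]
    bonds[, 2] <- hmap[bonds[, 2]]
  }
  nH <- integer(length(heavy))
  deg <- integer(length(heavy))
  if (nrow(bonds_all)) {
    for (e in seq_len(nrow(bonds_all))) {
      i <- bonds_all[e, 1]; j <- bonds_all[e, 2]
      if (elem[i] == "H" && elem[j] != "H") nH[hmap[j]] <- nH[hmap[j]] + 1L
      if (elem[j] == "H" && elem[i] != "H") nH[hmap[i]] <- nH[hmap[i]] + 1L
      if (elem[i] != "H" && elem[j] != "H") {
        deg[hmap[i]] <- deg[hmap[i]] + 1L
        deg[hmap[j]] <- deg[hmap[j]] + 1L
      }
    }
  }
  he <- elem[heavy]
  nh <- length(heavy)

  # hybridisation from bond orders; ring/aromatic perception from the graph
  maxord <- integer(nh); ndouble <- integer(nh)
  if (nrow(bonds)) {
    for (e in seq_len(nrow(bonds))) {
      for (a in bonds[e, 1:2]) {
        maxord[a] <- max(maxord[a], bonds[e, 3])
        if (bonds[e, 3] >= 2) ndouble[a] <- ndouble[a] + 1L
      }
    }
  }
  hyb <- ifelse(maxord >= 3 | ndouble >= 2, "sp",
                ifelse(maxord == 2, "sp2", ifelse(deg + nH > 0, "sp3", "sp3")))
  in_ring <- rep(FALSE, nh)
  if (nrow(bonds) > 0 && nh > 2) {
    g <- igraph::graph_from_edgelist(bonds[, 1:2, drop = FALSE], directed = FALSE)
    if (igraph::vcount(g) < nh) g <- igraph::add_vertices(g, nh - igraph::vcount(g))
    br <- igraph::bridges(g)
    ring_edges <- setdiff(seq_len(nrow(bonds)), as.integer(br))
    in_ring[unique(as.vector(bonds[ring_edges, 1:2]))] <- TRUE
  }
  arom <- in_ring & hyb == "sp2"

  atoms <- data.frame(
    elem = he, Z = as.integer(.elem_lookup(he, "Z")),
    charge = charge[heavy], nH = nH, degree = deg,
    in_ring = in_ring, aromatic = arom, hyb = hyb,
    stringsAsFactors = FALSE)
  structure(list(
    atoms = atoms, bonds = bonds,
    atoms_all = data.frame(elem = elem, charge = charge, stringsAsFactors = FALSE),
    bonds_all = bonds_all,
    name = if (is.null(name)) "" else name,
    smiles = smiles), class = "pox_mol")
}

#' @export
print.pox_mol <- function(x, ...) {
  cat("<pox_mol>", if (nzchar(x$name)) x$name else x$smiles,
      "-", nrow(x$atoms), "heavy atoms,", nrow(x$bonds), "bonds\n")
  invisible(x)
}

#' Number of heavy atoms
#' @param mol a `pox_mol`
#' @export
n_heavy <- function(mol) nrow(mol$atoms)

#' Molecular weight (g/mol)
#'
#' Average-mass formula weight over all atoms including hydrogens; dummy
#' attachment atoms contribute zero, so the weight of an attachment-marked
#' repeat unit is exactly the repeat-unit mass.
#' @param mol a `pox_mol`
#' @export
mol_weight <- function(mol) {
  sum(.elem_lookup(mol$atoms_all$elem, "mass"))
}

#' Molecular formula of the heavy + hydrogen graph
#' @param mol a `pox_mol`
#' @export
mol_formula <- function(mol) {
  tab <- table(mol$atoms_all$elem)
  ord <- c("C", "H", setdiff(sort(names(tab)), c("C", "H")))
  ord <- ord[ord %in% names(tab)]
  paste0(ord, ifelse(tab[ord] > 1, tab[ord], ""), collapse = "")
}

#' @keywords internal
mol_is_connected <- function(mol) {
  n <- n_heavy(mol)
  if (n <= 1) return(TRUE)
  g <- igraph::graph_from_edgelist(mol$bonds[, 1:2, drop = FALSE], directed = FALSE)
  if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
  igraph::is_connected(g)
}

#' @keywords internal
mol_distances <- function(mol) {
  n <- n_heavy(mol)
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (nrow(mol$bonds)) g <- igraph::add_edges(g, t(mol$bonds[, 1:2, drop = FALSE]))
  igraph::distances(g)
}

# Kier-Hall deltas on the heavy-atom graph: sigma delta = heavy degree,
# valence delta = (Zv - h) / (Z - Zv - 1) beyond the second period, Zv - h within.
#' @keywords internal
mol_deltas <- function(mol) {
  a <- mol$atoms
  Zv <- .elem_lookup(a$elem, "Zv")
  dv <- ifelse(a$Z > 10, (Zv - a$nH) / (a$Z - Zv - 1), Zv - a$nH)
  cbind(d = a$degree, dv = dv)
}

#' Count rotatable bonds
#'
#' Single non-ring bonds between two heavy atoms that each carry at least one
#' further heavy neighbour; amide C-N bonds are excluded.
#' @param mol a `pox_mol`
#' @export
count_rotatable_bonds <- function(mol) {
  b <- mol$bonds
  if (!nrow(b)) return(0L)
  ring_edge <- rep(FALSE, nrow(b))
  if (nrow(b) > 0) {
    g <- igraph::graph_from_edgelist(b[, 1:2, drop = FALSE], directed = FALSE)
    if (igraph::vcount(g) < n_heavy(mol)) {
      g <- igraph::add_vertices(g, n_heavy(mol) - igraph::vcount(g))
    }
    ring_edge[setdiff(seq_len(nrow(b)), as.integer(igraph::bridges(g)))] <- TRUE
  }
  a <- mol$atoms
  is_amide_cn <- function(i, j) {
    # carbonyl carbon bonded to nitrogen
    ci <- a$elem[i] == "C" && a$elem[j] == "N"
    cj <- a$elem[j] == "C" && a$elem[i] == "N"
    if (!ci && !cj) return(FALSE)
    cc <- if (ci) i else j
    any(b[, 3] == 2 &
          ((b[, 1] == cc & a$elem[b[, 2]] == "O") |
             (b[, 2] == cc & a$elem[b[, 1]] == "O")))
  }
  n <- 0L
  for (e in seq_len(nrow(b))) {
    i <- b[e, 1]; j <- b[e, 2]
    if (b[e, 3] != 1 || ring_edge[e]) next
    if (a$degree[i] < 2 || a$degree[j] < 2) next
    if (is_amide_cn(i, j)) next
    n <- n + 1L
  }
  n
}

#' Molecule-level properties from the OpenBabel backend
#'
#' Returns logP, molar refractivity, TPSA, hydrogen-bond donor and acceptor
#' counts and formula weight as computed by OpenBabel for a SMILES.
#' @param smiles SMILES string
#' @return one-row data.frame
#' @export
ob_properties <- function(smiles) {
  m <- ChemmineOB::forEachMol("SMILES", paste0(smiles, "\n"), identity)
  p <- ChemmineOB::prop_OB(m)
  data.frame(logP = p$logP, MR = p$MR, MW = p$MW, TPSA = p$TPSA,
             HBD = p$HBD, HBA = p$HBA2, stringsAsFactors = FALSE)
}

#' 3D coordinates for a molecule
#'
#' Generates a single conformer with OpenBabel's deterministic structure
#' builder followed by force-field clean-up, and returns heavy-atom
#' coordinates (hydrogens included in the build, stripped on return).
#' @param smiles SMILES string
#' @return matrix (n_heavy x 3) or NULL when generation fails
#' @export
mol_coords_3d <- function(smiles) {
  sdf <- tryCatch(
    suppressWarnings(ChemmineOB::convertFormat(
      "SMI", "SDF", paste0(smiles, "\n"),
      options = data.frame(names = "gen3D", args = "", stringsAsFactors = FALSE))),
    error = function(e) NULL)
  if (is.null(sdf)) return(NULL)
  tf <- tempfile(fileext = ".sdf")
  on.exit(unlink(tf), add = TRUE)
  writeLines(sdf, tf)
  set <- suppressWarnings(ChemmineR::read.SDFset(tf))
  ab <- ChemmineR::atomblock(set[[1]])
  elem <- sub("_.*$", "", rownames(ab))
  xyz <- ab[elem != "H", 1:3, drop = FALSE]
  storage.mode(xyz) <- "double"
  unname(xyz)
}
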