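# Monomer registry, capping rules and polymer construction.
#
# ABA-triblock poly(2-oxazoline)/poly(2-oxazine) chains are described by their
# repeat units. For descriptor computation every repeat unit is turned into a
# valence-complete small molecule: one attachment point is capped with a
# hydrogen and the other with a methyl group, except that a backbone nitrogen
# is always methyl-capped so the capped molecule keeps the tertiary amide
# substitution pattern of the real backbone.

.registry_env <- new.env(parent = emptyenv())

#' Load the monomer registry
#'
#' @param path optional path to a registry JSON; defaults to the registry
#'   shipped with the package (the common pOx/pOzi repeat units and termini).
#' @return list with `monomers` and `termini` entries.
#' @export
monomer_registry <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.registry_env$default)) return(.registry_env$default)
    path <- system.file("extdata", "monomers.json", package = "poxload")
  }
  reg <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  reg <- list(monomers = reg$monomers, termini = reg$termini)
  if (is.null(.registry_env$default) &&
      identical(path, system.file("extdata", "monomers.json", package = "poxload"))) {
    .registry_env$default <- reg
  }
  reg
}

#' @keywords internal
count_attachments <- function(smiles) {
  lengths(regmatches(smiles, gregexpr("[[]\\*[]]", smiles)))
}

#' Cap an attachment-marked repeat unit into a small molecule
#'
#' @param smiles repeat-unit SMILES with `[*]` attachment markers (two for a
#'   repeat unit, one for a terminus).
#' @param role one of `"A"`, `"B"`, `"terminus_start"`, `"terminus_end"`;
#'   determines how many attachment points are expected.
#' @return a `pox_mol` of the capped molecule; the capped SMILES is in
#'   `$smiles`.
#' @export
build_capped_monomer <- function(smiles, role = "A") {
  expected <- if (role %in% c("terminus_start", "terminus_end")) 1L else 2L
  npts <- count_attachments(smiles)
  if (npts != expected) {
    stop("structural error: expected ", expected, " attachment point(s), found ",
         npts, " in ", smiles, call. = FALSE)
  }
  probe <- parse_smiles(smiles)
  dummies <- which(probe$atoms$elem == "*")
  nbr_elem <- vapply(dummies, function(d) {
    b <- probe$bonds
    nb <- c(b[b[, 1] == d, 2], b[b[, 2] == d, 1])
    if (!length(nb)) return("")
    probe$atoms$elem[nb[1]]
  }, character(1))
  # cap assignment: nitrogen attachments always methyl; otherwise exactly one
  # methyl per pair (the tail), the remaining attachment hydrogen
  caps <- rep("H", length(dummies))
  caps[nbr_elem == "N"] <- "C"
  if (length(dummies) == 2L && !any(caps == "C")) caps[2] <- "C"
  out <- smiles
  # replace [*] occurrences left to right (SDF atom order follows string order);
  # a methyl cap becomes a plain C, a hydrogen cap is an implicit H after removal
  for (k in seq_along(caps)) {
    out <- sub("[[]\\*[]]", if (caps[k] == "C") "C" else "", out)
  }
  capped <- tryCatch(parse_smiles(out), error = function(e)
    stop("chemistry error: cannot cap ", smiles, call. = FALSE))
  if (!mol_is_connected(capped)) {
    stop("chemistry error: capped structure is disconnected for ", smiles, call. = FALSE)
  }
  capped
}

#' Construct a monomer specification
#'
#' @param name registry name (e.g. `"MeOx"`, `"nPrOzi"`) or a label for a
#'   custom unit supplied through `smiles`.
#' @param role monomer role; taken from the registry when omitted.
#' @param smiles attachment-marked SMILES; taken from the registry when omitted.
#' @param registry registry list from [monomer_registry()].
#' @return object of class `pox_monomer` with fields `name`, `role`,
#'   `repeat_smiles`, `capped` (a `pox_mol`), `mw_repeat`.
#' @export
monomer_spec <- function(name, role = NULL, smiles = NULL, registry = monomer_registry()) {
  if (is.null(smiles)) {
    entry <- registry$monomers[[name]]
    if (is.null(entry)) entry <- registry$termini[[name]]
    if (is.null(entry)) stop("unknown monomer: ", name, call. = FALSE)
    smiles <- entry$smiles
    if (is.null(role)) role <- entry$role
  }
  if (is.null(role)) role <- "A"
  unit <- parse_smiles(smiles)
  mw <- mol_weight(unit)
  if (mw <= 0) stop("invalid repeat unit mass for ", name, call. = FALSE)
  capped <- build_capped_monomer(smiles, role)
  structure(list(name = name, role = role, repeat_smiles = smiles,
                 capped = capped, mw_repeat = mw),
            class = "pox_monomer")
}

#' @export
print.pox_monomer <- function(x, ...) {
  cat(sprintf("<pox_monomer> %s [%s] %.2f g/mol, capped: %s\n",
              x$name, x$role, x$mw_repeat, x$capped$smiles))
  invisible(x)
}

#' Construct an ABA-triblock polymer specification
#'
#' @param a_monomer,b_monomer monomer names or `pox_monomer` objects.
#' @param block_lengths integer vector `(nA1, nB, nA2)`, all >= 1.
#' @param termini length-2 character vector or list of `pox_monomer`s
#'   (start, end); defaults to a methyl initiator and a piperidide end group.
#' @param mw_polymer optional molar mass; validated against the block sum
#'   (tolerance 0.1 g/mol) when supplied, computed otherwise.
#' @return object of class `pox_polymer`.
#' @export
polymer_spec <- function(a_monomer, b_monomer, block_lengths,
                         termini = c("Me", "Pip"), mw_polymer = NULL) {
  as_mono <- function(m, role = NULL) {
    if (inherits(m, "pox_monomer")) m else monomer_spec(m, role = role)
  }
  a <- as_mono(a_monomer, "A")
  b <- as_mono(b_monomer, "B")
  t1 <- as_mono(termini[[1]], "terminus_start")
  t2 <- as_mono(termini[[2]], "terminus_end")
  bl <- as.integer(block_lengths)
  if (length(bl) != 3 || any(is.na(bl)) || any(bl < 1)) {
    stop("block_lengths must be three integers >= 1", call. = FALSE)
  }
  mw <- (bl[1] + bl[3]) * a$mw_repeat + bl[2] * b$mw_repeat +
    t1$mw_repeat + t2$mw_repeat
  if (!is.null(mw_polymer)) {
    if (abs(mw_polymer - mw) > 0.1) {
      stop(sprintf("mw_polymer %.2f inconsistent with block sum %.2f", mw_polymer, mw),
           call. = FALSE)
    }
    mw <- mw_polymer
  }
  structure(list(a_monomer = a, b_monomer = b, block_lengths = bl,
                 termini = list(t1, t2), mw_polymer = mw,
                 name = sprintf("A-%s-A", b$name)),
            class = "pox_polymer")
}

#' @export
print.pox_polymer <- function(x, ...) {
  cat(sprintf("<pox_polymer> %s%d-%s%d-%s%d (%s/%s termini), %.1f g/mol\n",
              x$a_monomer$name, x$block_lengths[1],
              x$b_monomer$name, x$block_lengths[2],
              x$a_monomer$name, x$block_lengths[3],
              x$termini[[1]]$name, x$termini[[2]]$name, x$mw_polymer))
  invisible(x)
}

#' Build the pseudotrimer molecule of a polymer
#'
#' A single linear molecule T1-A-B-A-T2 containing each building block and
#' both termini exactly once. It is the SiRMS input proxy for the full chain;
#' as a fixed-size proxy it assumes the typical A/B monomer ratio of about 2:1.
#'
#' @param polymer a `pox_polymer`
#' @return a `pox_mol`
#' @export
build_pseudotrimer <- function(polymer) {
  strip <- function(smiles, terminal = FALSE) {
    s <- sub("^\\[\\*\\]", "", smiles)
    s <- sub("\\[\\*\\]$", "", s)
    if (count_attachments(s) > 0) {
      stop("structural error: interior attachment markers in ", smiles, call. = FALSE)
    }
    s
  }
  parts <- c(strip(polymer$termini[[1]]$repeat_smiles),
             strip(polymer$a_monomer$repeat_smiles),
             strip(polymer$b_monomer$repeat_smiles),
             strip(polymer$a_monomer$repeat_smiles),
             strip(polymer$termini[[2]]$repeat_smiles))
  smi <- paste0(parts, collapse = "")
  mol <- tryCatch(parse_smiles(smi, name = paste0(polymer$name, "-pseudotrimer")),
                  error = function(e)
                    stop("structural error: pseudotrimer assembly failed", call. = FALSE))
  if (!mol_is_connected(mol)) {
    stop("structural error: pseudotrimer is disconnected", call. = FALSE)
  }
  mol
}
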