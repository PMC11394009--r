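# Count fingerprints for micellar components and their mixture combination.
#
# Families:
#  * ecfp4 / ecfp6 - circular (Morgan-style) environment counts, radii 2 / 3
#  * rdk5 / rdk7   - linear subgraph (path) counts, maximum lengths 5 / 7
#  * maccs         - MACCS key incidences through the OpenBabel backend
# The hashed families default to 16,384 bits to limit bit collisions.

#' Compute a count fingerprint
#'
#' @param x a `pox_mol`, `pox_drug`, `pox_monomer` or SMILES string.
#' @param family one of `"ecfp4"`, `"ecfp6"`, `"rdk5"`, `"rdk7"`, `"maccs"`.
#'   `"avalon"` is part of the subset vocabulary but no installed backend
#'   provides it; requesting it is a configuration error.
#' @param width number of bits for the hashed families (default 16384).
#' @return object of class `pox_fp`: sparse counts (`bit`, `count`), `family`,
#'   `width`.
#' @export
count_fingerprint <- function(x, family = c("ecfp4", "ecfp6", "rdk5", "rdk7",
                                            "maccs", "avalon"),
                              width = 16384L) {
  family <- match.arg(family)
  if (family == "avalon") {
    stop("configuration error: no installed backend provides Avalon fingerprints",
         call. = FALSE)
  }
  if (inherits(x, "pox_drug")) x <- x$mol
  if (inherits(x, "pox_monomer")) x <- x$capped
  if (is.character(x)) x <- parse_smiles(x)
  stopifnot(inherits(x, "pox_mol"))
  a <- x$atoms
  counts <- if (family %in% c("rdk5", "rdk7")) {
    atype <- as.integer(factor(paste(a$elem, a$aromatic, a$charge)))
    cpp_path_fp(nrow(a), x$bonds, atype, 1L,
                if (family == "rdk5") 5L else 7L, as.integer(width))
  } else if (family %in% c("ecfp4", "ecfp6")) {
    # invariants must be molecule-independent: hash the description itself
    desc <- paste(a$Z, a$degree, a$nH, a$charge, a$in_ring, a$aromatic)
    inv <- vapply(desc, function(s) {
      sum(utf8ToInt(s) * seq_along(utf8ToInt(s))) %% 1000003L
    }, numeric(1))
    cpp_morgan_fp(nrow(a), x$bonds, as.integer(inv),
                  if (family == "ecfp4") 2L else 3L, as.integer(width))
  } else {  # maccs
    m <- ChemmineOB::forEachMol("SMILES", paste0(x$smiles, "\n"), identity)
    fp <- ChemmineOB::fingerprint_OB(m, "MACCS")
    width <- length(fp)
    as.integer(fp)
  }
  bit <- which(counts > 0)
  structure(list(bit = bit, count = as.numeric(counts[bit]),
                 family = family, width = as.integer(width)),
            class = "pox_fp")
}

#' @export
print.pox_fp <- function(x, ...) {
  cat(sprintf("<pox_fp> %s (%d bits), %d bits set, total count %g\n",
              x$family, x$width, length(x$bit), sum(x$count)))
  invisible(x)
}

#' Combine component count fingerprints into a mixture fingerprint
#'
#' `FP_MIX[b] = sum_i N_i * FP_i[b]` where `N_i` is the per-chain count of the
#' component (block lengths, 2 termini, fractional drugs per chain).
#'
#' @param fps list of `pox_fp` objects of one family and width
#' @param counts numeric vector of per-chain multiplicities
#' @param round_drug_count round multiplicities to integers before summing
#' @return a `pox_fp` with real-valued counts
#' @export
mix_count_fingerprints <- function(fps, counts, round_drug_count = FALSE) {
  stopifnot(length(fps) == length(counts))
  fam <- unique(vapply(fps, `[[`, "", "family"))
  wid <- unique(vapply(fps, `[[`, 1L, "width"))
  if (length(fam) != 1 || length(wid) != 1) {
    stop("configuration error: fingerprint family/width mismatch", call. = FALSE)
  }
  if (round_drug_count) counts <- round(counts)
  dense <- numeric(wid)
  for (i in seq_along(fps)) {
    f <- fps[[i]]
    dense[f$bit] <- dense[f$bit] + counts[i] * f$count
  }
  bit <- which(dense != 0)
  structure(list(bit = bit, count = dense[bit], family = fam,
                 width = as.integer(wid)), class = "pox_fp")
}
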