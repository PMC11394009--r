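# Per-atom lipophilicity (logp) and molar refractivity (mr) contributions.
# Compact Crippen-style atomic contribution scheme: atoms are typed by element,
# aromaticity and neighbourhood, and each type carries additive logp/mr values.
# Downstream only the SiRMS property bins (A-D) of these values are consumed.

.CRIPPEN <- list(
  C_aliph      = c(logp =  0.1441, mr = 2.503),
  C_aliph_het  = c(logp = -0.2035, mr = 2.753),
  C_carbonyl   = c(logp = -0.2783, mr = 2.730),
  C_sp2        = c(logp =  0.2641, mr = 3.000),
  C_arom_H     = c(logp =  0.1581, mr = 3.350),
  C_arom_sub   = c(logp =  0.1360, mr = 3.509),
  C_arom_het   = c(logp = -0.0300, mr = 3.243),
  N_amine      = c(logp = -1.0190, mr = 2.262),
  N_amide      = c(logp = -0.5188, mr = 2.819),
  N_arom       = c(logp = -0.3239, mr = 2.202),
  N_other      = c(logp = -0.3396, mr = 2.134),
  O_hydroxyl   = c(logp = -0.2893, mr = 0.8238),
  O_ether      = c(logp = -0.0684, mr = 1.085),
  O_arom       = c(logp =  0.1552, mr = 1.080),
  O_carbonyl   = c(logp = -0.1526, mr = 1.700),
  F_           = c(logp =  0.4202, mr = 0.8897),
  Cl_          = c(logp =  0.6895, mr = 5.853),
  Br_          = c(logp =  0.8456, mr = 8.927),
  I_           = c(logp =  0.8857, mr = 14.02),
  S_           = c(logp =  0.6482, mr = 7.591),
  P_           = c(logp =  0.8612, mr = 6.920),
  H_onC        = c(logp =  0.1230, mr = 1.057),
  H_onHet      = c(logp = -0.2677, mr = 1.057),
  dummy        = c(logp =  0.0000, mr = 0.000),
  other        = c(logp =  0.0000, mr = 2.000)
)

#' @keywords internal
crippen_type <- function(mol) {
  a <- mol$atoms
  b <- mol$bonds
  nbrs <- function(i) {
    c(b[b[, 1] == i, 2], b[b[, 2] == i, 1])
  }
  has_double_O <- function(i) {
    any(b[, 3] == 2 &
          ((b[, 1] == i & a$elem[b[, 2]] == "O") |
             (b[, 2] == i & a$elem[b[, 1]] == "O")))
  }
  vapply(seq_len(nrow(a)), function(i) {
    e <- a$elem[i]
    nb <- nbrs(i)
    nbe <- a$elem[nb]
    switch(e,
      "C" = if (a$aromatic[i]) {
        if (any(nbe %in% c("N", "O", "S") & !a$aromatic[nb])) "C_arom_het"
        else if (a$nH[i] > 0) "C_arom_H" else "C_arom_sub"
      } else if (has_double_O(i)) "C_carbonyl"
        else if (a$hyb[i] %in% c("sp2", "sp")) "C_sp2"
        else if (any(!nbe %in% c("C", "H", "*"))) "C_aliph_het"
        else "C_aliph",
      "N" = if (a$aromatic[i]) "N_arom"
        else if (any(nbe == "C" & vapply(nb, has_double_O, logical(1)))) "N_amide"
        else if (a$hyb[i] == "sp3") "N_amine" else "N_other",
      "O" = if (a$aromatic[i]) "O_arom"
        else if (any(b[, 3] == 2 & (b[, 1] == i | b[, 2] == i))) "O_carbonyl"
        else if (a$nH[i] > 0) "O_hydroxyl" else "O_ether",
      "F" = "F_", "Cl" = "Cl_", "Br" = "Br_", "I" = "I_",
      "S" = "S_", "P" = "P_", "*" = "dummy",
      "other")
  }, character(1))
}

#' Crippen-style atomic logp and mr contributions
#'
#' @param mol a `pox_mol`
#' @param hydrogens if TRUE, values for explicit hydrogens are appended
#'   (assigned by the heavy atom they sit on), in the order of the
#'   hydrogen-explicit atom table.
#' @return data.frame with columns `logp` and `mr`, one row per atom.
#' @export
crippen_atomic <- function(mol, hydrogens = FALSE) {
  ty <- crippen_type(mol)
  out <- do.call(rbind, lapply(ty, function(t) .CRIPPEN[[t]]))
  out <- as.data.frame(out)
  rownames(out) <- NULL
  if (!hydrogens) return(out)
  # hydrogen contributions follow the heavy-atom order of the full table
  elem_all <- mol$atoms_all$elem
  heavy_idx <- which(elem_all != "H")
  full <- data.frame(logp = numeric(length(elem_all)), mr = numeric(length(elem_all)))
  full[heavy_idx, ] <- out
  ba <- mol$bonds_all
  for (h in which(elem_all == "H")) {
    nb <- c(ba[ba[, 1] == h, 2], ba[ba[, 2] == h, 1])
    onC <- length(nb) && elem_all[nb[1]] == "C"
    full[h, ] <- .CRIPPEN[[if (onC) "H_onC" else "H_onHet"]]
  }
  full
}

#' Whole-molecule Crippen-style logP (sum of atomic contributions)
#' @param mol a `pox_mol`
#' @export
crippen_logp <- function(mol) {
  sum(crippen_atomic(mol, hydrogens = TRUE)$logp)
}
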