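# Assembly of mixture feature rows and matrices for model building.

.FEATURE_SUBSETS <- c("mordred", "rdk5", "rdk7", "ecfp4", "ecfp6", "avalon",
                      "maccs", "sirms", "sirms-noH")

# feature assembly is invariant to coformulation drug order: drugs are
# sorted by name before any per-drug feature is derived
#' @keywords internal
canonical_drug_order <- function(x) {
  if (length(x$drugs) < 2) return(x)
  ord <- order(vapply(x$drugs, `[[`, "", "name"))
  x$drugs <- x$drugs[ord]
  x$drug_feed <- x$drug_feed[ord]
  x$m_solubilized <- x$m_solubilized[ord]
  x
}

#' @keywords internal
experimental_features <- function(x) {
  st <- molar_fractions(x)
  nd <- drugs_per_chain(x)
  bl <- x$polymer$block_lengths
  drug_n <- st$n[st$class %in% c("drug1", "drug2")]
  c(DF = sum(x$drug_feed),
    DF1 = x$drug_feed[1],
    DF2 = if (length(x$drug_feed) > 1) x$drug_feed[2] else 0,
    polymer_feed = x$polymer_feed,
    t_measure = x$t_days,
    nA1 = bl[1], nB = bl[2], nA2 = bl[3],
    n_T1 = st$n[st$class == "T1"], n_A = st$n[st$class == "A"],
    n_B = st$n[st$class == "B"], n_T2 = st$n[st$class == "T2"],
    n_drug1 = drug_n[1], n_drug2 = if (length(drug_n) > 1) drug_n[2] else 0,
    N_drug1 = nd[1], N_drug2 = if (length(nd) > 1) nd[2] else 0)
}

#' Assemble the feature row of one formulation
#'
#' Combines subset-specific mixture features (molar-fraction weighted
#' descriptors, count fingerprints or SiRMS simplexes) with the experimental
#' features (feeds, time point, block lengths, molar fractions, drugs per
#' chain) that every subset carries.
#'
#' @param x a `pox_formulation`
#' @param subset one of `r paste0('"', .FEATURE_SUBSETS, '"', collapse = ", ")`
#' @param fp_width fingerprint width for the hashed families
#' @param include_3d include 3D-MoRSE descriptors in the `mordred` subset
#' @param sirms_schemes labelling schemes for the SiRMS subsets
#' @return named numeric vector with attribute `group_key`
#' @export
assemble_feature_row <- function(x, subset = "mordred", fp_width = 16384L,
                                 include_3d = TRUE,
                                 sirms_schemes = c("atom", "logp", "mr")) {
  if (!subset %in% .FEATURE_SUBSETS) {
    stop("configuration error: unknown subset '", subset, "'", call. = FALSE)
  }
  x <- canonical_drug_order(x)
  st <- molar_fractions(x)
  pol <- x$polymer
  feats <- experimental_features(x)
  if (subset == "mordred") {
    comp <- list(T1 = component_descriptors(pol$termini[[1]], include_3d = include_3d),
                 A = component_descriptors(pol$a_monomer, include_3d = include_3d),
                 B = component_descriptors(pol$b_monomer, include_3d = include_3d),
                 T2 = component_descriptors(pol$termini[[2]], include_3d = include_3d))
    for (d in seq_along(x$drugs)) {
      comp[[paste0("D", d)]] <-
        component_descriptors(x$drugs[[d]], include_3d = include_3d)
    }
    frac <- st$n[match(c("T1", "A", "B", "T2",
                         paste0("drug", seq_along(x$drugs)))[seq_along(comp)],
                       st$class)]
    mix <- mix_descriptors(comp, frac)
    ablock <- comp$A
    bblock <- comp$B
    drug_idx <- grep("^D", names(comp))
    drug <- mix_descriptors(comp[drug_idx], frac[drug_idx])
    pre <- function(p, v) stats::setNames(v, paste0(p, "_", names(v)))
    feats <- c(feats, pre("MIX", mix), pre("ABLOCK", ablock),
               pre("BBLOCK", bblock), pre("DRUG", drug))
  } else if (subset %in% c("rdk5", "rdk7", "ecfp4", "ecfp6", "maccs", "avalon")) {
    fps <- list(count_fingerprint(pol$termini[[1]], subset, fp_width),
                count_fingerprint(pol$a_monomer, subset, fp_width),
                count_fingerprint(pol$b_monomer, subset, fp_width),
                count_fingerprint(pol$termini[[2]], subset, fp_width))
    for (d in seq_along(x$drugs)) {
      fps <- c(fps, list(count_fingerprint(x$drugs[[d]], subset, fp_width)))
    }
    cnt <- st$N[match(c("T1", "A", "B", "T2",
                        paste0("drug", seq_along(x$drugs))), st$class)]
    mixfp <- mix_count_fingerprints(fps, cnt)
    drug_idx <- seq.int(5L, length(fps))
    drugfp <- mix_count_fingerprints(fps[drug_idx], cnt[drug_idx])
    v <- c(stats::setNames(mixfp$count, sprintf("MIX_%s_%d", subset, mixfp$bit)),
           stats::setNames(drugfp$count, sprintf("DRUG_%s_%d", subset, drugfp$bit)))
    feats <- c(feats, v)
  } else {  # sirms / sirms-noH
    explicit_h <- subset == "sirms"
    tri <- build_pseudotrimer(pol)
    comps <- c(list(tri), lapply(x$drugs, `[[`, "mol"))
    frac_pol <- sum(st$n[st$class %in% c("T1", "A", "B", "T2")])
    fracs <- c(frac_pol, st$n[st$class %in% c("drug1", "drug2")])
    for (sc in sirms_schemes) {
      sv <- mixture_simplexes(comps, fracs, scheme = sc, explicit_h = explicit_h)
      if (nrow(sv)) {
        feats <- c(feats, stats::setNames(
          sv$count, paste0(subset, "_", sc, "_", sv$key)))
      }
    }
  }
  attr(feats, "group_key") <- group_key(x)
  feats
}

#' Assemble the feature matrix of a formulation table
#'
#' Rows are formulations, columns the union of all row features; fingerprint
#' and simplex keys absent from a row count zero there.
#'
#' @param table a `pox_formulation_table`
#' @param subset,fp_width,include_3d,sirms_schemes see [assemble_feature_row()]
#' @return list with `X` (numeric matrix), `groups` (group key per row) and
#'   `meta` (subset and backend configuration)
#' @export
assemble_feature_matrix <- function(table, subset = "mordred", fp_width = 16384L,
                                    include_3d = TRUE,
                                    sirms_schemes = c("atom", "logp", "mr")) {
  rows <- lapply(table$rows, assemble_feature_row, subset = subset,
                 fp_width = fp_width, include_3d = include_3d,
                 sirms_schemes = sirms_schemes)
  nms <- unique(unlist(lapply(rows, names)))
  X <- matrix(0, nrow = length(rows), ncol = length(nms),
              dimnames = list(NULL, nms))
  for (i in seq_along(rows)) X[i, names(rows[[i]])] <- rows[[i]]
  groups <- vapply(rows, attr, "", "group_key")
  list(X = X, groups = groups,
       meta = list(subset = subset, fp_width = fp_width,
                   include_3d = include_3d, sirms_schemes = sirms_schemes))
}
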