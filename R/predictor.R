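# End-user prediction: the eight-threshold model ensemble, ladder estimates,
# solubilized-mass conversion and library screening.

.LC_LADDER <- c(10, 20, 30, 40)
.LE_LADDER <- c(20, 40, 60, 80)

#' Fit the eight-threshold classifier ensemble
#'
#' Trains one classifier per LC threshold (10/20/30/40 %) and LE threshold
#' (20/40/60/80 %) on a formulation table, all on the same descriptor subset
#' and family unless per-threshold overrides are given.
#'
#' @param table a `pox_formulation_table` with measured solubilization
#' @param subset descriptor subset (see [assemble_feature_row()])
#' @param family model family per [pox_train()] (single value or named vector
#'   by threshold id)
#' @param config a [pox_config()]
#' @param fp_width,include_3d feature assembly options
#' @return object of class `pox_ensemble`
#' @export
pox_ensemble <- function(table, subset = "rdk5", family = "RF",
                         config = pox_config(), fp_width = 16384L,
                         include_3d = FALSE) {
  fm <- assemble_feature_matrix(table, subset = subset, fp_width = fp_width,
                                include_3d = include_3d)
  thresholds <- c(paste0("LC", .LC_LADDER), paste0("LE", .LE_LADDER))
  models <- list()
  for (tid in thresholds) {
    kind <- substr(tid, 1, 2)
    thr <- as.numeric(substr(tid, 3, nchar(tid)))
    y <- label_thresholds(table, kind, thr)
    fam <- if (length(family) > 1) family[[tid]] else family
    models[[tid]] <- pox_train(fm$X, y, family = fam, threshold_id = tid,
                               config = config, subset_meta = fm$meta)
  }
  structure(list(models = models, meta = fm$meta, feature_names = colnames(fm$X)),
            class = "pox_ensemble")
}

#' @export
print.pox_ensemble <- function(x, ...) {
  cat("<pox_ensemble> subset", x$meta$subset, "\n")
  for (m in x$models) print(m)
  invisible(x)
}

#' Run all threshold models on one formulation
#'
#' Each bundle applies its own preprocessing, feature selection and
#' applicability domain; out-of-domain predictions are treated as negative.
#'
#' @param x a `pox_formulation` (solubilization may be absent)
#' @param ensemble a `pox_ensemble`
#' @return data.frame with one row per threshold: `threshold`, `score`,
#'   `pass`, `in_ad`, `distance`
#' @export
predict_thresholds <- function(x, ensemble) {
  row <- assemble_feature_row(x, subset = ensemble$meta$subset,
                              fp_width = ensemble$meta$fp_width,
                              include_3d = ensemble$meta$include_3d,
                              sirms_schemes = ensemble$meta$sirms_schemes)
  X <- matrix(0, 1, length(ensemble$feature_names),
              dimnames = list(NULL, ensemble$feature_names))
  common <- intersect(names(row), ensemble$feature_names)
  X[1, common] <- row[common]
  out <- do.call(rbind, lapply(ensemble$models, predict, newdata = X,
                               type = "report"))
  rownames(out) <- NULL
  out
}

#' Ladder estimate of the maximum metric value
#'
#' Walks an ascending threshold ladder, stopping after two consecutive
#' failures; the estimate is one percentage point below the threshold above
#' the last passed rung. Passing the top rung returns the top threshold value
#' itself as a conservative lower bound (attribute `lower_bound`).
#'
#' @param passes logical vector of pass/fail per rung (ascending order)
#' @param thresholds ascending threshold values (default the LC ladder when
#'   4 values starting at 10, otherwise supply explicitly)
#' @return estimate in percent
#' @export
ladder_estimate <- function(passes, thresholds) {
  stopifnot(length(passes) == length(thresholds), !is.unsorted(thresholds))
  last_passed <- NA_integer_
  consec_fail <- 0L
  for (i in seq_along(passes)) {
    if (isTRUE(passes[i])) {
      last_passed <- i
      consec_fail <- 0L
    } else {
      consec_fail <- consec_fail + 1L
      if (consec_fail >= 2L) break
    }
  }
  if (is.na(last_passed)) return(0)
  if (last_passed == length(thresholds)) {
    return(structure(thresholds[last_passed], lower_bound = TRUE))
  }
  thresholds[last_passed + 1L] - 1
}

#' Convert LC/LE ladder estimates into solubilized-drug masses
#'
#' `m_LE = LE/100 * DF`; `m_LC` inverts `LC = 100 * m / (m + P)` to
#' `m = (LC/100) * P / (1 - LC/100)`; the combined estimate is their mean.
#'
#' @param lc_estimate,le_estimate ladder estimates in percent
#' @param polymer_feed polymer feed P (g/L)
#' @param df drug feed (g/L), scalar or vector (a DF grid)
#' @return data.frame with `df`, `m_lc`, `m_le`, `m_combined` (g/L)
#' @export
estimate_solubilized <- function(lc_estimate, le_estimate, polymer_feed, df) {
  if (lc_estimate >= 100) {
    warning("LC estimate at 100%: cannot invert, capping", call. = FALSE)
    m_lc <- rep(NA_real_, length(df))
  } else {
    m_lc <- rep((lc_estimate / 100) * polymer_feed / (1 - lc_estimate / 100),
                length(df))
  }
  m_le <- (le_estimate / 100) * df
  data.frame(df = df, m_lc = m_lc, m_le = m_le,
             m_combined = (m_lc + m_le) / 2)
}

#' Full prediction report for one formulation setting
#'
#' @param x a `pox_formulation` (feeds define the DF grid point)
#' @param ensemble a `pox_ensemble`
#' @return list (class `pox_prediction_report`): per-threshold table, ladder
#'   estimates and solubilized-mass estimates at the formulation's DF
#' @export
prediction_report <- function(x, ensemble) {
  thr <- predict_thresholds(x, ensemble)
  lc <- thr[substr(thr$threshold, 1, 2) == "LC", ]
  le <- thr[substr(thr$threshold, 1, 2) == "LE", ]
  lc_est <- ladder_estimate(lc$pass, .LC_LADDER)
  le_est <- ladder_estimate(le$pass, .LE_LADDER)
  est <- estimate_solubilized(as.numeric(lc_est), as.numeric(le_est),
                              x$polymer_feed, sum(x$drug_feed))
  structure(list(thresholds = thr, lc_estimate = lc_est, le_estimate = le_est,
                 estimates = est, formulation = x),
            class = "pox_prediction_report")
}

#' @export
print.pox_prediction_report <- function(x, ...) {
  print(x$formulation)
  print(x$thresholds, row.names = FALSE)
  cat(sprintf("ladder estimates: LC %g%%%s, LE %g%%%s\n",
              as.numeric(x$lc_estimate),
              if (isTRUE(attr(x$lc_estimate, "lower_bound"))) " (>=)" else "",
              as.numeric(x$le_estimate),
              if (isTRUE(attr(x$le_estimate, "lower_bound"))) " (>=)" else ""))
  print(x$estimates, row.names = FALSE)
  invisible(x)
}

#' Screen a drug library against a polymer panel
#'
#' One row per drug x polymer at the given conditions; rows are ranked by the
#' number of threshold models passed. Drugs whose SMILES do not parse are
#' skipped with a message. An optional logS-based solubility prefilter keeps
#' only poorly soluble drugs (estimated solubility below `solubility_limit`).
#'
#' @param drugs named character vector of SMILES (names = drug ids) or path
#'   to a `.smi` file (one `SMILES [name]` per line)
#' @param polymers list of `pox_polymer` or B-monomer names (default panel
#'   built as A-<B>-A with MeOx A blocks and 35/20/35 blocks)
#' @param ensemble a `pox_ensemble`
#' @param polymer_feed,df,t_days screening conditions (defaults 10 g/L,
#'   6 g/L, 0 days)
#' @param prefilter_solubility apply the logS prefilter
#' @param solubility_limit g/L limit of the prefilter (default 10)
#' @return data.frame ranked by thresholds passed
#' @export
screen_library <- function(drugs, polymers, ensemble, polymer_feed = 10,
                           df = 6, t_days = 0, prefilter_solubility = FALSE,
                           solubility_limit = 10) {
  if (length(drugs) == 1 && file.exists(drugs)) {
    ln <- readLines(drugs)
    ln <- ln[nzchar(trimws(ln))]
    parts <- strsplit(trimws(ln), "\\s+")
    smi <- vapply(parts, `[[`, "", 1)
    nms <- vapply(seq_along(parts), function(i)
      if (length(parts[[i]]) > 1) parts[[i]][2] else paste0("mol", i), "")
    drugs <- stats::setNames(smi, nms)
  }
  if (is.null(names(drugs))) names(drugs) <- paste0("mol", seq_along(drugs))
  pols <- lapply(polymers, function(p) {
    if (inherits(p, "pox_polymer")) p
    else polymer_spec("MeOx", p, c(35, 20, 35))
  })
  out <- list()
  for (dn in names(drugs)) {
    ds <- tryCatch(cached_drug(dn, drugs[[dn]]), error = function(e) NULL)
    if (is.null(ds)) {
      message("skipping unparsable SMILES for ", dn)
      next
    }
    if (prefilter_solubility) {
      desc <- component_descriptors(ds, include_3d = FALSE)
      sol_gl <- 10^desc[["FilterItLogS"]] * ds$mw_drug
      if (is.na(sol_gl) || sol_gl >= solubility_limit) next
    }
    for (pol in pols) {
      f <- formulation(pol, ds, df, polymer_feed, t_days)
      rep <- prediction_report(f, ensemble)
      thr <- rep$thresholds
      row <- data.frame(drug = dn, polymer = pol$name,
                        n_passed = sum(thr$pass), n_in_ad = sum(thr$in_ad),
                        lc_estimate = as.numeric(rep$lc_estimate),
                        le_estimate = as.numeric(rep$le_estimate),
                        m_combined = rep$estimates$m_combined[1],
                        stringsAsFactors = FALSE)
      for (i in seq_len(nrow(thr))) row[[thr$threshold[i]]] <- thr$pass[i]
      out[[paste(dn, pol$name)]] <- row
    }
  }
  if (!length(out)) return(data.frame())
  res <- do.call(rbind, out)
  res <- res[order(-res$n_passed, -res$m_combined), ]
  rownames(res) <- NULL
  res
}
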