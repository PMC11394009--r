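# Binary classification metrics. Acc is the balanced accuracy
# (Sens + Spec) / 2 and nMCC rescales Matthews' correlation to [0, 1].

#' Classification metrics from a confusion matrix
#'
#' Undefined ratios (zero denominators) are reported as NA, not zero.
#'
#' @param TP,TN,FP,FN nonnegative counts
#' @return named list (class `pox_metrics`) with counts and Sens, Spec, PPV,
#'   NPV, Acc (balanced accuracy), F1, MCC, nMCC
#' @export
classification_metrics <- function(TP, TN, FP, FN) {
  if (any(c(TP, TN, FP, FN) < 0)) stop("counts must be nonnegative", call. = FALSE)
  total <- TP + TN + FP + FN
  if (total == 0) stop("domain error: empty confusion matrix", call. = FALSE)
  sdiv <- function(a, b) if (b > 0) a / b else NA_real_
  sens <- sdiv(TP, TP + FN)
  spec <- sdiv(TN, TN + FP)
  ppv <- sdiv(TP, TP + FP)
  npv <- sdiv(TN, TN + FN)
  acc <- if (!is.na(sens) && !is.na(spec)) (sens + spec) / 2 else NA_real_
  f1 <- if (!is.na(ppv) && !is.na(sens) && (ppv + sens) > 0) {
    2 * ppv * sens / (ppv + sens)
  } else NA_real_
  den <- prod(as.numeric(c(TP + FP, TP + FN, TN + FP, TN + FN)))
  mcc <- if (den > 0) {
    (as.numeric(TP) * TN - as.numeric(FP) * FN) / sqrt(den)
  } else NA_real_
  structure(list(TP = TP, TN = TN, FP = FP, FN = FN,
                 Sens = sens, Spec = spec, PPV = ppv, NPV = npv,
                 Acc = acc, F1 = f1, MCC = mcc,
                 nMCC = if (is.na(mcc)) NA_real_ else (mcc + 1) / 2),
            class = "pox_metrics")
}

#' @export
print.pox_metrics <- function(x, ...) {
  cat(sprintf("TP %d TN %d FP %d FN %d | Sens %.3f Spec %.3f PPV %.3f NPV %.3f\n",
              x$TP, x$TN, x$FP, x$FN, x$Sens, x$Spec, x$PPV, x$NPV))
  cat(sprintf("Acc(bal) %.3f F1 %.3f nMCC %.3f\n", x$Acc, x$F1, x$nMCC))
  invisible(x)
}

#' Metrics of the all-positive null classifier
#'
#' The trivial baseline assigning every instance to the positive class. At
#' prevalence p: Sens 1, Spec 0, PPV p, Acc 0.5, F1 = 2p / (1 + p).
#'
#' @param n_pos,n_neg class counts (or `prevalence` with a nominal total)
#' @param prevalence alternative specification as a fraction
#' @param total nominal total used with `prevalence`
#' @export
null_model_metrics <- function(n_pos = NULL, n_neg = NULL,
                               prevalence = NULL, total = 10000L) {
  if (!is.null(prevalence)) {
    n_pos <- round(prevalence * total)
    n_neg <- total - n_pos
  }
  classification_metrics(TP = n_pos, TN = 0, FP = n_neg, FN = 0)
}
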