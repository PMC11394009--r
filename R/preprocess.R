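# Training-set preprocessing: missing-value, near-zero-variance and
# correlation filters (limit 0.9, deterministic lexicographic representative),
# then per-feature Yeo-Johnson transformation with centring and scaling.
# Fitted strictly on training data.

#' Fit the preprocessing state on a training feature matrix
#'
#' @param X numeric matrix (training rows only)
#' @param cor_limit correlation filter limit (default 0.9)
#' @return object of class `pox_preprocess`: `kept`, `dropped` (with reasons),
#'   fitted transform
#' @export
preprocess_fit <- function(X, cor_limit = 0.9) {
  stopifnot(is.matrix(X), !is.null(colnames(X)))
  dropped <- data.frame(feature = character(0), reason = character(0),
                        stringsAsFactors = FALSE)
  drop <- function(f, why) {
    if (length(f)) {
      dropped <<- rbind(dropped, data.frame(feature = f, reason = why,
                                            stringsAsFactors = FALSE))
    }
  }
  has_na <- colnames(X)[colSums(is.na(X)) > 0]
  drop(has_na, "missing")
  keep <- setdiff(colnames(X), has_na)
  nzv <- caret::nearZeroVar(X[, keep, drop = FALSE])
  drop(keep[nzv], "near-zero-variance")
  if (length(nzv)) keep <- keep[-nzv]
  zero_sd <- keep[apply(X[, keep, drop = FALSE], 2, stats::sd) == 0]
  drop(zero_sd, "constant")
  keep <- setdiff(keep, zero_sd)
  # greedy correlation filter over lexicographically ordered features
  keep <- sort(keep)
  retained <- character(0)
  for (f in keep) {
    if (!length(retained)) { retained <- f; next }
    cc <- suppressWarnings(abs(stats::cor(X[, retained, drop = FALSE], X[, f])))
    if (any(cc > cor_limit, na.rm = TRUE)) {
      drop(f, "correlated")
    } else {
      retained <- c(retained, f)
    }
  }
  if (!length(retained)) stop("pipeline error: all features dropped", call. = FALSE)
  pp <- caret::preProcess(as.data.frame(X[, retained, drop = FALSE]),
                          method = c("YeoJohnson", "center", "scale"))
  structure(list(kept = retained, dropped = dropped, transform = pp,
                 cor_limit = cor_limit),
            class = "pox_preprocess")
}

#' Apply a fitted preprocessing state
#'
#' Features absent from `X` are treated as zero (unseen fingerprint bits).
#' @param spec a `pox_preprocess`
#' @param X numeric matrix
#' @return transformed matrix over the retained features
#' @export
preprocess_apply <- function(spec, X) {
  missing <- setdiff(spec$kept, colnames(X))
  if (length(missing)) {
    X <- cbind(X, matrix(0, nrow(X), length(missing),
                         dimnames = list(NULL, missing)))
  }
  out <- stats::predict(spec$transform,
                        as.data.frame(X[, spec$kept, drop = FALSE]))
  as.matrix(out)
}

#' @export
print.pox_preprocess <- function(x, ...) {
  cat(sprintf("<pox_preprocess> %d features retained, %d dropped (%s)\n",
              length(x$kept), nrow(x$dropped),
              paste(sprintf("%s: %d", names(table(x$dropped$reason)),
                            table(x$dropped$reason)), collapse = ", ")))
  invisible(x)
}
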