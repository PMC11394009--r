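# Distance-based applicability domain in the scaled descriptor space:
# the cutoff is <D> + z * s over the mean k-nearest-neighbour Euclidean
# distances of the training rows (self excluded); membership is inclusive.

#' Fit the applicability-domain model
#'
#' @param X scaled training feature matrix (rows = mixtures)
#' @param k neighbour count (default 5)
#' @param z cutoff multiplier (default 0.5)
#' @return object of class `pox_ad`: reference matrix, `k`, `z`,
#'   `mean_distance`, `sd`, `cutoff`
#' @export
fit_ad <- function(X, k = 5, z = 0.5) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (k >= n) stop("configuration error: k must be smaller than nrow(X)", call. = FALSE)
  D <- as.matrix(stats::dist(X))
  knn_mean <- vapply(seq_len(n), function(i) {
    mean(sort(D[i, -i])[seq_len(k)])
  }, numeric(1))
  m <- mean(knn_mean)
  s <- stats::sd(knn_mean)
  if (is.na(s)) s <- 0
  structure(list(reference = X, k = k, z = z,
                 mean_distance = m, sd = s, cutoff = m + z * s),
            class = "pox_ad")
}

#' Applicability-domain membership of query rows
#'
#' @param query numeric vector (one row) or matrix, preprocessed identically
#'   to the reference
#' @param ad a `pox_ad`
#' @return data.frame with `distance` (mean distance to the k nearest
#'   reference rows) and `in_domain` (inclusive at the cutoff)
#' @export
in_domain <- function(query, ad) {
  if (is.null(dim(query))) query <- matrix(query, nrow = 1)
  if (ncol(query) != ncol(ad$reference)) {
    stop("configuration error: query dimension mismatch", call. = FALSE)
  }
  d <- vapply(seq_len(nrow(query)), function(i) {
    di <- sqrt(colSums((t(ad$reference) - query[i, ])^2))
    mean(sort(di)[seq_len(ad$k)])
  }, numeric(1))
  data.frame(distance = d, in_domain = d <= ad$cutoff)
}

#' @export
print.pox_ad <- function(x, ...) {
  cat(sprintf("<pox_ad> k=%d z=%.2f <D>=%.4f s=%.4f cutoff=%.4f (%d reference rows)\n",
              x$k, x$z, x$mean_distance, x$sd, x$cutoff, nrow(x$reference)))
  invisible(x)
}
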