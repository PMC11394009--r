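# Shadow-feature all-relevant feature selection (Boruta-style): each round
# appends a permuted copy of every feature, fits a random forest, and a
# feature scores a hit when its importance exceeds the best shadow importance.
# Binomial tests against p = 0.5 confirm or reject features over the rounds.

#' Boruta-style feature selection
#'
#' @param X preprocessed numeric matrix
#' @param y binary factor or numeric response
#' @param seed integer seed (results are deterministic given the seed)
#' @param max_runs maximum number of shadow rounds
#' @param p_value decision threshold of the binomial tests
#' @param tentative `"keep"` (default) retains undecided features alongside
#'   the confirmed set; `"drop"` discards them
#' @param num_trees trees per random forest round
#' @return character vector of selected feature names with attribute
#'   `decisions` (data.frame feature/decision/hits/runs)
#' @export
boruta_select <- function(X, y, seed = 1, max_runs = 40, p_value = 0.01,
                          tentative = c("keep", "drop"), num_trees = 300) {
  tentative <- match.arg(tentative)
  stopifnot(is.matrix(X), !is.null(colnames(X)))
  if (is.factor(y) && nlevels(droplevels(y)) < 2) {
    stop("pipeline error: response has a single class", call. = FALSE)
  }
  p <- ncol(X)
  feats <- colnames(X)
  active <- rep(TRUE, p)
  decision <- rep("tentative", p)
  hits <- integer(p)
  runs <- 0L
  df_y <- if (is.factor(y)) droplevels(y) else y
  for (run in seq_len(max_runs)) {
    if (!any(active)) break
    runs <- run
    act_idx <- which(active)
    Xa <- X[, act_idx, drop = FALSE]
    shadow <- with_seed(seed * 1000L + run, {
      apply(Xa, 2, sample)
    })
    colnames(shadow) <- paste0(".shadow.", seq_len(ncol(shadow)))
    dat <- data.frame(cbind(Xa, shadow), check.names = TRUE)
    dat$.response <- df_y
    fit <- ranger::ranger(
      dependent.variable.name = ".response", data = dat,
      num.trees = num_trees, importance = "permutation",
      seed = seed + run, num.threads = 1,
      probability = FALSE)
    imp <- fit$variable.importance
    sh_max <- max(imp[grep("^\\.shadow\\.", names(imp))])
    real_imp <- imp[make.names(feats[act_idx])]
    hits[act_idx] <- hits[act_idx] + as.integer(real_imp > sh_max)
    if (run >= 5) {
      for (i in which(active)) {
        p_conf <- stats::pbinom(hits[i] - 1L, run, 0.5, lower.tail = FALSE)
        p_rej <- stats::pbinom(hits[i], run, 0.5)
        if (p_conf < p_value) { decision[i] <- "confirmed"; active[i] <- FALSE }
        else if (p_rej < p_value) { decision[i] <- "rejected"; active[i] <- FALSE }
      }
    }
  }
  selected <- feats[decision == "confirmed" |
                      (tentative == "keep" & decision == "tentative")]
  attr(selected, "decisions") <- data.frame(
    feature = feats, decision = decision, hits = hits, runs = runs,
    stringsAsFactors = FALSE)
  selected
}
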