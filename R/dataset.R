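# Formulation tables: CSV reading/writing, threshold labels, mixtures-out
# splitting.
#
# Table dialect (UTF-8 CSV, decimal point, one row per formulation x time
# point): a_monomer, b_monomer, nA1, nB, nA2, terminus_start, terminus_end,
# polymer_feed, drug1, drug1_smiles, drug1_feed, drug1_solubilized,
# [drug2, drug2_smiles, drug2_feed, drug2_solubilized,] t_days and optional
# free-form setting columns (organic_solvent, evap_temp, aqueous_solvent,
# hydration_temp).

.MANDATORY_COLS <- c("a_monomer", "b_monomer", "nA1", "nB", "nA2",
                     "polymer_feed", "drug1", "drug1_smiles", "drug1_feed",
                     "t_days")
.KNOWN_COLS <- c(.MANDATORY_COLS, "terminus_start", "terminus_end",
                 "drug1_solubilized", "drug2", "drug2_smiles", "drug2_feed",
                 "drug2_solubilized", "organic_solvent", "evap_temp",
                 "aqueous_solvent", "hydration_temp")

.spec_cache <- new.env(parent = emptyenv())

#' @keywords internal
cached_drug <- function(name, smiles) {
  key <- paste0("drug|", name, "|", smiles)
  hit <- .spec_cache[[key]]
  if (is.null(hit)) {
    hit <- drug_spec(name, smiles)
    .spec_cache[[key]] <- hit
  }
  hit
}

#' @keywords internal
cached_polymer <- function(a, b, bl, t1, t2) {
  key <- paste("poly", a, b, paste(bl, collapse = "-"), t1, t2, sep = "|")
  hit <- .spec_cache[[key]]
  if (is.null(hit)) {
    hit <- polymer_spec(a, b, bl, termini = c(t1, t2))
    .spec_cache[[key]] <- hit
  }
  hit
}

#' Build a formulation table from a data.frame
#'
#' @param df data.frame in the documented dialect
#' @param provenance free-form source tag
#' @return object of class `pox_formulation_table`: `rows` (list of
#'   `pox_formulation`), `data` (the frame), `provenance`
#' @export
formulation_table <- function(df, provenance = "in-memory") {
  missing_cols <- setdiff(.MANDATORY_COLS, names(df))
  if (length(missing_cols)) {
    stop("format error: missing mandatory columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  unknown <- setdiff(names(df), .KNOWN_COLS)
  if (length(unknown)) {
    warning("ignoring unknown columns: ", paste(unknown, collapse = ", "),
            call. = FALSE)
  }
  if (!"terminus_start" %in% names(df)) df$terminus_start <- "Me"
  if (!"terminus_end" %in% names(df)) df$terminus_end <- "Pip"
  if (!"drug1_solubilized" %in% names(df)) df$drug1_solubilized <- NA_real_
  rows <- vector("list", nrow(df))
  errors <- character(0)
  for (i in seq_len(nrow(df))) {
    r <- df[i, ]
    res <- tryCatch({
      pol <- cached_polymer(r$a_monomer, r$b_monomer,
                            c(r$nA1, r$nB, r$nA2),
                            r$terminus_start, r$terminus_end)
      drugs <- list(cached_drug(r$drug1, r$drug1_smiles))
      feeds <- r$drug1_feed
      msol <- r$drug1_solubilized
      if (!is.null(r$drug2) && !is.na(r$drug2) && nzchar(r$drug2)) {
        drugs <- c(drugs, list(cached_drug(r$drug2, r$drug2_smiles)))
        feeds <- c(feeds, r$drug2_feed)
        msol <- c(msol, if ("drug2_solubilized" %in% names(r))
          r$drug2_solubilized else NA_real_)
      }
      settings <- as.list(r[intersect(names(r), c("organic_solvent", "evap_temp",
                                                  "aqueous_solvent",
                                                  "hydration_temp"))])
      formulation(pol, drugs, feeds, r$polymer_feed, r$t_days, msol, settings)
    }, error = function(e) conditionMessage(e))
    if (is.character(res)) errors <- c(errors, sprintf("row %d: %s", i, res))
    else rows[[i]] <- res
  }
  if (length(errors)) {
    stop("validation error:\n  ", paste(errors, collapse = "\n  "), call. = FALSE)
  }
  structure(list(rows = rows, data = df, provenance = provenance),
            class = "pox_formulation_table")
}

#' Read a formulation table from CSV
#'
#' Rows without measured solubilization are kept and flagged prediction-only;
#' malformed rows are reported with their line numbers.
#' @param path CSV file path
#' @return a `pox_formulation_table`
#' @export
read_formulation_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  formulation_table(df, provenance = path)
}

#' Write a formulation table to CSV
#' @param table a `pox_formulation_table`
#' @param path output path
#' @export
write_formulation_table <- function(table, path) {
  utils::write.csv(table$data, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @export
print.pox_formulation_table <- function(x, ...) {
  np <- sum(vapply(x$rows, function(r) any(is.na(r$m_solubilized)), logical(1)))
  cat(sprintf("<pox_formulation_table> %d formulations (%d prediction-only), %d mixture groups\n",
              length(x$rows), np, length(unique(table_group_keys(x)))))
  invisible(x)
}

#' Group keys of all rows
#' @param table a `pox_formulation_table`
#' @export
table_group_keys <- function(table) {
  vapply(table$rows, group_key, character(1))
}

#' Binary threshold labels for a table
#'
#' Positive iff the metric is greater than or equal to the threshold
#' (inclusive). For coformulations the label refers to the first (reported)
#' drug.
#'
#' @param table a `pox_formulation_table`
#' @param kind `"LC"` or `"LE"`
#' @param threshold percent threshold
#' @return factor with levels `neg`, `pos` (NA for prediction-only rows)
#' @export
label_thresholds <- function(table, kind = c("LC", "LE"), threshold) {
  kind <- match.arg(kind)
  v <- vapply(table$rows, function(r) {
    if (any(is.na(r$m_solubilized))) return(NA_real_)
    loading_metrics(r)[[kind]][1]
  }, numeric(1))
  factor(ifelse(v >= threshold, "pos", "neg"), levels = c("neg", "pos"))
}

#' @keywords internal
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Mixtures-out training/holdout split
#'
#' Assigns whole mixture groups (same A monomer, B monomer and drug set) to
#' the training (TS) or holdout set (HS) so no mixture straddles the split.
#' Greedy seeded bin-packing targets the requested TS row share and, when
#' labels are supplied, a holdout class ratio similar to the full set.
#'
#' @param table a `pox_formulation_table`
#' @param fraction target TS share of rows (default 0.8)
#' @param seed integer seed; the same seed reproduces the split exactly
#' @param labels optional label factor (from [label_thresholds()]) used for
#'   stratification
#' @return object of class `pox_split`: `assignment` (named vector
#'   group -> "TS"/"HS"), `ts`/`hs` row indices, `fraction`, `seed`
#' @export
mixtures_out_split <- function(table, fraction = 0.8, seed = 1, labels = NULL) {
  keys <- table_group_keys(table)
  n <- length(keys)
  groups <- split(seq_len(n), keys)
  gsizes <- lengths(groups)
  if (any(gsizes > (1 - fraction) * n & gsizes > 0.5 * n)) {
    warning("a single mixture group dominates the table; split will be skewed",
            call. = FALSE)
  }
  pos <- if (is.null(labels)) rep(0, n) else as.numeric(labels == "pos")
  pos[is.na(pos)] <- 0
  gpos <- vapply(groups, function(ix) sum(pos[ix]), numeric(1))
  prev_all <- sum(gpos) / n
  # seeded randomized search: many candidate group-level fills of the holdout,
  # scored by row-share and class-ratio deviation; best candidate wins
  hs_target <- (1 - fraction) * n
  best <- NULL; best_cost <- Inf
  cands <- with_seed(seed, {
    lapply(seq_len(50), function(t) sample(seq_along(groups)))
  })
  for (ordg in cands) {
    hs_rows <- 0; hs_pos <- 0; in_hs <- logical(length(groups))
    for (g in ordg) {
      if (hs_rows + gsizes[g] <= hs_target + 0.5 * gsizes[g]) {
        in_hs[g] <- TRUE
        hs_rows <- hs_rows + gsizes[g]
        hs_pos <- hs_pos + gpos[g]
        if (hs_rows >= hs_target) break
      }
    }
    prev_hs <- if (hs_rows > 0) hs_pos / hs_rows else 0
    cost <- abs(hs_rows - hs_target) / n +
      (if (is.null(labels)) 0 else 2 * abs(prev_hs - prev_all))
    if (cost < best_cost) { best_cost <- cost; best <- in_hs }
  }
  assignment <- stats::setNames(ifelse(best, "HS", "TS"), names(groups))
  ts <- sort(unlist(groups[names(assignment)[assignment == "TS"]], use.names = FALSE))
  hs <- sort(unlist(groups[names(assignment)[assignment == "HS"]], use.names = FALSE))
  structure(list(assignment = assignment, ts = ts, hs = hs,
                 fraction = fraction, seed = seed),
            class = "pox_split")
}

#' @export
print.pox_split <- function(x, ...) {
  cat(sprintf("<pox_split> %d TS / %d HS rows (%d groups, seed %d)\n",
              length(x$ts), length(x$hs), length(x$assignment), x$seed))
  invisible(x)
}

#' Serialize a split plan to JSON
#' @param x a `pox_split`
#' @param path output path
#' @export
write_split_plan <- function(x, path) {
  jsonlite::write_json(list(seed = x$seed, fraction = x$fraction,
                            assignment = as.list(x$assignment)),
                       path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
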