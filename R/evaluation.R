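# Pairwise linkage quality against a truth set.
#
# Evaluation is pair-level, not cluster-level: the unit is an unordered
# record pair, a true pair being two distinct records assigned to the same
# entity.  precision = TP/(TP+FP), recall = TP/(TP+FN), F the harmonic
# mean.  Degenerate denominators follow the usual convention (1.0 when
# nothing was found / nothing was there to find) and are logged rather
# than raised, so threshold sweeps never crash on an empty end of the
# range.

pair_key <- function(id_a, id_b) {
  paste(pmin(id_a, id_b), pmax(id_a, id_b), sep = "\x1f")
}

#' Enumerate true pairs from a truth set
#'
#' All unordered pairs of distinct records (among `ids`) sharing an
#' entity.
#'
#' @param truth A [truth_set()].
#' @param ids Record IDs under evaluation (default: all records in
#'   `truth`).  Every id must be present in the truth set.
#' @return Data frame with columns `id_a`, `id_b` (`id_a < id_b`).
#' @export
true_pairs <- function(truth, ids = truth$record_id) {
  ids <- as.character(ids)
  miss <- setdiff(ids, truth$record_id)
  if (length(miss)) {
    stop_data("record id(s) absent from truth set: ",
              paste(utils::head(miss, 5L), collapse = ", "))
  }
  ent <- truth$entity_id[match(ids, truth$record_id)]
  groups <- split(ids, ent)
  groups <- groups[lengths(groups) >= 2L]
  if (!length(groups)) {
    return(data.frame(id_a = character(0), id_b = character(0),
                      stringsAsFactors = FALSE))
  }
  pairs <- do.call(cbind, lapply(groups, function(g) combn(sort(g), 2L)))
  data.frame(id_a = pmin(pairs[1, ], pairs[2, ]),
             id_b = pmax(pairs[1, ], pairs[2, ]),
             stringsAsFactors = FALSE)
}

quality_report <- function(tp, fp, fn, threshold = NA_real_) {
  precision <- if (tp + fp == 0L) {
    clk_log("warn", "no pairs found; precision := 1 by convention")
    1
  } else tp / (tp + fp)
  recall <- if (tp + fn == 0L) {
    clk_log("warn", "no true pairs; recall := 1 by convention")
    1
  } else tp / (tp + fn)
  f <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  structure(list(true_positives = as.integer(tp),
                 false_positives = as.integer(fp),
                 false_negatives = as.integer(fn),
                 precision = precision, recall = recall, f_measure = f,
                 threshold = threshold),
            class = "quality_report")
}

#' @export
print.quality_report <- function(x, ...) {
  cat("<quality_report>",
      if (!is.na(x$threshold)) paste0(" threshold=", x$threshold), "\n",
      "  TP=", x$true_positives, " FP=", x$false_positives,
      " FN=", x$false_negatives, "\n",
      "  precision=", sprintf("%.4f", x$precision),
      " recall=", sprintf("%.4f", x$recall),
      " F=", sprintf("%.4f", x$f_measure), "\n", sep = "")
  invisible(x)
}

#' Evaluate candidate pairs against a truth set
#'
#' @param found A `candidate_pairs` data frame (or any data frame with
#'   `id_a`, `id_b`).
#' @param truth A [truth_set()].
#' @param ids Record IDs under evaluation (default: all records in
#'   `truth`); all pair members must be covered.
#' @param threshold Optional threshold annotation carried into the report.
#' @return A `quality_report` with TP/FP/FN counts and precision, recall,
#'   F-measure.
#' @export
evaluate_pairs <- function(found, truth, ids = truth$record_id,
                           threshold = NA_real_) {
  tp_df <- true_pairs(truth, ids)
  found_ids <- unique(c(found$id_a, found$id_b))
  outside <- setdiff(found_ids, ids)
  if (length(outside)) {
    stop_data("found pairs mention record(s) outside the evaluated ids: ",
              paste(utils::head(outside, 5L), collapse = ", "))
  }
  fk <- unique(pair_key(found$id_a, found$id_b))
  tk <- pair_key(tp_df$id_a, tp_df$id_b)
  tp <- sum(fk %in% tk)
  quality_report(tp = tp, fp = length(fk) - tp, fn = length(tk) - tp,
                 threshold = threshold)
}

#' Sweep Tanimoto thresholds and evaluate each
#'
#' Runs one de-duplication at the most permissive threshold and filters
#' upward (valid because pair sets nest: the pairs at a higher threshold
#' are exactly the pairs at a lower one with similarity above it).
#'
#' @param clks A [clk_dataset()].
#' @param truth A [truth_set()] covering the dataset.
#' @param thresholds Numeric vector of thresholds in (0, 1].
#' @param leaf_limit Tree leaf limit.
#' @return List of `quality_report`, one per threshold (in input order).
#' @export
threshold_sweep <- function(clks, truth, thresholds, leaf_limit = 1L) {
  for (t in thresholds) check_threshold(t)
  ds <- as_clk_dataset(clks)
  base <- deduplicate(ds, min(thresholds), leaf_limit)
  lapply(thresholds, function(t) {
    keep <- base$similarity >= t
    evaluate_pairs(base[keep, , drop = FALSE], truth, ids = ds$ids,
                   threshold = t)
  })
}

#' Tabulate a list of quality reports
#'
#' @param reports List of `quality_report` (e.g. from
#'   [threshold_sweep()]).
#' @return Data frame with one row per report: threshold, counts and
#'   metrics — ready to write as the sweep CSV.
#' @export
sweep_table <- function(reports) {
  do.call(rbind, lapply(reports, function(r)
    data.frame(threshold = r$threshold, tp = r$true_positives,
               fp = r$false_positives, fn = r$false_negatives,
               precision = r$precision, recall = r$recall,
               f_measure = r$f_measure)))
}
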