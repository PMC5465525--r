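# Linkage engine: de-duplication within one CLK dataset or linkage across
# two, with optional external blocking on a hashed key.
#
# The engine emits raw candidate pairs above the Tanimoto threshold; no
# transitive closure or one-to-one assignment is applied (clustering is a
# downstream concern, and many linkage systems differ exactly here).

new_candidate_pairs <- function(id_a, id_b, similarity,
                                nodes_visited = NA_real_,
                                comparisons = NA_real_) {
  out <- data.frame(id_a = as.character(id_a), id_b = as.character(id_b),
                    similarity = as.numeric(similarity),
                    stringsAsFactors = FALSE)
  o <- order(-out$similarity, out$id_a, out$id_b, method = "radix")
  out <- out[o, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("candidate_pairs", "data.frame")
  attr(out, "nodes_visited") <- nodes_visited
  attr(out, "comparisons") <- comparisons
  out
}

#' De-duplicate a CLK dataset under a Tanimoto threshold
#'
#' Builds one multibit tree over the CLKs and queries every CLK against it.
#' The result equals the brute-force pair set
#' \{ (i, j) : i < j, jaccard >= threshold \}: self pairs are removed and
#' each unordered pair appears once with `id_a < id_b`.
#'
#' @param clks A [clk_dataset()] or list of [clk()] objects.
#' @param threshold Tanimoto threshold in (0, 1].
#' @param leaf_limit Tree leaf limit (default 1).
#' @return A `candidate_pairs` data frame (`id_a`, `id_b`, `similarity`),
#'   sorted by similarity descending then IDs; attribute `comparisons`
#'   logs the number of leaf similarity evaluations performed.
#' @export
deduplicate <- function(clks, threshold, leaf_limit = 1L) {
  check_threshold(threshold)
  ds <- as_clk_dataset(clks)
  if (!length(ds$ids)) {
    return(new_candidate_pairs(character(0), character(0), numeric(0), 0, 0))
  }
  t0 <- Sys.time()
  tree <- multibit_tree(ds, leaf_limit)
  t1 <- Sys.time()
  r <- mbt_query_self(tree$ptr, threshold)
  t2 <- Sys.time()
  ida <- ds$ids[r$i]
  idb <- ds$ids[r$j]
  swap <- ida > idb
  tmp <- ida[swap]; ida[swap] <- idb[swap]; idb[swap] <- tmp
  out <- new_candidate_pairs(ida, idb, r$sim, r$nodes_visited, r$comparisons)
  clk_log("info", "deduplicate: n=", length(ds$ids), " threshold=", threshold,
          " pairs=", nrow(out), " comparisons=", r$comparisons,
          " build=", format(difftime(t1, t0), digits = 3),
          " query=", format(difftime(t2, t1), digits = 3))
  out
}

#' Link two CLK datasets under a Tanimoto threshold
#'
#' Builds a multibit tree over `clks_a` and queries every member of
#' `clks_b` sequentially; emits every cross pair with similarity at or
#' above the threshold (`id_a` from the left dataset, `id_b` from the
#' right).
#'
#' @param clks_a,clks_b CLK datasets of equal bit length.
#' @inheritParams deduplicate
#' @return A `candidate_pairs` data frame.
#' @export
link_datasets <- function(clks_a, clks_b, threshold, leaf_limit = 1L) {
  check_threshold(threshold)
  a <- as_clk_dataset(clks_a)
  b <- as_clk_dataset(clks_b)
  if (a$l != b$l) {
    stop_data("CLK length mismatch between datasets: ", a$l, " vs ", b$l)
  }
  if (!length(a$ids) || !length(b$ids)) {
    return(new_candidate_pairs(character(0), character(0), numeric(0), 0, 0))
  }
  tree <- multibit_tree(a, leaf_limit)
  r <- mbt_query_batch(tree$ptr, b$positions, threshold)
  out <- new_candidate_pairs(a$ids[r$j], b$ids[r$qi], r$sim,
                             r$nodes_visited, r$comparisons)
  clk_log("info", "link: n_left=", length(a$ids), " n_right=", length(b$ids),
          " threshold=", threshold, " pairs=", nrow(out),
          " comparisons=", r$comparisons)
  out
}

#' Partition records by an external blocking key
#'
#' @param records A `person_records` data frame.
#' @param rule Either a field name (the key is the field value), a string
#'   `"<field>:year"` (first four characters, e.g. year of birth from
#'   `dob`), or a function mapping the records data frame to a character
#'   key vector.
#' @param secret Optional secret; when given, block labels are keyed
#'   hashes of the key values, so clear-text keys are never stored
#'   alongside CLKs.
#' @return Named list of `person_records` blocks forming a disjoint cover
#'   of the input; records with a MISSING key form their own block
#'   (`"<missing>"`), which is never compared to the others (a documented
#'   recall cost).
#' @export
external_block <- function(records, rule, secret = NULL) {
  records <- person_records(records)
  keys <- blocking_keys(records, rule)
  lab <- keys
  if (!is.null(secret)) {
    ok <- !is.na(keys)
    lab[ok] <- paste0("b", substr(as.character(
      openssl::sha256(keys[ok], key = paste0(secret, SEP, "block"))), 1, 12))
  }
  lab[is.na(lab)] <- "<missing>"
  if (any(is.na(keys))) {
    clk_log("warn", "external_block: ", sum(is.na(keys)),
            " record(s) with MISSING blocking key form their own block")
  }
  idx <- split(seq_len(nrow(records)), lab)
  blocks <- lapply(idx, function(i) records[i, , drop = FALSE])
  clk_log("info", "external_block: ", length(blocks), " block(s), sizes: ",
          paste(vapply(blocks, nrow, integer(1)), collapse = ","))
  blocks
}

blocking_keys <- function(records, rule) {
  if (is.function(rule)) {
    keys <- as.character(rule(records))
    if (length(keys) != nrow(records)) {
      stop_data("blocking rule returned ", length(keys), " keys for ",
                nrow(records), " records")
    }
    return(keys)
  }
  rule <- as.character(rule)
  parts <- strsplit(rule, ":", fixed = TRUE)[[1]]
  field <- match.arg(parts[1], PERSON_FIELDS)
  v <- records[[field]]
  if (length(parts) == 1L) return(v)
  deriv <- match.arg(parts[2], c("year"))
  substr(v, 1L, 4L)
}

#' Blocked de-duplication of person records
#'
#' Partitions records with [external_block()], encodes and de-duplicates
#' each block independently, and concatenates the per-block pairs.  Only
#' within-block pairs can be found, so the output is always a subset of the
#' unblocked result; the payoff is less comparison work per query.
#'
#' @param records A `person_records` data frame.
#' @param rule Blocking rule, as in [external_block()].
#' @param pset A [parameter_set()].
#' @param config An [encoding_config()].
#' @inheritParams deduplicate
#' @return A `candidate_pairs` data frame; attributes `comparisons` and
#'   `nodes_visited` are summed over blocks, and `block_sizes` logs the
#'   per-block record counts.
#' @export
run_blocked_dedup <- function(records, rule, pset, config, threshold,
                              leaf_limit = 1L) {
  check_threshold(threshold)
  blocks <- external_block(records, rule, secret = config$secret)
  parts <- vector("list", length(blocks))
  comparisons <- 0
  nodes <- 0
  for (i in seq_along(blocks)) {
    clks <- encode_dataset(blocks[[i]], pset, config)
    p <- deduplicate(clks, threshold, leaf_limit)
    comparisons <- comparisons + attr(p, "comparisons")
    nodes <- nodes + attr(p, "nodes_visited")
    clk_log("info", "block ", i, ": size=", nrow(blocks[[i]]),
            " pairs=", nrow(p))
    parts[[i]] <- p
  }
  all <- do.call(rbind, lapply(parts, as.data.frame))
  out <- if (is.null(all) || !nrow(all)) {
    new_candidate_pairs(character(0), character(0), numeric(0))
  } else {
    new_candidate_pairs(all$id_a, all$id_b, all$similarity)
  }
  attr(out, "comparisons") <- comparisons
  attr(out, "nodes_visited") <- nodes
  attr(out, "block_sizes") <- vapply(blocks, nrow, integer(1))
  out
}

#' Write candidate pairs to CSV
#'
#' Columns `id_a,id_b,similarity` with similarity printed to 6 decimal
#' places, sorted by similarity descending then IDs.
#'
#' @param pairs A `candidate_pairs` data frame.
#' @param path Output path.
#' @export
write_pairs <- function(pairs, path) {
  df <- data.frame(id_a = pairs$id_a, id_b = pairs$id_b,
                   similarity = sprintf("%.6f", pairs$similarity))
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read candidate pairs from CSV
#' @param path Path written by [write_pairs()].
#' @return A `candidate_pairs` data frame.
#' @export
read_pairs <- function(path) {
  if (!file.exists(path)) stop_data("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = ",",
                          colClasses = c("character", "character", "numeric"),
                          stringsAsFactors = FALSE)
  new_candidate_pairs(df$id_a, df$id_b, df$similarity)
}
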