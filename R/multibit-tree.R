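# R interface to the multibit-tree forest.
#
# CLKs are binned by popcount; within a bin, a split-half tree is grown by
# repeatedly choosing the bit that divides the current members closest to
# half set / half unset (ties: lowest bit index, so trees are
# deterministic).  A query with popcount a visits only bins with popcount b
# in [threshold*a, a/threshold] (since J <= min(a,b)/max(a,b)) and prunes
# any subtree whose accumulated match-bit upper bound falls below the
# threshold.  Both bounds dominate the true Tanimoto of every record below,
# so retrieval is exact: no false dismissals, no spurious admissions.
#
# Trees are in-memory only and rebuilt per run; the threshold comparison is
# inclusive (similarity >= threshold counts as a match).

#' Build a multibit tree forest over a CLK dataset
#'
#' @param clks A [clk_dataset()] or list of [clk()] objects (equal length).
#' @param leaf_limit Maximum records per leaf before splitting stops
#'   (default 1).  A leaf may exceed the limit only when its members are
#'   bit-identical (no splitting bit exists).
#' @return A `multibit_tree` handle.
#' @export
multibit_tree <- function(clks, leaf_limit = 1L) {
  ds <- as_clk_dataset(clks)
  leaf_limit <- as.integer(leaf_limit)
  if (is.na(leaf_limit) || leaf_limit < 1L) stop_data("leaf_limit must be >= 1")
  ptr <- mbt_build(ds$positions, ds$l, leaf_limit)
  structure(list(ptr = ptr, ids = ds$ids, l = ds$l, n = length(ds$ids),
                 leaf_limit = leaf_limit),
            class = "multibit_tree")
}

#' @export
print.multibit_tree <- function(x, ...) {
  info <- mbt_info(x$ptr)
  cat("<multibit_tree> n=", info$n, " l=", info$l,
      " bins=", info$n_bins, " nodes=", info$n_nodes,
      " leaf_limit=", info$leaf_limit, "\n", sep = "")
  invisible(x)
}

#' Flat structural description of a multibit tree
#'
#' One row per node: its popcount bin, parent, split bit, children, the
#' match bit/value on the edge from its parent, and (for leaves) member
#' record IDs.  Intended for structural audits and teaching, not for the
#' query path.
#'
#' @param tree A [multibit_tree()].
#' @return A list with a node table (`data.frame`) and a parallel list of
#'   leaf member IDs.
#' @export
tree_structure <- function(tree) {
  d <- mbt_describe(tree$ptr)
  nodes <- data.frame(node = d$node, parent = d$parent,
                      bin_popcount = d$bin_popcount, split_bit = d$split_bit,
                      child0 = d$child0, child1 = d$child1,
                      match_bit = d$match_bit, match_value = d$match_value)
  members <- lapply(d$members, function(ix) tree$ids[ix])
  list(nodes = nodes, members = members,
       member_index = d$members)
}

#' Split-half bit choice
#'
#' Returns the unused bit position whose set-count among `members` is
#' closest to half (ties: lowest index), or `NA` if every unused bit is
#' constant across the members.
#'
#' @param members A [clk_dataset()] or list of [clk()] objects.
#' @param used Integer vector of 0-based bit positions to exclude.
#' @return 0-based bit position, or `NA_integer_`.
#' @export
choose_split_bit <- function(members, used = integer(0)) {
  ds <- as_clk_dataset(members)
  if (!length(ds$ids)) stop_data("members must be non-empty")
  r <- mbt_choose_split_bit(ds$positions, ds$l, as.integer(used))
  if (r < 0L) NA_integer_ else r
}

#' Tanimoto upper bound from accumulated match bits
#'
#' For a query with popcount `a` against a subtree in a bin of popcount
#' `b`, with `M1`/`M0` the match-bit positions of value 1/0 accumulated on
#' the path: `i_max = min(a - |{p in M0 : query bit p set}|,
#' b - |{p in M1 : query bit p unset}|)` and the bound is
#' `i_max / (a + b - i_max)` (0 when `a + b = 0` or `i_max <= 0`).  This
#' dominates the true Tanimoto of every CLK in the subtree.
#'
#' @param query A [clk()].
#' @param match_bits Data frame (or list) with elements `bit` (0-based
#'   positions) and `value` (0/1) accumulated along the root-to-node path;
#'   empty for a root.
#' @param bin_popcount Popcount of the bin the node belongs to.
#' @return Upper bound in \[0, 1\].
#' @export
tanimoto_upper_bound <- function(query, match_bits, bin_popcount) {
  a <- query$popcount
  b <- as.integer(bin_popcount)
  if (a + b == 0L) return(0)
  bits <- as.integer(match_bits$bit %||% integer(0))
  vals <- as.integer(match_bits$value %||% integer(0))
  q1 <- bits %in% query$positions
  a_def <- sum(vals == 0L & q1)        # query bits unmatchable below here
  b_def <- sum(vals == 1L & !q1)       # member bits the query cannot share
  i_max <- min(a - a_def, b - b_def, a, b)
  if (i_max <= 0L) return(0)
  i_max / (a + b - i_max)
}

#' Exact Tanimoto threshold query against a multibit tree
#'
#' Returns exactly the indexed CLKs whose Jaccard similarity with the query
#' is `>= threshold`, sorted by similarity descending, ties by record ID
#' ascending.
#'
#' @param tree A [multibit_tree()].
#' @param query A [clk()] with the tree's bit length.
#' @param threshold Tanimoto threshold in (0, 1].
#' @return Data frame with columns `record_id`, `similarity`; attributes
#'   `nodes_visited` and `comparisons` report traversal effort.
#' @export
query_tree <- function(tree, query, threshold) {
  check_threshold(threshold)
  if (!inherits(query, "clk")) stop_data("query must be a clk")
  if (query$l != tree$l) {
    stop_data("query length ", query$l, " != tree length ", tree$l)
  }
  r <- mbt_query(tree$ptr, query$positions, threshold)
  out <- data.frame(record_id = tree$ids[r$idx], similarity = r$sim,
                    stringsAsFactors = FALSE)
  o <- order(-out$similarity, out$record_id, method = "radix")
  out <- out[o, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "nodes_visited") <- r$nodes_visited
  attr(out, "comparisons") <- r$comparisons
  out
}

check_threshold <- function(threshold) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      is.na(threshold) || threshold <= 0 || threshold > 1) {
    stop_data("threshold must be a single number in (0, 1]")
  }
}
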