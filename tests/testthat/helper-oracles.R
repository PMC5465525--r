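# Shared fixtures and independent oracles.  The brute-force oracle works on
# a dense 0/1 matrix via cross products and never touches the multibit tree
# code path it is used to check.

test_config <- function(...) {
  encoding_config(secret = "test-secret", l = 1000L, k = 10L, ...)
}

# dense 0/1 matrix of a clk_dataset
clk_matrix <- function(ds) {
  n <- length(ds$ids)
  M <- matrix(0L, n, ds$l)
  for (i in seq_len(n)) {
    if (length(ds$positions[[i]])) M[i, ds$positions[[i]] + 1L] <- 1L
  }
  M
}

# full pairwise Jaccard matrix (0/0 := 0)
jaccard_matrix <- function(ds) {
  M <- clk_matrix(ds)
  I <- tcrossprod(M)
  pc <- rowSums(M)
  U <- outer(pc, pc, "+") - I
  S <- ifelse(U == 0, 0, I / U)
  S
}

# O(n^2) enumeration oracle for de-duplication
brute_pairs <- function(ds, threshold, sim = NULL) {
  if (is.null(sim)) sim <- jaccard_matrix(ds)
  hit <- which(upper.tri(sim) & sim >= threshold, arr.ind = TRUE)
  if (!nrow(hit)) {
    return(data.frame(id_a = character(0), id_b = character(0),
                      similarity = numeric(0), stringsAsFactors = FALSE))
  }
  ida <- ds$ids[hit[, 1]]
  idb <- ds$ids[hit[, 2]]
  data.frame(id_a = pmin(ida, idb), id_b = pmax(ida, idb),
             similarity = sim[hit], stringsAsFactors = FALSE)
}

pair_keys <- function(df) {
  sort(paste(pmin(df$id_a, df$id_b), pmax(df$id_a, df$id_b), sep = "|"))
}

# random CLK dataset drawn directly (independent of the encoder)
random_clks <- function(n, l = 1000L, pop_range = c(40L, 220L), seed = 1L) {
  set.seed(seed)
  pcs <- sample(pop_range[1]:pop_range[2], n, replace = TRUE)
  clk_dataset(sprintf("c%04d", seq_len(n)),
              lapply(pcs, function(p) sample.int(l, p) - 1L), l)
}

# random CLKs with planted near-duplicates so thresholds actually fire
random_clks_with_dups <- function(n, l = 1000L, seed = 1L) {
  set.seed(seed)
  base <- floor(n / 2)
  pmax_ <- min(200L, l %/% 3L)
  pmin_ <- min(60L, pmax_ - 1L)
  pcs <- sample(pmin_:pmax_, base, replace = TRUE)
  pos <- lapply(pcs, function(p) sample.int(l, p) - 1L)
  out <- pos
  for (i in seq_len(n - base)) {
    src <- pos[[sample.int(base, 1)]]
    flip <- sample.int(length(src), sample.int(8, 1))
    out[[base + i]] <- unique(c(src[-flip], sample.int(l, 4) - 1L))
  }
  clk_dataset(sprintf("c%04d", seq_len(n)), out, l)
}

# accumulated match bits (bit, value) along the path from the root to a node
node_match_bits <- function(struct, node_id) {
  nodes <- struct$nodes
  bits <- integer(0); vals <- integer(0)
  cur <- node_id
  while (!is.na(nodes$parent[cur])) {
    bits <- c(bits, nodes$match_bit[cur])
    vals <- c(vals, nodes$match_value[cur])
    cur <- nodes$parent[cur]
  }
  list(bit = bits, value = vals)
}

# record indices stored at or below a node
subtree_members <- function(struct, node_id) {
  nodes <- struct$nodes
  acc <- integer(0)
  stack <- node_id
  while (length(stack)) {
    cur <- stack[[1]]; stack <- stack[-1]
    acc <- c(acc, struct$member_index[[cur]])
    if (!is.na(nodes$child0[cur])) {
      stack <- c(stack, nodes$child0[cur], nodes$child1[cur])
    }
  }
  acc
}

# subtree members for every node in one bottom-up pass (children are
# always created after their parent, so reverse node order works)
subtree_members_all <- function(struct) {
  nodes <- struct$nodes
  acc <- struct$member_index
  for (id in rev(seq_len(nrow(nodes)))) {
    if (!is.na(nodes$child0[id])) {
      acc[[id]] <- c(acc[[id]], acc[[nodes$child0[id]]],
                     acc[[nodes$child1[id]]])
    }
  }
  acc
}

# match bits for every node, accumulated from the root downward
node_match_bits_all <- function(struct) {
  nodes <- struct$nodes
  acc <- vector("list", nrow(nodes))
  for (id in seq_len(nrow(nodes))) {
    p <- nodes$parent[id]
    if (is.na(p)) {
      acc[[id]] <- list(bit = integer(0), value = integer(0))
    } else {
      acc[[id]] <- list(bit = c(acc[[p]]$bit, nodes$match_bit[id]),
                        value = c(acc[[p]]$value, nodes$match_value[id]))
    }
  }
  acc
}

# Small raw CSV fixture written on the fly
write_fixture_csv <- function(lines, path = tempfile(fileext = ".csv")) {
  writeLines(lines, path)
  path
}
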