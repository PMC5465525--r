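test_that("choose_split_bit prefers the most balanced unused bit", {
  # bit 7 set in exactly half the members beats bit 3 set in all
  mk <- function(id, pos) clk(id, pos, 16)
  members <- list(mk("m1", c(3, 7)), mk("m2", c(3, 7)),
                  mk("m3", c(3, 1)), mk("m4", c(3, 2)))
  expect_equal(choose_split_bit(members), 7L)
  # all members bit-identical: no discriminating bit
  same <- list(mk("s1", c(1, 5)), mk("s2", c(1, 5)))
  expect_true(is.na(choose_split_bit(same)))
  # excluding the best bit falls back to the next most balanced
  expect_equal(choose_split_bit(members, used = 7L), 1L)
})

test_that("choose_split_bit equals an exhaustive argmin oracle", {
  set.seed(31)
  for (trial in 1:20) {
    l <- 64L
    n <- 20L
    ds <- clk_dataset(sprintf("m%02d", 1:n),
                      lapply(1:n, function(i) sample.int(l, 25) - 1L), l)
    M <- clk_matrix(ds)
    cnt <- colSums(M)
    bal <- abs(cnt / n - 0.5)
    bal[cnt == 0 | cnt == n] <- Inf
    oracle <- if (all(is.infinite(bal))) NA_integer_ else
      which.min(bal) - 1L  # lowest index wins ties by which.min
    expect_equal(choose_split_bit(ds), oracle)
  }
})

test_that("build_tree: degenerate inputs and structural invariants", {
  one <- clk_dataset("solo", list(c(1L, 5L)), 32)
  t1 <- multibit_tree(one)
  s1 <- tree_structure(t1)
  expect_equal(nrow(s1$nodes), 1L)
  expect_identical(s1$members[[1]], "solo")

  # two bit-identical CLKs with leaf_limit 1: one oversized leaf
  twins <- clk_dataset(c("a", "b"), list(c(2L, 9L), c(2L, 9L)), 32)
  s2 <- tree_structure(multibit_tree(twins, leaf_limit = 1))
  expect_equal(nrow(s2$nodes), 1L)
  expect_setequal(s2$members[[1]], c("a", "b"))

  # empty input is a valid empty tree
  empty <- clk_dataset(character(0), list(), 32)
  t0 <- multibit_tree(empty)
  q <- query_tree(t0, clk("q", c(1L, 2L), 32), 0.5)
  expect_equal(nrow(q), 0L)
})

test_that("structural audit: leaves partition input, members obey match bits", {
  ds <- random_clks(100, l = 200L, pop_range = c(20L, 60L), seed = 13)
  tree <- multibit_tree(ds, leaf_limit = 1)
  st <- tree_structure(tree)
  nodes <- st$nodes

  # every CLK appears in exactly one leaf, in the bin of its true popcount
  all_members <- unlist(st$member_index)
  expect_setequal(all_members, seq_len(100))
  expect_equal(length(all_members), 100L)
  leaf_rows <- which(is.na(nodes$split_bit))
  for (lr in leaf_rows) {
    for (m in st$member_index[[lr]]) {
      expect_equal(length(ds$positions[[m]]), nodes$bin_popcount[lr])
      mb <- node_match_bits(st, lr)
      if (length(mb$bit)) {
        has <- mb$bit %in% ds$positions[[m]]
        expect_identical(as.integer(has), mb$value)
      }
    }
  }

  # leaves hold at most leaf_limit members unless no split bit existed,
  # i.e. unless members are bit-identical
  for (lr in leaf_rows) {
    mem <- st$member_index[[lr]]
    if (length(mem) > 1L) {
      expect_true(length(unique(ds$positions[mem])) == 1L)
    }
  }
})

test_that("tanimoto_upper_bound matches its closed form on stated cases", {
  no_bits <- list(bit = integer(0), value = integer(0))
  q10 <- clk("q", 0:9, 100)
  expect_equal(tanimoto_upper_bound(q10, no_bits, 10), 1.0)
  expect_equal(tanimoto_upper_bound(q10, no_bits, 5), 5 / 10)
  q4 <- clk("q", c(1, 2, 3, 4), 100)
  expect_equal(tanimoto_upper_bound(q4, list(bit = 5L, value = 1L), 4),
               3 / 5)
  expect_equal(tanimoto_upper_bound(clk("z", integer(0), 100), no_bits, 0), 0)
})

test_that("bound dominates the true Tanimoto of every subtree member", {
  ds <- random_clks_with_dups(80, l = 150L, seed = 99)
  tree <- multibit_tree(ds)
  st <- tree_structure(tree)
  sim <- jaccard_matrix(ds)
  set.seed(100)
  queries <- sample.int(80, 10)
  for (qi in queries) {
    q <- ds[[qi]]
    for (nd in seq_len(nrow(st$nodes))) {
      mem <- subtree_members(st, nd)
      if (!length(mem)) next
      bound <- tanimoto_upper_bound(q, node_match_bits(st, nd),
                                    st$nodes$bin_popcount[nd])
      expect_gte(bound + 1e-12, max(sim[qi, mem]))
    }
  }
})

test_that("bound is non-increasing from parent to child", {
  ds <- random_clks(60, l = 100L, pop_range = c(10L, 40L), seed = 55)
  st <- tree_structure(multibit_tree(ds))
  q <- ds[[1]]
  for (nd in seq_len(nrow(st$nodes))) {
    p <- st$nodes$parent[nd]
    if (is.na(p)) next
    bp <- tanimoto_upper_bound(q, node_match_bits(st, p),
                               st$nodes$bin_popcount[p])
    bc <- tanimoto_upper_bound(q, node_match_bits(st, nd),
                               st$nodes$bin_popcount[nd])
    expect_lte(bc, bp + 1e-12)
  }
})

test_that("query_tree equals brute-force scan across thresholds", {
  ds <- random_clks_with_dups(200, l = 1000L, seed = 7)
  tree <- multibit_tree(ds)
  sim <- jaccard_matrix(ds)
  for (t in c(0.7, 0.85, 0.95)) {
    for (qi in c(1L, 50L, 150L, 200L)) {
      res <- query_tree(tree, ds[[qi]], t)
      oracle_idx <- which(sim[qi, ] >= t)
      expect_setequal(res$record_id, ds$ids[oracle_idx])
      expect_equal(sort(res$similarity), sort(sim[qi, oracle_idx]),
                   tolerance = 0)
      # sorted by similarity desc, ties by id asc
      expect_true(!is.unsorted(rev(res$similarity)))
    }
  }
})

test_that("threshold 1.0 returns exactly bit-identical CLKs; self always found", {
  ds <- random_clks_with_dups(100, l = 300L, seed = 17)
  tree <- multibit_tree(ds)
  for (qi in c(3L, 60L)) {
    res <- query_tree(tree, ds[[qi]], 1.0)
    ident <- which(vapply(ds$positions, identical,
                          logical(1), ds$positions[[qi]]))
    expect_setequal(res$record_id, ds$ids[ident])
    expect_true(all(res$similarity == 1.0))
    res2 <- query_tree(tree, ds[[qi]], 0.6)
    expect_true(ds$ids[qi] %in% res2$record_id)
    expect_equal(res2$similarity[res2$record_id == ds$ids[qi]], 1.0)
  }
})

test_that("query result sets nest as the threshold rises", {
  ds <- random_clks_with_dups(120, l = 400L, seed = 23)
  tree <- multibit_tree(ds)
  q <- ds[[10]]
  prev <- NULL
  for (t in c(0.6, 0.75, 0.9, 1.0)) {
    res <- query_tree(tree, q, t)
    if (!is.null(prev)) expect_true(all(res$record_id %in% prev))
    prev <- res$record_id
  }
})

test_that("query length mismatch and bad thresholds are hard errors", {
  ds <- random_clks(10, l = 100L, pop_range = c(5L, 20L), seed = 1)
  tree <- multibit_tree(ds)
  expect_error(query_tree(tree, clk("q", 1L, 50), 0.8), "length")
  expect_error(query_tree(tree, ds[[1]], 0), "threshold")
  expect_error(query_tree(tree, ds[[1]], 1.2), "threshold")
})
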