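test_that("to_grams produces overlapping bigrams, padding, unigrams", {
  expect_identical(to_grams("ANNA", "bigram", padding = FALSE),
                   c("AN", "NN", "NA"))
  expect_identical(to_grams("ANNA", "bigram", padding = TRUE),
                   c("_A", "AN", "NN", "NA", "A_"))
  expect_identical(to_grams("1990", "unigram"), c("1", "9", "9", "0"))
  # degenerate single-character value keeps its information
  expect_identical(to_grams("X", "bigram", padding = FALSE), "X")
  expect_identical(to_grams("X", "bigram", padding = TRUE), c("_X", "X_"))
  expect_error(to_grams(NA_character_, "bigram"), "non-missing")
})

test_that("hash_positions: bounds, determinism, secret sensitivity", {
  cfg <- test_config()
  p <- hash_positions("first_name\x1fAB", cfg)
  expect_true(length(p) >= 1 && length(p) <= cfg$k)
  expect_true(all(p >= 0 & p < cfg$l))
  expect_identical(p, hash_positions("first_name\x1fAB", cfg))

  # different secrets give different position sets for at least one of
  # 100 random grams (keyed-digest oracle: collision of all 100 is
  # negligible)
  cfg2 <- encoding_config(secret = "other-secret", l = 1000L, k = 10L)
  set.seed(9)
  grams <- replicate(100, paste(sample(LETTERS, 2), collapse = ""))
  differ <- vapply(grams, function(g)
    !identical(hash_positions(g, cfg), hash_positions(g, cfg2)), logical(1))
  expect_true(any(differ))

  # salting changes positions too
  expect_false(identical(hash_positions("AB", cfg),
                         hash_positions("AB", cfg, record_salt = "19900703")))
})

test_that("random hashing positions match a direct HMAC-SHA256 oracle", {
  cfg <- test_config()
  token <- "first_name\x1fAB"
  oracle <- sort(unique(vapply(seq_len(cfg$k), function(i) {
    hx <- as.character(openssl::sha256(token,
                                       key = paste0("test-secret", "\x1f", i)))
    strtoi(substr(hx, 1, 7), 16L) %% cfg$l
  }, integer(1))))
  expect_identical(hash_positions(token, cfg), oracle)
})

test_that("double hashing follows (h1 + i*h2) mod l", {
  cfg <- encoding_config(secret = "test-secret", l = 1000L, k = 10L,
                         scheme = "double_hashing")
  token <- "last_name\x1fSM"
  h1 <- strtoi(substr(as.character(
    openssl::sha256(token, key = "test-secret\x1fh1")), 1, 7), 16L)
  h2 <- strtoi(substr(as.character(
    openssl::sha256(token, key = "test-secret\x1fh2")), 1, 7), 16L)
  oracle <- sort(unique(as.integer((h1 + (0:9) * as.numeric(h2)) %% 1000)))
  expect_identical(hash_positions(token, cfg), oracle)
})

test_that("encode_clk: empty union, determinism, single-gram oracle", {
  cfg <- test_config()
  ps <- preset_parameter_set("set1")
  rec <- list(record_id = "r1", first_name = NA, last_name = NA,
              dob = NA, sex = NA)
  z <- encode_clk(rec, ps, cfg)
  expect_equal(z$popcount, 0L)
  expect_equal(z$l, 1000L)

  pop <- generate_population(20, dup_rate = 0, seed = 3)
  r <- pop$records[7, ]
  expect_identical(encode_clk(r, ps, cfg)$positions,
                   encode_clk(r, ps, cfg)$positions)

  # one bigram field value "AB" without padding: exactly the positions of
  # that single field-tagged gram
  ps1 <- parameter_set("one", "last_name",
                       gram_modes = c(last_name = "bigram"), padding = FALSE)
  c1 <- encode_clk(list(record_id = "x", last_name = "AB"), ps1, cfg)
  expect_identical(c1$positions, hash_positions("last_name\x1fAB", cfg))
  expect_true(c1$popcount >= 1 && c1$popcount <= cfg$k)
})

test_that("field tagging separates identical values in different fields", {
  cfg <- test_config()
  ps <- parameter_set("two", c("first_name", "last_name"))
  a <- encode_clk(list(record_id = "a", first_name = "ANNA",
                       last_name = "SMITH"), ps, cfg)
  b <- encode_clk(list(record_id = "b", first_name = "SMITH",
                       last_name = "ANNA"), ps, cfg)
  expect_false(identical(a$positions, b$positions))

  cfg_untagged <- test_config(field_tagging = FALSE)
  a2 <- encode_clk(list(record_id = "a", first_name = "ANNA",
                        last_name = "SMITH"), ps, cfg_untagged)
  b2 <- encode_clk(list(record_id = "b", first_name = "SMITH",
                        last_name = "ANNA"), ps, cfg_untagged)
  expect_identical(a2$positions, b2$positions)  # original untagged scheme
})

test_that("encode_dataset preserves order, count and encode_clk semantics", {
  cfg <- test_config()
  ps <- preset_parameter_set("set2")
  pop <- generate_population(40, dup_rate = 0.5,
                             model = corruption_profile("nsw_public"),
                             seed = 8)
  ds <- encode_dataset(pop$records, ps, cfg)
  expect_identical(ds$ids, pop$records$record_id)
  expect_equal(length(ds), nrow(pop$records))
  # batch encoding agrees with per-record encoding
  for (i in c(1L, 5L, nrow(pop$records))) {
    expect_identical(ds$positions[[i]],
                     encode_clk(pop$records[i, ], ps, cfg)$positions)
  }
  # permuting the input permutes the output identically
  perm <- sample(seq_len(nrow(pop$records)))
  ds2 <- encode_dataset(pop$records[perm, ], ps, cfg)
  expect_identical(ds2$ids, ds$ids[perm])
  expect_identical(ds2$positions, ds$positions[perm])
})

test_that("gram-set monotonicity: more identifiers never clear bits", {
  cfg <- test_config()
  ps_small <- preset_parameter_set("set1")
  ps_large <- preset_parameter_set("set4")  # set1 + middle name
  pop <- generate_population(100, dup_rate = 0, seed = 12)
  small <- encode_dataset(pop$records, ps_small, cfg)
  large <- encode_dataset(pop$records, ps_large, cfg)
  for (i in seq_len(100)) {
    expect_true(all(small$positions[[i]] %in% large$positions[[i]]))
  }
  expect_true(all(large$popcount >= small$popcount))
})

test_that("popcount is bounded by k times the distinct gram count", {
  cfg <- test_config()
  ps <- preset_parameter_set("set2")
  pop <- generate_population(50, dup_rate = 0, seed = 21)
  ds <- encode_dataset(pop$records, ps, cfg)
  for (i in seq_len(50)) {
    rec <- as.list(pop$records[i, ])
    ntok <- length(clklink:::record_tokens(rec, ps, cfg))
    expect_lte(ds$popcount[[i]], cfg$k * ntok)
  }
})

test_that("CLK files round-trip bit-exactly and never leak the secret", {
  cfg <- test_config()
  ps <- preset_parameter_set("set1")
  pop <- generate_population(30, dup_rate = 0.3, seed = 2)
  ds <- encode_dataset(pop$records, ps, cfg)
  path <- tempfile(fileext = ".clk")
  write_clks(ds, path)
  back <- read_clks(path)
  expect_identical(back$ids, ds$ids)
  expect_identical(back$positions, ds$positions)
  expect_equal(back$l, ds$l)
  txt <- readLines(path)
  expect_false(any(grepl("test-secret", txt, fixed = TRUE)))
  # no clear-text identifiers either
  expect_false(any(grepl(pop$records$last_name[1], txt, fixed = TRUE)))
})

test_that("encoding_config rejects bad parameters and hides the secret", {
  expect_error(encoding_config(secret = ""), "secret")
  expect_error(encoding_config(secret = "s", l = 0), "l must be")
  expect_error(encoding_config(secret = "s", k = 0), "k must be")
  out <- capture.output(print(test_config()))
  expect_false(any(grepl("test-secret", out, fixed = TRUE)))
})
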