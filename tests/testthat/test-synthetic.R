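test_that("generate_entities is deterministic, valid and unique", {
  a <- generate_entities(100, seed = 7)
  b <- generate_entities(100, seed = 7)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_equal(nrow(generate_entities(0)), 0L)

  big <- generate_entities(2000, seed = 1)
  expect_false(anyDuplicated(big$record_id) > 0)
  # all dobs valid calendar dates in canonical form
  expect_true(all(grepl("^[0-9]{8}$", big$dob)))
  expect_false(any(is.na(as.Date(big$dob, format = "%Y%m%d"))))
  expect_true(all(big$sex %in% c("M", "F")))
  # clean entities have no missing fields
  expect_false(anyNA(as.data.frame(big)[person_fields()]))
})

test_that("corrupt_value applies exactly one edit of the requested kind", {
  set.seed(11)
  expect_identical(nchar(corrupt_value("ANNA", kinds = "delete")), 3L)
  expect_identical(nchar(corrupt_value("ANNA", kinds = "insert")), 5L)
  sub <- corrupt_value("ANNA", kinds = "substitute")
  expect_identical(nchar(sub), 4L)
  expect_false(identical(sub, "ANNA"))
  tr <- corrupt_value("ABCD", kinds = "transpose")
  expect_identical(sort(strsplit(tr, "")[[1]]), c("A", "B", "C", "D"))
  expect_false(identical(tr, "ABCD"))
  # single characters skip transposition
  expect_no_error(for (i in 1:20) corrupt_value("A"))
  expect_error(corrupt_value(NA_character_), "missing")
})

test_that("all four edit kinds occur and edits stay within distance 2", {
  set.seed(13)
  out <- replicate(1000, corrupt_value("SMITH"))
  lens <- nchar(out)
  same_multiset <- vapply(out, function(o)
    identical(sort(strsplit(o, "")[[1]]), sort(strsplit("SMITH", "")[[1]])),
    logical(1))
  expect_true(any(lens == 4))                        # deletions
  expect_true(any(lens == 6))                        # insertions
  expect_true(any(lens == 5 & same_multiset))        # transpositions
  expect_true(any(lens == 5 & !same_multiset))       # substitutions
  expect_true(all(adist(out, "SMITH") <= 2))
  expect_true(all(adist(out, "SMITH") >= 1))
})

test_that("make_duplicates: clean degenerate settings reproduce originals", {
  ents <- generate_entities(50, seed = 2)
  pop0 <- make_duplicates(ents, dup_rate = 0,
                          model = corruption_model(typo_rate = 0), seed = 3)
  expect_identical(as.data.frame(pop0$records), as.data.frame(ents))
  expect_equal(nrow(true_pairs(pop0$truth)), 0L)

  # exact duplicates encode bit-identically
  popx <- make_duplicates(ents, dup_rate = 1,
                          model = corruption_model(typo_rate = 0,
                                                   field_swap_rate = 0),
                          seed = 4)
  ds <- encode_dataset(popx$records, preset_parameter_set("set1"),
                       test_config())
  tp <- true_pairs(popx$truth)
  expect_gt(nrow(tp), 0L)
  pos <- setNames(ds$positions, ds$ids)
  for (i in seq_len(nrow(tp))) {
    expect_identical(pos[[tp$id_a[i]]], pos[[tp$id_b[i]]])
  }
})

test_that("truth covers every record and duplicates share their entity", {
  pop <- generate_population(80, dup_rate = 0.8,
                             model = corruption_profile("nsw_public"),
                             seed = 9)
  expect_setequal(pop$truth$record_id, pop$records$record_id)
  # per-entity pair sets equal pairs among {original + duplicates}
  ent <- split(pop$truth$record_id, pop$truth$entity_id)
  manual <- unlist(lapply(ent[lengths(ent) > 1], function(g) {
    apply(combn(sort(g), 2), 2, paste, collapse = "|")
  }), use.names = FALSE)
  tp <- true_pairs(pop$truth)
  expect_setequal(paste(tp$id_a, tp$id_b, sep = "|"), manual)
})

test_that("population generation is fully reproducible from the seed", {
  m <- corruption_profile("wa")
  a <- generate_population(60, dup_rate = 0.5, model = m, seed = 123)
  b <- generate_population(60, dup_rate = 0.5, model = m, seed = 123)
  expect_identical(as.data.frame(a$records), as.data.frame(b$records))
  expect_identical(as.data.frame(a$truth), as.data.frame(b$truth))
})

test_that("observed missingness matches the configured marginal rate", {
  # middle name 54% missing (nsw_public profile): binomial check within
  # 3 standard errors at n = 20,000
  pop <- generate_population(14000, dup_rate = 0.45,
                             model = corruption_profile("nsw_public"),
                             seed = 42)
  n <- nrow(pop$records)
  expect_gt(n, 15000)
  p_obs <- mean(is.na(pop$records$middle_name))
  se <- sqrt(0.54 * 0.46 / n)
  expect_lt(abs(p_obs - 0.54), 3 * se)
  # a low-missingness field stays low
  expect_lt(mean(is.na(pop$records$last_name)), 0.02)
})

test_that("a single-character typo moves at most 2k bits per direction", {
  cfg <- test_config()
  ps <- parameter_set("one", "last_name")
  base <- encode_clk(list(record_id = "a", last_name = "SMITHSON"), ps, cfg)
  set.seed(33)
  for (i in 1:25) {
    corrupted <- corrupt_value("SMITHSON", kinds = "substitute")
    alt <- encode_clk(list(record_id = "b", last_name = corrupted), ps, cfg)
    lost <- setdiff(base$positions, alt$positions)
    gained <- setdiff(alt$positions, base$positions)
    expect_lte(length(lost), 2 * cfg$k)
    expect_lte(length(gained), 2 * cfg$k)
  }
})

test_that("corruption_model validates probabilities and profiles exist", {
  expect_error(corruption_model(c(first_name = 1.2)), "probabilities")
  expect_error(corruption_model(c(shoe_size = 0.1)), "unknown field")
  for (p in c("nsw_public", "nsw_private", "wa", "clean")) {
    m <- corruption_profile(p)
    expect_s3_class(m, "corruption_model")
  }
  expect_equal(corruption_profile("nsw_private")$per_field_missingness[["first_name"]], 1)
  expect_equal(corruption_profile("wa")$per_field_missingness[["middle_name"]], 0.41)
})
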