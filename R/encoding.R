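# CLK encoding: q-gram decomposition of identifier fields, keyed hashing of
# each gram k times into one shared bit vector of length l.
#
# Hashing is a secret-keyed HMAC-SHA256, so encodings cannot be rebuilt by
# anyone without the key (plain digests would be dictionary-attackable with
# public code).  Two schemes are supported:
#   random_hashing (default): k independent keyed digests per gram, the
#     iteration index mixed into the key material; resists the bit-pattern
#     frequency attacks that break double hashing.
#   double_hashing: position_i = (h1 + i*h2) mod l from two keyed digests;
#     retained for comparability with the original CLK construction.
# Optionally a stable per-record field (salt_field) is concatenated into the
# key material, hardening encodings against frequency analysis at the cost
# of only matching records that agree on the salt.

SEP <- "\x1f"  # unit separator: cannot occur in normalized values

#' Encoding configuration for CLKs
#'
#' @param secret Key material for the HMAC (required; never written to any
#'   output).
#' @param l Bloom filter length in bits (default 1000).
#' @param k Hash iterations per gram (default 10).
#' @param scheme `"random_hashing"` (default) or `"double_hashing"`.
#' @param salt_field Optional field name whose value salts the key per
#'   record.
#' @param field_tagging Prefix each gram with its field name before hashing
#'   so identical substrings in different fields set different bits
#'   (default TRUE; switch off for fidelity to the untagged original
#'   construction).
#' @param positional_unigrams Prefix unigrams with their position index so
#'   multiplicity survives set semantics (default FALSE).
#' @return An `encoding_config` object.
#' @export
encoding_config <- function(secret, l = 1000L, k = 10L,
                            scheme = c("random_hashing", "double_hashing"),
                            salt_field = NULL, field_tagging = TRUE,
                            positional_unigrams = FALSE) {
  if (missing(secret) || is.null(secret) || !nzchar(secret)) {
    stop_data("a non-empty secret is required")
  }
  scheme <- match.arg(scheme)
  l <- as.integer(l); k <- as.integer(k)
  if (is.na(l) || l < 1L) stop_data("l must be >= 1")
  if (is.na(k) || k < 1L) stop_data("k must be >= 1")
  if (!is.null(salt_field)) salt_field <- match.arg(salt_field, PERSON_FIELDS)
  structure(list(secret = secret, l = l, k = k, scheme = scheme,
                 salt_field = salt_field,
                 field_tagging = isTRUE(field_tagging),
                 positional_unigrams = isTRUE(positional_unigrams)),
            class = "encoding_config")
}

#' @export
print.encoding_config <- function(x, ...) {
  # never print the secret
  cat("<encoding_config> l=", x$l, " k=", x$k, " scheme=", x$scheme,
      " salt_field=", x$salt_field %||% "none",
      " field_tagging=", x$field_tagging, "\n", sep = "")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Decompose a normalized value into q-grams
#'
#' Bigram mode yields overlapping length-2 substrings; with `padding` a
#' boundary symbol `_` is added at each end first, so word boundaries
#' contribute grams.  Unigram mode yields single characters.  A
#' single-character value in bigram mode without padding yields that
#' character as a degenerate gram (information is preserved rather than
#' dropped).
#'
#' @param value Non-missing normalized string.
#' @param mode `"bigram"` or `"unigram"`.
#' @param padding Add boundary symbols in bigram mode (default TRUE).
#' @return Ordered character vector of grams.
#' @examples
#' to_grams("ANNA", "bigram", padding = FALSE)  # "AN" "NN" "NA"
#' to_grams("ANNA", "bigram", padding = TRUE)   # "_A" "AN" "NN" "NA" "A_"
#' to_grams("1990", "unigram")                  # "1" "9" "9" "0"
#' @export
to_grams <- function(value, mode = c("bigram", "unigram"), padding = TRUE) {
  mode <- match.arg(mode)
  if (length(value) != 1L || is.na(value) || !nzchar(value)) {
    stop_data("to_grams requires a single non-missing value")
  }
  chars <- strsplit(value, "", fixed = TRUE)[[1]]
  if (mode == "unigram") return(chars)
  if (padding) chars <- c("_", chars, "_")
  n <- length(chars)
  if (n == 1L) return(chars)  # degenerate single-character gram
  paste0(chars[-n], chars[-1L])
}

# 28-bit integer from the leading hex digits of a digest
hex_head_int <- function(hex) strtoi(substr(hex, 1L, 7L), 16L)

# Vectorized over tokens: list of sorted unique 0-based positions per token.
token_positions <- function(tokens, config, record_salt = NULL) {
  nt <- length(tokens)
  if (nt == 0L) return(list())
  l <- config$l
  k <- config$k
  saltpart <- if (is.null(record_salt) || is.na(record_salt)) "" else
    paste0(SEP, record_salt)
  if (config$scheme == "random_hashing") {
    mat <- matrix(0L, nrow = nt, ncol = k)
    for (i in seq_len(k)) {
      key <- paste0(config$secret, SEP, i, saltpart)
      hx <- as.character(openssl::sha256(tokens, key = key))
      mat[, i] <- hex_head_int(hx) %% l
    }
    lapply(seq_len(nt), function(r) sort(unique(mat[r, ])))
  } else {
    h1 <- hex_head_int(as.character(openssl::sha256(
      tokens, key = paste0(config$secret, SEP, "h1", saltpart))))
    h2 <- hex_head_int(as.character(openssl::sha256(
      tokens, key = paste0(config$secret, SEP, "h2", saltpart))))
    iters <- 0:(k - 1L)
    lapply(seq_len(nt), function(r)
      sort(unique(as.integer((h1[r] + iters * as.numeric(h2[r])) %% l))))
  }
}

#' Bit positions a field-tagged gram hashes to
#'
#' Draws exactly `k` positions in `[0, l)` (hash collisions may reduce the
#' distinct count).  Deterministic in (gram, config, salt).
#'
#' @param gram A field-tagged gram (the token actually hashed).
#' @param config An [encoding_config()].
#' @param record_salt Optional per-record salt value.
#' @return Sorted unique integer vector of 0-based bit positions.
#' @export
hash_positions <- function(gram, config, record_salt = NULL) {
  if (!inherits(config, "encoding_config")) {
    stop_data("config must be an encoding_config")
  }
  token_positions(as.character(gram), config, record_salt)[[1]]
}

#' Construct a CLK object
#'
#' @param record_id Record identifier.
#' @param positions Integer vector of 0-based set-bit positions.
#' @param l Bit vector length.
#' @return A `clk` object with cached popcount.
#' @export
clk <- function(record_id, positions, l) {
  positions <- sort(unique(as.integer(positions)))
  l <- as.integer(l)
  if (length(positions) && (positions[1] < 0L || positions[length(positions)] >= l)) {
    stop_data("bit positions must lie in [0, l)")
  }
  structure(list(record_id = as.character(record_id), positions = positions,
                 l = l, popcount = length(positions)), class = "clk")
}

#' @export
print.clk <- function(x, ...) {
  cat("<clk> ", x$record_id, ": l=", x$l, " popcount=", x$popcount, "\n",
      sep = "")
  invisible(x)
}

#' Construct a CLK dataset (columnar collection of CLKs)
#'
#' @param ids Character vector of unique record IDs.
#' @param positions List (parallel to `ids`) of 0-based set-bit position
#'   vectors.
#' @param l Bit vector length shared by all CLKs.
#' @param meta Optional named list of provenance (k, scheme, pset name);
#'   never contains the secret.
#' @return A `clk_dataset`.
#' @export
clk_dataset <- function(ids, positions, l, meta = list()) {
  ids <- as.character(ids)
  if (anyDuplicated(ids)) stop_data("duplicate record IDs in CLK dataset")
  if (length(ids) != length(positions)) {
    stop_data("ids and positions lengths differ")
  }
  l <- as.integer(l)
  positions <- lapply(positions, function(p) sort(unique(as.integer(p))))
  bad <- vapply(positions, function(p)
    length(p) > 0L && (p[1] < 0L || p[length(p)] >= l), logical(1))
  if (any(bad)) stop_data("bit positions must lie in [0, l)")
  structure(list(ids = ids, positions = positions, l = l,
                 popcount = vapply(positions, length, integer(1)),
                 meta = meta),
            class = "clk_dataset")
}

#' @export
length.clk_dataset <- function(x) length(x$ids)

#' @export
print.clk_dataset <- function(x, ...) {
  cat("<clk_dataset> n=", length(x$ids), " l=", x$l,
      " mean popcount=", round(mean(x$popcount), 1), "\n", sep = "")
  invisible(x)
}

#' Extract one CLK from a dataset
#' @param x A `clk_dataset`.
#' @param i Index or record ID.
#' @export
`[[.clk_dataset` <- function(x, i) {
  if (is.character(i)) i <- match(i, x$ids)
  clk(x$ids[[i]], x$positions[[i]], x$l)
}

as_clk_dataset <- function(x) {
  if (inherits(x, "clk_dataset")) return(x)
  if (inherits(x, "clk")) x <- list(x)
  if (is.list(x) && all(vapply(x, inherits, logical(1), "clk"))) {
    if (!length(x)) stop_data("empty list: construct clk_dataset() directly")
    ls <- unique(vapply(x, function(c) c$l, integer(1)))
    if (length(ls) != 1L) stop_data("CLKs have differing lengths: ",
                                    paste(ls, collapse = ", "))
    return(clk_dataset(vapply(x, function(c) c$record_id, ""),
                       lapply(x, function(c) c$positions), ls))
  }
  stop_data("expected a clk_dataset or list of clk objects")
}

# Tokens (field-tagged grams) for one record under a parameter set.
record_tokens <- function(rec, pset, config) {
  toks <- character(0)
  for (f in pset$included_fields) {
    v <- rec[[f]]
    if (is.null(v) || is.na(v) || !nzchar(v)) next
    g <- to_grams(v, pset$gram_modes[[f]], pset$padding)
    if (config$positional_unigrams && pset$gram_modes[[f]] == "unigram") {
      g <- paste0(seq_along(g), ":", g)
    }
    g <- unique(g)  # set semantics: duplicate grams contribute once
    toks <- c(toks, if (config$field_tagging) paste0(f, SEP, g) else g)
  }
  unique(toks)
}

#' Encode one person record into a CLK
#'
#' Bits are the union, over all included non-missing fields and all their
#' grams, of [hash_positions()].  Missing fields contribute nothing; a
#' record whose included fields are all missing yields the all-zero CLK
#' (with a logged warning) rather than an error, so it flows through the
#' pipeline and surfaces as a non-match.
#'
#' @param record A single-row `person_records` (or list with field values).
#' @param pset A [parameter_set()].
#' @param config An [encoding_config()].
#' @return A [clk()].
#' @export
encode_clk <- function(record, pset, config) {
  if (inherits(record, "data.frame")) {
    if (nrow(record) != 1L) stop_data("encode_clk expects exactly one record")
    record <- as.list(record)
  }
  toks <- record_tokens(record, pset, config)
  salt <- if (!is.null(config$salt_field)) record[[config$salt_field]] else NULL
  pos <- sort(unique(unlist(token_positions(toks, config, salt))))
  if (!length(toks)) {
    clk_log("warn", "record ", record$record_id,
            ": all included fields MISSING -> all-zero CLK")
  }
  clk(record$record_id %||% "<unnamed>", pos, config$l)
}

#' Encode a dataset of person records into CLKs
#'
#' One CLK per record, input order preserved; records are never dropped.
#' Hashing is memoised per distinct gram token, so large datasets with
#' repeated values encode quickly (unless `salt_field` is set, which makes
#' key material record-specific).
#'
#' @inheritParams encode_clk
#' @param records A `person_records` data frame.
#' @return A [clk_dataset()].
#' @export
encode_dataset <- function(records, pset, config) {
  records <- person_records(records)
  n <- nrow(records)
  rec_list <- lapply(seq_len(n), function(i) as.list(records[i, ]))
  tok_list <- lapply(rec_list, record_tokens, pset = pset, config = config)
  if (is.null(config$salt_field)) {
    all_tok <- unique(unlist(tok_list))
    posmap <- token_positions(all_tok, config, NULL)
    positions <- lapply(tok_list, function(tk) {
      if (!length(tk)) return(integer(0))
      sort(unique(unlist(posmap[match(tk, all_tok)])))
    })
  } else {
    positions <- lapply(seq_len(n), function(i) {
      sort(unique(unlist(token_positions(
        tok_list[[i]], config, rec_list[[i]][[config$salt_field]]))))
    })
  }
  zero <- sum(vapply(positions, length, integer(1)) == 0L)
  if (zero > 0L) {
    clk_log("warn", zero, " record(s) encoded to all-zero CLKs ",
            "(all included fields MISSING)")
  }
  clk_log("info", "encode_dataset: records in=", n, " CLKs out=", n,
          " (pset=", pset$name, ", l=", config$l, ", k=", config$k, ")")
  clk_dataset(records$record_id, positions, config$l,
              meta = list(k = config$k, scheme = config$scheme,
                          pset = pset$name))
}
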