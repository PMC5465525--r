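# Synthetic person populations with known truth, standing in for the
# restricted hospital admission datasets: per-entity duplicate records
# (Poisson counts, emulating repeat admissions), single-edit typographical
# corruption of duplicates, and per-field missingness applied marginally to
# all records so observed missingness matches the configured profile.

#' Corruption model for synthetic populations
#'
#' @param per_field_missingness Named numeric vector of per-field missing
#'   probabilities (fields omitted default to 0).
#' @param typo_rate Probability that each name/suburb/address field of a
#'   duplicate receives exactly one typographical edit (default 0.15).
#' @param edit_kinds Subset of `insert`, `delete`, `substitute`,
#'   `transpose`, drawn with equal weight.
#' @param field_swap_rate Probability that a duplicate's first and last
#'   names are swapped (default 0.02).
#' @param name Label.
#' @return A `corruption_model`.
#' @export
corruption_model <- function(per_field_missingness = numeric(0),
                             typo_rate = 0.15,
                             edit_kinds = c("insert", "delete",
                                            "substitute", "transpose"),
                             field_swap_rate = 0.02,
                             name = "custom") {
  miss <- setNames(numeric(length(PERSON_FIELDS)), PERSON_FIELDS)
  if (length(per_field_missingness)) {
    bad <- setdiff(names(per_field_missingness), PERSON_FIELDS)
    if (length(bad)) stop_data("unknown field(s): ", paste(bad, collapse = ", "))
    miss[names(per_field_missingness)] <- as.numeric(per_field_missingness)
  }
  edit_kinds <- match.arg(edit_kinds, several.ok = TRUE)
  probs <- c(miss, typo_rate = typo_rate, field_swap_rate = field_swap_rate)
  if (any(probs < 0 | probs > 1 | is.na(probs))) {
    stop_data("all probabilities must lie in [0, 1]")
  }
  structure(list(per_field_missingness = miss, typo_rate = typo_rate,
                 edit_kinds = edit_kinds, field_swap_rate = field_swap_rate,
                 name = name),
            class = "corruption_model")
}

#' Missingness profiles emulating the hospital datasets
#'
#' Named presets of marginal per-field missingness: `nsw_public` (high
#' middle-name missingness, 54%), `nsw_private` (all name fields entirely
#' missing — the stratum on which de-duplication degenerates into
#' dob/sex-only matching), and `wa` (low missingness overall, middle name
#' 41%).  Percentages below 1% are modeled as 0.5%.
#'
#' @param profile One of `"nsw_public"`, `"nsw_private"`, `"wa"`,
#'   `"clean"` (all zero).
#' @param ... Overrides passed to [corruption_model()] (e.g. `typo_rate`).
#' @return A `corruption_model`.
#' @export
corruption_profile <- function(profile = c("nsw_public", "nsw_private",
                                           "wa", "clean"), ...) {
  profile <- match.arg(profile)
  miss <- switch(profile,
    nsw_public = c(first_name = 0.03, middle_name = 0.54, last_name = 0.005,
                   dob = 0, sex = 0.005, suburb = 0.005, address = 0.02,
                   postcode = 0.005),
    nsw_private = c(first_name = 1, middle_name = 1, last_name = 1,
                    dob = 0, sex = 0.005, suburb = 0.03, address = 0.22,
                    postcode = 0.03),
    wa = c(first_name = 0.005, middle_name = 0.41, last_name = 0.005,
           dob = 0.005, sex = 0.005, suburb = 0.005, address = 0.005,
           postcode = 0.005),
    clean = numeric(0))
  corruption_model(per_field_missingness = miss, name = profile, ...)
}

# run code under a temporary RNG state seeded with `seed`
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate clean synthetic person entities
#'
#' `n` fully populated, normalized records with realistic name, date of
#' birth, sex and locality distributions drawn from bundled frequency
#' tables.  Deterministic given `seed`.  Record IDs are `p<index>-0`; the
#' entity a record belongs to is the record itself (duplicates added by
#' [make_duplicates()] share the prefix).
#'
#' @param n Number of entities.
#' @param seed Integer seed (optional).
#' @return A `person_records` data frame of `n` clean records.
#' @export
generate_entities <- function(n, seed = NULL) {
  n <- as.integer(n)
  if (is.na(n) || n < 0L) stop_data("n must be >= 0")
  if (n == 0L) {
    return(person_records(data.frame(record_id = character(0))))
  }
  with_seed(seed, {
    sex <- sample(c("M", "F"), n, replace = TRUE)
    first <- ifelse(sex == "M", sample_ranked(FIRST_NAMES_M, n),
                    sample_ranked(FIRST_NAMES_F, n))
    middle <- ifelse(sex == "M", sample_ranked(FIRST_NAMES_M, n),
                     sample_ranked(FIRST_NAMES_F, n))
    last <- sample_ranked(LAST_NAMES, n)
    dob <- format(as.Date("1915-01-01") +
                    sample.int(as.integer(as.Date("2006-01-01") -
                                          as.Date("1915-01-01")), n,
                               replace = TRUE) - 1L, "%Y%m%d")
    si <- sample.int(length(SUBURBS), n, replace = TRUE,
                     prob = rank_weights(length(SUBURBS)))
    address <- paste(sample.int(999L, n, replace = TRUE),
                     sample(STREET_NAMES, n, replace = TRUE),
                     sample(STREET_TYPES, n, replace = TRUE))
    person_records(data.frame(
      record_id = sprintf("p%06d-0", seq_len(n)),
      first_name = first, middle_name = middle, last_name = last,
      dob = dob, sex = sex, suburb = SUBURBS[si], address = address,
      postcode = POSTCODES[si], stringsAsFactors = FALSE))
  })
}

#' Apply one typographical edit to a value
#'
#' Exactly one edit at a uniformly chosen position: insertion of a random
#' letter, deletion, substitution (always to a different character), or
#' adjacent transposition (only at positions where the neighbours differ;
#' falls back to substitution when no such position exists, so the result
#' always differs from the input).  Uses the current RNG state.
#'
#' @param value Non-missing string.
#' @param kinds Edit kinds to draw from.
#' @return The corrupted string (Levenshtein distance 1, or 2 for a
#'   transposition).
#' @export
corrupt_value <- function(value, kinds = c("insert", "delete",
                                           "substitute", "transpose")) {
  if (is.na(value) || !nzchar(value)) stop_data("cannot corrupt a missing value")
  chars <- strsplit(value, "", fixed = TRUE)[[1]]
  n <- length(chars)
  kinds <- match.arg(kinds, several.ok = TRUE)
  if (n < 2L) kinds <- setdiff(kinds, "transpose")
  if (n < 2L && "delete" %in% kinds && length(kinds) > 1L) {
    kinds <- setdiff(kinds, "delete")  # deleting the only character loses the value
  }
  kind <- kinds[sample.int(length(kinds), 1L)]
  if (kind == "transpose") {
    cand <- which(chars[-n] != chars[-1L])
    if (!length(cand)) kind <- "substitute"  # e.g. "AAAA"
  }
  out <- switch(kind,
    insert = {
      pos <- sample.int(n + 1L, 1L)
      append(chars, sample(LETTERS, 1L), after = pos - 1L)
    },
    delete = chars[-sample.int(n, 1L)],
    substitute = {
      pos <- sample.int(n, 1L)
      chars[pos] <- sample(setdiff(LETTERS, chars[pos]), 1L)
      chars
    },
    transpose = {
      pos <- cand[sample.int(length(cand), 1L)]
      chars[c(pos, pos + 1L)] <- chars[c(pos + 1L, pos)]
      chars
    })
  paste(out, collapse = "")
}

TYPO_FIELDS <- c("first_name", "middle_name", "last_name", "suburb",
                 "address")

#' Add corrupted duplicate records and apply missingness
#'
#' Each entity receives a Poisson(`dup_rate`) number of duplicate records.
#' Duplicates are independently corrupted: with probability
#' `field_swap_rate` first and last names swap, and each name/suburb/
#' address field receives one typographical edit with probability
#' `typo_rate`.  Missingness is then applied independently per field to
#' originals and duplicates alike, so the observed marginal missingness
#' matches `per_field_missingness`.  (Dates of birth are never typo-edited:
#' an edit could leave the canonical `YYYYMMDD` space; dob data entry
#' errors are not modeled.)
#'
#' @param entities Clean records from [generate_entities()].
#' @param dup_rate Expected duplicates per entity (default 0.5).
#' @param model A [corruption_model()] or [corruption_profile()].
#' @param seed Integer seed (optional).
#' @return A `synthetic_population`: list with `records`
#'   (`person_records`, originals first), `truth` ([truth_set()] mapping
#'   each record to its entity), `seed`, and `model`.
#' @export
make_duplicates <- function(entities, dup_rate = 0.5,
                            model = corruption_model(), seed = NULL) {
  if (dup_rate < 0) stop_data("dup_rate must be >= 0")
  entities <- person_records(entities)
  n <- nrow(entities)
  with_seed(seed, {
    entity_of <- sub("-0$", "", entities$record_id)
    ndup <- if (n) rpois(n, dup_rate) else integer(0)
    dups <- vector("list", sum(ndup > 0L))
    dup_entity <- vector("list", sum(ndup > 0L))
    di <- 0L
    for (i in which(ndup > 0L)) {
      orig <- entities[i, , drop = FALSE]
      block <- orig[rep(1L, ndup[i]), , drop = FALSE]
      block$record_id <- sprintf("%s-%d", entity_of[i], seq_len(ndup[i]))
      for (d in seq_len(ndup[i])) {
        if (runif(1) < model$field_swap_rate) {
          tmp <- block$first_name[d]
          block$first_name[d] <- block$last_name[d]
          block$last_name[d] <- tmp
        }
        for (f in TYPO_FIELDS) {
          v <- block[[f]][d]
          if (!is.na(v) && runif(1) < model$typo_rate) {
            # re-normalize so stored values stay canonical (an edit can
            # create a leading/trailing or doubled space)
            block[[f]][d] <- normalize_field(corrupt_value(v, model$edit_kinds), f)
          }
        }
      }
      di <- di + 1L
      dups[[di]] <- block
      dup_entity[[di]] <- rep(entity_of[i], ndup[i])
    }
    all_df <- rbind(as.data.frame(entities),
                    if (di) do.call(rbind, lapply(dups, as.data.frame)))
    all_entity <- c(entity_of, unlist(dup_entity))
    # marginal missingness on originals and duplicates alike
    for (f in PERSON_FIELDS) {
      p <- model$per_field_missingness[[f]]
      if (p > 0) {
        hit <- runif(nrow(all_df)) < p
        all_df[[f]][hit] <- NA_character_
      }
    }
    records <- person_records(all_df)
    truth <- truth_set(records$record_id, all_entity)
    structure(list(records = records, truth = truth, seed = seed,
                   model = model),
              class = "synthetic_population")
  })
}

#' Generate a full synthetic population in one call
#'
#' @inheritParams generate_entities
#' @inheritParams make_duplicates
#' @return A `synthetic_population` (see [make_duplicates()]).
#' @export
generate_population <- function(n, dup_rate = 0.5,
                                model = corruption_model(), seed = NULL) {
  s2 <- if (is.null(seed)) NULL else (seed + 1L) %% .Machine$integer.max
  ents <- generate_entities(n, seed)
  make_duplicates(ents, dup_rate, model, s2)
}

#' @export
print.synthetic_population <- function(x, ...) {
  cat("<synthetic_population> records=", nrow(x$records),
      " entities=", length(unique(x$truth$entity_id)),
      " model=", x$model$name, "\n", sep = "")
  invisible(x)
}
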