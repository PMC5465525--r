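# Parameter sets: which identifier fields enter the CLK and how each is
# q-gram decomposed.  The four presets mirror typical blocking/linkage
# variable choices in operational record linkage: set 1 is the lean
# name/dob/sex key, set 2 uses all eight identifiers, set 3 adds locality
# to set 1, set 4 adds middle name to set 1.

# Default gram mode per field: bigrams for free-text fields, unigrams for
# short (near-)numeric fields, where a single typo would otherwise destroy
# both of the only bigrams the value has.
DEFAULT_GRAM_MODES <- c(first_name = "bigram", middle_name = "bigram",
                        last_name = "bigram", dob = "unigram",
                        sex = "unigram", suburb = "bigram",
                        address = "bigram", postcode = "unigram")

#' Define a CLK parameter set
#'
#' @param name Label for the set.
#' @param included_fields Non-empty subset of [person_fields()], in the
#'   order fields should be processed.
#' @param gram_modes Named character vector mapping fields to `"unigram"`
#'   or `"bigram"`; defaults to bigrams for name/address-like fields and
#'   unigrams for dob, sex and postcode.
#' @param padding Add one boundary symbol (`_`) at each end of a value
#'   before bigram decomposition (default TRUE).
#' @return A `parameter_set` object.
#' @export
parameter_set <- function(name, included_fields, gram_modes = NULL,
                          padding = TRUE) {
  included_fields <- as.character(included_fields)
  if (!length(included_fields)) stop_data("included_fields must be non-empty")
  bad <- setdiff(included_fields, PERSON_FIELDS)
  if (length(bad)) {
    stop_data("unknown field(s): ", paste(bad, collapse = ", "))
  }
  if (anyDuplicated(included_fields)) stop_data("included_fields must be unique")
  modes <- DEFAULT_GRAM_MODES[included_fields]
  if (!is.null(gram_modes)) {
    if (is.null(names(gram_modes))) stop_data("gram_modes must be named")
    for (f in names(gram_modes)) {
      m <- match.arg(gram_modes[[f]], c("unigram", "bigram"))
      modes[[f]] <- m
    }
  }
  structure(list(name = as.character(name),
                 included_fields = included_fields,
                 gram_modes = modes,
                 padding = isTRUE(padding)),
            class = "parameter_set")
}

#' The four preset parameter sets
#'
#' * `set1`: first name, last name, date of birth, sex
#' * `set2`: all eight identifier fields
#' * `set3`: set 1 plus suburb and postcode
#' * `set4`: set 1 plus middle name
#'
#' @param name One of `"set1"`..`"set4"`.
#' @param ... Passed on to [parameter_set()] (e.g. `gram_modes`, `padding`).
#' @return A `parameter_set`.
#' @export
preset_parameter_set <- function(name = c("set1", "set2", "set3", "set4"),
                                 ...) {
  name <- match.arg(name)
  base1 <- c("first_name", "last_name", "dob", "sex")
  fields <- switch(name,
    set1 = base1,
    set2 = PERSON_FIELDS,
    set3 = c(base1, "suburb", "postcode"),
    set4 = c("first_name", "middle_name", "last_name", "dob", "sex"))
  parameter_set(name, fields, ...)
}

#' @export
print.parameter_set <- function(x, ...) {
  cat("<parameter_set>", x$name, "\n")
  for (f in x$included_fields) {
    cat("  ", format(f, width = 12), x$gram_modes[[f]], "\n")
  }
  cat("  padding:", x$padding, "\n")
  invisible(x)
}
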