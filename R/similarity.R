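# Bit-vector similarity between CLKs.  Both measures are set measures over
# set-bit positions; they are monotonically related by D = 2J/(1+J).

check_same_length <- function(a, b) {
  if (!inherits(a, "clk") || !inherits(b, "clk")) {
    stop_data("jaccard/dice expect clk objects")
  }
  if (a$l != b$l) {
    stop_data("CLK length mismatch: ", a$l, " vs ", b$l)
  }
}

intersection_size <- function(a, b) {
  length(intersect(a$positions, b$positions))
}

#' Jaccard (Tanimoto) similarity of two CLKs
#'
#' \eqn{J(A,B) = |A \cap B| / |A \cup B|} over set-bit positions.  Two
#' all-zero vectors return 0 by convention (with a logged warning), so
#' records with fully missing identifiers flow through as non-matches.
#'
#' @param a,b [clk()] objects of equal length.
#' @return Similarity in \[0, 1\].
#' @export
jaccard <- function(a, b) {
  check_same_length(a, b)
  i <- intersection_size(a, b)
  u <- a$popcount + b$popcount - i
  if (u == 0L) {
    clk_log("warn", "jaccard of two all-zero CLKs (", a$record_id, ", ",
            b$record_id, ") -> 0 by convention")
    return(0)
  }
  i / u
}

#' Sørensen-Dice coefficient of two CLKs
#'
#' \eqn{D(A,B) = 2|A \cap B| / (|A| + |B|)}; both all-zero returns 0 by
#' convention.
#'
#' @inheritParams jaccard
#' @return Similarity in \[0, 1\].
#' @export
dice <- function(a, b) {
  check_same_length(a, b)
  i <- intersection_size(a, b)
  s <- a$popcount + b$popcount
  if (s == 0L) {
    clk_log("warn", "dice of two all-zero CLKs -> 0 by convention")
    return(0)
  }
  2 * i / s
}
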