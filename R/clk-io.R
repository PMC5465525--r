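# Line-oriented CLK file format:
#   #clklink<TAB>l=1000<TAB>k=10<TAB>scheme=random_hashing<TAB>pset=set1
#   <record_id><TAB><base64 bit vector><TAB><popcount>
# Bit order: position 0 is the most significant bit of the first byte, so
# files are bit-exact across platforms.  The secret never appears.

pack_positions <- function(pos, l) {
  nb <- (l + 7L) %/% 8L
  b <- integer(nb)
  if (length(pos)) {
    idx <- pos %/% 8L + 1L
    val <- bitwShiftL(1L, 7L - pos %% 8L)
    agg <- tapply(val, idx, function(v) Reduce(bitwOr, v))
    b[as.integer(names(agg))] <- as.integer(agg)
  }
  as.raw(b)
}

unpack_positions <- function(bytes, l) {
  bits <- as.integer(rawToBits(bytes))  # LSB-first within each byte
  nb <- length(bytes)
  pos_of <- rep((seq_len(nb) - 1L) * 8L, each = 8L) + rep(7:0, nb)
  pos <- sort(pos_of[bits == 1L])
  pos[pos < l]
}

#' Write CLKs to a text file
#'
#' @param clks A [clk_dataset()] (or list of [clk()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_clks <- function(clks, path) {
  ds <- as_clk_dataset(clks)
  meta <- ds$meta
  header <- paste0("#clklink\tl=", ds$l,
                   "\tk=", meta$k %||% NA,
                   "\tscheme=", meta$scheme %||% NA,
                   "\tpset=", meta$pset %||% NA)
  enc <- vapply(ds$positions, function(p)
    openssl::base64_encode(pack_positions(p, ds$l)), "")
  lines <- c(header, paste(ds$ids, enc, ds$popcount, sep = "\t"))
  writeLines(lines, path)
  clk_log("info", "write_clks: ", length(ds$ids), " CLKs -> ", path)
  invisible(path)
}

#' Read CLKs from a text file written by [write_clks()]
#'
#' @param path Input path.
#' @return A [clk_dataset()].
#' @export
read_clks <- function(path) {
  if (!file.exists(path)) stop_data("file not found: ", path)
  lines <- readLines(path)
  if (!length(lines) || !startsWith(lines[1], "#clklink")) {
    stop_data("not a CLK file (missing #clklink header): ", path)
  }
  hdr <- strsplit(lines[1], "\t", fixed = TRUE)[[1]][-1]
  kv <- strsplit(hdr, "=", fixed = TRUE)
  meta <- setNames(lapply(kv, `[`, 2L), vapply(kv, `[`, "", 1L))
  l <- as.integer(meta$l)
  if (is.na(l)) stop_data("CLK header lacks a valid l: ", path)
  body <- lines[-1]
  body <- body[nzchar(body)]
  parts <- strsplit(body, "\t", fixed = TRUE)
  if (length(parts) && any(lengths(parts) != 3L)) {
    stop_data("malformed CLK line(s) in ", path)
  }
  ids <- vapply(parts, `[`, "", 1L)
  positions <- lapply(parts, function(p)
    unpack_positions(openssl::base64_decode(p[2]), l))
  pop_declared <- as.integer(vapply(parts, `[`, "", 3L))
  pop_actual <- vapply(positions, length, integer(1))
  if (any(pop_declared != pop_actual)) {
    stop_data("popcount mismatch for record(s): ",
              paste(utils::head(ids[pop_declared != pop_actual], 5L),
                    collapse = ", "))
  }
  clk_dataset(ids, positions, l,
              meta = list(k = as.integer(meta$k),
                          scheme = meta$scheme, pset = meta$pset))
}
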