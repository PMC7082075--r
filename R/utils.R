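# Shared constants and small helpers.

#' The 20 canonical amino-acid one-letter codes
#' @keywords internal
AA_CANONICAL <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Kyte-Doolittle hydropathy scale (kcal-free index units).
KD_HYDROPATHY <- c(
  A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
  Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I =  4.5,
  L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
  S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2
)

seq_chars <- function(x) {
  if (nchar(x) == 0L) return(character(0))
  strsplit(x, "", fixed = TRUE)[[1L]]
}

assert_protein_sequence <- function(sequence, id = "<sequence>") {
  ch <- seq_chars(sequence)
  bad <- setdiff(unique(ch), c(AA_CANONICAL, "X"))
  if (length(bad) > 0L) {
    stop("protein '", id, "' contains non-canonical letters: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

# Empty interval table; start/end are 1-based inclusive residue coordinates.
interval_df <- function(start = integer(0), end = integer(0)) {
  data.frame(start = as.integer(start), end = as.integer(end))
}

# Parse "50-72;80-90" -> interval_df. Empty/NA -> zero rows.
parse_intervals <- function(text) {
  if (is.na(text) || !nzchar(trimws(text))) return(interval_df())
  parts <- trimws(strsplit(text, ";", fixed = TRUE)[[1L]])
  parts <- parts[nzchar(parts)]
  m <- regmatches(parts, regexec("^([0-9]+)-([0-9]+)$", parts))
  ok <- vapply(m, length, integer(1)) == 3L
  if (any(!ok)) {
    stop("malformed interval '", parts[!ok][1L], "' (expected 'start-end')",
         call. = FALSE)
  }
  start <- as.integer(vapply(m, `[`, character(1), 2L))
  end <- as.integer(vapply(m, `[`, character(1), 3L))
  bad <- start > end
  if (any(bad)) {
    stop("malformed interval '", parts[bad][1L], "': start > end", call. = FALSE)
  }
  interval_df(start, end)
}

format_intervals <- function(iv) {
  if (nrow(iv) == 0L) return("")
  paste(sprintf("%d-%d", iv$start, iv$end), collapse = ";")
}

# TRUE where [s1,e1] overlaps [s2,e2] by at least one residue.
intervals_overlap <- function(s1, e1, s2, e2) s1 <= e2 & s2 <= e1

split_field <- function(text, sep = ";") {
  if (is.na(text) || !nzchar(trimws(text))) return(character(0))
  out <- trimws(strsplit(text, sep, fixed = TRUE)[[1L]])
  out[nzchar(out)]
}

# Small deterministic content hash (polynomial rolling hash mod 2^31-1),
# used only to stamp generator configs into run logs / truth tables.
content_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 0
  p <- 2147483647
  for (b in bytes) h <- (h * 131 + b) %% p
  sprintf("%08x", h)
}
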