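# Independent oracles and small fixture builders used across the suite.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Brute-force SBM scanner: tests every (start, linker) pair by direct
# character-class membership. Deliberately structured as plain nested loops,
# independent of the package's vectorized implementation.
oracle_matches <- function(sequence, motif_type) {
  ch <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  L <- length(ch)
  ali <- c("I", "L", "M", "V")
  aro <- c("F", "Y", "W")
  phi <- c("F", "I", "L", "M", "V", "W", "Y")
  fy <- c("F", "Y")
  rk <- c("R", "K")
  n_len <- if (motif_type == "I") 5L else 3L
  linkers <- if (motif_type == "I") 2:13 else 3:15
  hits <- list()
  for (s in seq_len(L)) {
    n_ok <- if (motif_type == "I") {
      s + 4L <= L &&
        ch[s] %in% ali && ch[s + 1L] %in% AA20 && ch[s + 2L] %in% fy &&
        ch[s + 3L] %in% AA20 && ch[s + 4L] %in% rk
    } else {
      s + 2L <= L &&
        ch[s] %in% aro && ch[s + 1L] %in% AA20 && ch[s + 2L] %in% fy
    }
    if (!n_ok) next
    for (lk in linkers) {
      a <- s + n_len + lk
      if (a + 2L > L) next
      linker_ok <- TRUE
      for (j in (s + n_len):(a - 1L)) {
        if (!ch[j] %in% AA20) { linker_ok <- FALSE; break }
      }
      if (!linker_ok) next
      if (ch[a] %in% phi && ch[a + 1L] %in% AA20 && ch[a + 2L] %in% phi) {
        hits[[length(hits) + 1L]] <- c(s, lk)
      }
    }
  }
  if (length(hits) == 0L) {
    return(matrix(integer(0), ncol = 2L,
                  dimnames = list(NULL, c("n_start", "linker_length"))))
  }
  m <- do.call(rbind, hits)
  colnames(m) <- c("n_start", "linker_length")
  m[order(m[, 1L], m[, 2L]), , drop = FALSE]
}

match_key <- function(df) {
  if (nrow(df) == 0L) return(character(0))
  sort(paste(df$n_start, df$linker_length, sep = ":"))
}

oracle_key <- function(m) {
  if (nrow(m) == 0L) return(character(0))
  sort(paste(m[, "n_start"], m[, "linker_length"], sep = ":"))
}

# Exact-integer hypergeometric upper tail via base choose(); exact doubles
# for the small universes used in tests.
oracle_hypergeom_upper <- function(m, M, n, N) {
  if (m <= 0) return(1)
  mp <- m:n
  terms <- choose(M, mp) * choose(N - M, n - mp)
  sum(terms) / choose(N, n)
}

# Deterministic residue -> state training corpus (V->E, A->H, G->C).
make_gor_corpus <- function(n_seq, len = 200L) {
  rule <- c(V = "E", A = "H", G = "C")
  lapply(seq_len(n_seq), function(i) {
    sq <- sample(names(rule), len, replace = TRUE)
    list(sequence = paste(sq, collapse = ""),
         ss = paste(rule[sq], collapse = ""))
  })
}

# One handcrafted match row in protein coordinates.
make_match <- function(n_start = 10L, n_len = 5L, linker = 3L) {
  data.frame(motif_type = if (n_len == 5L) "I" else "II",
             n_start = n_start, n_end = n_start + n_len - 1L,
             linker_length = linker,
             phi_start = n_start + n_len + linker,
             phi_end = n_start + n_len + linker + 2L,
             stringsAsFactors = FALSE)
}

# Replace positions [from, to] of a state string.
set_states <- function(ss, from, to, state) {
  paste0(substr(ss, 1L, from - 1L), strrep(state, to - from + 1L),
         substr(ss, to + 1L, nchar(ss)))
}
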