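# The bipartite SBM grammar: residue classes, Type I/II variable-gap
# patterns, exhaustive match enumeration, and canonicalization.
#
# Type I : [ILMV] X [FY] X [RK]  X{2-13}  Phi X Phi
# Type II: [FYW]  X [FY]         X{3-15}  Phi X Phi
#
# "X" matches any canonical residue; the letter X in a sequence (unknown
# residue) matches nothing, including the pattern's X positions. Key positions
# follow the field's convention: the first N-element residue is position 1 and
# the first anchor residue position 21, whatever the linker length.

#' Residue classes of the SBM grammar
#'
#' Defaults: aliphatic (Psi) = I/L/M/V, aromatic (Omega) = F/Y/W, hydrophobic
#' (Phi) = F/I/L/M/V/W/Y, plus the F/Y and R/K constraint sets. All sets are
#' configurable; none may contain `X`.
#'
#' @param aliphatic,aromatic,hydrophobic,fy,rk Character vectors of one-letter
#'   codes.
#' @return A list of class `ResidueClasses`.
#' @export
residue_classes <- function(aliphatic = c("I", "L", "M", "V"),
                            aromatic = c("F", "Y", "W"),
                            hydrophobic = c("F", "I", "L", "M", "V", "W", "Y"),
                            fy = c("F", "Y"),
                            rk = c("R", "K")) {
  cls <- list(aliphatic = aliphatic, aromatic = aromatic,
              hydrophobic = hydrophobic, fy = fy, rk = rk)
  for (nm in names(cls)) {
    bad <- setdiff(cls[[nm]], AA_CANONICAL)
    if (length(bad) > 0L) {
      stop("class '", nm, "' contains invalid letter(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  structure(cls, class = "ResidueClasses")
}

#' Default linker-length bounds per motif type
#' @param motif_type `"I"` or `"II"`.
#' @return Integer vector `c(min, max)` of admissible linker lengths.
#' @export
linker_bounds <- function(motif_type = c("I", "II")) {
  motif_type <- match.arg(motif_type)
  if (motif_type == "I") c(2L, 13L) else c(3L, 15L)
}

#' Class membership of one residue
#'
#' @param aa One canonical amino-acid letter, or `X`.
#' @param classes A [residue_classes()] object.
#' @return Character vector of class labels among `aliphatic`, `aromatic`,
#'   `hydrophobic`, `fy`, `rk`; empty for `X` and for residues in no class
#'   (e.g. `H`).
#' @export
classify_residue <- function(aa, classes = residue_classes()) {
  if (!aa %in% c(AA_CANONICAL, "X")) {
    stop("non-canonical residue '", aa, "'", call. = FALSE)
  }
  if (aa == "X") return(character(0))
  names(classes)[vapply(classes, function(s) aa %in% s, logical(1))]
}

empty_raw_matches <- function() {
  data.frame(motif_type = character(0), n_start = integer(0),
             n_end = integer(0), linker_length = integer(0),
             phi_start = integer(0), phi_end = integer(0),
             pos1 = character(0), pos3 = character(0), pos5 = character(0),
             pos21 = character(0), pos23 = character(0),
             stringsAsFactors = FALSE)
}

#' Enumerate every raw SBM match in a region
#'
#' Returns all `(start, linker length)` combinations satisfying the grammar,
#' including overlapping ones, in protein-frame coordinates.
#'
#' @param region_sequence Amino-acid string of the search region.
#' @param region_offset Protein coordinate of the region's first residue
#'   (local position 1 maps to this coordinate).
#' @param motif_type `"I"` or `"II"`.
#' @param classes A [residue_classes()] object.
#' @param linker Integer `c(min, max)` linker-length bounds; defaults to the
#'   grammar's bounds for the motif type.
#' @return Data frame of raw matches: `motif_type`, `n_start`, `n_end`,
#'   `linker_length`, `phi_start`, `phi_end`, and the key residues
#'   `pos1`/`pos3`/`pos5`/`pos21`/`pos23` (`pos5` is `NA` for Type II).
#' @export
enumerate_matches <- function(region_sequence, region_offset = 1L,
                              motif_type = c("I", "II"),
                              classes = residue_classes(),
                              linker = NULL) {
  motif_type <- match.arg(motif_type)
  if (is.null(linker)) linker <- linker_bounds(motif_type)
  ch <- seq_chars(region_sequence)
  L <- length(ch)
  n_len <- if (motif_type == "I") 5L else 3L
  if (L < n_len + linker[1L] + 3L) return(empty_raw_matches())
  assert_protein_sequence(region_sequence)

  canon <- ch %in% AA_CANONICAL
  in_set <- function(set) ch %in% set
  phi <- in_set(classes$hydrophobic)
  fy <- in_set(classes$fy)

  at <- function(v, idx) {
    ok <- idx >= 1L & idx <= L
    out <- logical(length(idx))
    out[ok] <- v[idx[ok]]
    out
  }
  i <- seq_len(L)
  if (motif_type == "I") {
    n_ok <- in_set(classes$aliphatic) & at(canon, i + 1L) & at(fy, i + 2L) &
      at(canon, i + 3L) & at(in_set(classes$rk), i + 4L)
  } else {
    n_ok <- in_set(classes$aromatic) & at(canon, i + 1L) & at(fy, i + 2L)
  }
  anchor_ok <- phi & at(canon, i + 1L) & at(phi, i + 2L)
  # Run-length prefix sums of canonical letters to test linker validity.
  canon_cum <- cumsum(canon)
  all_canon <- function(from, to) {
    # All positions in [from, to] canonical; from > to means empty (valid).
    ifelse(from > to, TRUE,
           canon_cum[to] - c(0, canon_cum)[from] == to - from + 1L)
  }

  rows <- vector("list", linker[2L] - linker[1L] + 1L)
  r <- 0L
  for (lk in seq.int(linker[1L], linker[2L])) {
    a <- i + n_len + lk              # anchor start for n-element start i
    cand <- which(n_ok & at(anchor_ok, a) & a + 2L <= L)
    if (length(cand) == 0L) next
    ok_linker <- all_canon(cand + n_len, cand + n_len + lk - 1L)
    cand <- cand[ok_linker]
    if (length(cand) == 0L) next
    r <- r + 1L
    rows[[r]] <- data.frame(
      motif_type = motif_type,
      n_start = cand, n_end = cand + n_len - 1L,
      linker_length = lk,
      phi_start = cand + n_len + lk, phi_end = cand + n_len + lk + 2L,
      stringsAsFactors = FALSE)
  }
  if (r == 0L) return(empty_raw_matches())
  out <- do.call(rbind, rows[seq_len(r)])
  out$pos1 <- ch[out$n_start]
  out$pos3 <- ch[out$n_start + 2L]
  out$pos5 <- if (motif_type == "I") ch[out$n_start + 4L] else NA_character_
  out$pos21 <- ch[out$phi_start]
  out$pos23 <- ch[out$phi_end]
  off <- as.integer(region_offset) - 1L
  for (col in c("n_start", "n_end", "phi_start", "phi_end")) {
    out[[col]] <- as.integer(out[[col]] + off)
  }
  out <- out[order(out$phi_start, out$n_start), , drop = FALSE]
  rownames(out) <- NULL
  out[names(empty_raw_matches())]
}

#' Collapse raw matches to canonical SBM instances
#'
#' Raw matches sharing an identical anchor interval describe the same SBM
#' instance: each anchor group collapses to one representative, preferring
#' (a) Type I over Type II, then (b) the linker length closest to 5 residues
#' (the experimentally optimal loop length), ties broken toward the shorter
#' linker, then (c) the smallest N-element start. A protein's SBM count is the
#' number of distinct anchors.
#'
#' @param raw_matches Data frame from [enumerate_matches()] (both types may be
#'   concatenated).
#' @return Data frame with one row per distinct anchor, ordered by anchor
#'   start.
#' @export
canonical_sbms <- function(raw_matches) {
  if (nrow(raw_matches) == 0L) return(empty_raw_matches())
  pr <- order(raw_matches$phi_start,
              raw_matches$motif_type != "I",          # Type I first
              abs(raw_matches$linker_length - 5L),
              raw_matches$linker_length,
              raw_matches$n_start)
  sorted <- raw_matches[pr, , drop = FALSE]
  key <- paste(sorted$phi_start, sorted$phi_end)
  out <- sorted[!duplicated(key), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Re-check one match row against the grammar, character by character.
validate_match <- function(match, sequence, classes = residue_classes()) {
  ch <- seq_chars(sequence)
  type <- match$motif_type
  n_len <- if (type == "I") 5L else 3L
  lb <- linker_bounds(type)
  stopifnot(
    match$n_end == match$n_start + n_len - 1L,
    match$phi_end == match$phi_start + 2L,
    match$n_end + match$linker_length + 1L == match$phi_start,
    match$linker_length >= lb[1L], match$linker_length <= lb[2L])
  span <- ch[match$n_start:match$phi_end]
  canon <- all(span %in% AA_CANONICAL)
  first_ok <- if (type == "I") {
    ch[match$n_start] %in% classes$aliphatic &&
      ch[match$n_start + 2L] %in% classes$fy &&
      ch[match$n_start + 4L] %in% classes$rk
  } else {
    ch[match$n_start] %in% classes$aromatic &&
      ch[match$n_start + 2L] %in% classes$fy
  }
  anchor_ok <- ch[match$phi_start] %in% classes$hydrophobic &&
    ch[match$phi_end] %in% classes$hydrophobic
  canon && first_ok && anchor_ok
}
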