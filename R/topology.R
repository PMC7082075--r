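# Topology interpretation: cytoplasmic segments, search-region selection,
# subcellular-location gate, and a hydropathy fallback transmembrane caller.

#' Default subcellular-location allow-list
#'
#' Membrane compartments whose transmembrane proteins enter the SBM search:
#' plasma membrane, endosome, Golgi, lysosome.
#'
#' @return Character vector of location labels (matched case-insensitively).
#' @export
sbm_locations <- function() c("plasma membrane", "endosome", "golgi", "lysosome")

#' Cytoplasmic segments of a transmembrane protein
#'
#' Splits `[1, L]` into inter-TM and terminal loops and assigns each loop a
#' membrane side by alternating sides across successive TM segments, starting
#' from the side of the N-terminus. Returns the loops on the `"inside"`
#' (cytoplasmic) side; empty loops (adjacent TM ends) are omitted.
#'
#' @param sequence_length Protein length (positive integer).
#' @param tm_segments Interval data frame of TM helices (sorted, disjoint,
#'   non-empty).
#' @param n_term_side `"inside"` or `"outside"`.
#' @return Interval data frame of cytoplasmic segments.
#' @export
cytoplasmic_segments <- function(sequence_length, tm_segments, n_term_side) {
  n_term_side <- match.arg(n_term_side, c("inside", "outside"))
  tm <- tm_segments
  if (is.null(tm) || nrow(tm) == 0L) {
    stop("not a transmembrane protein", call. = FALSE)
  }
  L <- as.integer(sequence_length)
  if (tm$start[1L] < 1L || tm$end[nrow(tm)] > L) {
    stop("tm_segments outside [1, ", L, "]", call. = FALSE)
  }
  # Loop k sits before TM k (k = 1..n) plus the C-terminal loop after TM n.
  starts <- c(1L, tm$end + 1L)
  ends <- c(tm$start - 1L, L)
  sides <- rep(c(n_term_side, setdiff(c("inside", "outside"), n_term_side)),
               length.out = length(starts))
  keep <- sides == "inside" & starts <= ends
  interval_df(starts[keep], ends[keep])
}

#' Select the SBM search region of a protein
#'
#' Single-pass proteins are searched in their unique cytoplasmic segment;
#' multipass proteins in the last (greatest-start) cytoplasmic segment.
#'
#' @param record A `ProteinRecord` with at least one TM segment.
#' @return A list with `protein_id`, `start`, `end`, and `kind`
#'   (`"single_pass_tail"` or `"multipass_last"`), or `NULL` when the protein
#'   has no cytoplasmic segment.
#' @export
search_region <- function(record) {
  segs <- cytoplasmic_segments(nchar(record$sequence), record$tm_segments,
                               record$n_term_side)
  if (nrow(segs) == 0L) return(NULL)
  if (nrow(record$tm_segments) == 1L) {
    # A single-pass protein has one inside loop at most.
    pick <- 1L
    kind <- "single_pass_tail"
  } else {
    pick <- which.max(segs$start)
    kind <- "multipass_last"
  }
  list(protein_id = record$id, start = segs$start[pick], end = segs$end[pick],
       kind = kind)
}

#' Subcellular-location gate
#'
#' @param record A `ProteinRecord`.
#' @param allowed Allow-list of location labels; defaults to
#'   [sbm_locations()]. Matching is case-insensitive.
#' @return `TRUE` iff the record carries at least one allowed location.
#' @export
passes_location_filter <- function(record, allowed = sbm_locations()) {
  length(intersect(tolower(record$locations), tolower(allowed))) > 0L
}

#' Hydropathy-based transmembrane caller
#'
#' Fallback for sequences lacking topology annotation: sliding-window mean
#' Kyte-Doolittle hydropathy; maximal runs of window centres above `threshold`
#' are expanded to the window extent, merged when overlapping, and kept only
#' when at least `min_length` residues long. `X` contributes hydropathy 0.
#'
#' @param sequence Amino-acid string.
#' @param window Odd window width (residues).
#' @param threshold Mean-hydropathy cutoff for a window centre.
#' @param min_length Minimum length of a reported segment.
#' @return Interval data frame of putative TM segments (possibly empty).
#' @export
hydropathy_tm <- function(sequence, window = 19L, threshold = 1.6,
                          min_length = 15L) {
  window <- as.integer(window)
  if (window %% 2L == 0L) stop("window must be odd", call. = FALSE)
  ch <- seq_chars(sequence)
  L <- length(ch)
  if (L < window) return(interval_df())
  h <- unname(KD_HYDROPATHY[ch])
  h[is.na(h)] <- 0
  hw <- (window - 1L) %/% 2L
  means <- as.numeric(stats::filter(h, rep(1 / window, window), sides = 2))
  centres <- seq.int(hw + 1L, L - hw)
  hot <- means[centres] > threshold
  if (!any(hot)) return(interval_df())
  r <- rle(hot)
  stops <- cumsum(r$lengths)
  starts_run <- stops - r$lengths + 1L
  keep <- which(r$values)
  iv <- interval_df(pmax(1L, centres[starts_run[keep]] - hw),
                    pmin(L, centres[stops[keep]] + hw))
  # Merge overlapping/adjacent expansions.
  iv <- iv[order(iv$start), , drop = FALSE]
  merged_s <- iv$start[1L]
  merged_e <- iv$end[1L]
  if (nrow(iv) > 1L) {
    for (k in 2L:nrow(iv)) {
      if (iv$start[k] <= merged_e[length(merged_e)] + 1L) {
        merged_e[length(merged_e)] <- max(merged_e[length(merged_e)], iv$end[k])
      } else {
        merged_s <- c(merged_s, iv$start[k])
        merged_e <- c(merged_e, iv$end[k])
      }
    }
  }
  out <- interval_df(merged_s, merged_e)
  out[out$end - out$start + 1L >= min_length, , drop = FALSE]
}

#' Guess N-terminus orientation from hydropathy
#'
#' Used only when the annotation is absent: the mean Kyte-Doolittle hydropathy
#' of the 10 N-terminal residues decides the side (hydrophobic N-terminus ->
#' `"outside"`). The guess is flagged in the returned attribute.
#'
#' @param sequence Amino-acid string.
#' @return `"inside"` or `"outside"` with attribute `guessed = TRUE`.
#' @export
guess_n_term_side <- function(sequence) {
  ch <- utils::head(seq_chars(sequence), 10L)
  h <- unname(KD_HYDROPATHY[ch])
  h[is.na(h)] <- 0
  side <- if (mean(h) > 0) "outside" else "inside"
  structure(side, guessed = TRUE)
}
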