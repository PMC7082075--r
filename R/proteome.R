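# ProteinRecord construction and validation.

#' Construct a ProteinRecord
#'
#' A `ProteinRecord` bundles a protein sequence with the annotations the SBM
#' pipeline consumes: transmembrane segments, membrane orientation of the
#' N-terminus, subcellular locations, folded-domain intervals, and GO terms.
#' All residue coordinates are 1-based and inclusive.
#'
#' @param id Unique accession string (non-empty).
#' @param sequence Amino-acid string over the 20 canonical letters, optionally
#'   `X` for unknown residues. `X` never matches any residue class.
#' @param tm_segments Data frame with `start`/`end` columns: transmembrane
#'   helices, sorted by start and pairwise disjoint.
#' @param n_term_side `"inside"` (cytoplasm) or `"outside"`: the membrane side
#'   of the N-terminus.
#' @param locations Character vector of subcellular location labels
#'   (free text, matched case-insensitively by the location gate).
#' @param domains Data frame with `start`/`end` columns: folded-domain spans.
#' @param go_terms Character vector of GO identifiers.
#' @return A list of class `ProteinRecord`.
#' @examples
#' protein_record("P1", strrep("A", 100), interval_bounds(50, 72), "outside",
#'                "plasma membrane")
#' @export
protein_record <- function(id, sequence,
                           tm_segments = interval_bounds(),
                           n_term_side = c("outside", "inside"),
                           locations = character(0),
                           domains = interval_bounds(),
                           go_terms = character(0)) {
  n_term_side <- match.arg(n_term_side)
  rec <- structure(
    list(id = as.character(id), sequence = as.character(sequence),
         tm_segments = tm_segments, n_term_side = n_term_side,
         locations = as.character(locations), domains = domains,
         go_terms = as.character(go_terms)),
    class = "ProteinRecord")
  validate_record(rec)
  rec
}

#' Build an interval table
#'
#' @param start,end Integer vectors of equal length; 1-based inclusive bounds
#'   with `start <= end`.
#' @return Data frame with `start` and `end` columns.
#' @export
interval_bounds <- function(start = integer(0), end = integer(0)) {
  iv <- interval_df(start, end)
  if (any(iv$start > iv$end) || any(iv$start < 1L)) {
    bad <- which(iv$start > iv$end | iv$start < 1L)[1L]
    stop("invalid interval '", iv$start[bad], "-", iv$end[bad], "'",
         call. = FALSE)
  }
  iv
}

validate_record <- function(rec) {
  if (!nzchar(rec$id)) stop("protein id must be non-empty", call. = FALSE)
  assert_protein_sequence(rec$sequence, rec$id)
  L <- nchar(rec$sequence)
  check_iv <- function(iv, what) {
    if (nrow(iv) == 0L) return(invisible(TRUE))
    if (any(iv$start > iv$end)) {
      bad <- which(iv$start > iv$end)[1L]
      stop("protein '", rec$id, "': ", what, " interval '",
           iv$start[bad], "-", iv$end[bad], "' has start > end", call. = FALSE)
    }
    if (any(iv$start < 1L | iv$end > L)) {
      bad <- which(iv$start < 1L | iv$end > L)[1L]
      stop("protein '", rec$id, "': ", what, " interval '",
           iv$start[bad], "-", iv$end[bad], "' outside [1, ", L, "]",
           call. = FALSE)
    }
    invisible(TRUE)
  }
  check_iv(rec$tm_segments, "transmembrane")
  check_iv(rec$domains, "domain")
  tm <- rec$tm_segments
  if (nrow(tm) > 1L) {
    if (is.unsorted(tm$start, strictly = TRUE)) {
      stop("protein '", rec$id, "': tm_segments must be sorted by start",
           call. = FALSE)
    }
    if (any(tm$start[-1L] <= tm$end[-nrow(tm)])) {
      stop("protein '", rec$id, "': tm_segments overlap", call. = FALSE)
    }
  }
  if (!rec$n_term_side %in% c("inside", "outside")) {
    stop("protein '", rec$id, "': unknown n_term_side '", rec$n_term_side, "'",
         call. = FALSE)
  }
  invisible(rec)
}

#' @export
print.ProteinRecord <- function(x, ...) {
  cat("ProteinRecord", x$id, "(", nchar(x$sequence), "aa,",
      nrow(x$tm_segments), "TM, N-term", x$n_term_side, ")\n")
  invisible(x)
}
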