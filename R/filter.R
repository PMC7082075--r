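# Secondary-structure filter rules, folded-domain exclusion, and the
# end-to-end pipeline: location gate -> search region -> scan -> canonicalize
# -> structure rules -> domain exclusion.
#
# Each structure rule is existential over prediction sources: it passes when
# at least one source satisfies it, and reports which sources did.

# predictions: named character vector, source id -> full-protein {H,E,C} string.
check_predictions <- function(predictions, protein_length, protein_id = "") {
  if (length(predictions) == 0L) return(invisible(TRUE))
  len <- nchar(predictions)
  if (any(len != protein_length)) {
    bad <- names(predictions)[len != protein_length][1L]
    stop("prediction '", bad, "' for protein '", protein_id, "' has length ",
         nchar(predictions[[bad]]), ", expected ", protein_length,
         call. = FALSE)
  }
  invisible(TRUE)
}

states_at <- function(ss, positions) {
  vapply(positions, function(p) substr(ss, p, p), character(1))
}

rule_result <- function(pass_by_source) {
  list(pass = any(pass_by_source),
       sources = names(pass_by_source)[pass_by_source])
}

#' Rule 1: the N-element starts in a beta-strand
#'
#' Passes when at least one prediction source labels the first three residues
#' of the N-element all `E`.
#'
#' @param match One canonical SBM row (from [canonical_sbms()]).
#' @param predictions Named character vector of full-protein `{H,E,C}` strings
#'   (names are source ids).
#' @param protein_length Protein length, for the coverage check.
#' @return List with `pass` (logical) and `sources` (satisfying source ids).
#' @export
rule_beta_strand <- function(match, predictions, protein_length = NULL) {
  if (!is.null(protein_length)) check_predictions(predictions, protein_length)
  pos <- match$n_start + 0:2
  hits <- vapply(predictions, function(ss) all(states_at(ss, pos) == "E"),
                 logical(1))
  rule_result(hits)
}

#' Rule 2: a random coil within the eight residues upstream of the motif
#'
#' The window is the up-to-8 residues immediately before the N-element start,
#' truncated at `floor` (the search-region start inside the pipeline; the
#' protein start for standalone calls). An empty window fails: absence of
#' evidence for a coil is treated as failure.
#'
#' @inheritParams rule_beta_strand
#' @param floor First position the window may reach (1-based).
#' @return List with `pass` and `sources`.
#' @export
rule_coil_upstream <- function(match, predictions, protein_length = NULL,
                               floor = 1L) {
  if (!is.null(protein_length)) check_predictions(predictions, protein_length)
  from <- max(as.integer(floor), match$n_start - 8L)
  to <- match$n_start - 1L
  if (from > to) {
    return(list(pass = FALSE, sources = character(0)))
  }
  hits <- vapply(predictions,
                 function(ss) any(states_at(ss, from:to) == "C"), logical(1))
  rule_result(hits)
}

#' Rule 3: a random coil within the linker
#'
#' Passes when at least one source labels any residue strictly between the
#' N-element end and the anchor start as `C`.
#'
#' @inheritParams rule_beta_strand
#' @return List with `pass` and `sources`.
#' @export
rule_coil_linker <- function(match, predictions, protein_length = NULL) {
  if (!is.null(protein_length)) check_predictions(predictions, protein_length)
  from <- match$n_end + 1L
  to <- match$phi_start - 1L
  if (from > to) {
    return(list(pass = FALSE, sources = character(0)))
  }
  hits <- vapply(predictions,
                 function(ss) any(states_at(ss, from:to) == "C"), logical(1))
  rule_result(hits)
}

#' Folded-domain exclusion
#'
#' @param match One SBM row.
#' @param domains Interval data frame of folded-domain spans.
#' @return `TRUE` iff the motif span (N-element start to anchor end) overlaps
#'   no domain interval by even one residue.
#' @export
outside_domains <- function(match, domains) {
  if (is.null(domains) || nrow(domains) == 0L) return(TRUE)
  !any(intervals_overlap(match$n_start, match$phi_end,
                         domains$start, domains$end))
}

#' Pipeline configuration
#'
#' @param allowed_locations Location allow-list for the subcellular gate.
#' @param classes Residue classes of the motif grammar.
#' @param linker_I,linker_II Linker-length bounds per motif type.
#' @param sources Optional character vector restricting which prediction
#'   sources are consulted (`NULL` = all available).
#' @param upstream_floor `"region"` (default: the coil-upstream window stops
#'   at the search-region start) or `"protein"`.
#' @return A list of class `sbm_config`.
#' @export
pipeline_config <- function(allowed_locations = sbm_locations(),
                            classes = residue_classes(),
                            linker_I = linker_bounds("I"),
                            linker_II = linker_bounds("II"),
                            sources = NULL,
                            upstream_floor = c("region", "protein")) {
  structure(list(allowed_locations = allowed_locations, classes = classes,
                 linker_I = linker_I, linker_II = linker_II,
                 sources = sources,
                 upstream_floor = match.arg(upstream_floor)),
            class = "sbm_config")
}

empty_verdicts <- function() {
  cbind(
    data.frame(protein_id = character(0)),
    empty_raw_matches(),
    data.frame(region_start = integer(0), region_end = integer(0),
               region_kind = character(0),
               rule_beta = logical(0), rule_beta_sources = character(0),
               rule_coil_upstream = logical(0),
               rule_coil_upstream_sources = character(0),
               rule_coil_linker = logical(0),
               rule_coil_linker_sources = character(0),
               outside_domains = logical(0), overall = logical(0),
               stringsAsFactors = FALSE))
}

# Evaluate the three structure rules for one match row.
structure_rules <- function(match, predictions, floor) {
  list(beta = rule_beta_strand(match, predictions),
       up = rule_coil_upstream(match, predictions, floor = floor),
       linker = rule_coil_linker(match, predictions))
}

#' Run the full SBM discovery pipeline
#'
#' For each protein: subcellular-location gate, search-region selection, raw
#' enumeration of both motif types, canonicalization to one instance per
#' anchor, the three secondary-structure rules (existential over sources), and
#' the folded-domain exclusion. Filters apply to motifs, not representatives:
#' when the canonical representative of an anchor fails the structure rules
#' but another raw match of the same anchor passes all of them (and the domain
#' exclusion), that raw match is reported instead and the anchor passes.
#'
#' @param proteome Named list of `ProteinRecord`s.
#' @param predictions Data frame with columns `id`, `source`, `ss` (as from
#'   [read_ss_predictions()]), or `NULL` for none.
#' @param config A [pipeline_config()].
#' @return List with `verdicts` (one row per canonical SBM instance, ordered
#'   by protein id then anchor start) and `summary` (stage counts and
#'   per-protein SBM multiplicity of passing instances).
#' @export
run_pipeline <- function(proteome, predictions = NULL,
                         config = pipeline_config()) {
  if (is.null(predictions)) {
    predictions <- data.frame(id = character(0), source = character(0),
                              ss = character(0), stringsAsFactors = FALSE)
  }
  if (!is.null(config$sources)) {
    predictions <- predictions[predictions$source %in% config$sources, ,
                               drop = FALSE]
  }
  ids <- vapply(proteome, `[[`, character(1), "id")
  orphan <- setdiff(unique(predictions$id), ids)
  if (length(orphan) > 0L) {
    warning("predictions reference unknown protein(s): ",
            paste(orphan, collapse = ", "), call. = FALSE)
  }

  n_pass_location <- 0L
  n_with_region <- 0L
  n_with_raw <- 0L
  n_with_canonical <- 0L
  verdict_rows <- list()

  for (rec in proteome) {
    if (!passes_location_filter(rec, config$allowed_locations)) next
    n_pass_location <- n_pass_location + 1L
    region <- search_region(rec)
    if (is.null(region)) next
    n_with_region <- n_with_region + 1L
    region_seq <- substr(rec$sequence, region$start, region$end)
    raw <- rbind(
      enumerate_matches(region_seq, region$start, "I", config$classes,
                        config$linker_I),
      enumerate_matches(region_seq, region$start, "II", config$classes,
                        config$linker_II))
    if (nrow(raw) == 0L) next
    n_with_raw <- n_with_raw + 1L
    canon <- canonical_sbms(raw)
    n_with_canonical <- n_with_canonical + 1L

    preds <- predictions[predictions$id == rec$id, , drop = FALSE]
    pred_vec <- stats::setNames(preds$ss, preds$source)
    check_predictions(pred_vec, nchar(rec$sequence), rec$id)
    floor <- if (config$upstream_floor == "region") region$start else 1L

    for (ci in seq_len(nrow(canon))) {
      rep_row <- canon[ci, , drop = FALSE]
      sr <- structure_rules(rep_row, pred_vec, floor)
      dom <- outside_domains(rep_row, rec$domains)
      if (!(sr$beta$pass && sr$up$pass && sr$linker$pass)) {
        # Re-test alternative raw matches of the same anchor (the filters
        # apply to motifs, not to the canonical representative).
        grp <- raw[raw$phi_start == rep_row$phi_start &
                     raw$phi_end == rep_row$phi_end, , drop = FALSE]
        grp <- canonical_order(grp)
        for (gi in seq_len(nrow(grp))) {
          alt <- grp[gi, , drop = FALSE]
          sr_alt <- structure_rules(alt, pred_vec, floor)
          dom_alt <- outside_domains(alt, rec$domains)
          if (sr_alt$beta$pass && sr_alt$up$pass && sr_alt$linker$pass &&
              dom_alt) {
            rep_row <- alt
            sr <- sr_alt
            dom <- dom_alt
            break
          }
        }
      }
      overall <- sr$beta$pass && sr$up$pass && sr$linker$pass && dom
      verdict_rows[[length(verdict_rows) + 1L]] <- cbind(
        data.frame(protein_id = rec$id, stringsAsFactors = FALSE),
        rep_row[c("motif_type", "n_start", "n_end", "linker_length",
                  "phi_start", "phi_end", "pos1", "pos3", "pos5", "pos21",
                  "pos23")],
        data.frame(
          region_start = region$start, region_end = region$end,
          region_kind = region$kind,
          rule_beta = sr$beta$pass,
          rule_beta_sources = paste(sr$beta$sources, collapse = ","),
          rule_coil_upstream = sr$up$pass,
          rule_coil_upstream_sources = paste(sr$up$sources, collapse = ","),
          rule_coil_linker = sr$linker$pass,
          rule_coil_linker_sources = paste(sr$linker$sources, collapse = ","),
          outside_domains = dom, overall = overall,
          stringsAsFactors = FALSE))
    }
  }

  verdicts <- if (length(verdict_rows) == 0L) empty_verdicts() else
    do.call(rbind, verdict_rows)
  if (nrow(verdicts) > 0L) {
    verdicts <- verdicts[order(verdicts$protein_id, verdicts$phi_start), ,
                         drop = FALSE]
    rownames(verdicts) <- NULL
  }
  passing <- verdicts[verdicts$overall, , drop = FALSE]
  multiplicity <- if (nrow(passing) > 0L) table(passing$protein_id) else
    table(character(0))
  summary <- list(
    n_proteins = length(proteome),
    n_pass_location = n_pass_location,
    n_with_region = n_with_region,
    n_with_raw_matches = n_with_raw,
    n_with_canonical = n_with_canonical,
    n_candidates = nrow(verdicts),
    n_pass_candidates = nrow(passing),
    n_pass_proteins = length(unique(passing$protein_id)),
    multiplicity = multiplicity)
  list(verdicts = verdicts, summary = summary)
}

# Order raw matches by the canonicalization priority.
canonical_order <- function(grp) {
  grp[order(grp$motif_type != "I", abs(grp$linker_length - 5L),
            grp$linker_length, grp$n_start), , drop = FALSE]
}
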