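# On-disk artifacts: FASTA + annotation TSV -> ProteinRecords; secondary-
# structure TSV; candidate and enrichment tables.
#
# Annotation TSV columns (tab-separated, header required):
#   id, tm_segments ("start-end" joined by ";"), n_term_side (inside/outside),
#   locations (";"-joined), domains ("start-end" joined by ";", may be empty),
#   go_terms (";"-joined, may be empty).

#' Read a proteome from FASTA plus an annotation table
#'
#' Every FASTA entry must have a matching row (by `id`) in the annotation
#' table; a missing row is a hard error naming the id. Annotation rows without
#' a FASTA entry are ignored with a warning.
#'
#' @param fasta_path Path to a FASTA file of amino-acid sequences.
#' @param annotation_path Path to the tab-separated annotation table.
#' @return Named list of [protein_record()] objects, in FASTA order.
#' @export
read_proteome <- function(fasta_path, annotation_path) {
  seqs <- Biostrings::readAAStringSet(fasta_path)
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA id '", ids[duplicated(ids)][1L], "'", call. = FALSE)
  }
  ann <- utils::read.delim(annotation_path, stringsAsFactors = FALSE,
                           colClasses = "character")
  required <- c("id", "tm_segments", "n_term_side", "locations", "domains",
                "go_terms")
  missing_cols <- setdiff(required, names(ann))
  if (length(missing_cols) > 0L) {
    stop("annotation table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(ann$id)) {
    stop("duplicate annotation id '", ann$id[duplicated(ann$id)][1L], "'",
         call. = FALSE)
  }
  absent <- setdiff(ids, ann$id)
  if (length(absent) > 0L) {
    stop("FASTA id '", absent[1L], "' has no annotation row", call. = FALSE)
  }
  extra <- setdiff(ann$id, ids)
  if (length(extra) > 0L) {
    warning("annotation rows without FASTA entry ignored: ",
            paste(extra, collapse = ", "), call. = FALSE)
  }
  records <- vector("list", length(ids))
  names(records) <- ids
  for (k in seq_along(ids)) {
    id <- ids[k]
    row_i <- match(id, ann$id)
    side <- ann$n_term_side[row_i]
    if (!side %in% c("inside", "outside")) {
      stop("annotation row ", row_i, " (id '", id, "'): unknown n_term_side '",
           side, "'", call. = FALSE)
    }
    rec <- tryCatch(
      protein_record(
        id = id,
        sequence = as.character(seqs[[k]]),
        tm_segments = parse_intervals(ann$tm_segments[row_i]),
        n_term_side = side,
        locations = split_field(ann$locations[row_i]),
        domains = parse_intervals(ann$domains[row_i]),
        go_terms = split_field(ann$go_terms[row_i])),
      error = function(e) {
        stop("annotation row ", row_i, ": ", conditionMessage(e),
             call. = FALSE)
      })
    records[[k]] <- rec
  }
  records
}

#' Write a proteome back to FASTA + annotation TSV
#'
#' Inverse of [read_proteome()]; used by the synthetic-data generator.
#'
#' @param records Named list of `ProteinRecord`s.
#' @param fasta_path,annotation_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_proteome <- function(records, fasta_path, annotation_path) {
  seqs <- Biostrings::AAStringSet(vapply(records, `[[`, character(1),
                                         "sequence"))
  names(seqs) <- vapply(records, `[[`, character(1), "id")
  Biostrings::writeXStringSet(seqs, fasta_path, width = 60L)
  ann <- data.frame(
    id = names(seqs),
    tm_segments = vapply(records, function(r) format_intervals(r$tm_segments),
                         character(1)),
    n_term_side = vapply(records, `[[`, character(1), "n_term_side"),
    locations = vapply(records, function(r) paste(r$locations, collapse = ";"),
                       character(1)),
    domains = vapply(records, function(r) format_intervals(r$domains),
                     character(1)),
    go_terms = vapply(records, function(r) paste(r$go_terms, collapse = ";"),
                      character(1)),
    stringsAsFactors = FALSE)
  utils::write.table(ann, annotation_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, eol = "\n")
  invisible(c(fasta_path, annotation_path))
}

#' Read per-residue secondary-structure predictions
#'
#' The table is tab-separated with columns `id`, `source`, `ss`; `ss` is a
#' string over `{H, E, C}` covering the full protein. Several sources per
#' protein are allowed and all are retained.
#'
#' @param path Path to the predictions TSV.
#' @return Data frame with columns `id`, `source`, `ss`.
#' @export
read_ss_predictions <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  required <- c("id", "source", "ss")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols) > 0L) {
    stop("secondary-structure table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (i in seq_len(nrow(tab))) {
    bad <- regexpr("[^HEC]", tab$ss[i])
    if (bad > 0L) {
      stop("row ", i, " (id '", tab$id[i], "', source '", tab$source[i],
           "'): invalid state '", substr(tab$ss[i], bad, bad),
           "' at position ", bad, call. = FALSE)
    }
  }
  if (anyDuplicated(tab[c("id", "source")])) {
    stop("duplicate (id, source) pair in secondary-structure table",
         call. = FALSE)
  }
  tab[c("id", "source", "ss")]
}

#' Write secondary-structure predictions
#' @param predictions Data frame with columns `id`, `source`, `ss`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_ss_predictions <- function(predictions, path) {
  utils::write.table(predictions[c("id", "source", "ss")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, eol = "\n")
  invisible(path)
}

candidate_columns <- c(
  "protein_id", "motif_type", "region_start", "region_end", "region_kind",
  "n_start", "n_end", "linker_length", "phi_start", "phi_end",
  "pos1", "pos3", "pos5", "pos21", "pos23",
  "rule_beta", "rule_beta_sources",
  "rule_coil_upstream", "rule_coil_upstream_sources",
  "rule_coil_linker", "rule_coil_linker_sources",
  "outside_domains", "overall")

#' Write the candidate table
#'
#' One row per canonical SBM instance with its coordinates, the residues at
#' the conventional key positions (1/3/5/21/23; position 5 is empty for
#' Type II), each filter verdict as pass/fail, and the overall status. Rows
#' are ordered by protein id then anchor start, so identical inputs produce
#' byte-identical files.
#'
#' @param verdicts Verdict data frame from [run_pipeline()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_candidates <- function(verdicts, path) {
  df <- verdicts
  if (nrow(df) > 0L) {
    df <- df[order(df$protein_id, df$phi_start, df$motif_type), , drop = FALSE]
  }
  out <- data.frame(matrix(character(0), nrow = nrow(df), ncol = 0))
  for (col in candidate_columns) {
    v <- if (col %in% names(df)) df[[col]] else rep(NA, nrow(df))
    if (is.logical(v)) v <- ifelse(v, "pass", "fail")
    v <- as.character(v)
    v[is.na(v)] <- ""
    out[[col]] <- v
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     eol = "\n")
  invisible(path)
}

#' Read a candidate table written by [write_candidates()]
#' @param path Path to the candidate TSV.
#' @return Data frame with typed columns (integers, logical verdicts).
#' @export
read_candidates <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  int_cols <- c("region_start", "region_end", "n_start", "n_end",
                "linker_length", "phi_start", "phi_end")
  for (col in int_cols) tab[[col]] <- as.integer(tab[[col]])
  flag_cols <- c("rule_beta", "rule_coil_upstream", "rule_coil_linker",
                 "outside_domains", "overall")
  for (col in flag_cols) tab[[col]] <- tab[[col]] == "pass"
  tab$pos5[!nzchar(tab$pos5)] <- NA_character_
  tab
}

#' Write a GO-enrichment table
#' @param results Data frame from [enrich()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_enrichment <- function(results, path) {
  df <- results
  num <- vapply(df, is.numeric, logical(1))
  for (col in names(df)[num]) {
    v <- format(df[[col]], digits = 15, scientific = FALSE, trim = TRUE)
    v[is.na(df[[col]])] <- ""
    df[[col]] <- v
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     eol = "\n")
  invisible(path)
}
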