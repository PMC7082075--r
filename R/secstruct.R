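# A trainable GOR-style (information-theoretic, singlet) secondary-structure
# predictor over the three states H (helix), E (strand), C (coil). It is the
# package's built-in prediction source; externally computed predictions read
# with read_ss_predictions() are first-class substitutes.

SS_STATES <- c("H", "E", "C")

#' Train a GOR-style information table
#'
#' For every state `S`, residue `R`, and window offset `m` in `[-w, w]` the
#' table stores the information value
#' `log((c(S,R,m)+pc) / (c(notS,R,m)+pc)) + log((c(notS)+pc) / (c(S)+pc))`,
#' where counts run over all labeled positions `j` paired with the residue at
#' `j+m` (window positions outside the sequence are skipped). Priors are the
#' state frequencies.
#'
#' @param labeled_set List of `list(sequence =, ss =)` pairs (or a data frame
#'   with `sequence` and `ss` columns); `ss` over `{H,E,C}`, same length as
#'   the sequence.
#' @param window_half_width Half-width `w` of the sliding window (residues).
#' @param pseudocount Additive smoothing constant; must be positive.
#' @return A list of class `InfoTable` with elements `w`, `info` (3 x 20 x
#'   (2w+1) array), and `priors`.
#' @export
train_gor <- function(labeled_set, window_half_width = 8L, pseudocount = 1.0) {
  if (is.data.frame(labeled_set)) {
    labeled_set <- lapply(seq_len(nrow(labeled_set)), function(i) {
      list(sequence = labeled_set$sequence[i], ss = labeled_set$ss[i])
    })
  }
  if (length(labeled_set) == 0L) stop("empty training set", call. = FALSE)
  if (!is.finite(pseudocount) || pseudocount <= 0) {
    stop("pseudocount must be positive", call. = FALSE)
  }
  w <- as.integer(window_half_width)
  offsets <- seq.int(-w, w)
  counts <- array(0, dim = c(3L, 20L, 2L * w + 1L),
                  dimnames = list(SS_STATES, AA_CANONICAL,
                                  as.character(offsets)))
  state_totals <- stats::setNames(numeric(3L), SS_STATES)

  for (item in labeled_set) {
    sq <- seq_chars(item$sequence)
    ss <- seq_chars(item$ss)
    if (length(sq) != length(ss)) {
      stop("sequence/label length mismatch", call. = FALSE)
    }
    bad <- setdiff(unique(ss), SS_STATES)
    if (length(bad) > 0L) {
      stop("invalid secondary-structure state '", bad[1L], "'", call. = FALSE)
    }
    L <- length(sq)
    if (L == 0L) next
    tt <- table(factor(ss, levels = SS_STATES))
    state_totals <- state_totals + as.numeric(tt)
    for (k in seq_along(offsets)) {
      m <- offsets[k]
      j <- seq_len(L)
      keep <- j + m >= 1L & j + m <= L
      res <- sq[j[keep] + m]
      st <- ss[keep]
      canon <- res %in% AA_CANONICAL
      if (!any(canon)) next
      tab <- table(factor(st[canon], levels = SS_STATES),
                   factor(res[canon], levels = AA_CANONICAL))
      counts[, , k] <- counts[, , k] + tab
    }
  }

  total <- sum(state_totals)
  if (total == 0) stop("empty training set", call. = FALSE)
  info <- array(0, dim = dim(counts), dimnames = dimnames(counts))
  for (s in SS_STATES) {
    c_s <- counts[s, , , drop = FALSE]
    c_not <- colSums(counts) - adrop3(c_s)     # sum over the other two states
    prior_term <- log((total - state_totals[s] + pseudocount) /
                        (state_totals[s] + pseudocount))
    info[s, , ] <- log((adrop3(c_s) + pseudocount) / (c_not + pseudocount)) +
      prior_term
  }
  structure(list(w = w, info = info, priors = state_totals / total),
            class = "InfoTable")
}

# Drop the first (length-1) dimension of a 1 x R x M array.
adrop3 <- function(a) array(a, dim = dim(a)[2:3], dimnames = dimnames(a)[2:3])

#' Predict secondary structure with a trained information table
#'
#' Each position is scored as the state's prior log-odds plus the sum of
#' information values over the in-range window offsets (the Bayes decision for
#' this model: the per-offset information values are likelihood ratios against
#' the state's complement, so the prior enters exactly once); the label is the
#' highest-scoring state. Any tie resolves to `C` (coil, the unopinionated
#' state). Non-canonical residues contribute zero to every state's score.
#'
#' @param sequence Amino-acid string.
#' @param table An `InfoTable` from [train_gor()].
#' @return A string over `{H,E,C}` of the same length as `sequence`.
#' @export
predict_ss <- function(sequence, table) {
  stopifnot(inherits(table, "InfoTable"))
  ch <- seq_chars(sequence)
  L <- length(ch)
  if (L == 0L) return("")
  w <- table$w
  res_idx <- match(ch, AA_CANONICAL)           # NA for X / unknown
  prior_odds <- log(table$priors / (1 - table$priors))
  scores <- matrix(prior_odds, nrow = 3L, ncol = L,
                   dimnames = list(SS_STATES, NULL))
  for (k in seq_len(2L * w + 1L)) {
    m <- k - w - 1L
    j <- seq_len(L)
    src <- j + m
    ok <- src >= 1L & src <= L
    ridx <- res_idx[src[ok]]
    known <- !is.na(ridx)
    if (!any(known)) next
    cols <- j[ok][known]
    scores[, cols] <- scores[, cols] + table$info[, ridx[known], k]
  }
  labels <- apply(scores, 2L, function(col) {
    top <- which(col == max(col))
    if (length(top) > 1L) "C" else SS_STATES[top]
  })
  paste(labels, collapse = "")
}

#' Three-state prediction accuracy (Q3)
#'
#' @param predicted,truth Equal-length strings over `{H,E,C}`.
#' @return Fraction of positions with identical state, in `[0, 1]`.
#' @export
q3 <- function(predicted, truth) {
  if (nchar(predicted) != nchar(truth)) {
    stop("length mismatch: ", nchar(predicted), " vs ", nchar(truth),
         call. = FALSE)
  }
  if (nchar(predicted) == 0L) return(NaN)
  mean(seq_chars(predicted) == seq_chars(truth))
}

#' Serialize an information table to TSV
#'
#' The file carries a small header block (`# key=value`) with the format
#' version, window half-width and priors, followed by columns
#' `state`, `residue`, `offset`, `value`.
#'
#' @param table An `InfoTable`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_info_table <- function(table, path) {
  stopifnot(inherits(table, "InfoTable"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# info_table_version=1",
               sprintf("# window_half_width=%d", table$w),
               sprintf("# prior_%s=%.17g", names(table$priors), table$priors)),
             con)
  grid <- expand.grid(state = SS_STATES, residue = AA_CANONICAL,
                      offset = seq.int(-table$w, table$w),
                      stringsAsFactors = FALSE)
  grid$value <- sprintf("%.17g", table$info[cbind(
    match(grid$state, SS_STATES), match(grid$residue, AA_CANONICAL),
    grid$offset + table$w + 1L)])
  writeLines(paste("state", "residue", "offset", "value", sep = "\t"), con)
  writeLines(do.call(paste, c(grid, sep = "\t")), con)
  invisible(path)
}

#' Read an information table written by [write_info_table()]
#' @param path Path to the TSV.
#' @return An `InfoTable`.
#' @export
read_info_table <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  kv <- sub("^#\\s*", "", hdr)
  keys <- sub("=.*$", "", kv)
  vals <- sub("^[^=]*=", "", kv)
  w <- as.integer(vals[keys == "window_half_width"])
  priors <- stats::setNames(
    as.numeric(vals[match(paste0("prior_", SS_STATES), keys)]), SS_STATES)
  body <- utils::read.delim(text = lines[!grepl("^#", lines)],
                            stringsAsFactors = FALSE)
  info <- array(0, dim = c(3L, 20L, 2L * w + 1L),
                dimnames = list(SS_STATES, AA_CANONICAL,
                                as.character(seq.int(-w, w))))
  info[cbind(match(body$state, SS_STATES),
             match(body$residue, AA_CANONICAL),
             body$offset + w + 1L)] <- body$value
  structure(list(w = w, info = info, priors = priors), class = "InfoTable")
}
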