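# GO-term enrichment of the candidate set: contingency counts restricted to
# proteins carrying at least one GO term, the enrichment ratio
# E = (m/M) / (n/N), and the exact upper-tail hypergeometric p-value
#   p = sum_{m'=m}^{n} C(M, m') C(N-M, n-m') / C(N, n),
# evaluated in log space with compensated summation so small-universe results
# are bit-stable. p-values are only computed for enriched terms (E >= 1).

#' Contingency counts for one GO term
#'
#' Only proteins annotated with at least one GO term enter the universe count
#' `N` and the hit-set count `M`.
#'
#' @param hits Character vector of hit protein ids (subset of the universe).
#' @param universe Named list: protein id -> character vector of GO ids
#'   (possibly empty).
#' @param term GO id to count.
#' @return Named integer vector `c(N, n, M, m)`: annotated universe size,
#'   universe proteins with `term`, annotated hits, hits with `term`.
#' @export
build_contingency <- function(hits, universe, term) {
  stray <- setdiff(hits, names(universe))
  if (length(stray) > 0L) {
    stop("hit id(s) absent from universe: ", paste(stray, collapse = ", "),
         call. = FALSE)
  }
  annotated <- names(universe)[vapply(universe, length, integer(1)) > 0L]
  has_term <- vapply(universe[annotated], function(g) term %in% g, logical(1))
  hit_annot <- intersect(hits, annotated)
  c(N = length(annotated),
    n = sum(has_term),
    M = length(hit_annot),
    m = sum(has_term[match(hit_annot, annotated)]))
}

#' Enrichment ratio
#'
#' @param m,M,n,N Contingency counts as in [build_contingency()].
#' @return `(m/M) / (n/N)`, or `NA_real_` when `M == 0` or `n == 0` (not
#'   computable).
#' @export
e_ratio <- function(m, M, n, N) {
  if (M == 0 || n == 0) return(NA_real_)
  unname((m / M) / (n / N))
}

#' Exact upper-tail hypergeometric p-value
#'
#' Probability of drawing at least `m` term-annotated proteins among `n`
#' term-annotated universe members when `M` of the `N` universe proteins are
#' hits, summed term by term; combinations where a binomial coefficient is
#' undefined contribute zero.
#'
#' @param m,M,n,N Contingency counts with `0 <= m <= min(n, M)`, `n <= N`,
#'   `M <= N`.
#' @return p-value in `(0, 1]`.
#' @export
hypergeom_upper <- function(m, M, n, N) {
  m <- as.numeric(m); M <- as.numeric(M); n <- as.numeric(n); N <- as.numeric(N)
  if (any(c(m, M, n, N) < 0) || M > N || n > N || m > min(n, M)) {
    stop("inconsistent hypergeometric arguments (m=", m, ", M=", M,
         ", n=", n, ", N=", N, ")", call. = FALSE)
  }
  if (m <= 0) return(1)
  mp <- seq.int(m, n)
  log_terms <- lchoose(M, mp) + lchoose(N - M, n - mp) - lchoose(N, n)
  log_terms <- log_terms[is.finite(log_terms)]
  if (length(log_terms) == 0L) return(0)
  top <- max(log_terms)
  # Compensated (Kahan) summation of the rescaled terms.
  s <- 0; comp <- 0
  for (t in exp(log_terms - top)) {
    y <- t - comp
    tt <- s + y
    comp <- (tt - s) - y
    s <- tt
  }
  min(1, exp(top) * s)
}

#' GO enrichment of a hit set
#'
#' One result per GO term appearing in at least one hit protein. p-values are
#' computed only for enriched terms (E-ratio >= 1); depleted terms are
#' reported with an empty p column. Results are sorted by ascending p (ties
#' and missing p by term id).
#'
#' @param hits Character vector of hit protein ids.
#' @param universe Named list: protein id -> character vector of GO ids.
#' @param adjust If `TRUE`, add a Benjamini-Hochberg adjusted column `p_adj`
#'   over the computed p-values.
#' @return Data frame with columns `term`, `N`, `n`, `M`, `m`, `e_ratio`, `p`
#'   (and `p_adj` when requested).
#' @export
enrich <- function(hits, universe, adjust = FALSE) {
  empty <- data.frame(term = character(0), N = integer(0), n = integer(0),
                      M = integer(0), m = integer(0), e_ratio = numeric(0),
                      p = numeric(0), stringsAsFactors = FALSE)
  if (adjust) empty$p_adj <- numeric(0)
  if (length(hits) == 0L) return(empty)
  terms <- sort(unique(unlist(universe[intersect(hits, names(universe))])))
  if (length(terms) == 0L) return(empty)
  rows <- lapply(terms, function(tm) {
    ct <- build_contingency(hits, universe, tm)
    er <- e_ratio(ct["m"], ct["M"], ct["n"], ct["N"])
    p <- if (!is.na(er) && er >= 1) {
      hypergeom_upper(ct["m"], ct["M"], ct["n"], ct["N"])
    } else {
      NA_real_
    }
    data.frame(term = tm, N = ct[["N"]], n = ct[["n"]], M = ct[["M"]],
               m = ct[["m"]], e_ratio = unname(er), p = unname(p),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$p, out$term, na.last = TRUE), , drop = FALSE]
  rownames(out) <- NULL
  if (adjust) out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out
}
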