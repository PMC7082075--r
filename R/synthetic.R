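# Seeded generators for every pipeline input, with known ground truth:
# membrane proteomes carrying planted SBMs and rule-specific decoys (plus
# consistent secondary-structure labels), GO annotations with a planted
# enriched term, and single-site ITC thermograms.
#
# Planted and decoy tails are built over a "filter-inert" filler alphabet
# (no hydrophobic-class, F/Y, or R/K letters), so the planted motif is
# provably the only possible match in those proteins; background tails use
# the full alphabet with hydrophobics down-weighted and are rejection-sampled
# until they contain no rule-passing chance match. Every emitted dataset is
# verified against the pipeline's own predicates before it is returned.

# Letters outside every grammar class: cannot seed an N-element or anchor.
FILLER_AA <- c("A", "D", "E", "G", "N", "P", "Q", "S", "T")

# Background residue weights: hydrophobics and R/K down-weighted to keep the
# chance-SBM density low at the generated tail lengths.
background_weights <- function() {
  w <- stats::setNames(rep(1, 20L), AA_CANONICAL)
  w[c("F", "I", "L", "M", "V", "W", "Y")] <- 0.25
  w[c("R", "K")] <- 0.5
  w / sum(w)
}

sample_filler <- function(k) {
  paste(sample(FILLER_AA, k, replace = TRUE), collapse = "")
}

sample_background_seq <- function(k) {
  w <- background_weights()
  paste(sample(names(w), k, replace = TRUE, prob = w), collapse = "")
}

# Random-run secondary-structure labels for background tails.
sample_ss <- function(k) {
  out <- character(0)
  while (length(out) < k) {
    out <- c(out, rep(sample(SS_STATES, 1L, prob = c(0.3, 0.25, 0.45)),
                      sample(3:9, 1L)))
  }
  paste(out[seq_len(k)], collapse = "")
}

# One planted motif: sequence chars and the local coordinates of its parts.
plant_motif <- function(motif_type, linker_length, classes) {
  lb <- linker_bounds(motif_type)
  if (linker_length < lb[1L] || linker_length > lb[2L]) {
    stop("linker length ", linker_length, " outside [", lb[1L], ", ", lb[2L],
         "] for Type ", motif_type, call. = FALSE)
  }
  n_elem <- if (motif_type == "I") {
    c(sample(classes$aliphatic, 1L), sample(FILLER_AA, 1L),
      sample(classes$fy, 1L), sample(FILLER_AA, 1L), sample(classes$rk, 1L))
  } else {
    c(sample(classes$aromatic, 1L), sample(FILLER_AA, 1L),
      sample(classes$fy, 1L))
  }
  # Anchor Phi letters avoid F/Y so the anchor cannot double as an N-element.
  anchor_phi <- setdiff(classes$hydrophobic, classes$fy)
  anchor <- c(sample(anchor_phi, 1L), sample(FILLER_AA, 1L),
              sample(anchor_phi, 1L))
  chars <- c(n_elem, sample(FILLER_AA, linker_length, replace = TRUE), anchor)
  list(chars = chars, n_len = length(n_elem),
       linker_length = as.integer(linker_length),
       motif_type = motif_type)
}

# Assemble a single-pass (N-terminus outside) membrane protein whose tail
# carries the given planted motifs; returns record pieces + truth rows.
assemble_planted <- function(id, motifs, location, domain_on = integer(0)) {
  ecto_len <- sample(30:50, 1L)
  tm_len <- 21L
  ecto <- sample_filler(ecto_len)
  tm <- paste(sample(c("I", "L", "V", "F", "A"), tm_len, replace = TRUE),
              collapse = "")
  up_len <- sample(10:20, 1L)
  tail_parts <- sample_filler(up_len)
  tail_ss <- strrep("C", up_len)
  motif_local <- integer(0)        # local (tail-frame) n_start of each motif
  truth_rows <- list()
  for (mi in seq_along(motifs)) {
    m <- motifs[[mi]]
    n_start_local <- nchar(tail_parts) + 1L
    tail_parts <- paste0(tail_parts, paste(m$chars, collapse = ""))
    ss_motif <- paste0("EEE", strrep("C", length(m$chars) - 3L))
    tail_ss <- paste0(tail_ss, ss_motif)
    motif_local <- c(motif_local, n_start_local)
    if (mi < length(motifs)) {
      gap <- sample(25:35, 1L)
      tail_parts <- paste0(tail_parts, sample_filler(gap))
      tail_ss <- paste0(tail_ss, strrep("C", gap))
    }
  }
  down_len <- sample(10:25, 1L)
  tail_parts <- paste0(tail_parts, sample_filler(down_len))
  tail_ss <- paste0(tail_ss, strrep("C", down_len))

  tail_offset <- ecto_len + tm_len     # protein coord of tail pos 1 minus 1
  sequence <- paste0(ecto, tm, tail_parts)
  ss <- paste0(strrep("C", ecto_len), strrep("H", tm_len), tail_ss)
  for (mi in seq_along(motifs)) {
    m <- motifs[[mi]]
    n_start <- tail_offset + motif_local[mi]
    truth_rows[[mi]] <- data.frame(
      id = id, motif_type = m$motif_type,
      linker_length = m$linker_length,
      n_start = n_start, n_end = n_start + m$n_len - 1L,
      phi_start = n_start + m$n_len + m$linker_length,
      phi_end = n_start + m$n_len + m$linker_length + 2L,
      stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, truth_rows)
  domains <- if (length(domain_on) > 0L) {
    interval_df(truth$phi_start[domain_on], truth$phi_end[domain_on])
  } else {
    interval_df()
  }
  rec <- protein_record(id, sequence,
                        tm_segments = interval_df(ecto_len + 1L,
                                                  ecto_len + tm_len),
                        n_term_side = "outside", locations = location,
                        domains = domains)
  list(record = rec, ss = ss, truth = truth)
}

# Apply a per-protein secondary-structure override for decoys.
override_ss <- function(ss, from, to, state) {
  paste0(substr(ss, 1L, from - 1L), strrep(state, to - from + 1L),
         substr(ss, to + 1L, nchar(ss)))
}

verify_single <- function(record, ss, config, expect) {
  preds <- data.frame(id = record$id, source = "truth", ss = ss,
                      stringsAsFactors = FALSE)
  res <- run_pipeline(stats::setNames(list(record), record$id), preds, config)
  expect(res)
}

decoy_kinds <- c("grammar", "location", "beta", "coil_upstream",
                 "coil_linker", "domain")

#' Generate a synthetic membrane proteome with planted SBMs
#'
#' Emits `n_true` single-pass membrane proteins carrying one planted,
#' all-rules-passing SBM each (`n_true_double` of them carry two),
#' rule-specific decoys that each violate exactly one pipeline rule, and
#' background proteins rejection-sampled to contain no rule-passing chance
#' match. Every planted/decoy protein is verified against the pipeline's own
#' predicates at generation time; a dataset whose truth table disagrees with
#' the pipeline is never emitted.
#'
#' @param n_background Number of background proteins.
#' @param n_true Number of planted true-positive proteins.
#' @param decoy_spec Named integer vector over
#'   `grammar`, `location`, `beta`, `coil_upstream`, `coil_linker`, `domain`.
#' @param seed Integer seed; the generator is a pure function of
#'   `(arguments, seed)`.
#' @param n_true_double How many of the true positives carry two SBMs.
#' @param motif_types Motif types to draw planted motifs from.
#' @param config Pipeline configuration used for self-verification.
#' @param dir Optional output directory; when given, writes `proteome.fasta`,
#'   `annotations.tsv`, `ss.tsv`, and `truth.tsv`.
#' @return List with `records` (named list of `ProteinRecord`s), `ss`
#'   (data frame `id`/`source`/`ss`, source `"truth"`), `truth` (one row per
#'   protein-motif with `role` and `rule_violated`), `seed`, `config_hash`,
#'   and `paths` when `dir` was given.
#' @export
gen_proteome <- function(n_background = 100L, n_true = 10L,
                         decoy_spec = c(grammar = 5L, location = 5L,
                                        beta = 5L, coil_linker = 5L,
                                        domain = 5L),
                         seed = 1L, n_true_double = 0L,
                         motif_types = c("I", "II"),
                         config = pipeline_config(), dir = NULL) {
  stopifnot(n_background >= 0L, n_true >= 0L, n_true_double <= n_true)
  bad <- setdiff(names(decoy_spec), decoy_kinds)
  if (length(bad) > 0L) {
    stop("unknown decoy kind(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  withr::with_seed(as.integer(seed), {
    records <- list()
    ss_rows <- list()
    truth_rows <- list()
    allowed <- config$allowed_locations
    classes <- config$classes

    add <- function(rec, ss, truth) {
      records[[rec$id]] <<- rec
      ss_rows[[rec$id]] <<- data.frame(id = rec$id, source = "truth", ss = ss,
                                       stringsAsFactors = FALSE)
      truth_rows[[length(truth_rows) + 1L]] <<- truth
    }

    draw_motifs <- function(k) {
      lapply(seq_len(k), function(i) {
        ty <- sample(motif_types, 1L)
        lb <- linker_bounds(ty)
        plant_motif(ty, sample(lb[1L]:lb[2L], 1L), classes)
      })
    }

    # --- true positives -------------------------------------------------
    for (i in seq_len(n_true)) {
      id <- sprintf("TP%03d", i)
      k <- if (i <= n_true_double) 2L else 1L
      built <- assemble_planted(id, draw_motifs(k), sample(allowed, 1L))
      tr <- built$truth
      verify_single(built$record, built$ss, config, function(res) {
        v <- res$verdicts
        pass <- v[v$overall, , drop = FALSE]
        ok <- nrow(pass) == nrow(tr) &&
          all(pass$phi_start == tr$phi_start) &&
          all(pass$n_start == tr$n_start)
        if (!ok) stop("generator self-verification failed for planted ",
                      "positive '", id, "'", call. = FALSE)
      })
      tr$role <- "true_positive"
      tr$rule_violated <- NA_character_
      add(built$record, built$ss, tr)
    }

    # --- decoys ---------------------------------------------------------
    for (kind in names(decoy_spec)) {
      for (i in seq_len(decoy_spec[[kind]])) {
        id <- sprintf("DC_%s_%02d", kind, i)
        loc <- if (kind == "location") "mitochondrion" else sample(allowed, 1L)
        motif <- draw_motifs(1L)
        built <- assemble_planted(
          id, motif, loc,
          domain_on = if (kind == "domain") 1L else integer(0))
        tr <- built$truth
        ss <- built$ss
        if (kind == "grammar") {
          # Position 3 F/Y -> H, mirroring the non-binding insulin receptor.
          sq <- built$record$sequence
          p3 <- tr$n_start + 2L
          sq <- paste0(substr(sq, 1L, p3 - 1L), "H",
                       substr(sq, p3 + 1L, nchar(sq)))
          built$record$sequence <- sq
        } else if (kind == "beta") {
          ss <- override_ss(ss, tr$n_start, tr$n_start + 2L, "C")
        } else if (kind == "coil_upstream") {
          ss <- override_ss(ss, tr$n_start - 8L, tr$n_start - 1L, "E")
        } else if (kind == "coil_linker") {
          ss <- override_ss(ss, tr$n_start, tr$phi_start - 1L, "E")
        }
        expected <- switch(
          kind,
          grammar = function(res) {
            v <- res$verdicts
            hit <- any(v$phi_start == tr$phi_start)
            if (res$summary$n_pass_candidates != 0L || hit) {
              stop("grammar decoy '", id, "' still matches", call. = FALSE)
            }
          },
          location = function(res) {
            if (res$summary$n_pass_location != 0L) {
              stop("location decoy '", id, "' passed the gate", call. = FALSE)
            }
          },
          function(res) {
            v <- res$verdicts
            row <- v[v$phi_start == tr$phi_start, , drop = FALSE]
            flag <- c(beta = "rule_beta", coil_upstream = "rule_coil_upstream",
                      coil_linker = "rule_coil_linker",
                      domain = "outside_domains")[[kind]]
            others <- setdiff(c("rule_beta", "rule_coil_upstream",
                                "rule_coil_linker", "outside_domains"), flag)
            ok <- nrow(row) == 1L && !row[[flag]] &&
              all(unlist(row[others])) && res$summary$n_pass_candidates == 0L
            if (!ok) stop("decoy '", id, "' does not fail exactly rule '",
                          kind, "'", call. = FALSE)
          })
        verify_single(built$record, ss, config, expected)
        tr$role <- "decoy"
        tr$rule_violated <- kind
        add(built$record, ss, tr)
      }
    }

    # --- background -----------------------------------------------------
    for (i in seq_len(n_background)) {
      id <- sprintf("BG%03d", i)
      for (attempt in seq_len(200L)) {
        ecto_len <- sample(30:50, 1L)
        tail_len <- sample(60:120, 1L)
        ecto <- sample_background_seq(ecto_len)
        tm <- paste(sample(c("I", "L", "V", "F", "A"), 21L, replace = TRUE),
                    collapse = "")
        tail <- sample_background_seq(tail_len)
        ss <- paste0(sample_ss(ecto_len), strrep("H", 21L),
                     sample_ss(tail_len))
        rec <- protein_record(id, paste0(ecto, tm, tail),
                              tm_segments = interval_df(ecto_len + 1L,
                                                        ecto_len + 21L),
                              n_term_side = "outside",
                              locations = sample(allowed, 1L))
        clean <- TRUE
        verify_single(rec, ss, config, function(res) {
          if (res$summary$n_pass_candidates != 0L) clean <<- FALSE
        })
        if (clean) break
        if (attempt == 200L) {
          stop("could not sample a clean background protein", call. = FALSE)
        }
      }
      add(rec, ss, data.frame(
        id = id, motif_type = NA_character_, linker_length = NA_integer_,
        n_start = NA_integer_, n_end = NA_integer_, phi_start = NA_integer_,
        phi_end = NA_integer_, role = "background",
        rule_violated = NA_character_, stringsAsFactors = FALSE))
    }

    truth <- do.call(rbind, truth_rows)
    rownames(truth) <- NULL
    ss_df <- do.call(rbind, unname(ss_rows))
    out <- list(records = records, ss = ss_df, truth = truth,
                seed = as.integer(seed),
                config_hash = content_hash(list(
                  n_background, n_true, decoy_spec, n_true_double,
                  motif_types, unclass(config))))
    if (!is.null(dir)) {
      if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
      fasta <- file.path(dir, "proteome.fasta")
      ann <- file.path(dir, "annotations.tsv")
      write_proteome(records, fasta, ann)
      ssp <- file.path(dir, "ss.tsv")
      write_ss_predictions(ss_df, ssp)
      tp <- file.path(dir, "truth.tsv")
      utils::write.table(truth, tp, sep = "\t", quote = FALSE,
                         row.names = FALSE, eol = "\n")
      out$paths <- c(fasta = fasta, annotations = ann, ss = ssp, truth = tp)
    }
    out
  })
}

#' Generate GO annotations with one planted enriched term
#'
#' The planted term is assigned to `ceiling(coverage * count)` members of the
#' hit set and of the background set (a deterministic seeded choice); noise
#' terms are assigned uniformly so that every protein carries at least one GO
#' term. The exact contingency counts produced are returned alongside.
#'
#' @param hits,background Character vectors of protein ids (disjoint).
#' @param enriched_term Identifier of the planted term.
#' @param coverage_in_hits,coverage_in_background Fractions in `[0, 1]`.
#' @param n_noise_terms Size of the noise-term vocabulary (0 = planted term
#'   only).
#' @param seed Integer seed.
#' @param path Optional output path for the annotation TSV (columns `id`,
#'   `go_terms`).
#' @return List with `universe` (named list id -> GO ids), `expected`
#'   (named vector `N`, `n`, `M`, `m` for the planted term), `enriched_term`,
#'   and `path` when written.
#' @export
gen_go <- function(hits, background, enriched_term = "GO:0006915",
                   coverage_in_hits = 0.5, coverage_in_background = 0.05,
                   n_noise_terms = 20L, seed = 1L, path = NULL) {
  stopifnot(coverage_in_hits >= 0, coverage_in_hits <= 1,
            coverage_in_background >= 0, coverage_in_background <= 1,
            length(intersect(hits, background)) == 0L)
  withr::with_seed(as.integer(seed), {
    ids <- c(hits, background)
    universe <- stats::setNames(vector("list", length(ids)), ids)
    pick <- function(set, coverage) {
      k <- ceiling(coverage * length(set))
      if (k == 0L) character(0) else sample(set, k)
    }
    planted <- c(pick(hits, coverage_in_hits),
                 pick(background, coverage_in_background))
    vocab <- if (n_noise_terms > 0L) {
      sprintf("GO:N%04d", seq_len(n_noise_terms))
    } else {
      character(0)
    }
    for (id in ids) {
      terms <- character(0)
      if (id %in% planted) terms <- enriched_term
      if (length(vocab) > 0L) {
        terms <- c(terms, sample(vocab, sample(1:3, 1L)))
      }
      universe[[id]] <- unique(terms)
    }
    expected <- build_contingency(hits, universe, enriched_term)
    out <- list(universe = universe, expected = expected,
                enriched_term = enriched_term)
    if (!is.null(path)) {
      tab <- data.frame(
        id = ids,
        go_terms = vapply(universe, paste, character(1), collapse = ";"),
        stringsAsFactors = FALSE)
      utils::write.table(tab, path, sep = "\t", quote = FALSE,
                         row.names = FALSE, eol = "\n")
      out$path <- path
    }
    out
  })
}

#' Read a GO annotation table written by [gen_go()]
#' @param path Path to the TSV (columns `id`, `go_terms` joined by `;`).
#' @return Named list: protein id -> character vector of GO ids.
#' @export
read_go_universe <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  stats::setNames(lapply(tab$go_terms, split_field), tab$id)
}

#' Simulate a single-site ITC thermogram
#'
#' Heats are the exact model heats of [injection_heats()] plus i.i.d. Gaussian
#' noise.
#'
#' @param n Stoichiometry.
#' @param Kd Dissociation constant (molar).
#' @param dH Enthalpy in kcal/mol.
#' @param design An `ItcExperiment` giving the injection schedule; defaults to
#'   [default_itc_design()].
#' @param noise_sd Noise standard deviation in microcal.
#' @param seed Integer seed (required when `noise_sd > 0`).
#' @return An `ItcExperiment` with `observed_heats` filled in; the generating
#'   parameters are attached as attribute `truth`.
#' @export
gen_itc <- function(n = 1, Kd = 18e-6, dH = -10,
                    design = default_itc_design(), noise_sd = 0,
                    seed = NULL) {
  stopifnot(Kd > 0, n > 0, noise_sd >= 0)
  heats <- injection_heats(design, n = n, Ka = 1 / Kd, dH = dH * 1000)
  if (noise_sd > 0) {
    if (is.null(seed)) stop("seed required when noise_sd > 0", call. = FALSE)
    heats <- withr::with_seed(
      as.integer(seed), heats + stats::rnorm(length(heats), 0, noise_sd))
  }
  out <- design
  out$observed_heats <- heats
  attr(out, "truth") <- c(n = n, Kd = Kd, dH = dH)
  out
}
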