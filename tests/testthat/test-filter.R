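# Handy scaffold: one Type I match at positions 10-14, linker 3, anchor 18-20
# on a 30-residue protein; predictions are built per test.
base_ss <- strrep("C", 30L)

test_that("rule 1 requires a full beta-strand over the N-element start", {
  m <- make_match()
  preds <- c(A = set_states(base_ss, 10L, 12L, "E"))
  r <- rule_beta_strand(m, preds, protein_length = 30L)
  expect_true(r$pass)
  expect_equal(r$sources, "A")

  preds2 <- c(A = set_states(base_ss, 11L, 12L, "E"),   # CEE
              B = set_states(set_states(base_ss, 10L, 10L, "E"),
                             12L, 12L, "E"))            # ECE
  expect_false(rule_beta_strand(m, preds2, 30L)$pass)

  both <- c(preds, preds2["A"])
  names(both) <- c("good", "bad")
  r3 <- rule_beta_strand(m, both, 30L)
  expect_true(r3$pass)
  expect_equal(r3$sources, "good")

  expect_error(rule_beta_strand(m, c(A = "CCC"), 30L), "length")
})

test_that("rule 2 needs a coil in the 8 residues upstream of the motif", {
  m <- make_match()
  upstream_e <- set_states(base_ss, 2L, 9L, "E")
  expect_false(rule_coil_upstream(m, c(A = upstream_e), 30L)$pass)
  one_c <- set_states(upstream_e, 9L, 9L, "C")
  expect_true(rule_coil_upstream(m, c(A = one_c), 30L)$pass)

  # Motif at position 1: empty window fails.
  m1 <- make_match(n_start = 1L)
  expect_false(rule_coil_upstream(m1, c(A = strrep("C", 30L)), 30L)$pass)

  # The window is truncated at the floor (region start in the pipeline).
  m2 <- make_match(n_start = 10L)
  coil_before_region <- set_states(set_states(base_ss, 2L, 9L, "E"),
                                   2L, 2L, "C")
  expect_true(rule_coil_upstream(m2, c(A = coil_before_region), 30L,
                                 floor = 1L)$pass)
  expect_false(rule_coil_upstream(m2, c(A = coil_before_region), 30L,
                                  floor = 5L)$pass)
})

test_that("rule 3 needs a coil strictly between the hydrophobic elements", {
  m <- make_match()   # linker at 15-17
  expect_true(rule_coil_linker(m, c(A = base_ss), 30L)$pass)
  all_e <- set_states(base_ss, 15L, 17L, "E")
  expect_false(rule_coil_linker(m, c(A = all_e), 30L)$pass)
  mixed <- set_states(all_e, 16L, 16L, "C")
  expect_true(rule_coil_linker(m, c(A = mixed), 30L)$pass)
})

test_that("domain exclusion uses strict interval overlap", {
  m <- make_match()   # motif span 10-20
  expect_true(outside_domains(m, interval_bounds(1, 9)))
  expect_false(outside_domains(m, interval_bounds(20, 25)))
  expect_false(outside_domains(m, interval_bounds(12, 13)))
  expect_true(outside_domains(m, interval_bounds()))
})

test_that("pipeline passes exactly the planted candidate in a mixed fixture", {
  sim <- gen_proteome(n_background = 0L, n_true = 1L,
                      decoy_spec = c(location = 1L, beta = 1L), seed = 21L)
  res <- run_pipeline(sim$records, sim$ss)
  expect_equal(res$summary$n_pass_candidates, 1L)
  pass <- res$verdicts[res$verdicts$overall, ]
  expect_equal(pass$protein_id, "TP001")
  expect_equal(res$summary$n_proteins, 3L)
  expect_equal(res$summary$n_pass_location, 2L)

  empty <- run_pipeline(list(), NULL)
  expect_equal(nrow(empty$verdicts), 0L)
  expect_equal(empty$summary$n_proteins, 0L)
  expect_equal(empty$summary$n_pass_candidates, 0L)
})

test_that("a protein with two planted anchors reports multiplicity two", {
  sim <- gen_proteome(n_background = 0L, n_true = 2L, n_true_double = 1L,
                      decoy_spec = c(), seed = 31L)
  res <- run_pipeline(sim$records, sim$ss)
  mult <- res$summary$multiplicity
  expect_equal(unname(mult[["TP001"]]), 2L)
  expect_equal(unname(mult[["TP002"]]), 1L)
})

test_that("adding a prediction source never shrinks the pass set", {
  sim <- gen_proteome(n_background = 10L, n_true = 5L,
                      decoy_spec = c(beta = 2L, coil_linker = 2L), seed = 41L)
  res1 <- run_pipeline(sim$records, sim$ss)
  # A second, all-coil source: satisfies rules 2-3 everywhere, never rule 1.
  allc <- sim$ss
  allc$source <- "allcoil"
  allc$ss <- vapply(allc$id,
                    function(id) strrep("C", nchar(sim$records[[id]]$sequence)),
                    character(1))
  res2 <- run_pipeline(sim$records, rbind(sim$ss, allc))
  key <- function(res) {
    v <- res$verdicts[res$verdicts$overall, ]
    paste(v$protein_id, v$phi_start)
  }
  expect_true(all(key(res1) %in% key(res2)))
})

test_that("removing domain annotations never shrinks the pass set", {
  sim <- gen_proteome(n_background = 5L, n_true = 3L,
                      decoy_spec = c(domain = 3L), seed = 51L)
  res1 <- run_pipeline(sim$records, sim$ss)
  stripped <- lapply(sim$records, function(r) {
    r$domains <- interval_bounds()
    r
  })
  res2 <- run_pipeline(stripped, sim$ss)
  expect_gte(res2$summary$n_pass_candidates, res1$summary$n_pass_candidates)
  # The domain decoys pass once their domains are gone.
  expect_equal(res2$summary$n_pass_candidates, 6L)
})

test_that("predictions for unknown proteins warn but do not fail", {
  sim <- gen_proteome(n_background = 0L, n_true = 1L, decoy_spec = c(),
                      seed = 61L)
  extra <- rbind(sim$ss, data.frame(id = "GHOST", source = "truth",
                                    ss = "CCC", stringsAsFactors = FALSE))
  expect_warning(res <- run_pipeline(sim$records, extra), "GHOST")
  expect_equal(res$summary$n_pass_candidates, 1L)
})
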