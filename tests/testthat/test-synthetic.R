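test_that("the proteome generator is a pure function of its seed", {
  a <- gen_proteome(n_background = 5L, n_true = 2L,
                    decoy_spec = c(grammar = 1L, beta = 1L), seed = 12L)
  b <- gen_proteome(n_background = 5L, n_true = 2L,
                    decoy_spec = c(grammar = 1L, beta = 1L), seed = 12L)
  expect_identical(a$records, b$records)
  expect_identical(a$ss, b$ss)
  expect_identical(a$truth, b$truth)

  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  gen_proteome(n_background = 3L, n_true = 1L, decoy_spec = c(), seed = 9L,
               dir = d1)
  gen_proteome(n_background = 3L, n_true = 1L, decoy_spec = c(), seed = 9L,
               dir = d2)
  for (f in c("proteome.fasta", "annotations.tsv", "ss.tsv", "truth.tsv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
})

test_that("generated files read back into an equivalent dataset", {
  d <- withr::local_tempdir()
  sim <- gen_proteome(n_background = 4L, n_true = 2L,
                      decoy_spec = c(domain = 1L), seed = 18L, dir = d)
  recs <- read_proteome(file.path(d, "proteome.fasta"),
                        file.path(d, "annotations.tsv"))
  expect_equal(names(recs), names(sim$records))
  for (id in names(recs)) {
    expect_equal(recs[[id]]$sequence, sim$records[[id]]$sequence)
    expect_equal(recs[[id]]$tm_segments, sim$records[[id]]$tm_segments)
    expect_equal(recs[[id]]$domains, sim$records[[id]]$domains)
  }
  ss <- read_ss_predictions(file.path(d, "ss.tsv"))
  res_disk <- run_pipeline(recs, ss)
  res_mem <- run_pipeline(sim$records, sim$ss)
  expect_equal(res_disk$verdicts, res_mem$verdicts)
})

test_that("a motif-free proteome yields zero passing candidates", {
  sim <- gen_proteome(n_background = 15L, n_true = 0L, decoy_spec = c(),
                      seed = 33L)
  res <- run_pipeline(sim$records, sim$ss)
  expect_equal(res$summary$n_pass_candidates, 0L)
})

test_that("requesting an illegal planted linker length fails loudly", {
  expect_error(sbmhunt:::plant_motif("I", 1L, residue_classes()), "linker")
  expect_error(sbmhunt:::plant_motif("II", 16L, residue_classes()), "linker")
})

test_that("GO generator produces the exact planted contingency", {
  hits <- paste0("H", 1:40)
  bg <- paste0("B", 1:400)
  sim <- gen_go(hits, bg, coverage_in_hits = 0.5,
                coverage_in_background = 0.05, n_noise_terms = 10L, seed = 2L)
  expect_equal(unname(sim$expected),
               c(440L, ceiling(0.5 * 40) + ceiling(0.05 * 400), 40L,
                 ceiling(0.5 * 40)))
  expect_equal(sim$expected,
               build_contingency(hits, sim$universe, sim$enriched_term))

  # Equal coverage in hits and background: no enrichment.
  null <- gen_go(hits, bg, coverage_in_hits = 0.5,
                 coverage_in_background = 0.5, n_noise_terms = 10L, seed = 3L)
  ct <- null$expected
  expect_equal(e_ratio(ct["m"], ct["M"], ct["n"], ct["N"]), 1.0,
               tolerance = 1e-12)

  # Without noise terms only the planted term exists.
  bare <- gen_go(hits, bg, n_noise_terms = 0L, seed = 4L)
  expect_equal(unique(unlist(bare$universe)), bare$enriched_term)

  # Annotation table round trip.
  path <- withr::local_tempfile(fileext = ".tsv")
  sim2 <- gen_go(hits, bg, seed = 5L, path = path)
  expect_equal(read_go_universe(path), sim2$universe)
})

test_that("ITC generator adds noise only through the seed", {
  exact <- gen_itc(n = 1, Kd = 10e-6, dH = -12)
  model <- injection_heats(default_itc_design(), 1, 1 / 10e-6, -12000)
  expect_equal(exact$observed_heats, model, tolerance = 1e-15)
  expect_equal(exact$injection_volumes, c(0.2e-6, rep(2e-6, 19L)))

  n1 <- gen_itc(Kd = 10e-6, dH = -12, noise_sd = 1, seed = 1L)
  n2 <- gen_itc(Kd = 10e-6, dH = -12, noise_sd = 1, seed = 2L)
  n1b <- gen_itc(Kd = 10e-6, dH = -12, noise_sd = 1, seed = 1L)
  expect_identical(n1$observed_heats, n1b$observed_heats)
  expect_false(identical(n1$observed_heats, n2$observed_heats))
  expect_equal(sd(n1$observed_heats - model) < 3, TRUE)
})
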