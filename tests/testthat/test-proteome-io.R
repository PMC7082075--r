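write_fixture_proteome <- function(dir, ann_rows = NULL) {
  fasta <- file.path(dir, "p.fasta")
  writeLines(c(">P1", strrep("A", 100), ">P2", paste0(strrep("G", 50),
                                                      strrep("L", 30))),
             fasta)
  if (is.null(ann_rows)) {
    ann_rows <- c("P1\t50-72\toutside\tplasma membrane\t\t",
                  "P2\t10-30\tinside\tendosome;golgi\t40-60\tGO:1;GO:2")
  }
  ann <- file.path(dir, "ann.tsv")
  writeLines(c("id\ttm_segments\tn_term_side\tlocations\tdomains\tgo_terms",
               ann_rows), ann)
  list(fasta = fasta, ann = ann)
}

test_that("read_proteome maps annotation fields onto records", {
  d <- withr::local_tempdir()
  fx <- write_fixture_proteome(d)
  recs <- read_proteome(fx$fasta, fx$ann)
  expect_length(recs, 2L)
  expect_equal(recs$P1$tm_segments, data.frame(start = 50L, end = 72L))
  expect_equal(recs$P1$n_term_side, "outside")
  expect_equal(recs$P1$locations, "plasma membrane")
  expect_equal(nrow(recs$P1$domains), 0L)
  expect_equal(recs$P2$domains, data.frame(start = 40L, end = 60L))
  expect_setequal(recs$P2$go_terms, c("GO:1", "GO:2"))
})

test_that("read_proteome rejects malformed or missing annotations", {
  d <- withr::local_tempdir()
  fx <- write_fixture_proteome(
    d, c("P1\t72-50\toutside\tplasma membrane\t\t",
         "P2\t10-30\tinside\tendosome\t\t"))
  expect_error(read_proteome(fx$fasta, fx$ann), "72-50")

  fx2 <- write_fixture_proteome(d, "P1\t50-72\toutside\tplasma membrane\t\t")
  expect_error(read_proteome(fx2$fasta, fx2$ann), "P2")

  fx3 <- write_fixture_proteome(
    d, c("P1\t50-72\tsideways\tplasma membrane\t\t",
         "P2\t10-30\tinside\tendosome\t\t"))
  expect_error(read_proteome(fx3$fasta, fx3$ann), "sideways")
})

test_that("read_proteome is insensitive to annotation row order", {
  d <- withr::local_tempdir()
  fx <- write_fixture_proteome(d)
  rows <- readLines(fx$ann)
  writeLines(c(rows[1L], rows[3L], rows[2L]), fx$ann)
  recs <- read_proteome(fx$fasta, fx$ann)
  expect_equal(names(recs), c("P1", "P2"))
  expect_equal(recs$P2$tm_segments, data.frame(start = 10L, end = 30L))
})

test_that("protein_record rejects non-canonical sequence letters", {
  expect_error(protein_record("P1", "ACDEFB", n_term_side = "outside"), "B")
  expect_silent(protein_record("P1", "ACDEFX", n_term_side = "outside"))
})

test_that("read_ss_predictions validates states and keeps all sources", {
  d <- withr::local_tempdir()
  path <- file.path(d, "ss.tsv")
  writeLines(c("id\tsource\tss",
               "P1\ttoolA\tCCCEEECCC",
               "P1\ttoolB\tHHHCCCEEE"), path)
  ss <- read_ss_predictions(path)
  expect_equal(nrow(ss), 2L)
  expect_setequal(ss$source, c("toolA", "toolB"))

  writeLines(c("id\tsource\tss", "P1\ttoolA\tCCBEE"), path)
  expect_error(read_ss_predictions(path), "position 3")
})

test_that("candidate tables round-trip and are byte-deterministic", {
  sim <- gen_proteome(n_background = 2L, n_true = 2L,
                      decoy_spec = c(beta = 1L), seed = 3L)
  res <- run_pipeline(sim$records, sim$ss)
  d <- withr::local_tempdir()
  p1 <- file.path(d, "c1.tsv")
  p2 <- file.path(d, "c2.tsv")
  write_candidates(res$verdicts, p1)
  write_candidates(res$verdicts, p2)
  expect_identical(readLines(p1), readLines(p2))

  back <- read_candidates(p1)
  expect_equal(nrow(back), nrow(res$verdicts))
  v <- res$verdicts[order(res$verdicts$protein_id, res$verdicts$phi_start), ]
  for (col in c("protein_id", "motif_type", "n_start", "n_end",
                "linker_length", "phi_start", "phi_end", "pos1", "pos21",
                "pos23", "rule_beta", "rule_coil_upstream",
                "rule_coil_linker", "outside_domains", "overall")) {
    expect_equal(back[[col]], unname(v[[col]]), label = col)
  }

  write_candidates(res$verdicts[0L, ], p1)
  expect_length(readLines(p1), 1L)   # header only
})
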