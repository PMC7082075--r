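test_that("classify_residue reports every containing class", {
  expect_setequal(classify_residue("L"), c("aliphatic", "hydrophobic"))
  expect_setequal(classify_residue("F"), c("aromatic", "hydrophobic", "fy"))
  expect_setequal(classify_residue("W"), c("aromatic", "hydrophobic"))
  expect_equal(classify_residue("H"), character(0))   # the INSR position-3 case
  expect_equal(classify_residue("X"), character(0))
  expect_error(classify_residue("B"), "non-canonical")
})

test_that("enumerate_matches reproduces the worked grammar examples", {
  m <- enumerate_matches("LAYAKAAWLM", 1L, "I")
  expect_equal(nrow(m), 1L)
  expect_equal(m$n_start, 1L)
  expect_equal(m$n_end, 5L)
  expect_equal(m$linker_length, 2L)
  expect_equal(c(m$phi_start, m$phi_end), c(8L, 10L))
  expect_equal(unlist(m[c("pos1", "pos3", "pos5", "pos21", "pos23")],
                      use.names = FALSE),
               c("L", "Y", "K", "W", "M"))

  expect_equal(nrow(enumerate_matches("LAYAKAWLM", 1L, "I")), 0L)  # gap 1 < 2

  m2 <- enumerate_matches("FAYAAAWLM", 1L, "II")
  expect_equal(nrow(m2), 1L)
  expect_equal(m2$linker_length, 3L)
  expect_equal(c(m2$phi_start, m2$phi_end), c(7L, 9L))
  expect_true(is.na(m2$pos5))

  # Offsets shift coordinates into the protein frame.
  m3 <- enumerate_matches("LAYAKAAWLM", 51L, "I")
  expect_equal(c(m3$n_start, m3$phi_start), c(51L, 58L))
})

test_that("X matches nothing, including the pattern's any positions", {
  expect_equal(nrow(enumerate_matches("LXYAKAAWLM", 1L, "I")), 0L)
  expect_equal(nrow(enumerate_matches("LAYAKAXWLM", 1L, "I")), 0L)
  expect_equal(nrow(enumerate_matches("LAYAKAAWXM", 1L, "I")), 0L)
})

test_that("scanner agrees with the brute-force oracle on random sequences", {
  set.seed(23)
  for (case in 1:200) {
    sq <- paste(sample(AA20, sample(60:200, 1L), replace = TRUE),
                collapse = "")
    for (ty in c("I", "II")) {
      expect_identical(match_key(enumerate_matches(sq, 1L, ty)),
                       oracle_key(oracle_matches(sq, ty)),
                       label = paste("type", ty, "case", case))
    }
  }
})

test_that("every reported match re-validates against the grammar", {
  set.seed(5)
  checked <- 0L
  while (checked < 50L) {
    sq <- paste(sample(AA20, 150L, replace = TRUE), collapse = "")
    raw <- rbind(enumerate_matches(sq, 1L, "I"),
                 enumerate_matches(sq, 1L, "II"))
    for (i in seq_len(nrow(raw))) {
      expect_true(sbmhunt:::validate_match(raw[i, ], sq))
      checked <- checked + 1L
    }
  }
})

test_that("widening a residue class never loses matches", {
  set.seed(91)
  wide <- residue_classes(hydrophobic = c("F", "I", "L", "M", "V", "W", "Y",
                                          "A", "C"))
  for (case in 1:60) {
    sq <- paste(sample(AA20, 120L, replace = TRUE), collapse = "")
    for (ty in c("I", "II")) {
      n_default <- nrow(enumerate_matches(sq, 1L, ty))
      n_wide <- nrow(enumerate_matches(sq, 1L, ty, classes = wide))
      expect_gte(n_wide, n_default)
    }
  }
})

test_that("canonicalization keeps one representative per anchor", {
  raw <- rbind(make_match(n_start = 10L, linker = 4L),
               make_match(n_start = 8L, linker = 6L))
  raw$pos1 <- "L"; raw$pos3 <- "Y"; raw$pos5 <- "K"
  raw$pos21 <- "W"; raw$pos23 <- "M"
  stopifnot(raw$phi_start[1L] == raw$phi_start[2L])
  canon <- canonical_sbms(raw)
  expect_equal(nrow(canon), 1L)
  expect_equal(canon$linker_length, 4L)   # |4-5| == |6-5|, tie -> shorter

  # Type I beats Type II at the same anchor.
  t2 <- make_match(n_start = 12L, n_len = 3L, linker = 4L)
  t2[c("pos1", "pos3", "pos21", "pos23")] <- c("F", "Y", "W", "M")
  t2$pos5 <- NA_character_
  mixed <- rbind(raw[1L, ], t2)
  stopifnot(mixed$phi_start[1L] == mixed$phi_start[2L])
  expect_equal(canonical_sbms(mixed)$motif_type, "I")

  # Disjoint anchors stay separate: a "two SBMs" protein.
  two <- rbind(make_match(n_start = 10L, linker = 4L),
               make_match(n_start = 40L, linker = 4L))
  two[c("pos1", "pos3", "pos5", "pos21", "pos23")] <-
    list("L", "Y", "K", "W", "M")
  expect_equal(nrow(canonical_sbms(two)), 2L)

  expect_equal(nrow(canonical_sbms(sbmhunt:::empty_raw_matches())), 0L)
})
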