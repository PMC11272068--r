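# Panels, composition codes, FASTA parsing and library building.

test_that("channel and panel validation enforces the code contract", {
  expect_error(channel("empty"), "no residues")
  expect_error(channel("bad", c("C", "B")), "B")
  expect_silent(channel("Cterm", c_terminus = TRUE))
  expect_error(channel_panel(list(channel("C", "C"), channel("C2", "C"))),
               "more than one channel")
  expect_error(channel_panel(list(channel("C", "C"), channel("C", "K"))),
               "duplicated channel labels")
  expect_error(canonical_panel(10), "between 1 and 9")
  expect_equal(panel_labels(canonical_panel(9)),
               c("C", "K", "M", "D/E", "Y", "R", "H", "W", "S"))
})

test_that("termini presets place terminus counts where the chemistry acts", {
  lib_default <- canonical_panel(4, "library-default")
  expect_false(any(vapply(lib_default$channels,
                          function(ch) ch$n_terminus || ch$c_terminus,
                          logical(1))))
  assay <- canonical_panel(4, "assay-matched")
  de <- assay$channels[[4]]
  expect_true(de$c_terminus)
  expect_false(assay$channels[[2]]$n_terminus)
  assay_n <- canonical_panel(4, "assay-matched", lys_n_terminus = TRUE)
  expect_true(assay_n$channels[[2]]$n_terminus)
})

test_that("compute_code counts channel residues and flagged termini", {
  p4 <- assay_panel4()
  expect_equal(unname(code_values(compute_code("ACFWKYCV", p4))),
               c(2, 1, 0, 1))
  p5 <- panel_from_labels(c("C", "K", "M", "D/E", "Y"), "assay-matched")
  expect_equal(unname(code_values(compute_code("ACFWKYCV", p5))),
               c(2, 1, 0, 1, 1))
  # residue-only panel on a sequence hitting no channel: all-zero code
  expect_equal(unname(code_values(compute_code("GGG", canonical_panel(4)))),
               c(0, 0, 0, 0))
  # the model peptide: two Cys, two Lys, two Met, a C-terminal carboxylate
  expect_equal(unname(code_values(compute_code("CCKKMMGG", p4))),
               c(2, 2, 2, 1))
  # ambiguity codes count toward no channel
  expect_equal(unname(code_values(compute_code("CBZXUK", canonical_panel(2)))),
               c(1, 1))
  expect_error(compute_code("", p4), "non-empty")
})

test_that("code counts are integers bounded by sequence length plus termini", {
  p <- canonical_panel(9, "assay-matched", lys_n_terminus = TRUE)
  set.seed(11)
  for (i in 1:20) {
    s <- paste(sample(LETTERS[LETTERS %in% names(human_aa_frequencies())],
                      sample(5:40, 1), replace = TRUE), collapse = "")
    v <- code_values(compute_code(s, p))
    expect_true(all(v == floor(v) & v >= 0))
    expect_lte(sum(v), nchar(s) + 2)
  }
})

test_that("appending a channel residue increments exactly that value", {
  p <- canonical_panel(4)
  base <- code_values(compute_code("ACK", p))
  for (j in seq_along(p$channels)) {
    res <- p$channels[[j]]$residues[1]
    v <- code_values(compute_code(paste0("ACK", res), p))
    expect_equal(unname(v - base), as.numeric(seq_along(base) == j))
  }
  # non-channel residue increments nothing
  expect_equal(code_values(compute_code("ACKG", p)), base)
})

test_that("normalize_code handles reference and unit modes and their errors", {
  p4 <- assay_panel4()
  cd <- composition_code(c(2, 2, 2, 1), p4)
  expect_equal(unname(code_values(normalize_code(cd, "reference", "K"))),
               c(1, 1, 1, 0.5))
  expect_equal(unname(code_values(normalize_code(
    composition_code(c(3, 4), toy_panel2()), "unit"))), c(0.6, 0.8))
  expect_error(normalize_code(composition_code(c(2, 0, 1, 1), p4),
                              "reference", "K"), "cannot normalize")
  expect_error(normalize_code(composition_code(c(0, 0), toy_panel2()),
                              "unit"), "all-zero")
  # unit normalization is idempotent
  u1 <- normalize_code(cd, "unit")
  u2 <- normalize_code(u1, "unit")
  expect_equal(code_values(u2), code_values(u1), tolerance = 1e-12)
})

test_that("read_fasta parses headers, wraps, and validates sequences", {
  r <- read_fasta(">sp|P1|X\nMKC")
  expect_equal(nrow(r), 1)
  expect_equal(r$sequence, "MKC")
  expect_equal(r$id, "sp|P1|X")
  r2 <- read_fasta(">a first protein\nMK\nCD\n>b\nWW\nYY")
  expect_equal(r2$sequence, c("MKCD", "WWYY"))
  expect_equal(r2$description[1], "first protein")
  expect_equal(nrow(read_fasta("")), 0)
  expect_error(read_fasta(">bad\nMK9C"), "bad")
  # file round trip
  f <- tempfile(fileext = ".fasta")
  write_fasta(r2, f)
  expect_equal(read_fasta(f)$sequence, r2$sequence)
})

test_that("build_library groups records by parent accession", {
  p <- toy_panel2()
  r3 <- protein_records(c("a", "b", "c"), c("CK", "KK", "CC"))
  lib <- build_library(r3, p)
  expect_equal(length(lib), 3)
  expect_equal(length(lib$group_members), 3)
  shared <- protein_records(c("x:1", "x:2"), c("CK", "KK"),
                            parent_accession = c("x", "x"))
  lib2 <- build_library(shared, p)
  expect_equal(length(lib2$group_members), 1)
  expect_equal(sort(lib2$ids[lib2$group_members[["x"]]]), c("x:1", "x:2"))
  expect_error(build_library(protein_records(c("a", "a"), c("C", "K")), p),
               "duplicate")
  expect_error(build_library(protein_records(character(0), character(0)), p),
               "zero records")
})

test_that("library TSV serialization round-trips bit-exactly", {
  lib <- build_library(
    protein_records(c("a", "b:1", "b:2"), c("CCKD", "KKMG", "CMMG"),
                    parent_accession = c("a", "b", "b")),
    canonical_panel(4, "assay-matched"))
  f <- tempfile(fileext = ".tsv")
  write_library(lib, f)
  lib2 <- read_library(f)
  expect_identical(lib2$codes, lib$codes)
  expect_identical(lib2$ids, lib$ids)
  expect_identical(lib2$groups, lib$groups)
  expect_true(lib2$panel$channels[[4]]$c_terminus)
  expect_equal(panel_labels(lib2$panel), panel_labels(lib$panel))
})
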