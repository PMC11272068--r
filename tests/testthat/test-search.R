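# Cosine similarity and ranked identification.

test_that("cosine similarity matches hand-computed values and conventions", {
  expect_equal(cosine_similarity(c(1, 1, 1, 0.5), c(1, 1, 1, 0.5)), 1)
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0)
  expect_equal(cosine_similarity(c(1, 0), c(1, 1)), 1 / sqrt(2))
  expect_equal(cosine_similarity(c(0.97, 1, 0.98, 0.49), c(1, 1, 1, 0.5)),
               0.9999253, tolerance = 1e-6)
  # degenerate zero vectors are defined deterministically
  expect_equal(cosine_similarity(c(0, 0), c(0, 0)), 1)
  expect_equal(cosine_similarity(c(0, 0), c(1, 1)), 0)
  expect_error(cosine_similarity(c(1, 0), c(1, 0, 0)), "lengths differ")
  p <- toy_panel2()
  expect_error(cosine_similarity(composition_code(c(1, 0), p),
                                 composition_code(c(1, 0, 0),
                                                  canonical_panel(3))),
               "mismatched panels")
})

test_that("cosine similarity is symmetric, scale-invariant and bounded", {
  set.seed(3)
  for (i in 1:50) {
    k <- sample(2:9, 1)
    u <- stats::runif(k, 0, 5)
    v <- stats::runif(k, 0, 5)
    a <- sample(c(0.01, 0.5, 3, 100), 1)
    expect_equal(cosine_similarity(u, v), cosine_similarity(v, u))
    expect_equal(cosine_similarity(a * u, v), cosine_similarity(u, v),
                 tolerance = 1e-12)
    s <- cosine_similarity(u, v)
    expect_gte(s, 0); expect_lte(s, 1)
  }
})

test_that("rank_entries orders by similarity with deterministic id ties", {
  lib <- build_library(
    protein_records(c("A", "B", "C"), c("C", "K", "CK")), toy_panel2())
  hits <- rank_entries(c(1, 0), lib)
  expect_equal(hits$record_id, c("A", "C", "B"))
  expect_equal(hits$similarity, c(1, 1 / sqrt(2), 0), tolerance = 1e-12)
  expect_equal(hits$rank, 1:3)
  # query equal to an entry's code puts that entry first with similarity 1
  hits2 <- rank_entries(c(1, 1), lib)
  expect_equal(hits2$record_id[1], "C")
  expect_equal(hits2$similarity[1], 1)
  # identical codes tie and are reported in id order
  lib2 <- build_library(
    protein_records(c("zz", "aa"), c("CK", "CK")), toy_panel2())
  hits3 <- rank_entries(c(1, 1), lib2)
  expect_equal(hits3$record_id, c("aa", "zz"))
  expect_error(rank_entries(c(1, 0), lib, collapse_groups = TRUE), NA)
})

test_that("group collapsing keeps each group's best member", {
  lib <- build_library(
    protein_records(c("x:1", "x:2", "y"), c("C", "K", "CCKK"),
                    parent_accession = c("x", "x", "y")),
    toy_panel2())
  hits <- rank_entries(c(1, 0), lib, collapse_groups = TRUE)
  expect_equal(nrow(hits), 2)
  x_hit <- hits[hits$group_id == "x", ]
  expect_equal(x_hit$record_id, "x:1")   # the (1,0) member, similarity 1
  expect_equal(x_hit$similarity, 1)
})

test_that("ranking matches an exhaustive compute-then-sort oracle", {
  for (seed in 1:5) {
    n <- sample(20:100, 1)
    lib <- random_library(n, n_channels = sample(2:5, 1), seed = seed)
    set.seed(seed + 100)
    q <- stats::runif(length(lib$panel), 0, 6)
    hits <- rank_entries(q, lib, collapse_groups = FALSE)
    # oracle: scalar cosine per entry, base-R sort with id tiebreak
    sims <- vapply(seq_len(n), function(i)
      cosine_similarity(q, lib$codes[i, ]), numeric(1))
    ord <- order(-sims, lib$ids)
    expect_equal(hits$record_id, lib$ids[ord])
    expect_equal(hits$similarity, sims[ord], tolerance = 1e-12)
  }
})

test_that("identify_protein reports at most n group hits at set precision", {
  lib <- build_library(
    protein_records(c("A", "B", "C"), c("C", "K", "CK")), toy_panel2())
  expect_equal(nrow(identify_protein(c(1, 0), lib, n = 5)), 3)
  hits <- identify_protein(c(1, 0), lib, n = 2)
  expect_equal(nrow(hits), 2)
  expect_equal(hits$similarity[2], round(1 / sqrt(2), 3))
})

test_that("the measured URP code identifies its entry among decoys", {
  lib <- library_from_codes4(list(c(2, 1, 0, 1), c(1, 1, 1, 1), c(0, 1, 0, 1)),
                             ids = c("UTS2B", "D1", "D2"))
  hits <- identify_protein(c(2.04, 1, 0.00, 0.95), lib, n = 5)
  expect_equal(hits$record_id[1], "UTS2B")
  expect_gte(hits$similarity[1], 0.999)
})

test_that("tie policies implement the conservative/optimistic contract", {
  lib <- build_library(
    protein_records(c("A", "B", "C"), c("CK", "CK", "K")), toy_panel2())
  q <- c(1, 1)
  # two groups share the query's exact code
  expect_false(is_identified("A", q, lib, n = 1, policy = "conservative"))
  expect_true(is_identified("A", q, lib, n = 1, policy = "optimistic"))
  expect_true(is_identified("A", q, lib, n = 2, policy = "conservative"))
  # n >= number of groups is always identified
  expect_true(is_identified("C", q, lib, n = 3, policy = "conservative"))
  expect_error(is_identified("nope", q, lib, n = 1), "unknown true group")
  # unique code at the top identifies under both policies
  lib2 <- build_library(
    protein_records(c("A", "B"), c("C", "K")), toy_panel2())
  expect_true(is_identified("A", c(1, 0), lib2, n = 1, "conservative"))
  expect_true(is_identified("A", c(1, 0), lib2, n = 1, "optimistic"))
})

test_that("conservative identification implies optimistic identification", {
  for (seed in 1:3) {
    lib <- random_library(40, n_channels = 3, dup_frac = 0.3, seed = seed)
    set.seed(seed)
    ids <- sample(lib$ids, 10)
    for (id in ids) {
      q <- lib$codes[match(id, lib$ids), ]
      g <- lib$groups[match(id, lib$ids)]
      for (n in c(1, 5)) {
        if (is_identified(g, q, lib, n, "conservative"))
          expect_true(is_identified(g, q, lib, n, "optimistic"))
      }
    }
  }
})

test_that("hit reports serialize to TSV and JSON", {
  lib <- build_library(protein_records(c("A", "B"), c("C", "CK")),
                       toy_panel2())
  hits <- identify_protein(c(1, 0), lib)
  f1 <- tempfile(fileext = ".tsv"); f2 <- tempfile(fileext = ".json")
  write_hits(hits, f1); write_hits(hits, f2)
  expect_equal(utils::read.delim(f1)$record_id, hits$record_id)
  expect_equal(jsonlite::read_json(f2, simplifyVector = TRUE)$record_id,
               hits$record_id)
})
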