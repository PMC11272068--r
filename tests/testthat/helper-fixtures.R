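# Shared fixtures, built in code.

toy_panel2 <- function() {
  channel_panel(list(channel("C", "C"), channel("K", "K")), name = "toy2")
}

# assay-matched 4-channel panel: C, K, M, D/E with the C-terminus on D/E
assay_panel4 <- function() canonical_panel(4, "assay-matched")

# library whose entries hold prescribed codes: sequences are built so their
# counts on the assay-matched C,K,M,D/E panel equal the requested integers
# (D/E channel value includes the +1 C-terminus).
library_from_codes4 <- function(codes, ids = NULL) {
  seq_for <- function(v) {
    stopifnot(length(v) == 4, v[4] >= 1)   # C-terminus contributes 1 to D/E
    paste0(strrep("C", v[1]), strrep("K", v[2]), strrep("M", v[3]),
           strrep("D", v[4] - 1), strrep("G", 1))
  }
  seqs <- vapply(codes, seq_for, character(1))
  ids <- ids %||% paste0("P", seq_along(codes))
  build_library(protein_records(ids, seqs), assay_panel4())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# random integer-count library for property tests; optionally inject
# duplicated codes and multi-member groups
random_library <- function(n_entries, n_channels = 3, max_count = 6,
                           dup_frac = 0.2, seed = 1) {
  labels <- c("C", "K", "M", "D/E", "Y", "R", "H", "W", "S")[seq_len(n_channels)]
  panel <- channel_panel(lapply(labels, function(lb)
    channel(lb, setdiff(strsplit(lb, "/", fixed = TRUE)[[1]], ""))),
    name = paste0("rand", n_channels))
  withr_seed <- function(expr) { set.seed(seed); expr }
  withr_seed({
    M <- matrix(sample(0:max_count, n_entries * n_channels, replace = TRUE),
                nrow = n_entries)
    ndup <- floor(dup_frac * n_entries)
    if (ndup > 0 && n_entries > 1) {
      src <- sample(n_entries, ndup, replace = TRUE)
      dst <- sample(setdiff(seq_len(n_entries), src[1]), ndup)
      M[dst, ] <- M[src, ]
    }
    M[rowSums(M) == 0, 1] <- 1   # avoid all-zero codes
    seqs <- apply(M, 1, function(v)
      paste(mapply(strrep, vapply(panel$channels, function(ch) ch$residues[1],
                                  character(1)), v),
            collapse = ""))
    seqs[!nzchar(seqs)] <- "G"
    ids <- sprintf("R%03d", seq_len(n_entries))
    groups <- ids
    if (n_entries >= 6) groups[2] <- groups[1]   # one two-member group
    recs <- protein_records(ids, seqs, parent_accession = groups)
    build_library(recs, panel)
  })
}

# exact-line standard curve: perfect doubling per cycle, Ct 40 at 1 copy/uL
perfect_curve <- function() {
  fit_standard_curve(data.frame(copies_per_uL = 10^(4:8),
                                ct = 40 - (1 / log10(2)) * (4:8)))
}

# amyloid-beta 1-42, used in the worked examples
ABETA42 <- "DAEFRHDSGYEVHHQKLVFFAEDVGSNKGAIIGLMVGGVVIA"
# urotensin II-related peptide
URP_SEQ <- "ACFWKYCV"
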