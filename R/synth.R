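# Seeded synthetic data: proteomes with human-like residue frequencies,
# secretome-like chain sets with shared precursors, and simulated qPCR runs.
# Every generator is a pure function of its seed so fixtures are
# reproducible bit for bit.

#' Average amino-acid frequencies of human proteins
#'
#' The published Swiss-Prot average composition (percent per residue),
#' pinned as a constant and normalized to sum to 1 so that synthetic
#' proteomes are deterministic across package versions.
#'
#' @return Named numeric vector over the 20 standard residues, summing to 1.
#' @export
human_aa_frequencies <- function() {
  f <- c(A = 8.25, R = 5.53, N = 4.06, D = 5.45, C = 1.38, Q = 3.93,
         E = 6.72, G = 7.07, H = 2.27, I = 5.91, L = 9.65, K = 5.80,
         M = 2.41, F = 3.86, P = 4.74, S = 6.64, T = 5.35, W = 1.10,
         Y = 2.92, V = 6.86)
  f / sum(f)
}

#' Specify a synthetic proteome
#'
#' @param n_proteins Number of proteins.
#' @param length_range Integer `(min, max)`; lengths are uniform on the
#'   range.
#' @param residue_frequencies Named sampling probabilities per residue
#'   letter (must sum to 1 within 1e-9); default [human_aa_frequencies()].
#' @param chains_per_protein Integer vector the per-precursor chain count is
#'   drawn from uniformly (secretome fixtures only); default `1:3`.
#' @param seed Integer seed.
#' @return A list of class `"proteome_spec"`.
#' @export
proteome_spec <- function(n_proteins = 1000L, length_range = c(50L, 500L),
                          residue_frequencies = human_aa_frequencies(),
                          chains_per_protein = 1:3, seed = 1L) {
  stopifnot(n_proteins >= 1L, length(length_range) == 2L,
            length_range[1] >= 1L, length_range[2] >= length_range[1])
  if (is.null(names(residue_frequencies)) ||
      any(!nzchar(names(residue_frequencies))))
    stop("residue frequencies must be named by residue letter")
  if (any(residue_frequencies < 0))
    stop("residue frequencies must be non-negative")
  if (abs(sum(residue_frequencies) - 1) > 1e-9)
    stop("residue frequencies must sum to 1 (got ",
         sum(residue_frequencies), ")")
  structure(list(n_proteins = as.integer(n_proteins),
                 length_range = as.integer(length_range),
                 residue_frequencies = residue_frequencies,
                 chains_per_protein = as.integer(chains_per_protein),
                 seed = as.integer(seed)),
            class = "proteome_spec")
}

#' Generate a synthetic proteome
#'
#' Sequence lengths are uniform on the spec's range; residues are i.i.d.
#' draws from the frequency table. Deterministic under the spec's seed.
#'
#' @param spec A [proteome_spec()].
#' @return A [protein_records()] data frame with ids `SYN00001`, ...
#' @export
generate_proteome <- function(spec) {
  stopifnot(inherits(spec, "proteome_spec"))
  with_seed(spec$seed, {
    n_lens <- spec$length_range[2] - spec$length_range[1] + 1L
    lens <- spec$length_range[1] +
      sample.int(n_lens, spec$n_proteins, replace = TRUE) - 1L
    letters_pool <- sample(names(spec$residue_frequencies), sum(lens),
                           replace = TRUE, prob = spec$residue_frequencies)
    ends <- cumsum(lens)
    starts <- c(1L, utils::head(ends, -1L) + 1L)
    seqs <- vapply(seq_along(lens), function(i)
      paste(letters_pool[starts[i]:ends[i]], collapse = ""), character(1))
    protein_records(sprintf("SYN%05d", seq_along(seqs)), seqs,
                    description = "synthetic protein")
  })
}

#' Generate a secretome-like chain fixture
#'
#' Emulates mature chains and active peptides processed from shared
#' precursors: each synthetic precursor is cut into 1 to 3 (per the spec's
#' `chains_per_protein`) contiguous non-overlapping chains, each carrying
#' the precursor accession as `parent_accession`, so group collapsing is
#' exercised exactly as with real secretome annotation.
#'
#' @param spec A [proteome_spec()]; precursors are generated from it.
#' @return A [protein_records()] data frame of chains.
#' @export
generate_secretome_fixture <- function(spec) {
  stopifnot(inherits(spec, "proteome_spec"))
  precursors <- generate_proteome(spec)
  with_seed(derive_seed(spec$seed, 104729L), {
    min_len <- 5L
    out <- vector("list", nrow(precursors))
    for (i in seq_len(nrow(precursors))) {
      L <- nchar(precursors$sequence[i])
      k <- if (length(spec$chains_per_protein) == 1L)
        spec$chains_per_protein else sample(spec$chains_per_protein, 1L)
      k <- min(k, max(1L, L %/% (2L * min_len)))
      # contiguous split into k chains of length >= min_len
      extra <- L - k * min_len
      u <- if (k > 1L) sort(sample(0:extra, k - 1L, replace = TRUE))
           else integer(0)
      lens <- min_len + diff(c(0L, u, extra))
      end <- cumsum(lens)
      begin <- c(1L, utils::head(end, -1L) + 1L)
      out[[i]] <- protein_records(
        id = sprintf("%s:CHAIN:%d-%d", precursors$id[i], begin, end),
        sequence = substring(precursors$sequence[i], begin, end),
        entry_name = precursors$entry_name[i],
        parent_accession = precursors$id[i],
        description = "synthetic mature chain")
    }
    res <- do.call(rbind, out)
    class(res) <- c("protein_records", "data.frame")
    rownames(res) <- NULL
    res
  })
}

#' Simulate one qPCR run for a known code
#'
#' Forward model inverting [code_from_measurements()]: each channel's true
#' copy number is its code value times `reference_copies`; the aliquot's
#' fluorescence is log-normal with unit mean and the stated coefficient of
#' variation, and the loaded amount scales with it; three wells each read
#' the curve-predicted Ct plus Gaussian noise. Zero-copy channels emit
#' undetermined wells (`NA`).
#'
#' @param true_code A [composition_code()] (reference element > 0).
#' @param curve A [fit_standard_curve()] result.
#' @param reference_copies Copies/uL carried by a unit code element
#'   (default 1e8).
#' @param ct_noise_sd Per-well Gaussian Ct noise SD (cycles).
#' @param fluorescence_cv Coefficient of variation of the aliquot
#'   fluorescence (0 means every aliquot carries exactly the nominal
#'   amount).
#' @param measurement_id Run index recorded in the output.
#' @param seed Integer seed.
#' @return A data frame of wells: `measurement_id`, `channel`, `well`,
#'   `ct`, `fluorescence`.
#' @export
simulate_qpcr_run <- function(true_code, curve, reference_copies = 1e8,
                              ct_noise_sd = 0, fluorescence_cv = 0,
                              measurement_id = 1L, seed = 1L) {
  stopifnot(inherits(true_code, "composition_code"),
            inherits(curve, "standard_curve"),
            reference_copies > 0, ct_noise_sd >= 0, fluorescence_cv >= 0)
  v <- code_values(true_code)
  with_seed(seed, {
    rows <- lapply(seq_along(v), function(j) {
      fl <- if (fluorescence_cv > 0) {
        sdlog <- sqrt(log(1 + fluorescence_cv^2))
        stats::rlnorm(1, meanlog = -sdlog^2 / 2, sdlog = sdlog)
      } else 1
      copies <- v[j] * reference_copies * fl   # loaded amount tracks the dye
      ct <- if (copies > 0)
        curve$intercept + curve$slope * log10(copies) +
          stats::rnorm(3, 0, ct_noise_sd)
      else rep(NA_real_, 3)
      data.frame(measurement_id = as.integer(measurement_id),
                 channel = names(v)[j], well = 1:3, ct = ct,
                 fluorescence = fl, stringsAsFactors = FALSE)
    })
    res <- do.call(rbind, rows)
    rownames(res) <- NULL
    res
  })
}
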