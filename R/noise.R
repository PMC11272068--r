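# Monte Carlo error tolerance: identification coverage as a function of
# measurement precision.
#
# Each code element x is measured with Gaussian relative error: the observed
# value is drawn from Normal(x, (rsd * x)^2), i.e. the standard deviation is
# proportional to the true value and the relative standard deviation (RSD)
# is the single precision parameter.  Zero elements have zero sigma and stay
# exactly zero.

#' Define a Gaussian relative-error model
#'
#' @param rsd Relative standard deviation sigma/mu of a measured code
#'   element (e.g. `0.05` for 5% precision).
#' @param clip_negative Clip negative draws to 0 (codes are physical
#'   abundances; default `TRUE`). Clipping introduces a small upward bias at
#'   high RSD, documented rather than hidden.
#' @return A list of class `"noise_model"`.
#' @export
noise_model <- function(rsd, clip_negative = TRUE) {
  stopifnot(is.numeric(rsd), length(rsd) == 1L, rsd >= 0)
  structure(list(rsd = rsd, clip_negative = isTRUE(clip_negative)),
            class = "noise_model")
}

# evaluate expr with a temporary RNG state seeded from `seed`, restoring the
# caller's stream afterwards; NULL seed uses the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# fold indices into a master seed: a Lehmer-style walk keeping everything
# below 2^31 - 1 so derived seeds are valid 32-bit integers.
derive_seed <- function(master, ...) {
  x <- as.double(master) %% 2147483647
  for (i in c(...)) x <- (x * 48271 + i + 1) %% 2147483647
  as.integer(x)
}

perturb_matrix <- function(M, model) {
  if (model$rsd == 0) return(M)
  E <- matrix(stats::rnorm(length(M), mean = 0, sd = 1), nrow = nrow(M))
  out <- M + E * (model$rsd * M)       # sigma = rsd * mu; zero stays zero
  if (model$clip_negative) out[out < 0] <- 0
  out
}

#' Perturb a composition code with Gaussian relative error
#'
#' @param code A [composition_code()].
#' @param model A [noise_model()].
#' @param seed Optional integer seed giving a self-contained draw (the
#'   caller's RNG stream is untouched); `NULL` consumes the current stream.
#' @return A perturbed [composition_code()].
#' @export
perturb_code <- function(code, model, seed = NULL) {
  stopifnot(inherits(code, "composition_code"),
            inherits(model, "noise_model"))
  v <- with_seed(seed,
                 perturb_matrix(matrix(code_values(code), nrow = 1),
                                model)[1, ])
  composition_code(v, code$panel)
}

#' Monte Carlo coverage under measurement noise
#'
#' Per replicate, every entry's code is perturbed under the noise model and
#' queried against the clean library; coverage is the fraction identified at
#' depth `n` under the tie policy. Fully reproducible given `seed`
#' (replicate r uses a sub-seed derived from it).
#'
#' @param library A `"code_library"`.
#' @param model A [noise_model()].
#' @param n Identification depth.
#' @param replicates Number of independent simulated coverage values whose
#'   mean is reported (default 5).
#' @param policy Tie policy, see [is_identified()].
#' @param seed Integer master seed.
#' @return A list of class `"noisy_sweep_result"`: `rsd`, `panel_name`,
#'   `panel_size`, `top_n`, `replicate_coverages`, `mean_coverage`.
#' @export
noisy_coverage <- function(library, model, n = 1L, replicates = 5L,
                           policy = c("conservative", "optimistic"),
                           seed = 1L) {
  policy <- match.arg(policy)
  stopifnot(inherits(library, "code_library"),
            inherits(model, "noise_model"), replicates >= 1L)
  own <- match(library$groups, names(library$group_members))
  covs <- vapply(seq_len(replicates), function(r) {
    Q <- with_seed(derive_seed(seed, r), perturb_matrix(library$codes, model))
    S <- similarity_matrix(Q, library$codes)
    G <- collapse_to_groups(S, library)
    mean(identified_batch(G, own, n, policy))
  }, numeric(1))
  structure(list(rsd = model$rsd, panel_name = library$panel$name,
                 panel_size = length(library$panel), top_n = as.integer(n),
                 replicate_coverages = covs, mean_coverage = mean(covs)),
            class = "noisy_sweep_result")
}

#' @export
print.noisy_sweep_result <- function(x, ...) {
  cat(sprintf(
    "<noisy_sweep_result> panel %s, rsd %.4g, top %d: mean coverage %.3f (%d replicates)\n",
    x$panel_name, x$rsd, x$top_n, x$mean_coverage,
    length(x$replicate_coverages)))
  invisible(x)
}

#' Coverage sweep over RSD grid and panels
#'
#' Evaluates the cross-product of noise levels and panel sizes; every
#' (rsd, panel, replicate) cell draws from an independent stream derived
#' deterministically from the master seed, so any cell can be reproduced in
#' isolation.
#'
#' @param records A [protein_records()] data frame (the library is rebuilt
#'   per panel).
#' @param rsds Non-negative noise levels (the customary grid spans 0.05% to
#'   10%).
#' @param panel_sizes Canonical panel sizes, each in 2..9.
#' @param n Identification depth (default top 1).
#' @param replicates Replicates per cell (default 5).
#' @param policy Tie policy.
#' @param termini Termini preset for [canonical_panel()].
#' @param seed Integer master seed.
#' @return A long-format data frame: `rsd`, `panel_size`, `top_n`,
#'   `replicate`, `coverage`, `mean_coverage`.
#' @export
rsd_sweep <- function(records, rsds, panel_sizes = c(4L, 9L), n = 1L,
                      replicates = 5L,
                      policy = c("conservative", "optimistic"),
                      termini = "library-default", seed = 1L) {
  policy <- match.arg(policy)
  stopifnot(all(rsds >= 0))
  rows <- list()
  for (pi in seq_along(panel_sizes)) {
    lib <- build_library(records, canonical_panel(panel_sizes[pi], termini))
    for (ri in seq_along(rsds)) {
      res <- noisy_coverage(lib, noise_model(rsds[ri]), n = n,
                            replicates = replicates, policy = policy,
                            seed = derive_seed(seed, ri, pi))
      rows[[length(rows) + 1L]] <- data.frame(
        rsd = rsds[ri], panel_size = panel_sizes[pi], top_n = as.integer(n),
        replicate = seq_len(replicates),
        coverage = res$replicate_coverages,
        mean_coverage = res$mean_coverage)
    }
  }
  do.call(rbind, rows)
}
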