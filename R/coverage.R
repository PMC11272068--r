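# Noise-free identification coverage: what fraction of a library's entries
# can be re-identified by searching their own (exact) code against the whole
# database?

#' Self-search identification coverage
#'
#' Queries every entry's code against the full library (the query stays in
#' the database, so its own group scores similarity 1) and counts it as
#' identified when its group survives [is_identified()] at depth `n`.
#' Coverage is reported over entries (chains) and, when groups have several
#' members, also over groups (a group counts if any member is identified).
#'
#' @param library A `"code_library"`.
#' @param n Identification depth (top N; the customary depths are 1 and 5).
#' @param policy Tie policy, see [is_identified()].
#' @param tie_tol Tie tolerance, see [is_identified()].
#' @return A list of class `"coverage_report"`: `panel_name`, `panel_size`,
#'   `top_n`, `policy`, `n_queries`, `n_identified`, `coverage`, plus
#'   `n_groups`, `n_groups_identified`, `coverage_groups`.
#' @export
self_search_coverage <- function(library, n = 1L,
                                 policy = c("conservative", "optimistic"),
                                 tie_tol = 1e-9) {
  policy <- match.arg(policy)
  stopifnot(inherits(library, "code_library"))
  S <- similarity_matrix(library$codes, library$codes)
  G <- collapse_to_groups(S, library)
  own <- match(library$groups, colnames(G))
  ok <- identified_batch(G, own, n, policy, tie_tol)
  grp_ok <- tapply(ok, library$groups, any)
  structure(list(
    panel_name = library$panel$name, panel_size = length(library$panel),
    top_n = as.integer(n), policy = policy,
    n_queries = length(ok), n_identified = sum(ok),
    coverage = mean(ok),
    n_groups = length(grp_ok), n_groups_identified = sum(grp_ok),
    coverage_groups = mean(grp_ok)
  ), class = "coverage_report")
}

#' @export
print.coverage_report <- function(x, ...) {
  cat(sprintf(
    "<coverage_report> panel %s, top %d, %s ties: %d/%d entries (%.1f%%), %d/%d groups (%.1f%%)\n",
    x$panel_name, x$top_n, x$policy, x$n_identified, x$n_queries,
    100 * x$coverage, x$n_groups_identified, x$n_groups,
    100 * x$coverage_groups))
  invisible(x)
}

# per-entry uniqueness flags: an entry is unique when no OTHER group holds a
# code with the same direction (unit-normalized, rounded at 1e-9 — the same
# resolution as the search tie tolerance).
unique_entry_flags <- function(library) {
  M <- library$codes
  nrm <- sqrt(rowSums(M^2))
  U <- M / ifelse(nrm > 0, nrm, 1)
  key <- apply(round(U, 9), 1, paste, collapse = ",")
  groups_per_key <- tapply(library$groups, key,
                           function(g) length(unique(g)))
  as.vector(groups_per_key[key] == 1L)
}

#' Fraction of entries with a unique composition code
#'
#' An entry's code is unique when its direction (unit-normalized code,
#' rounded at 1e-9) is shared by no other group; members of the same
#' precursor group sharing a code do not break uniqueness. This equals
#' noise-free conservative top-1 self-search coverage.
#'
#' @param library A `"code_library"`.
#' @return The unique fraction in `[0, 1]`.
#' @export
uniqueness_fraction <- function(library) {
  stopifnot(inherits(library, "code_library"))
  if (length(library) == 0L) stop("empty library")
  mean(unique_entry_flags(library))
}

#' Coverage sweep over canonical panel sizes
#'
#' Rebuilds the library once per panel size (canonical prefix order C, K, M,
#' D/E, Y, R, H, W, S) and evaluates noise-free self-search coverage at each
#' requested depth.
#'
#' @param records A [protein_records()] data frame.
#' @param sizes Panel sizes, each in 2..9.
#' @param top_ns Identification depths (default 1 and 5).
#' @param policy Tie policy.
#' @param termini Termini preset passed to [canonical_panel()].
#' @return A long-format data frame: `panel_size`, `top_n`, `n_queries`,
#'   `n_identified`, `coverage`, `coverage_groups`.
#' @export
panel_sweep <- function(records, sizes = 2:9, top_ns = c(1L, 5L),
                        policy = c("conservative", "optimistic"),
                        termini = "library-default") {
  policy <- match.arg(policy)
  if (any(sizes < 2 | sizes > 9))
    stop("panel sizes must lie in 2..9")
  rows <- list()
  for (size in sizes) {
    lib <- build_library(records, canonical_panel(size, termini))
    for (n in top_ns) {
      rep <- self_search_coverage(lib, n = n, policy = policy)
      rows[[length(rows) + 1L]] <- data.frame(
        panel_size = size, top_n = as.integer(n),
        n_queries = rep$n_queries, n_identified = rep$n_identified,
        coverage = rep$coverage, coverage_groups = rep$coverage_groups)
    }
  }
  do.call(rbind, rows)
}
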