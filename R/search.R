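# Cosine-similarity search against a code library.
#
# Identification ranks every database entry by the cosine of the angle
# between the query code and the entry code,
#
#     similarity(u, v) = (u . v) / (||u|| ||v||),
#
# which is scale-invariant: raw counts and relative ratios rank identically.
# For non-negative codes the similarity lies in [0, 1].

#' Cosine similarity between two composition codes
#'
#' @param u,v [composition_code()] objects or plain numeric vectors of equal
#'   length (and on the same panel, when panels are carried).
#' @return The cosine similarity, clamped to `[0, 1]` for non-negative
#'   inputs. Degenerate cases are defined deterministically: two all-zero
#'   codes are identical (similarity 1); exactly one all-zero code is
#'   maximally dissimilar (similarity 0).
#' @examples
#' cosine_similarity(c(1, 0), c(1, 1))   # 1/sqrt(2)
#' @export
cosine_similarity <- function(u, v) {
  if (inherits(u, "composition_code") && inherits(v, "composition_code") &&
      !panels_compatible(u$panel, v$panel))
    stop("codes are on mismatched panels")
  uu <- as_code_values(u); vv <- as_code_values(v)
  if (length(uu) != length(vv))
    stop("code lengths differ (", length(uu), " vs ", length(vv), ")")
  nu <- sqrt(sum(uu^2)); nv <- sqrt(sum(vv^2))
  if (nu == 0 && nv == 0) return(1)
  if (nu == 0 || nv == 0) return(0)
  s <- sum(uu * vv) / (nu * nv)
  min(max(s, 0), 1)
}

# similarity of each row of Q (queries x channels) against each row of M
# (entries x channels); returns queries x entries matrix.  Zero-norm rows
# follow the scalar conventions above.
similarity_matrix <- function(Q, M) {
  nq <- sqrt(rowSums(Q^2)); nm <- sqrt(rowSums(M^2))
  S <- tcrossprod(Q, M)
  denom <- outer(nq, nm)
  S <- ifelse(denom > 0, S / denom, 0)
  if (any(nq == 0) && any(nm == 0))
    S[nq == 0, nm == 0] <- 1
  S[S < 0] <- 0; S[S > 1] <- 1
  S
}

# collapse an entry-level similarity matrix (queries x entries) to group
# level by the maximum over each group's members; returns queries x groups.
# Columns follow the order of library$group_members (sorted group ids).
collapse_to_groups <- function(S, library) {
  gm <- library$group_members
  if (length(gm) == length(library$ids)) {
    # all groups are singletons: reorder columns only
    idx <- vapply(gm, `[[`, integer(1), 1L)
    G <- S[, idx, drop = FALSE]
  } else {
    G <- vapply(gm, function(ix) {
      if (length(ix) == 1L) S[, ix]
      else do.call(pmax, lapply(ix, function(i) S[, i]))
    }, numeric(nrow(S)))
    if (nrow(S) == 1L) G <- matrix(G, nrow = 1L)
  }
  colnames(G) <- names(gm)
  G
}

#' Rank all library entries against a query code
#'
#' @param query A [composition_code()] or numeric vector on the library
#'   panel.
#' @param library A `"code_library"`.
#' @param collapse_groups Represent each precursor group once, by its
#'   maximum-similarity member (default `TRUE`): processed chains of one
#'   precursor count as a single database entry.
#' @return A data frame with columns `rank`, `record_id`, `group_id`,
#'   `entry_name`, `similarity`, sorted by non-increasing similarity; ties
#'   are broken by ascending record id so results are reproducible across
#'   platforms.
#' @export
rank_entries <- function(query, library, collapse_groups = TRUE) {
  stopifnot(inherits(library, "code_library"))
  if (length(library) == 0L) stop("empty library")
  q <- as_code_values(query, library$panel)
  sims <- similarity_matrix(matrix(q, nrow = 1), library$codes)[1, ]
  if (collapse_groups) {
    rep_idx <- vapply(library$group_members, function(ix) {
      best <- ix[sims[ix] == max(sims[ix])]
      best[order(library$ids[best])][1]   # smallest id among the argmax
    }, integer(1))
    df <- data.frame(record_id = library$ids[rep_idx],
                     group_id = names(library$group_members),
                     entry_name = library$entry_names[rep_idx],
                     similarity = sims[rep_idx],
                     stringsAsFactors = FALSE)
  } else {
    df <- data.frame(record_id = library$ids, group_id = library$groups,
                     entry_name = library$entry_names, similarity = sims,
                     stringsAsFactors = FALSE)
  }
  df <- df[order(-df$similarity, df$record_id), , drop = FALSE]
  df <- cbind(rank = seq_len(nrow(df)), df)
  rownames(df) <- NULL
  df
}

#' Identify a measured code: top-N group-collapsed hits
#'
#' @inheritParams rank_entries
#' @param n Number of top candidates to report (if the library has fewer
#'   groups, all are returned).
#' @param digits Decimal places for the reported similarity (default 3,
#'   the precision measured codes are customarily reported at).
#' @return The first `n` rows of [rank_entries()] with rounded similarities.
#' @export
identify_protein <- function(query, library, n = 5L, digits = 3L) {
  stopifnot(n >= 1L)
  hits <- rank_entries(query, library, collapse_groups = TRUE)
  hits <- utils::head(hits, n)
  hits$similarity <- round(hits$similarity, digits)
  hits
}

#' Is the true group identified within the top N?
#'
#' Let `s*` be the true group's similarity to the query (maximum over its
#' members). Under the `"conservative"` tie policy a query is identified iff
#' strictly better groups plus tied other groups number fewer than `n` —
#' ties count against the query, so noise-free top-1 coverage equals the
#' code-uniqueness fraction. Under `"optimistic"` only strictly better
#' groups count.
#'
#' @inheritParams rank_entries
#' @param true_group Group id of the query's true precursor.
#' @param n Identification depth (top N).
#' @param policy `"conservative"` or `"optimistic"`.
#' @param tie_tol Similarities within `tie_tol` of `s*` count as ties
#'   (absorbs floating-point error in the cosine of parallel count vectors).
#' @return Logical scalar.
#' @export
is_identified <- function(true_group, query, library, n = 1L,
                          policy = c("conservative", "optimistic"),
                          tie_tol = 1e-9) {
  policy <- match.arg(policy)
  stopifnot(inherits(library, "code_library"), n >= 1L)
  if (!true_group %in% library$groups)
    stop("unknown true group: ", true_group)
  q <- as_code_values(query, library$panel)
  S <- similarity_matrix(matrix(q, nrow = 1), library$codes)
  G <- collapse_to_groups(S, library)[1, ]
  s_star <- G[[true_group]]
  better <- sum(G > s_star + tie_tol)
  if (policy == "conservative") {
    ties_other <- sum(abs(G - s_star) <= tie_tol) - 1L
    (better + ties_other) < n
  } else {
    better < n
  }
}

# vectorized identification for self-search / simulation: Ggrp is a
# queries x groups similarity matrix, own is the column index of each
# query's true group.
identified_batch <- function(Ggrp, own, n, policy, tie_tol = 1e-9) {
  s_star <- Ggrp[cbind(seq_len(nrow(Ggrp)), own)]
  D <- sweep(Ggrp, 1, s_star)
  better <- rowSums(D > tie_tol)
  if (policy == "conservative") {
    ties_other <- rowSums(abs(D) <= tie_tol) - 1L
    (better + ties_other) < n
  } else {
    better < n
  }
}

#' Write an identification report
#'
#' @param hits A data frame from [identify_protein()] or [rank_entries()].
#' @param path Output path; `.json` extension selects JSON, anything else
#'   TSV.
#' @return `path`, invisibly.
#' @export
write_hits <- function(hits, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::write_json(hits, path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA)
  else
    utils::write.table(hits, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(path)
}
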