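# Composition codes: the per-channel residue counts (or relative ratios) that
# fingerprint a protein.

#' Construct a composition code
#'
#' @param values Numeric vector, one non-negative finite value per panel
#'   channel; raw counts or relative ratios (cosine comparison is
#'   scale-invariant, so the two are interchangeable for search).
#' @param panel The [channel_panel()] the values refer to.
#' @return An object of class `"composition_code"`.
#' @export
composition_code <- function(values, panel) {
  stopifnot(inherits(panel, "channel_panel"))
  values <- as.numeric(values)
  if (length(values) != length(panel))
    stop("code length (", length(values), ") does not match panel length (",
         length(panel), ")")
  if (any(!is.finite(values)))
    stop("composition code values must be finite")
  if (any(values < 0))
    stop("composition code values must be non-negative")
  names(values) <- panel_labels(panel)
  structure(list(values = values, panel = panel), class = "composition_code")
}

#' Numeric values of a composition code
#' @param code A [composition_code()].
#' @return Named numeric vector in panel order.
#' @export
code_values <- function(code) {
  stopifnot(inherits(code, "composition_code"))
  code$values
}

#' @export
print.composition_code <- function(x, digits = 3, ...) {
  cat("<composition_code> [", x$panel$name, "] ",
      paste(sprintf("%s=%.*g", names(x$values), digits, x$values),
            collapse = " "), "\n", sep = "")
  invisible(x)
}

#' @export
length.composition_code <- function(x) length(x$values)

# count matrix for many sequences at once: one row per sequence, one column
# per channel.  Residue counting is delegated to Biostrings::letterFrequency.
code_matrix <- function(sequences, panel) {
  stopifnot(inherits(panel, "channel_panel"))
  sequences <- as.character(sequences)
  if (length(sequences) == 0L)
    return(matrix(numeric(0), nrow = 0, ncol = length(panel),
                  dimnames = list(NULL, panel_labels(panel))))
  if (any(!nzchar(sequences)))
    stop("empty sequence at position ", which(!nzchar(sequences))[1])
  bad <- !grepl("^[A-Z]+$", sequences)
  if (any(bad))
    stop("sequence ", which(bad)[1],
         " contains characters outside A-Z")
  aas <- Biostrings::AAStringSet(sequences)
  letters_needed <- unique(unlist(lapply(panel$channels, `[[`, "residues")))
  counts <- if (length(letters_needed))
    Biostrings::letterFrequency(aas, letters = letters_needed)
  else
    matrix(0L, nrow = length(sequences), ncol = 0)
  out <- matrix(0, nrow = length(sequences), ncol = length(panel),
                dimnames = list(NULL, panel_labels(panel)))
  for (j in seq_along(panel$channels)) {
    ch <- panel$channels[[j]]
    v <- 0
    if (length(ch$residues))
      v <- rowSums(counts[, ch$residues, drop = FALSE])
    if (ch$n_terminus) v <- v + 1
    if (ch$c_terminus) v <- v + 1
    out[, j] <- v
  }
  out
}

#' Compute the composition code of a sequence
#'
#' Each channel's value is the number of that channel's residue letters in the
#' sequence, plus one per terminus the channel is flagged to count. Ambiguity
#' codes (B/Z/X) and selenocysteine (U) count toward no channel; a sequence
#' hitting no channel yields the all-zero code.
#'
#' @param sequence Non-empty uppercase amino-acid string (IUPAC one-letter).
#' @param panel A [channel_panel()].
#' @return A [composition_code()] of raw counts.
#' @examples
#' p <- canonical_panel(4, "assay-matched")
#' compute_code("ACFWKYCV", p)   # C=2 K=1 M=0 D/E=1 (the C-terminus)
#' @export
compute_code <- function(sequence, panel) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (!nzchar(sequence)) stop("sequence must be non-empty")
  composition_code(code_matrix(sequence, panel)[1, ], panel)
}

#' Normalize a composition code
#'
#' Reference-channel mode divides every value by the chosen channel's value —
#' the convention used to report measured codes relative to the Lys channel
#' (e.g. 0.97:1:0.98:0.49). Unit mode divides by the Euclidean norm, mapping
#' codes with the same residue ratios to the same point.
#'
#' @param code A [composition_code()].
#' @param mode `"reference"` or `"unit"`.
#' @param reference Reference channel label (reference mode only);
#'   default `"K"`.
#' @return A normalized [composition_code()].
#' @export
normalize_code <- function(code, mode = c("reference", "unit"),
                           reference = "K") {
  stopifnot(inherits(code, "composition_code"))
  mode <- match.arg(mode)
  v <- code$values
  if (mode == "reference") {
    if (!reference %in% names(v))
      stop("reference channel '", reference, "' is not in the panel")
    ref <- v[[reference]]
    if (ref <= 0)
      stop("reference channel '", reference, "' has value ", ref,
           "; cannot normalize")
    composition_code(v / ref, code$panel)
  } else {
    nrm <- sqrt(sum(v^2))
    if (nrm == 0)
      stop("cannot unit-normalize the all-zero code")
    composition_code(v / nrm, code$panel)
  }
}

#' Element-wise average of composition codes
#'
#' Replicate measured codes from independent runs are combined by the
#' arithmetic mean of each channel's relative ratio.
#'
#' @param codes A list of [composition_code()] objects on a common panel.
#' @return A [composition_code()].
#' @export
average_codes <- function(codes) {
  if (inherits(codes, "composition_code")) codes <- list(codes)
  stopifnot(is.list(codes))
  if (length(codes) == 0L) stop("no codes to average")
  if (!all(vapply(codes, inherits, logical(1), "composition_code")))
    stop("'codes' must be a list of composition_code objects")
  p <- codes[[1]]$panel
  for (cd in codes[-1])
    if (!panels_compatible(p, cd$panel)) stop("codes are on mismatched panels")
  m <- do.call(rbind, lapply(codes, code_values))
  composition_code(colMeans(m), p)
}

# coerce a numeric vector or composition_code to plain numeric values,
# checking panel compatibility when both sides carry a panel
as_code_values <- function(x, panel = NULL) {
  if (inherits(x, "composition_code")) {
    if (!is.null(panel) && !panels_compatible(x$panel, panel))
      stop("code panel does not match the library panel")
    code_values(x)
  } else {
    v <- as.numeric(x)
    if (!is.null(panel) && length(v) != length(panel))
      stop("code length (", length(v), ") does not match panel length (",
           length(panel), ")")
    v
  }
}
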