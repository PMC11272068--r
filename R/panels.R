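# Residue channels and channel panels.
#
# A "channel" is one coordinate of a composition code: the set of amino-acid
# letters that one residue-specific labeling chemistry addresses (Asp and Glu
# share carboxylate chemistry, so they form a single combined channel).  A
# channel may additionally count one of the peptide termini: the Asp/Glu
# chemistry also hits the C-terminal carboxylate, and the Lys chemistry hits a
# free N-terminal amine.

# canonical incremental order of labelable residue types
.CANONICAL_CHANNELS <- list(
  "C"   = "C",
  "K"   = "K",
  "M"   = "M",
  "D/E" = c("D", "E"),
  "Y"   = "Y",
  "R"   = "R",
  "H"   = "H",
  "W"   = "W",
  "S"   = "S"
)

# letters that may never be counted: ambiguity codes and rare residues whose
# side chains are not addressed by the labeling chemistries
.UNCOUNTABLE_LETTERS <- c("B", "Z", "X", "U")

#' Define a residue channel
#'
#' A channel groups one or more amino-acid letters that are counted together
#' in a composition code, optionally adding one count per sequence for a free
#' terminus (the Asp/Glu carboxylate chemistry also labels the C-terminal
#' carboxylate; the Lys amine chemistry can label a free N-terminal amine).
#'
#' @param label Channel label, unique within a panel (e.g. `"C"`, `"D/E"`).
#' @param residues Character vector of uppercase one-letter residue codes
#'   counted by this channel. Ambiguity codes (B, Z, X) and selenocysteine (U)
#'   are not allowed: they count toward no channel.
#' @param n_terminus If `TRUE`, add one count per sequence for the free
#'   N-terminal amine.
#' @param c_terminus If `TRUE`, add one count per sequence for the C-terminal
#'   carboxylate.
#' @return An object of class `"channel"`.
#' @examples
#' channel("D/E", c("D", "E"), c_terminus = TRUE)
#' @export
channel <- function(label, residues = character(), n_terminus = FALSE,
                    c_terminus = FALSE) {
  stopifnot(is.character(label), length(label) == 1L, nzchar(label))
  residues <- as.character(residues)
  if (length(residues) == 0L && !n_terminus && !c_terminus)
    stop("channel '", label, "' counts no residues and no terminus")
  if (length(residues) > 0L) {
    bad <- residues[!residues %in% setdiff(LETTERS, .UNCOUNTABLE_LETTERS)]
    if (length(bad))
      stop("invalid channel residues for '", label, "': ",
           paste(bad, collapse = ", "),
           " (must be uppercase amino-acid letters other than B/Z/X/U)")
    if (anyDuplicated(residues))
      stop("duplicated residues in channel '", label, "'")
  }
  structure(
    list(label = label, residues = residues,
         n_terminus = isTRUE(n_terminus), c_terminus = isTRUE(c_terminus)),
    class = "channel"
  )
}

#' Assemble an ordered panel of residue channels
#'
#' @param channels A list of [channel()] objects, in code order.
#' @param name Optional panel name used in reports.
#' @return An object of class `"channel_panel"`.
#' @details Labels must be unique and no residue letter may be claimed by two
#'   channels. Panels hold between 1 and 9 channels, matching the nine residue
#'   types with established residue-specific labeling chemistry.
#' @examples
#' channel_panel(list(channel("C", "C"), channel("K", "K")), name = "toy")
#' @export
channel_panel <- function(channels, name = NULL) {
  if (inherits(channels, "channel")) channels <- list(channels)
  stopifnot(is.list(channels), length(channels) >= 1L)
  if (!all(vapply(channels, inherits, logical(1), "channel")))
    stop("'channels' must be a list of channel objects")
  if (length(channels) > 9L)
    stop("a panel holds at most 9 channels")
  labels <- vapply(channels, `[[`, character(1), "label")
  if (anyDuplicated(labels))
    stop("duplicated channel labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  all_res <- unlist(lapply(channels, `[[`, "residues"))
  if (anyDuplicated(all_res))
    stop("residue letter(s) assigned to more than one channel: ",
         paste(unique(all_res[duplicated(all_res)]), collapse = ", "))
  if (is.null(name)) name <- paste(labels, collapse = ",")
  structure(list(channels = channels, labels = labels, name = name),
            class = "channel_panel")
}

#' @export
length.channel_panel <- function(x) length(x$channels)

#' @export
print.channel_panel <- function(x, ...) {
  cat("<channel_panel> ", x$name, " (", length(x), " channels)\n", sep = "")
  for (ch in x$channels) {
    term <- c(if (ch$n_terminus) "N-term", if (ch$c_terminus) "C-term")
    cat(sprintf("  %-4s %s%s\n", ch$label,
                paste(ch$residues, collapse = ""),
                if (length(term)) paste0(" +", paste(term, collapse = "+")) else ""))
  }
  invisible(x)
}

#' Panel labels
#' @param panel A [channel_panel()].
#' @return Character vector of channel labels in panel order.
#' @export
panel_labels <- function(panel) {
  stopifnot(inherits(panel, "channel_panel"))
  panel$labels
}

#' Build a canonical prefix panel
#'
#' The canonical incremental channel order is C, K, M, D/E, Y, R, H, W, S; a
#' canonical panel of size *k* takes the first *k* channels of that order.
#'
#' @param size Number of channels, 1 to 9.
#' @param termini Termini preset. `"library-default"` counts residues only and
#'   is used for proteome-wide library sweeps. `"assay-matched"` adds the
#'   C-terminal carboxylate to the D/E channel (the Asp/Glu chemistry labels
#'   it too) and, when `lys_n_terminus = TRUE`, the free N-terminal amine to
#'   the K channel — matching assays where the N-terminus is unblocked.
#' @param lys_n_terminus Count the N-terminus on the K channel (only under
#'   `"assay-matched"`); use when the peptide's N-terminal amine is free,
#'   leave `FALSE` when it carries a calibration dye.
#' @param name Optional panel name.
#' @return A [channel_panel()].
#' @examples
#' canonical_panel(4)                       # C, K, M, D/E; residues only
#' canonical_panel(4, "assay-matched")      # D/E channel counts the C-terminus
#' @export
canonical_panel <- function(size = 9,
                            termini = c("library-default", "assay-matched"),
                            lys_n_terminus = FALSE, name = NULL) {
  stopifnot(length(size) == 1L, size == as.integer(size))
  if (size < 1L || size > 9L)
    stop("canonical panel size must be between 1 and 9, got ", size)
  termini <- match.arg(termini)
  labels <- names(.CANONICAL_CHANNELS)[seq_len(size)]
  panel_from_labels(labels, termini = termini, lys_n_terminus = lys_n_terminus,
                    name = name)
}

#' Build a panel from canonical channel labels
#'
#' @param labels Character vector of canonical labels (subset of `"C"`, `"K"`,
#'   `"M"`, `"D/E"`, `"Y"`, `"R"`, `"H"`, `"W"`, `"S"`), in the desired order.
#' @inheritParams canonical_panel
#' @return A [channel_panel()].
#' @export
panel_from_labels <- function(labels,
                              termini = c("library-default", "assay-matched"),
                              lys_n_terminus = FALSE, name = NULL) {
  termini <- match.arg(termini)
  unknown <- setdiff(labels, names(.CANONICAL_CHANNELS))
  if (length(unknown))
    stop("unknown channel label(s): ", paste(unknown, collapse = ", "))
  assay <- identical(termini, "assay-matched")
  chans <- lapply(labels, function(lb) {
    channel(lb, .CANONICAL_CHANNELS[[lb]],
            n_terminus = assay && lb == "K" && isTRUE(lys_n_terminus),
            c_terminus = assay && lb == "D/E")
  })
  channel_panel(chans, name = name %||% paste(labels, collapse = ","))
}

#' Named panel presets
#'
#' `"core-4"` is C, K, M, D/E — the default labeling combination; `"core-4y"`
#' swaps D/E for Tyr (C, K, M, Y), useful when a single Tyr is easier to
#' quantify than several acidic residues; `"core-5"` is C, K, M, D/E, Y; and
#' `"full-9"` is the full nine-channel panel.
#'
#' @param preset One of `"core-4"`, `"core-4y"`, `"core-5"`, `"full-9"`.
#' @inheritParams canonical_panel
#' @return A [channel_panel()].
#' @export
panel_preset <- function(preset = c("core-4", "core-4y", "core-5", "full-9"),
                         termini = c("library-default", "assay-matched"),
                         lys_n_terminus = FALSE) {
  preset <- match.arg(preset)
  labels <- switch(preset,
    "core-4"  = c("C", "K", "M", "D/E"),
    "core-4y" = c("C", "K", "M", "Y"),
    "core-5"  = c("C", "K", "M", "D/E", "Y"),
    "full-9"  = names(.CANONICAL_CHANNELS)
  )
  panel_from_labels(labels, termini = match.arg(termini),
                    lys_n_terminus = lys_n_terminus, name = preset)
}

# panels are compatible when their channel structure is identical
panels_compatible <- function(a, b) {
  identical(a$labels, b$labels) &&
    identical(lapply(a$channels, `[`, c("residues", "n_terminus", "c_terminus")),
              lapply(b$channels, `[`, c("residues", "n_terminus", "c_terminus")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
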