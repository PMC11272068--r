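# Code libraries: the searchable database of composition codes.

new_code_library <- function(panel, ids, groups, entry_names, codes) {
  stopifnot(inherits(panel, "channel_panel"))
  ids <- as.character(ids); groups <- as.character(groups)
  entry_names <- as.character(entry_names)
  stopifnot(nrow(codes) == length(ids), length(groups) == length(ids),
            length(entry_names) == length(ids),
            ncol(codes) == length(panel))
  if (anyDuplicated(ids))
    stop("duplicate record id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  rownames(codes) <- ids
  colnames(codes) <- panel_labels(panel)
  structure(
    list(panel = panel, ids = ids, groups = groups,
         entry_names = entry_names, codes = codes,
         group_members = split(seq_along(ids), groups)),
    class = "code_library"
  )
}

#' Build a composition code library
#'
#' Converts every record's sequence into a composition code on the given
#' panel. Records sharing a `parent_accession` form one group: processed
#' chains of the same precursor are collapsed to a single database entry at
#' search time, so a match to any chain identifies the precursor.
#'
#' @param records A [protein_records()] data frame (unique ids required).
#' @param panel A [channel_panel()].
#' @return An object of class `"code_library"` holding the panel, per-record
#'   ids, group ids, entry names and the count matrix (records x channels).
#' @export
build_library <- function(records, panel) {
  stopifnot(is.data.frame(records))
  if (nrow(records) == 0L) stop("cannot build a library from zero records")
  if (anyDuplicated(records$id))
    stop("duplicate record id(s): ",
         paste(unique(records$id[duplicated(records$id)]), collapse = ", "))
  codes <- code_matrix(records$sequence, panel)
  new_code_library(panel, records$id, records$parent_accession,
                   records$entry_name, codes)
}

#' @export
print.code_library <- function(x, ...) {
  cat("<code_library> ", length(x$ids), " entries, ",
      length(x$group_members), " groups, panel ", x$panel$name, "\n", sep = "")
  invisible(x)
}

#' Number of entries in a code library
#' @param x A `"code_library"`.
#' @export
length.code_library <- function(x) length(x$ids)

#' Extract one entry's code from a library
#' @param library A `"code_library"`.
#' @param id Record id.
#' @return A [composition_code()].
#' @export
library_code <- function(library, id) {
  stopifnot(inherits(library, "code_library"))
  i <- match(id, library$ids)
  if (is.na(i)) stop("unknown record id: ", id)
  composition_code(library$codes[i, ], library$panel)
}
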