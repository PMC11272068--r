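# Sequence records and FASTA / library-table input-output.

#' Construct a table of protein records
#'
#' Records are kept as a plain data frame: one row per protein or mature
#' chain, with `parent_accession` tying processed chains back to their
#' precursor entry (equal to `id` for whole proteins).
#'
#' @param id Unique record identifiers.
#' @param sequence Uppercase amino-acid sequences.
#' @param entry_name Human-readable entry names (default: `id`).
#' @param parent_accession Precursor accession per record (default: `id`).
#' @param description Free-text descriptions.
#' @return A data frame with class `"protein_records"` prepended.
#' @export
protein_records <- function(id, sequence, entry_name = id,
                            parent_accession = id, description = "") {
  id <- as.character(id); sequence <- as.character(sequence)
  stopifnot(length(id) == length(sequence))
  if (any(!nzchar(id))) stop("record ids must be non-empty")
  if (any(!nzchar(sequence))) stop("record sequences must be non-empty")
  parent_accession <- as.character(parent_accession)
  if (any(!nzchar(parent_accession)))
    stop("parent accessions must be non-empty")
  df <- data.frame(
    id = id,
    entry_name = rep_len(as.character(entry_name), length(id)),
    parent_accession = rep_len(parent_accession, length(id)),
    sequence = sequence,
    description = rep_len(as.character(description), length(id)),
    stringsAsFactors = FALSE
  )
  class(df) <- c("protein_records", class(df))
  df
}

empty_records <- function() {
  protein_records(character(0), character(0))
}

#' Read protein records from FASTA
#'
#' Standard FASTA dialect: `">"` headers, the token up to the first
#' whitespace is the record id, the remainder the description, wrapped
#' sequence lines are concatenated. `parent_accession` defaults to the id.
#'
#' @param input Path to a FASTA file, or a character scalar containing FASTA
#'   text itself (detected by an embedded newline or leading `">"`).
#' @return A [protein_records()] data frame; empty input yields zero rows.
#' @export
read_fasta <- function(input) {
  stopifnot(is.character(input), length(input) == 1L)
  path <- input
  if (grepl("\n", input, fixed = TRUE) || startsWith(input, ">") ||
      !file.exists(input)) {
    if (!grepl("\n", input, fixed = TRUE) && !startsWith(input, ">") &&
        nzchar(input))
      stop("file not found: ", input)
    if (!nzchar(gsub("[[:space:]]", "", input))) return(empty_records())
    path <- tempfile(fileext = ".fasta")
    on.exit(unlink(path), add = TRUE)
    writeLines(input, path)
  }
  if (file.size(path) == 0) return(empty_records())
  # validate raw lines first: the FASTA reader silently drops invalid codes
  raw <- readLines(path)
  is_hdr <- startsWith(raw, ">")
  rec_of <- cumsum(is_hdr)
  bad_line <- !is_hdr & !grepl("^[A-Za-z]*$", trimws(raw))
  if (any(bad_line)) {
    hdr <- raw[is_hdr][rec_of[which(bad_line)[1]]]
    stop("record '", sub("\\s.*$", "", sub("^>", "", hdr)),
         "' contains characters outside A-Z")
  }
  aas <- Biostrings::readAAStringSet(path)
  if (length(aas) == 0L) return(empty_records())
  headers <- names(aas)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  seqs <- toupper(as.character(aas))
  bad <- !grepl("^[A-Z]+$", seqs)
  if (any(bad))
    stop("record '", ids[which(bad)[1]],
         "' contains characters outside A-Z")
  protein_records(ids, seqs, entry_name = ids, description = desc)
}

#' Write protein records to FASTA
#'
#' @param records A [protein_records()] data frame.
#' @param path Output file path.
#' @param width Sequence line width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  stopifnot(is.data.frame(records))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    hdr <- records$id[i]
    if (nzchar(records$description[i]))
      hdr <- paste(hdr, records$description[i])
    writeLines(paste0(">", hdr), con)
    s <- records$sequence[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Write a code library to a TSV file
#'
#' The panel definition is embedded in `#`-prefixed header comments so the
#' file round-trips without a sidecar; integer count codes round-trip
#' bit-exactly.
#'
#' @param library A [build_library()] result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_library <- function(library, path) {
  stopifnot(inherits(library, "code_library"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# panel_name\t", library$panel$name), con)
  for (ch in library$panel$channels) {
    writeLines(paste("# channel", ch$label,
                     paste(ch$residues, collapse = ""),
                     as.integer(ch$n_terminus), as.integer(ch$c_terminus),
                     sep = "\t"), con)
  }
  df <- data.frame(id = library$ids, group = library$groups,
                   entry_name = library$entry_names,
                   stringsAsFactors = FALSE, check.names = FALSE)
  codes <- as.data.frame(library$codes, check.names = FALSE)
  df <- cbind(df, codes)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a code library from a TSV file written by [write_library()]
#'
#' @param path Path to the TSV file.
#' @return A `"code_library"` object.
#' @export
read_library <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "# ")]
  body <- lines[!startsWith(lines, "# ")]
  name <- NULL
  chans <- list()
  for (h in hdr) {
    parts <- strsplit(sub("^# ", "", h), "\t", fixed = TRUE)[[1]]
    if (parts[1] == "panel_name") name <- parts[2]
    if (parts[1] == "channel") {
      res <- if (length(parts) >= 3 && nzchar(parts[3]))
        strsplit(parts[3], "")[[1]] else character(0)
      chans[[length(chans) + 1L]] <-
        channel(parts[2], res,
                n_terminus = parts[4] == "1", c_terminus = parts[5] == "1")
    }
  }
  if (length(chans) == 0L) stop("no channel definitions found in ", path)
  panel <- channel_panel(chans, name = name)
  df <- utils::read.table(text = body, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  value_cols <- panel_labels(panel)
  missing_cols <- setdiff(c("id", "group", "entry_name", value_cols),
                          colnames(df))
  if (length(missing_cols))
    stop("library file lacks column(s): ", paste(missing_cols, collapse = ", "))
  codes <- as.matrix(df[, value_cols, drop = FALSE])
  storage.mode(codes) <- "double"
  new_code_library(panel, df$id, df$group, df$entry_name, codes)
}
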