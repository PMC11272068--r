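# UniProt-style annotated entries and secreted mature-chain extraction.
#
# Secretome libraries are built from processed products (mature chains,
# active peptides, propeptides) rather than whole precursor sequences: the
# circulating molecule is the cleaved chain, and its composition code differs
# from the precursor's.  Chains keep their precursor accession as the group
# id so that database search can collapse products of one gene.

#' Construct an annotated UniProt-style entry
#'
#' @param accession Primary accession.
#' @param entry_name Entry name (e.g. `"EDN1_HUMAN"`).
#' @param sequence Full-length precursor sequence.
#' @param keywords Character vector of keywords and/or subcellular locations;
#'   the secreted filter looks for `"Secreted"` here (case-insensitive).
#' @param features Data frame with columns `kind`, `begin`, `end` (1-based
#'   inclusive coordinates; `NA` for unknown ends).
#' @return A list of class `"uniprot_entry"`.
#' @export
uniprot_entry <- function(accession, entry_name, sequence,
                          keywords = character(),
                          features = data.frame(kind = character(),
                                                begin = integer(),
                                                end = integer())) {
  stopifnot(nzchar(accession), nzchar(sequence))
  features <- as.data.frame(features, stringsAsFactors = FALSE)
  if (nrow(features) && !all(c("kind", "begin", "end") %in% names(features)))
    stop("features must have columns kind, begin, end")
  structure(list(accession = accession, entry_name = entry_name,
                 sequence = sequence, keywords = as.character(keywords),
                 features = features),
            class = "uniprot_entry")
}

entry_is_secreted <- function(entry) {
  any(grepl("secreted", entry$keywords, ignore.case = TRUE))
}

#' Read UniProt entries from a tab-separated export
#'
#' Expected columns: `accession`, `entry_name`, `sequence`, `keywords`
#' (semicolon-separated), `feature_kind`, `feature_begin`, `feature_end` —
#' one row per feature, entry-level columns repeated. Rows with an empty
#' `feature_kind` contribute the entry without features.
#'
#' @param path Path to the TSV file, or a character scalar of TSV text.
#' @return A list of [uniprot_entry()] objects.
#' @export
read_uniprot_tsv <- function(path) {
  txt <- if (grepl("\n", path, fixed = TRUE)) path else {
    if (!file.exists(path)) stop("file not found: ", path)
    paste(readLines(path), collapse = "\n")
  }
  df <- utils::read.table(text = txt, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, quote = "",
                          colClasses = "character")
  need <- c("accession", "entry_name", "sequence", "keywords",
            "feature_kind", "feature_begin", "feature_end")
  missing_cols <- setdiff(need, colnames(df))
  if (length(missing_cols))
    stop("UniProt TSV lacks column(s): ", paste(missing_cols, collapse = ", "))
  lapply(split(df, factor(df$accession, levels = unique(df$accession))),
         function(d) {
    has_ft <- nzchar(d$feature_kind)
    uniprot_entry(
      accession = d$accession[1], entry_name = d$entry_name[1],
      sequence = d$sequence[1],
      keywords = trimws(strsplit(d$keywords[1], ";", fixed = TRUE)[[1]]),
      features = data.frame(
        kind = d$feature_kind[has_ft],
        begin = suppressWarnings(as.integer(d$feature_begin[has_ft])),
        end = suppressWarnings(as.integer(d$feature_end[has_ft])),
        stringsAsFactors = FALSE
      )
    )
  }) |> unname()
}

#' Read UniProt entries from flat-text format
#'
#' Minimal parser for the UniProtKB flat-file record types the extraction
#' needs: `ID`, `AC`, `KW`, `CC -!- SUBCELLULAR LOCATION`, `FT` feature rows
#' (modern `begin..end` locations) and the `SQ` sequence block, with entries
#' terminated by `//`. Unknown coordinates (`?`) become `NA`; fuzzy markers
#' (`<`, `>`) are stripped.
#'
#' @param path Path to a flat-text file, or a character scalar of its text.
#' @return A list of [uniprot_entry()] objects.
#' @export
read_uniprot_flat <- function(path) {
  lines <- if (grepl("\n", path, fixed = TRUE))
    strsplit(path, "\n", fixed = TRUE)[[1]]
  else {
    if (!file.exists(path)) stop("file not found: ", path)
    readLines(path)
  }
  entries <- list()
  acc <- NULL; entry_name <- NULL; kw <- character(); loc <- character()
  ft <- list(); seq_lines <- character(); in_sq <- FALSE; in_loc <- FALSE
  reset <- function() {
    acc <<- NULL; entry_name <<- NULL; kw <<- character()
    loc <<- character(); ft <<- list(); seq_lines <<- character()
    in_sq <<- FALSE; in_loc <<- FALSE
  }
  parse_coord <- function(x) {
    x <- gsub("[<>]", "", x)
    if (x == "?" || !nzchar(x)) NA_integer_ else as.integer(x)
  }
  for (ln in lines) {
    tag <- substr(ln, 1, 2)
    if (tag == "//") {
      if (!is.null(acc)) {
        feats <- if (length(ft)) do.call(rbind, ft) else
          data.frame(kind = character(), begin = integer(), end = integer())
        entries[[length(entries) + 1L]] <- uniprot_entry(
          accession = acc, entry_name = entry_name %||% acc,
          sequence = gsub("[[:space:]]", "", paste(seq_lines, collapse = "")),
          keywords = c(kw, loc), features = feats)
      }
      reset()
    } else if (tag == "ID") {
      entry_name <- strsplit(trimws(substr(ln, 6, nchar(ln))), "\\s+")[[1]][1]
    } else if (tag == "AC") {
      if (is.null(acc))
        acc <- sub(";.*$", "", trimws(substr(ln, 6, nchar(ln))))
    } else if (tag == "KW") {
      kws <- strsplit(gsub("\\.$", "", trimws(substr(ln, 6, nchar(ln)))),
                      ";\\s*")[[1]]
      kw <- c(kw, kws[nzchar(kws)])
    } else if (tag == "CC") {
      body <- substr(ln, 6, nchar(ln))
      if (grepl("^-!- SUBCELLULAR LOCATION:", body)) {
        in_loc <- TRUE
        loc <- c(loc, trimws(sub("^-!- SUBCELLULAR LOCATION:", "", body)))
      } else if (grepl("^-!-", body)) {
        in_loc <- FALSE
      } else if (in_loc) {
        loc <- c(loc, trimws(body))
      }
    } else if (tag == "FT") {
      body <- substr(ln, 6, nchar(ln))
      m <- regmatches(body,
        regexec("^(\\S+)\\s+([?<>0-9]+)(?:\\.\\.([?<>0-9]+))?\\s*$", body))[[1]]
      if (length(m) && !startsWith(trimws(body), "/")) {
        begin <- parse_coord(m[3])
        end <- if (nzchar(m[4])) parse_coord(m[4]) else begin
        ft[[length(ft) + 1L]] <- data.frame(kind = m[2], begin = begin,
                                            end = end,
                                            stringsAsFactors = FALSE)
      }
    } else if (tag == "SQ") {
      in_sq <- TRUE
    } else if (in_sq && substr(ln, 1, 1) == " ") {
      seq_lines <- c(seq_lines, ln)
    }
  }
  entries
}

#' Extract secreted mature chains from annotated entries
#'
#' For every entry passing the secreted filter, emits one record per feature
#' row whose kind is in `feature_kinds`, with the sequence sliced at the
#' feature's 1-based inclusive coordinates. Record ids are
#' `"accession:kind:begin-end"` and `parent_accession` is the precursor
#' accession, so chains of one precursor share a group.
#'
#' @param entries A list of [uniprot_entry()] objects (or a single entry).
#' @param feature_kinds Feature kinds to slice; default mature chains, active
#'   peptides and propeptides.
#' @param require_secreted Keep only entries annotated `"Secreted"` in their
#'   keywords or subcellular location.
#' @return A [protein_records()] data frame. Features with unknown
#'   coordinates are skipped with a warning; coordinates outside the
#'   precursor length are an error.
#' @export
extract_secreted_chains <- function(entries,
                                    feature_kinds = c("CHAIN", "PEPTIDE",
                                                      "PROPEP"),
                                    require_secreted = TRUE) {
  if (inherits(entries, "uniprot_entry")) entries <- list(entries)
  stopifnot(is.list(entries))
  out <- list()
  for (entry in entries) {
    stopifnot(inherits(entry, "uniprot_entry"))
    if (require_secreted && !entry_is_secreted(entry)) next
    feats <- entry$features
    feats <- feats[feats$kind %in% feature_kinds, , drop = FALSE]
    for (i in seq_len(nrow(feats))) {
      b <- feats$begin[i]; e <- feats$end[i]
      if (is.na(b) || is.na(e)) {
        warning("skipping ", entry$accession, " ", feats$kind[i],
                " feature with unknown coordinates", call. = FALSE)
        next
      }
      L <- nchar(entry$sequence)
      if (b < 1L || e > L || b > e)
        stop("feature coordinates ", b, "..", e, " of ", entry$accession,
             " outside sequence length ", L)
      out[[length(out) + 1L]] <- protein_records(
        id = sprintf("%s:%s:%d-%d", entry$accession, feats$kind[i], b, e),
        sequence = substr(entry$sequence, b, e),
        entry_name = entry$entry_name,
        parent_accession = entry$accession,
        description = sprintf("%s %d-%d of %s", feats$kind[i], b, e,
                              entry$accession)
      )
    }
  }
  if (length(out) == 0L) return(empty_records())
  res <- do.call(rbind, out)
  class(res) <- c("protein_records", "data.frame")
  rownames(res) <- NULL
  res
}
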