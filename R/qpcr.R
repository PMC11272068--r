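# qPCR data analysis: standard curves, Ct-to-copies conversion, and turning
# per-channel Ct measurements into a measured composition code.
#
# Each residue channel of a peptide is DNA-barcoded in its own aliquot and
# quantified by qPCR; an N-terminal fluorescent dye calibrates the amount of
# peptide each aliquot actually carried.  The relative ratio of
# fluorescence-corrected copy numbers across channels is the measured
# composition code.

#' Fit a qPCR standard curve
#'
#' Ordinary least squares of Ct on log10(copies) over a dilution series.
#' Amplification efficiency is `10^(-1/slope) - 1` (1.0 means perfect
#' doubling per cycle, slope -3.3219).
#'
#' @param dilutions Data frame with columns `copies_per_uL` and `ct`, or a
#'   numeric vector of copies when `ct` is given separately.
#' @param ct Optional numeric vector of Ct values paired with `dilutions`.
#' @return A list of class `"standard_curve"`: `slope`, `intercept`
#'   (Ct at 1 copy/uL), `r_squared`, `efficiency`.
#' @examples
#' fit_standard_curve(data.frame(copies_per_uL = 10^(4:8),
#'                               ct = 40 - 3.3219 * (4:8)))
#' @export
fit_standard_curve <- function(dilutions, ct = NULL) {
  if (is.data.frame(dilutions)) {
    stopifnot(all(c("copies_per_uL", "ct") %in% names(dilutions)))
    copies <- dilutions$copies_per_uL; ct <- dilutions$ct
  } else {
    copies <- as.numeric(dilutions)
  }
  stopifnot(length(copies) == length(ct))
  if (any(copies <= 0)) stop("dilution copy numbers must be positive")
  if (length(copies) < 2L) stop("need at least 2 dilution points")
  x <- log10(copies)
  if (stats::var(x) == 0) stop("zero variance in log10(copies)")
  fit <- stats::lm(ct ~ x)
  slope <- unname(stats::coef(fit)[2])
  sst <- sum((ct - mean(ct))^2)   # manual R2: exact fits are routine here
  r2 <- if (sst == 0) 1 else 1 - sum(stats::residuals(fit)^2) / sst
  structure(list(slope = slope,
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2,
                 efficiency = 10^(-1 / slope) - 1),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf(
    "<standard_curve> Ct = %.4f * log10(copies) + %.4f (R2 %.4f, efficiency %.1f%%)\n",
    x$slope, x$intercept, x$r_squared, 100 * x$efficiency))
  invisible(x)
}

#' Convert a Ct value to absolute copies
#'
#' Inverts the standard curve: `copies = 10^((ct - intercept) / slope)`.
#' "Undetermined" wells (`NA`) mean no amplification and map to 0 copies.
#'
#' @param ct Numeric Ct value(s); `NA` for undetermined.
#' @param curve A [fit_standard_curve()] result (slope must be negative).
#' @return Copy number(s) per microliter.
#' @export
ct_to_copies <- function(ct, curve) {
  stopifnot(inherits(curve, "standard_curve"))
  if (curve$slope >= 0)
    stop("standard curve slope must be negative (got ", curve$slope, ")")
  ifelse(is.na(ct), 0, 10^((ct - curve$intercept) / curve$slope))
}

# parse Ct cells that may read "Undetermined" (any case) into numeric/NA
parse_ct <- function(x) {
  if (is.numeric(x)) return(x)
  x <- trimws(as.character(x))
  out <- suppressWarnings(as.numeric(x))
  undet <- grepl("^undeter", x, ignore.case = TRUE) | x == "" | is.na(x)
  out[undet] <- NA_real_
  if (any(is.na(out) & !undet))
    stop("unparseable Ct value(s): ",
         paste(unique(x[is.na(out) & !undet]), collapse = ", "))
  out
}

#' Read per-channel qPCR wells from CSV
#'
#' Expected columns: `measurement_id`, `channel`, `well`, `ct` (numeric or
#' `"Undetermined"`), `fluorescence`.
#'
#' @param path CSV file path.
#' @return A data frame with `ct` parsed to numeric (`NA` = undetermined).
#' @export
read_qpcr_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("measurement_id", "channel", "well", "ct", "fluorescence")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("qPCR CSV lacks column(s): ", paste(missing_cols, collapse = ", "))
  df$ct <- parse_ct(df$ct)
  df
}

#' Read a dilution series from CSV
#' @param path CSV with columns `copies_per_uL`, `ct`.
#' @return A data frame.
#' @export
read_dilution_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("copies_per_uL", "ct") %in% names(df)))
    stop("dilution CSV needs columns copies_per_uL, ct")
  df$ct <- parse_ct(df$ct)
  df
}

#' Convert one qPCR run into a measured composition code
#'
#' Per channel: the mean Ct over wells (undetermined wells carry no signal;
#' a channel with no determined well has 0 copies) is converted to copies
#' through that channel's standard curve, divided by the aliquot's
#' fluorescence calibration signal, and expressed relative to the reference
#' channel — whose value is 1 by construction.
#'
#' @param measurements Data frame of wells for one run: columns `channel`,
#'   `ct` (numeric, `NA` = undetermined), `fluorescence` (one positive value
#'   per channel aliquot).
#' @param curves A single [fit_standard_curve()] result shared by all
#'   channels, or a named list with one curve per channel label.
#' @param reference Reference channel label (customarily `"K"`).
#' @param panel The [channel_panel()] the measurement addresses; channel
#'   labels in `measurements` must cover the panel.
#' @return A [composition_code()] of relative ratios.
#' @export
code_from_measurements <- function(measurements, curves, reference = "K",
                                   panel) {
  stopifnot(is.data.frame(measurements),
            all(c("channel", "ct", "fluorescence") %in% names(measurements)),
            inherits(panel, "channel_panel"))
  labels <- panel_labels(panel)
  missing_ch <- setdiff(labels, measurements$channel)
  if (length(missing_ch))
    stop("no measurement for channel(s): ",
         paste(missing_ch, collapse = ", "))
  if (!reference %in% labels)
    stop("reference channel '", reference, "' is not in the panel")
  get_curve <- function(lb) {
    cv <- if (inherits(curves, "standard_curve")) curves else curves[[lb]]
    if (is.null(cv)) stop("missing standard curve for channel '", lb, "'")
    cv
  }
  value <- vapply(labels, function(lb) {
    d <- measurements[measurements$channel == lb, , drop = FALSE]
    fl <- unique(d$fluorescence)
    if (length(fl) != 1L || !is.finite(fl) || fl <= 0)
      stop("channel '", lb, "' needs one positive fluorescence value")
    cts <- parse_ct(d$ct)
    mean_ct <- if (all(is.na(cts))) NA_real_ else mean(cts, na.rm = TRUE)
    ct_to_copies(mean_ct, get_curve(lb)) / fl
  }, numeric(1))
  if (value[[reference]] <= 0)
    stop("reference channel '", reference,
         "' is undetermined; cannot form relative ratios")
  composition_code(value / value[[reference]], panel)
}

#' Measured codes for every run in a well table, averaged
#'
#' Splits a well table by `measurement_id`, converts each independent run
#' into a code with [code_from_measurements()], and returns the element-wise
#' average (the customary final result over three independent runs) along
#' with the per-run codes.
#'
#' @inheritParams code_from_measurements
#' @param wells Data frame as from [read_qpcr_csv()] (needs
#'   `measurement_id`).
#' @return A list: `code` (the averaged [composition_code()]) and
#'   `per_run` (list of per-run codes, named by measurement id).
#' @export
codes_from_runs <- function(wells, curves, reference = "K", panel) {
  stopifnot("measurement_id" %in% names(wells))
  runs <- split(wells, wells$measurement_id)
  per_run <- lapply(runs, code_from_measurements, curves = curves,
                    reference = reference, panel = panel)
  list(code = average_codes(per_run), per_run = per_run)
}
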