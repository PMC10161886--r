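# Sample spreadsheet: the contract between user input and automation. One
# CSV row per sample: mount address (puck + position), collection method,
# optional acquisition parameters (filled from config defaults), optional
# multi-orientation (chi, phi) pair list, threshold mode and flags. The
# validator coerces and checks every row, collecting ALL errors with
# row/column coordinates rather than failing fast.

sheetMethods <- c("standard", "multi_orientation", "serial", "robot_test",
                  "alc_test")
sheetThresholdModes <- c("default", "strong", "weak", "always_collect")
sheetRequiredCols <- c("puck", "position", "sample_name", "method")
sheetAllCols <- c(sheetRequiredCols, "exposure_time", "oscillation",
                  "total_range", "transmission", "resolution",
                  "orientation_pairs", "threshold_mode", "no_centering",
                  "processing")

#' Parse an orientation-pair list
#'
#' Multi-orientation collections are defined as a list of (chi, phi) pairs,
#' encoded in the spreadsheet as `"(0,0);(20,0)"`.
#'
#' @param text encoded pair list
#' @return a 2-column matrix (chi, phi) or `NULL` for empty input; `NA` on a
#'   malformed string
#' @export
parseOrientationPairs <- function(text) {
  if (is.null(text) || is.na(text) || !nzchar(trimws(text))) return(NULL)
  parts <- strsplit(trimws(text), ";", fixed = TRUE)[[1]]
  rx <- "^\\(\\s*(-?[0-9.]+)\\s*,\\s*(-?[0-9.]+)\\s*\\)$"
  m <- regmatches(trimws(parts), regexec(rx, trimws(parts)))
  if (any(lengths(m) != 3)) return(NA)
  vals <- vapply(m, function(g) as.numeric(g[2:3]), numeric(2))
  if (anyNA(vals)) return(NA)
  matrix(t(vals), ncol = 2, dimnames = list(NULL, c("chi", "phi")))
}

formatOrientationPairs <- function(pairs) {
  if (is.null(pairs) || (length(pairs) == 1 && is.na(pairs))) return("")
  paste(sprintf("(%s,%s)", as.character(pairs[, 1]),
                as.character(pairs[, 2])), collapse = ";")
}

#' Read a sample spreadsheet (CSV)
#'
#' Header-mapped, whitespace-trimmed raw rows; unknown columns are preserved
#' so they can be carried into the report. A file with no data rows is valid
#' and yields zero rows.
#'
#' @param path CSV path (UTF-8, comma separated)
#' @return a data.frame of character columns
#' @export
readSampleSheet <- function(path) {
  if (!file.exists(path)) stop("spreadsheet not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0 || all(!nzchar(trimws(lines)))) {
    df <- as.data.frame(stats::setNames(
      replicate(length(sheetRequiredCols), character(0), simplify = FALSE),
      sheetRequiredCols))
    return(df)
  }
  df <- utils::read.csv(path, colClasses = "character",
                        check.names = FALSE, strip.white = TRUE)
  names(df) <- trimws(names(df))
  missing <- setdiff(sheetRequiredCols, names(df))
  if (length(missing))
    blStop("missingColumn",
           paste("missing required column(s):", paste(missing, collapse = ", ")),
           columns = missing)
  df[] <- lapply(df, trimws)
  df
}

sheetError <- function(errors, row, column, message) {
  rbind(errors, data.frame(row = row, column = column, message = message,
                           stringsAsFactors = FALSE))
}

#' Validate raw spreadsheet rows
#'
#' Coerces every row to the typed sample model and checks the invariants:
#' method from the closed set; chi in [0, 40] and phi in [-360, 360] for
#' every orientation pair; orientation pairs required exactly for the
#' multi-orientation method; exposure/oscillation/range positive; mount
#' addresses (puck, position) unique per run. Absent acquisition parameters
#' are filled from the config defaults. All errors are collected (with row
#' and column coordinates); a single error blocks the run.
#'
#' @param raw data.frame from [readSampleSheet()] (typed input is also
#'   accepted, making validation idempotent)
#' @param config beamline config supplying acquisition-parameter defaults
#' @return a list with `rows` (typed data.frame; `orientation_pairs` is a
#'   list column of 2-column matrices), `errors` (data.frame row/column/
#'   message) and `valid` (logical)
#' @export
validateSampleSheet <- function(raw, config = beamlineConfig()) {
  errors <- data.frame(row = integer(0), column = character(0),
                       message = character(0), stringsAsFactors = FALSE)
  n <- nrow(raw)
  defaults <- config$defaults
  asNum <- function(x) suppressWarnings(as.numeric(x))

  getCol <- function(col) if (col %in% names(raw)) raw[[col]] else rep(NA, n)
  numCol <- function(col, default) {
    v <- getCol(col)
    out <- numeric(n)
    for (i in seq_len(n)) {
      xi <- v[i]
      if (is.null(xi) || is.na(xi) || (is.character(xi) && !nzchar(xi))) {
        out[i] <- default
      } else {
        num <- asNum(xi)
        if (is.na(num)) {
          errors <<- sheetError(errors, i, col, paste0("not a number: '", xi, "'"))
          out[i] <- default
        } else out[i] <- num
      }
    }
    out
  }

  puck <- as.character(getCol("puck"))
  posn <- as.character(getCol("position"))
  name <- as.character(getCol("sample_name"))
  method <- as.character(getCol("method"))
  for (i in seq_len(n)) {
    if (is.na(puck[i]) || !nzchar(puck[i]))
      errors <- sheetError(errors, i, "puck", "mount puck is required")
    if (is.na(posn[i]) || !nzchar(posn[i]))
      errors <- sheetError(errors, i, "position", "mount position is required")
    if (is.na(method[i]) || !method[i] %in% sheetMethods)
      errors <- sheetError(errors, i, "method",
                           paste0("method must be one of: ",
                                  paste(sheetMethods, collapse = ", ")))
  }

  addr <- paste(puck, posn, sep = "/")
  dup <- addr[duplicated(addr)]
  for (d in unique(dup)) {
    where <- which(addr == d)
    for (i in where)
      errors <- sheetError(errors, i, "position",
                           sprintf("duplicate mount address %s (rows %s)", d,
                                   paste(where, collapse = ", ")))
  }

  exposure <- numCol("exposure_time", defaults$exposure_time)
  oscillation <- numCol("oscillation", defaults$oscillation)
  range <- numCol("total_range", defaults$total_range)
  transmission <- numCol("transmission", defaults$transmission)
  resolution <- numCol("resolution", defaults$resolution)
  for (i in seq_len(n)) {
    if (!is.na(exposure[i]) && exposure[i] <= 0)
      errors <- sheetError(errors, i, "exposure_time", "must be > 0")
    if (!is.na(oscillation[i]) && oscillation[i] <= 0)
      errors <- sheetError(errors, i, "oscillation", "must be > 0")
    if (!is.na(range[i]) && range[i] <= 0)
      errors <- sheetError(errors, i, "total_range", "must be > 0")
  }

  rawPairs <- getCol("orientation_pairs")
  pairs <- vector("list", n)
  for (i in seq_len(n)) {
    pi <- rawPairs[[i]]
    p <- if (is.matrix(pi)) pi else parseOrientationPairs(pi)
    if (length(p) == 1 && is.na(p)) {
      errors <- sheetError(errors, i, "orientation_pairs",
                           "malformed pair list; expected \"(chi,phi);(chi,phi)\"")
      p <- NULL
    }
    if (identical(method[i], "multi_orientation") && is.null(p))
      errors <- sheetError(errors, i, "orientation_pairs",
                           "multi_orientation requires a (chi,phi) pair list")
    if (!is.null(p)) {
      bad <- p[, 1] < 0 | p[, 1] > 40
      if (any(bad))
        errors <- sheetError(errors, i, "orientation_pairs",
                             sprintf("chi %s outside the 0-40 degree limit",
                                     paste(p[bad, 1], collapse = ", ")))
      badPhi <- p[, 2] < -360 | p[, 2] > 360
      if (any(badPhi))
        errors <- sheetError(errors, i, "orientation_pairs",
                             sprintf("phi %s outside the +-360 degree limit",
                                     paste(p[badPhi, 2], collapse = ", ")))
    }
    pairs[i] <- list(p)     # keep NULL entries (list assignment, not [[)
  }

  thm <- as.character(getCol("threshold_mode"))
  for (i in seq_len(n)) {
    if (is.na(thm[i]) || !nzchar(thm[i])) thm[i] <- "default"
    else if (!thm[i] %in% sheetThresholdModes)
      errors <- sheetError(errors, i, "threshold_mode",
                           paste0("must be one of: ",
                                  paste(sheetThresholdModes, collapse = ", ")))
  }

  ncRaw <- getCol("no_centering")
  noCentering <- logical(n)
  for (i in seq_len(n)) {
    v <- ncRaw[i]
    noCentering[i] <-
      if (is.logical(v)) isTRUE(v)
      else if (is.na(v) || !nzchar(v)) FALSE
      else tolower(v) %in% c("true", "1", "yes")
  }

  processing <- as.character(getCol("processing"))
  processing[is.na(processing)] <- ""

  rows <- data.frame(puck = puck, position = posn, sample_name = name,
                     method = method, exposure_time = exposure,
                     oscillation = oscillation, total_range = range,
                     transmission = transmission, resolution = resolution,
                     threshold_mode = thm, no_centering = noCentering,
                     processing = processing, stringsAsFactors = FALSE)
  rows$orientation_pairs <- pairs
  list(rows = rows, errors = errors, valid = nrow(errors) == 0)
}

#' Write a sample sheet back to CSV
#'
#' Inverse of [readSampleSheet()] + [validateSampleSheet()]: a validated row
#' set round-trips exactly (orientation pairs re-encoded as
#' `"(chi,phi);(chi,phi)"`, logicals as `true`/`false`).
#'
#' @param rows typed rows from [validateSampleSheet()]
#' @param path output CSV path
#' @return the path, invisibly
#' @export
writeSampleSheet <- function(rows, path) {
  out <- rows
  out$orientation_pairs <- vapply(rows$orientation_pairs,
                                  formatOrientationPairs, character(1))
  out$no_centering <- ifelse(rows$no_centering, "true", "false")
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], as.character)
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Render a validation report
#'
#' @param validation result of [validateSampleSheet()]
#' @param jsonPath optional path to also dump the report as JSON
#' @return character vector of human-readable lines
#' @export
validationReport <- function(validation, jsonPath = NULL) {
  if (!is.null(jsonPath))
    jsonlite::write_json(list(valid = validation$valid,
                              errors = validation$errors),
                         jsonPath, auto_unbox = TRUE, digits = NA)
  if (validation$valid)
    return(sprintf("spreadsheet OK: %d sample(s)", nrow(validation$rows)))
  c(sprintf("spreadsheet INVALID: %d error(s)", nrow(validation$errors)),
    sprintf("  row %d, %s: %s", validation$errors$row,
            validation$errors$column, validation$errors$message))
}
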