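# End-of-run HTML report: a summary table (per-step status glyphs and three
# thumbnails per sample -- centered sample image, 2D grid heat map, line-scan
# heat map) plus a single-page detail sheet per sample with the collection
# parameters and decision provenance. The report is a pure function of the
# journal: rebuilding from the same journal is byte-identical (no clocks).

statusGlyph <- function(status) {
  switch(status,
    in_progress = "\U0001F3C3",   # running man
    success = "\U0001F44D",       # thumbs up
    skipped = "\U0001F438",       # frog
    failed = "\U0001F44E",        # thumb down
    unknown = "➖",           # minus
    "➖")
}

htmlEscape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

thumbCell <- function(path, outDir, label) {
  if (!is.null(path) && length(path) == 1 && !is.na(path) &&
      file.exists(path)) {
    rel <- file.path("assets", basename(path))
    target <- file.path(outDir, rel)
    dir.create(dirname(target), showWarnings = FALSE, recursive = TRUE)
    if (!identical(normalizePath(path, mustWork = FALSE),
                   normalizePath(target, mustWork = FALSE)))
      file.copy(path, target, overwrite = TRUE)
    sprintf('<img src="%s" alt="%s" width="120"/>', rel, label)
  } else {
    sprintf('<span class="placeholder">no %s</span>', label)
  }
}

fmt <- function(x, digits = 4) {
  if (is.null(x) || length(x) == 0 || all(is.na(x))) return("-")
  paste(vapply(x, function(v)
    if (is.numeric(v)) as.character(round(v, digits)) else as.character(v),
    character(1)), collapse = ", ")
}

reportCss <- paste(
  "body{font-family:sans-serif;margin:2em;}",
  "table{border-collapse:collapse;}",
  "td,th{border:1px solid #999;padding:4px 8px;text-align:center;}",
  ".placeholder{color:#999;font-style:italic;}",
  sep = "\n")

#' Build the end-of-run HTML report
#'
#' Generates `summary.html` (one row per sample: per-step status glyphs and
#' three thumbnails) and one `sample-<row>.html` detail page per sample
#' (data folder, exposure time, oscillation, range, orientation pairs and
#' grid-scan decision provenance, plus larger images). Missing artifacts
#' render as explicit placeholders. Deterministic: the same journal always
#' produces byte-identical HTML.
#'
#' @param journalPath the run journal
#' @param outDir report output directory (assets are copied under
#'   `outDir/assets` and referenced relatively)
#' @return list with `summary` and `details` paths, invisibly
#' @export
buildReport <- function(journalPath, outDir) {
  rep <- replayJournal(journalPath)
  records <- rep$records
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)

  stepCols <- c(safety_check = "Safety", mount = "Mount",
                optical_center = "ALC", diff_center = "Diff Center",
                daq = "DAQ")
  head <- paste0("<tr><th>Sample</th>",
                 paste(sprintf("<th>%s</th>", stepCols), collapse = ""),
                 "<th>Sample image</th><th>2D grid</th><th>Line scan</th></tr>")
  bodyRows <- character(0)
  detailPaths <- character(0)

  for (rec in records) {
    statuses <- vapply(names(stepCols), function(s) {
      st <- rec$steps[[s]]
      if (is.null(st)) "unknown" else st$status
    }, character(1))
    oc <- rec$payloads$optical_center
    dc <- rec$payloads$diff_center
    cells <- vapply(names(stepCols), function(s) {
      note <- if (s == "daq" && statuses[[s]] == "skipped")
        "<br/><small>skipped (no spots above threshold)</small>" else ""
      sprintf('<td title="%s">%s%s</td>', statuses[[s]],
              statusGlyph(statuses[[s]]), note)
    }, character(1))
    thumbs <- paste0(
      "<td>", thumbCell(oc$image, outDir, "sample image"), "</td>",
      "<td>", thumbCell(dc$grid2dImage, outDir, "2D heat map"), "</td>",
      "<td>", thumbCell(dc$lineImage, outDir, "line heat map"), "</td>")
    detail <- sprintf("sample-%03d.html", rec$row)
    bodyRows <- c(bodyRows, paste0(
      sprintf('<tr><td><a href="%s">%s</a></td>', detail,
              htmlEscape(rec$sample)),
      paste(cells, collapse = ""), thumbs, "</tr>"))

    manifests <- rec$manifests
    folder <- if (length(manifests))
      paste(dirname(manifests), collapse = "<br/>") else "-"
    params <- NULL
    if (length(manifests) && file.exists(manifests[1]))
      params <- jsonlite::read_json(manifests[1], simplifyVector = TRUE)
    pairRows <- if (length(manifests)) {
      paste(vapply(manifests, function(m) {
        p <- jsonlite::read_json(m, simplifyVector = TRUE)
        sprintf("<li>chi = %s, phi = %s</li>", fmt(p$chi), fmt(p$phi))
      }, character(1)), collapse = "")
    } else ""
    detailHtml <- paste0(
      "<!DOCTYPE html><html><head><meta charset='utf-8'/><style>",
      reportCss, "</style><title>", htmlEscape(rec$sample),
      "</title></head><body>",
      sprintf("<h1>Sample %s (row %d)</h1>", htmlEscape(rec$sample),
              rec$row),
      "<h2>Step status</h2><table>",
      "<tr>", paste(sprintf("<th>%s</th>", stepCols), collapse = ""),
      "</tr><tr>",
      paste(sprintf("<td>%s %s</td>",
                    vapply(statuses, statusGlyph, character(1)), statuses),
            collapse = ""),
      "</tr></table>",
      "<h2>Data collection</h2><ul>",
      sprintf("<li>Data folder: %s</li>", folder),
      sprintf("<li>Exposure time: %s s</li>", fmt(params$exposure_time)),
      sprintf("<li>Oscillation: %s deg/frame</li>", fmt(params$oscillation)),
      sprintf("<li>Total range: %s deg</li>", fmt(params$total_range)),
      sprintf("<li>Omega start: %s deg</li>", fmt(params$omega_start)),
      "<li>Orientations:<ul>", pairRows, "</ul></li>",
      "</ul><h2>Grid-scan decision</h2><ul>",
      sprintf("<li>Best 2D box index: %s (peak %s spots)</li>",
              fmt(dc$best2dIndex), fmt(dc$peak2d)),
      sprintf("<li>Best line box index: %s (peak %s spots)</li>",
              fmt(dc$bestLineIndex), fmt(dc$peakLine)),
      sprintf("<li>Outcome: %s</li>", fmt(dc$outcome)),
      "</ul><h2>Images</h2>",
      thumbCell(oc$image, outDir, "sample image"),
      thumbCell(dc$grid2dImage, outDir, "2D heat map"),
      thumbCell(dc$lineImage, outDir, "line heat map"),
      sprintf('<p><a href="summary.html">back to summary</a></p>'),
      "</body></html>")
    dpath <- file.path(outDir, detail)
    writeLines(detailHtml, dpath, useBytes = TRUE)
    detailPaths <- c(detailPaths, dpath)
  }

  summaryHtml <- paste0(
    "<!DOCTYPE html><html><head><meta charset='utf-8'/><style>", reportCss,
    "</style><title>Run summary</title></head><body>",
    "<h1>Automated collection run summary</h1>",
    sprintf("<p>%d sample(s)</p>", length(records)),
    "<table>", head, paste(bodyRows, collapse = ""), "</table>",
    "</body></html>")
  spath <- file.path(outDir, "summary.html")
  writeLines(summaryHtml, spath, useBytes = TRUE)
  invisible(list(summary = spath, details = detailPaths))
}
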