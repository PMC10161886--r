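# Per-sample automation state machine. The executor iterates over validated
# spreadsheet rows, builds the per-method execution stack, runs the steps
# and journals every status transition to an append-only JSON-lines file.
# The journal is the single source of truth: replaying it reconstructs the
# execution records exactly, and a run interrupted at any step boundary can
# be resumed from the point of failure. Any step failure stops the whole
# run; a grid-scan skip marks the sample's daq step skipped and continues
# with the next sample.

stepNames <- c("safety_check", "mount", "optical_center", "diff_center", "daq")
terminalStatuses <- c("success", "skipped", "failed")

#' Build the execution stack for a collection method
#'
#' `standard` and `multi_orientation` use all five steps; `serial` omits
#' diffraction centering; `robot_test` (sample-changer exercise) stops after
#' mounting; `alc_test` (optical-centering exercise) stops after centering.
#'
#' @param method collection method name
#' @return ordered character vector of step names
#' @examples
#' buildStack("standard")
#' @export
buildStack <- function(method) {
  switch(method,
    standard = stepNames,
    multi_orientation = stepNames,
    serial = setdiff(stepNames, "diff_center"),
    robot_test = stepNames[1:2],
    alc_test = stepNames[1:3],
    blStop("unknownMethod", paste("unknown collection method:", method)))
}

# ---------------------------------------------------------------------------
# Journal
# ---------------------------------------------------------------------------

journalAppend <- function(path, obj) {
  line <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  cat(line, "\n", sep = "", file = path, append = TRUE)
}

journalStep <- function(path, row, sample, method, step, status,
                        message = NULL, payload = NULL) {
  journalAppend(path, list(type = "step", row = row, sample = sample,
                           method = method, step = step, status = status,
                           time = as.numeric(Sys.time()),
                           message = message, payload = payload))
}

notifyEvent <- function(path, config, level, message) {
  ev <- list(type = "notification", level = level, message = message,
             time = as.numeric(Sys.time()))
  journalAppend(path, ev)
  if (is.function(config$notifySink)) config$notifySink(ev)
  invisible(NULL)
}

#' Read a JSON-lines journal
#'
#' @param path journal path
#' @return list of parsed events; raises `corruptJournal` on an unparsable
#'   line or a missing file
#' @export
readJournal <- function(path) {
  if (!file.exists(path)) blStop("corruptJournal", "journal file not found")
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lapply(lines, function(ln) {
    tryCatch(jsonlite::fromJSON(ln, simplifyVector = TRUE),
             error = function(e)
               blStop("corruptJournal",
                      paste("unparsable journal line:", substr(ln, 1, 60))))
  })
}

#' Reconstruct execution records from a journal
#'
#' Replays the append-only journal: for each (row, step) the last recorded
#' status wins, so a resumed run's re-executed steps override the earlier
#' failed attempt and replaying always yields one consistent record set.
#'
#' @param path journal path
#' @return list with `records` (per-row execution records), `meta` (seed,
#'   row count, done flag)
#' @export
replayJournal <- function(path) {
  events <- readJournal(path)
  records <- list()
  meta <- list(seed = NA, nrows = NA, done = FALSE, stopped = NULL)
  for (ev in events) {
    if (identical(ev$type, "run_started")) {
      meta$seed <- ev$seed; meta$nrows <- ev$nrows
    } else if (identical(ev$type, "run_done")) {
      meta$done <- TRUE
    } else if (identical(ev$type, "run_stopped")) {
      meta$stopped <- list(row = ev$row, step = ev$step)
    } else if (identical(ev$type, "step")) {
      key <- as.character(ev$row)
      if (is.null(records[[key]]))
        records[[key]] <- list(row = ev$row, sample = ev$sample,
                               method = ev$method, steps = list(),
                               payloads = list(), manifests = character(0))
      records[[key]]$steps[[ev$step]] <-
        list(status = ev$status, time = ev$time,
             message = if (is.null(ev$message)) NA_character_ else ev$message)
      if (!is.null(ev$payload)) {
        records[[key]]$payloads[[ev$step]] <- ev$payload
        if (ev$step == "daq" && !is.null(ev$payload$manifests))
          records[[key]]$manifests <- unlist(ev$payload$manifests)
      }
    }
  }
  records <- records[order(as.integer(names(records)))]
  list(records = records, meta = meta)
}

# Strip wall-clock fields and reduce artifact paths to their run-relative
# tails for record comparisons (resume/interrupt equivalence is defined up
# to timestamps and the output root).
stripTimes <- function(x) {
  if (is.list(x)) {
    x$time <- NULL
    x$timestamp <- NULL
    lapply(x, stripTimes)
  } else if (is.character(x)) {
    sub("^.*/(assets|datasets)/", "\\1/", x)
  } else x
}

#' Compare two record sets ignoring timestamps and output roots
#'
#' Execution records are equivalent when every status, message, payload and
#' manifest matches; wall-clock timestamps and the absolute output directory
#' (artifact paths are compared by their run-relative tails) are ignored.
#'
#' @param a,b record lists from [replayJournal()] / [runAutomation()]
#' @return TRUE/FALSE
#' @export
recordsEquivalent <- function(a, b) {
  isTRUE(all.equal(stripTimes(a), stripTimes(b), tolerance = 1e-9))
}

# ---------------------------------------------------------------------------
# Payload (de)serialization for resume
# ---------------------------------------------------------------------------

centeringPayload <- function(res, bl) {
  list(status = res@status, tipMotor = res@tipMotor,
       flatFaceOmega = res@flatFaceOmega, thicknessPx = res@thicknessPx,
       bbox = res@bbox, motor = bl$motor, omega = bl$omega)
}

payloadCentering <- function(p) {
  new("CenteringResult", tipMotor = as.numeric(unlist(p$tipMotor)),
      flatFaceOmega = as.numeric(p$flatFaceOmega),
      thicknessPx = as.numeric(p$thicknessPx),
      bbox = as.numeric(unlist(p$bbox)), status = p$status)
}

decisionPayload <- function(decision, counts2d) {
  list(outcome = decision@outcome, position = decision@position,
       omega = decision@omega, best2dIndex = decision@best2dIndex,
       bestLineIndex = decision@bestLineIndex, peak2d = decision@peak2d,
       peakLine = decision@peakLine, counts2d = counts2d)
}

payloadDecision <- function(p) {
  new("CenterDecision", outcome = p$outcome,
      position = as.numeric(unlist(p$position)),
      omega = as.numeric(p$omega),
      best2dIndex = as.numeric(p$best2dIndex),
      bestLineIndex = as.numeric(p$bestLineIndex),
      peak2d = as.numeric(p$peak2d), peakLine = as.numeric(p$peakLine))
}

# ---------------------------------------------------------------------------
# Step implementations
# ---------------------------------------------------------------------------

motorsWithinLimits <- function(bl) {
  lim <- bl$config$limits
  cur <- c(x = bl$motor[1], y = bl$motor[2], z = bl$motor[3],
           omega = bl$omega, chi = bl$chi, phi = bl$phi)
  all(vapply(names(cur), function(ax)
    cur[[ax]] >= lim[[ax]][1] && cur[[ax]] <= lim[[ax]][2], logical(1)))
}

stepIndex <- function(step) match(step, stepNames)

# Each step function returns list(ok, message, payload) and mutates the
# beamline / per-row state environment.
execStep <- function(step, i, row, bl, config, seed, scenes, calibration,
                     state, outDir) {
  sd <- deriveSeed(seed, i, stepIndex(step))
  switch(step,
    safety_check = {
      ok <- bl$mode %in% c("idle", "sample_exchange") && !bl$isMounted() &&
        motorsWithinLimits(bl)
      list(ok = ok,
           message = if (ok) "beamline ready" else "beamline not in a safe state",
           payload = NULL)
    },
    mount = {
      scene <- scenes(i, sd)
      # config$mountFailureRows: simulated intermittent robot faults pinned
      # to specific rows (used to exercise the stop/resume paths)
      prob <- if (i %in% config$mountFailureRows) 1 else
        config$mountFailureProb
      tryCatch({
        bl$mountSample(scene, sd, failureProb = prob)
        state$scene <- scene
        list(ok = TRUE, message = "sample mounted",
             payload = list(shift = bl$shift))
      }, beamloop_mountFailure = function(e)
        list(ok = FALSE, message = conditionMessage(e), payload = NULL))
    },
    optical_center = {
      if (isTRUE(row$no_centering)) {
        res <- centerToFlat(bl, config, noCentering = TRUE)
        state$centering <- res
        list(ok = TRUE, message = "centering disabled (noCentering)",
             payload = centeringPayload(res, bl))
      } else {
        res <- tryCatch({
          prelocate(bl, calibration)
          centerToFlat(bl, config)
        }, beamloop_loopNotFound = function(e) {
          new("CenteringResult", tipMotor = bl$motor,
              flatFaceOmega = NA_real_, thicknessPx = NA_real_,
              bbox = rep(NA_real_, 4), status = "not_found")
        }, beamloop_convergenceFailure = function(e) NULL)
        if (is.null(res) || res@status == "not_found") {
          list(ok = FALSE, message = "loop not found / centering failed",
               payload = NULL)
        } else {
          state$centering <- res
          # sample snapshot for the report
          assetDir <- file.path(outDir, "assets")
          dir.create(assetDir, showWarnings = FALSE, recursive = TRUE)
          img <- file.path(assetDir, sprintf("row%03d_sample.png", i))
          writeFramePNG(bl$render("microscope"), img)
          pl <- centeringPayload(res, bl)
          pl$image <- img
          list(ok = TRUE, message = "centered", payload = pl)
        }
      }
    },
    diff_center = {
      res <- state$centering
      if (is.null(res))
        return(list(ok = FALSE, message = "no optical centering result",
                    payload = NULL))
      policy <- thresholdPolicy(row$threshold_mode, config)
      bl$applyIceJitter(sd)
      if (res@status == "disabled") {
        # no grid box: only the always-collect mode proceeds, at the current
        # position
        decision <- if (policy@mode == "always_collect") {
          new("CenterDecision", outcome = "collect", position = bl$motor,
              omega = bl$omega, best2dIndex = NA_real_,
              bestLineIndex = NA_real_, peak2d = NA_real_,
              peakLine = NA_real_)
        } else {
          new("CenterDecision", outcome = "skip",
              position = rep(NA_real_, 3), omega = NA_real_,
              best2dIndex = NA_real_, bestLineIndex = NA_real_,
              peak2d = NA_real_, peakLine = NA_real_)
        }
        state$decision <- decision
        return(list(ok = TRUE, message = "no grid (centering disabled)",
                    payload = decisionPayload(decision, numeric(0))))
      }
      cam <- config$cameras$microscope
      grid <- gridFromResult(res, config$beamSizeMm, cam)
      counts <- bl$simulateGridScan(grid@positions, deriveSeed(seed, i, 101))
      res2d <- withCounts(grid, counts)
      decision <- decideCollection(res2d, policy, bl, res,
                                   deriveSeed(seed, i, 102))
      state$decision <- decision
      assetDir <- file.path(outDir, "assets")
      dir.create(assetDir, showWarnings = FALSE, recursive = TRUE)
      frame <- bl$render("microscope")
      p2d <- file.path(assetDir, sprintf("row%03d_grid2d.png", i))
      writeRGBPNG(heatMap(res2d, frame, cam), p2d)
      pl <- decisionPayload(decision, counts)
      pl$grid2dImage <- p2d
      line <- attr(decision, "line")
      if (!is.null(line)) {
        pline <- file.path(assetDir, sprintf("row%03d_line.png", i))
        writeRGBPNG(heatMap(line, frame, cam), pline)
        pl$lineImage <- pline
        pl$countsLine <- line@counts
      }
      list(ok = TRUE,
           message = if (decision@outcome == "skip")
             "no box above threshold" else "best spot selected",
           payload = pl)
    },
    daq = {
      decision <- state$decision
      if (is.null(decision)) {
        # serial method: collect at the centered position, no grid scans
        decision <- new("CenterDecision", outcome = "collect",
                        position = bl$motor, omega = bl$omega,
                        best2dIndex = NA_real_, bestLineIndex = NA_real_,
                        peak2d = NA_real_, peakLine = NA_real_)
      }
      bl$moveTo(x = decision@position[1], y = decision@position[2],
                z = decision@position[3], omega = decision@omega)
      bl$mode <- "acquiring"
      pairs <- row$orientation_pairs[[1]]
      if (is.null(pairs)) pairs <- matrix(c(0, 0), ncol = 2)
      manifests <- character(0)
      for (j in seq_len(nrow(pairs))) {
        u <- withSeed(deriveSeed(seed, i, 200 + j), stats::runif(1))
        if (u < config$acquisitionFailureProb) {
          bl$mode <- "alignment"
          return(list(ok = FALSE,
                      message = "simulated acquisition failure",
                      payload = NULL))
        }
        bl$moveTo(chi = pairs[j, 1], phi = pairs[j, 2])
        folder <- file.path(outDir, "datasets",
                            sprintf("row%03d_set%02d", i, j))
        dir.create(folder, showWarnings = FALSE, recursive = TRUE)
        manifest <- list(
          folder = folder, sample = row$sample_name, puck = row$puck,
          position = row$position, method = row$method,
          exposure_time = row$exposure_time, oscillation = row$oscillation,
          total_range = row$total_range, transmission = row$transmission,
          resolution = row$resolution, omega_start = decision@omega,
          chi = pairs[j, 1], phi = pairs[j, 2],
          n_frames = ceiling(row$total_range / row$oscillation),
          provenance = list(best2dIndex = decision@best2dIndex,
                            bestLineIndex = decision@bestLineIndex,
                            peak2d = decision@peak2d,
                            peakLine = decision@peakLine))
        mpath <- file.path(folder, "manifest.json")
        jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA)
        # verify the (simulated) data writing completed
        if (!file.exists(mpath) ||
            inherits(try(jsonlite::read_json(mpath), silent = TRUE),
                     "try-error")) {
          bl$mode <- "alignment"
          return(list(ok = FALSE, message = "manifest verification failed",
                      payload = NULL))
        }
        manifests <- c(manifests, mpath)
      }
      bl$mode <- "alignment"
      list(ok = TRUE,
           message = sprintf("%d dataset(s) collected", length(manifests)),
           payload = list(manifests = as.list(manifests)))
    },
    stop("unknown step: ", step))
}

# Restore the physical side effects of an already-successful step when
# resuming a partially executed row (the journal payload carries everything
# needed; seeds are re-derived so re-established state is bit-identical).
restoreStep <- function(step, i, row, bl, config, seed, scenes, payload,
                        state) {
  sd <- deriveSeed(seed, i, stepIndex(step))
  switch(step,
    safety_check = invisible(NULL),
    mount = {
      scene <- scenes(i, sd)
      bl$mountSample(scene, sd)
      state$scene <- scene
    },
    optical_center = {
      state$centering <- payloadCentering(payload)
      bl$moveTo(x = payload$motor[[1]], y = payload$motor[[2]],
                z = payload$motor[[3]], omega = payload$omega)
    },
    diff_center = {
      bl$applyIceJitter(sd)
      state$decision <- payloadDecision(payload)
    },
    daq = invisible(NULL))
  invisible(NULL)
}

# ---------------------------------------------------------------------------
# Run / resume
# ---------------------------------------------------------------------------

defaultSceneProvider <- function(i, seed) {
  randomLoopScene(seed, crystal = TRUE, backgroundSpots = 2)
}

asValidatedRows <- function(sheet, config) {
  if (is.data.frame(sheet)) sheet <- validateSampleSheet(sheet, config)
  if (!isTRUE(sheet$valid))
    blStop("validationError",
           paste(validationReport(sheet), collapse = "\n"),
           errors = sheet$errors)
  sheet$rows
}

runRows <- function(rows, fromRow, bl, config, journalPath, outDir, seed,
                    scenes, calibration, restored = NULL, restartStep = NULL) {
  for (i in seq(fromRow, nrow(rows))) {
    row <- rows[i, ]
    stack <- buildStack(row$method)
    state <- new.env(parent = emptyenv())
    startIdx <- 1L
    if (i == fromRow && !is.null(restartStep)) {
      startIdx <- match(restartStep, stack)
      for (s in stack[seq_len(startIdx - 1)])
        restoreStep(s, i, row, bl, config, seed, scenes,
                    restored$payloads[[s]], state)
    }
    for (k in seq(startIdx, length(stack))) {
      step <- stack[k]
      if (step == "daq" && !is.null(state$decision) &&
          state$decision@outcome == "skip") {
        journalStep(journalPath, i, row$sample_name, row$method, step,
                    "skipped", message = "skipped (no spots above threshold)")
        next
      }
      journalStep(journalPath, i, row$sample_name, row$method, step,
                  "in_progress")
      out <- tryCatch(
        execStep(step, i, row, bl, config, seed, scenes, calibration,
                 state, outDir),
        beamloop_error = function(e)
          list(ok = FALSE, message = conditionMessage(e), payload = NULL))
      if (out$ok) {
        journalStep(journalPath, i, row$sample_name, row$method, step,
                    "success", message = out$message, payload = out$payload)
      } else {
        journalStep(journalPath, i, row$sample_name, row$method, step,
                    "failed", message = out$message)
        notifyEvent(journalPath, config, "error",
                    sprintf("automation stopped at row %d, step %s: %s",
                            i, step, out$message))
        journalAppend(journalPath,
                      list(type = "run_stopped", row = i, step = step,
                           reason = out$message,
                           time = as.numeric(Sys.time())))
        blStop("automationStopped",
               sprintf("automation stopped at row %d, step %s: %s",
                       i, step, out$message),
               row = i, step = step,
               records = replayJournal(journalPath)$records)
      }
    }
    if (bl$isMounted()) bl$dismount()
  }
  journalAppend(journalPath, list(type = "run_done",
                                  time = as.numeric(Sys.time())))
  invisible(NULL)
}

#' Run automated data collection over a sample spreadsheet
#'
#' Iterates over the validated rows in order. For each sample the per-method
#' execution stack is built and executed step by step, with every status
#' transition journaled (JSON lines). A grid-scan skip marks the sample's
#' daq step skipped and continues with the next sample; any step failure
#' stops the whole run immediately with an `automationStopped` error
#' carrying the failing row and step (a structured notification event is
#' journaled in place of the production email/SMS alerts).
#'
#' @param sheet validated spreadsheet (output of [validateSampleSheet()]) or
#'   a raw data.frame (validated internally; errors block the run)
#' @param bl a `VirtualBeamline`
#' @param journalPath JSON-lines journal path (created/appended)
#' @param outDir output directory for assets and dataset manifests
#' @param seed integer run seed; all per-step randomness is derived from it
#' @param scenes per-row sample provider: a function `(i, seed) -> LoopScene`
#'   or a list of scenes
#' @param config beamline config (defaults to the beamline's)
#' @param calibration optional [CalibrationMap-class] (computed once at run
#'   start otherwise)
#' @return list of execution records (from replaying the journal)
#' @export
runAutomation <- function(sheet, bl, journalPath, outDir, seed = 1,
                          scenes = defaultSceneProvider,
                          config = bl$config, calibration = NULL) {
  rows <- asValidatedRows(sheet, config)
  if (is.list(scenes) && !is.function(scenes)) {
    sceneList <- scenes
    scenes <- function(i, seed) sceneList[[i]]
  }
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  dir.create(dirname(journalPath), showWarnings = FALSE, recursive = TRUE)
  journalAppend(journalPath, list(type = "run_started", seed = seed,
                                  nrows = nrow(rows),
                                  time = as.numeric(Sys.time())))
  if (is.null(calibration)) calibration <- calibrateTopCam(bl)
  if (nrow(rows) > 0)
    runRows(rows, 1L, bl, config, journalPath, outDir, seed, scenes,
            calibration)
  else
    journalAppend(journalPath, list(type = "run_done",
                                    time = as.numeric(Sys.time())))
  replayJournal(journalPath)$records
}

#' Resume an interrupted run from its journal
#'
#' Rows whose steps all reached a terminal success/skipped status are not
#' re-executed (their records are reconstructed from the journal). The first
#' incomplete or failed row restarts from its first non-success step: the
#' physical state of its already-successful steps is silently re-established
#' (re-mount with the identical derived seed, motor restore from the
#' centering payload), so no step is ever half-replayed, and re-executed
#' steps append to the same journal, which replays to one consistent record
#' set.
#'
#' @param journalPath journal of the interrupted run
#' @param sheet,bl,outDir,scenes,config,calibration as in [runAutomation()]
#' @return merged execution records
#' @export
resumeAutomation <- function(journalPath, sheet, bl, outDir,
                             scenes = defaultSceneProvider,
                             config = bl$config, calibration = NULL) {
  rows <- asValidatedRows(sheet, config)
  if (is.list(scenes) && !is.function(scenes)) {
    sceneList <- scenes
    scenes <- function(i, seed) sceneList[[i]]
  }
  rep0 <- replayJournal(journalPath)
  seed <- rep0$meta$seed
  if (is.na(seed)) blStop("corruptJournal", "journal has no run_started event")

  rowComplete <- function(i) {
    rec <- rep0$records[[as.character(i)]]
    if (is.null(rec)) return(FALSE)
    stack <- buildStack(rows$method[i])
    all(vapply(stack, function(s) {
      st <- rec$steps[[s]]
      !is.null(st) && st$status %in% c("success", "skipped")
    }, logical(1)))
  }
  complete <- vapply(seq_len(nrow(rows)), rowComplete, logical(1))
  if (all(complete)) {
    if (!rep0$meta$done)
      journalAppend(journalPath, list(type = "run_done",
                                      time = as.numeric(Sys.time())))
    return(replayJournal(journalPath)$records)
  }
  r0 <- which(!complete)[1]
  if (bl$isMounted()) bl$dismount()
  if (is.null(calibration)) calibration <- calibrateTopCam(bl)

  rec <- rep0$records[[as.character(r0)]]
  stack <- buildStack(rows$method[r0])
  restartStep <- stack[1]
  restored <- list(payloads = list())
  if (!is.null(rec)) {
    for (s in stack) {
      st <- rec$steps[[s]]
      if (!is.null(st) && identical(st$status, "success")) {
        restored$payloads[[s]] <- rec$payloads[[s]]
      } else break
    }
    done <- names(restored$payloads)
    restartStep <- stack[length(done) + 1]
  }
  runRows(rows, r0, bl, config, journalPath, outDir, seed, scenes,
          calibration, restored = restored, restartStep = restartStep)
  replayJournal(journalPath)$records
}
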