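# Fast scenes for the state-machine tests: moderate offsets, embedded
# crystal, deterministic per (row, seed).
testScenes <- function(i, seed) {
  randomLoopScene(seed, crystal = TRUE, backgroundSpots = 2)
}

runDirs <- function() {
  d <- withr::local_tempdir(.local_envir = parent.frame())
  list(journal = file.path(d, "journal.jsonl"), out = file.path(d, "out"),
       d = d)
}

test_that("execution stacks match the per-method step lists exactly", {
  expect_identical(buildStack("standard"),
                   c("safety_check", "mount", "optical_center",
                     "diff_center", "daq"))
  expect_identical(buildStack("multi_orientation"), buildStack("standard"))
  expect_identical(buildStack("serial"),
                   c("safety_check", "mount", "optical_center", "daq"))
  expect_identical(buildStack("robot_test"), c("safety_check", "mount"))
  expect_identical(buildStack("alc_test"),
                   c("safety_check", "mount", "optical_center"))
  expect_error(buildStack("bogus"), class = "beamloop_unknownMethod")
})

test_that("a full run completes all samples and writes one manifest per orientation", {
  cfg <- fastConfig()
  dirs <- runDirs()
  sheet <- makeRawSheet(3, method = c("standard", "standard",
                                      "multi_orientation"),
                        pairs = c("", "", "(0,0);(20,0)"))
  bl <- virtualBeamline(cfg)
  recs <- runAutomation(validateSampleSheet(sheet, cfg), bl, dirs$journal,
                        dirs$out, seed = 42, scenes = testScenes)
  expect_length(recs, 3)
  for (rec in recs) {
    expect_true(all(vapply(rec$steps, function(s) s$status, character(1)) ==
                      "success"))
  }
  expect_length(recs[[1]]$manifests, 1)
  expect_length(recs[[3]]$manifests, 2)
  m <- jsonlite::read_json(recs[[3]]$manifests[[2]], simplifyVector = TRUE)
  expect_equal(m$chi, 20)
  expect_equal(m$phi, 0)
  expect_true(m$n_frames > 0)
  # journal replay reconstructs the records exactly
  expect_identical(replayJournal(dirs$journal)$records, recs)
})

test_that("a crystal-free sample is skipped at daq and the run continues", {
  cfg <- fastConfig()
  dirs <- runDirs()
  scenes <- function(i, seed) {
    randomLoopScene(seed, crystal = i != 2, backgroundSpots = 0)
  }
  bl <- virtualBeamline(cfg)
  recs <- runAutomation(validateSampleSheet(makeRawSheet(3), cfg), bl,
                        dirs$journal, dirs$out, seed = 7, scenes = scenes)
  expect_equal(recs[[2]]$steps$daq$status, "skipped")
  expect_length(recs[[2]]$manifests, 0)
  expect_equal(recs[[1]]$steps$daq$status, "success")
  expect_equal(recs[[3]]$steps$daq$status, "success")
})

test_that("a mount failure stops the whole run; later rows stay untouched", {
  cfg <- fastConfig(mountFailureRows = 2)
  dirs <- runDirs()
  bl <- virtualBeamline(cfg)
  err <- tryCatch(
    runAutomation(validateSampleSheet(makeRawSheet(3), cfg), bl,
                  dirs$journal, dirs$out, seed = 11, scenes = testScenes),
    beamloop_automationStopped = function(e) e)
  expect_s3_class(err, "beamloop_automationStopped")
  expect_equal(err$row, 2)
  expect_equal(err$step, "mount")
  recs <- err$records
  expect_equal(recs[[2]]$steps$mount$status, "failed")
  expect_false("3" %in% names(recs))
  # every step journaled in_progress before its terminal status; nothing
  # after the failure
  events <- readJournal(dirs$journal)
  stepEv <- Filter(function(e) identical(e$type, "step"), events)
  seen <- list()
  for (ev in stepEv) {
    key <- paste(ev$row, ev$step)
    if (is.null(seen[[key]])) {
      expect_equal(ev$status, "in_progress")
    }
    seen[[key]] <- ev$status
  }
  last <- events[[length(events)]]
  expect_equal(last$type, "run_stopped")
  # a notification event was emitted
  expect_true(any(vapply(events, function(e)
    identical(e$type, "notification"), logical(1))))
})

test_that("resume picks up after a cleared mount failure and matches an uninterrupted run", {
  sheet <- makeRawSheet(3)
  # reference: uninterrupted run with the same seed
  refDirs <- runDirs()
  blRef <- virtualBeamline(fastConfig())
  ref <- runAutomation(validateSampleSheet(sheet, fastConfig()), blRef,
                       refDirs$journal, refDirs$out, seed = 11,
                       scenes = testScenes)

  dirs <- runDirs()
  cfgFail <- fastConfig(mountFailureRows = 2)
  bl1 <- virtualBeamline(cfgFail)
  tryCatch(runAutomation(validateSampleSheet(sheet, cfgFail), bl1,
                         dirs$journal, dirs$out, seed = 11,
                         scenes = testScenes),
           beamloop_automationStopped = function(e) NULL)

  # failure cause cleared: fresh beamline, no forced faults
  bl2 <- virtualBeamline(fastConfig())
  recs <- resumeAutomation(dirs$journal, validateSampleSheet(sheet, fastConfig()),
                           bl2, dirs$out, scenes = testScenes)
  expect_length(recs, 3)
  expect_true(recordsEquivalent(recs, ref))

  # resume of a completed run is a no-op
  recs2 <- resumeAutomation(dirs$journal,
                            validateSampleSheet(sheet, fastConfig()),
                            virtualBeamline(fastConfig()), dirs$out,
                            scenes = testScenes)
  expect_true(recordsEquivalent(recs2, recs))
})

test_that("a truncated journal line raises corruptJournal", {
  dirs <- runDirs()
  bl <- virtualBeamline(fastConfig())
  runAutomation(validateSampleSheet(makeRawSheet(1), fastConfig()), bl,
                dirs$journal, dirs$out, seed = 3, scenes = testScenes)
  txt <- readLines(dirs$journal)
  broken <- file.path(dirs$d, "broken.jsonl")
  writeLines(c(txt[1], substr(txt[2], 1, 25)), broken)
  expect_error(replayJournal(broken), class = "beamloop_corruptJournal")
  expect_error(readJournal(file.path(dirs$d, "missing.jsonl")),
               class = "beamloop_corruptJournal")
})

test_that("serial method collects without diffraction centering; chi limit enforced upstream", {
  cfg <- fastConfig()
  dirs <- runDirs()
  bl <- virtualBeamline(cfg)
  recs <- runAutomation(validateSampleSheet(makeRawSheet(1, method = "serial"),
                                            cfg),
                        bl, dirs$journal, dirs$out, seed = 9,
                        scenes = testScenes)
  expect_null(recs[[1]]$steps$diff_center)
  expect_equal(recs[[1]]$steps$daq$status, "success")
  expect_length(recs[[1]]$manifests, 1)

  # chi = 50 is rejected by spreadsheet validation before any execution
  bad <- makeRawSheet(1, method = "multi_orientation", pairs = "(50,0)")
  expect_error(runAutomation(bad, virtualBeamline(cfg), dirs$journal,
                             dirs$out, seed = 1),
               class = "beamloop_validationError")
})

test_that("robot_test and alc_test stacks stop after their last step", {
  cfg <- fastConfig()
  dirs <- runDirs()
  bl <- virtualBeamline(cfg)
  recs <- runAutomation(
    validateSampleSheet(makeRawSheet(2, method = c("robot_test", "alc_test")),
                        cfg),
    bl, dirs$journal, dirs$out, seed = 5, scenes = testScenes)
  expect_setequal(names(recs[[1]]$steps), c("safety_check", "mount"))
  expect_setequal(names(recs[[2]]$steps),
                  c("safety_check", "mount", "optical_center"))
  expect_length(recs[[1]]$manifests, 0)
})

test_that("noCentering rows: daq runs only under always_collect", {
  cfg <- fastConfig()
  sheet <- makeRawSheet(2)
  sheet$no_centering <- c("true", "true")
  sheet$threshold_mode <- c("default", "always_collect")
  dirs <- runDirs()
  bl <- virtualBeamline(cfg)
  recs <- runAutomation(validateSampleSheet(sheet, cfg), bl, dirs$journal,
                        dirs$out, seed = 21, scenes = testScenes)
  expect_equal(recs[[1]]$steps$daq$status, "skipped")
  expect_equal(recs[[2]]$steps$daq$status, "success")
  expect_equal(recs[[1]]$payloads$optical_center$status, "disabled")
})
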