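#' Error conditions
#'
#' All package errors are classed conditions so callers can branch on failure
#' modes (`tryCatch(..., beamloop_loopNotFound = ...)`). Classes in use:
#' `loopNotFound`, `motorLimit`, `noSampleMounted`, `mountFailure`,
#' `calibrationFailure`, `convergenceFailure`, `degenerateFit`, `notCentered`,
#' `emptyGrid`, `unknownMethod`, `automationStopped`, `corruptJournal`,
#' `validationError`, `acquisitionFailure`, `missingColumn`, each prefixed
#' with `beamloop_`.
#'
#' @param class short condition class (without package prefix)
#' @param message human-readable message
#' @param ... extra fields stored on the condition
#' @return never returns; signals the condition
#' @keywords internal
blStop <- function(class, message, ...) {
  stop(errorCondition(message,
                      ...,
                      class = c(paste0("beamloop_", class), "beamloop_error")))
}

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded simulator internals never
#' disturb the caller's RNG stream.
#'
#' @param seed integer seed
#' @param expr expression to evaluate
#' @keywords internal
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Deterministic per-(row, step) seed derivation, kept below 2^31.
deriveSeed <- function(base, row, step = 0L) {
  as.integer((as.numeric(base) * 10007 + row * 131 + step * 7 + 1) %% 2147483629)
}

degToRad <- function(deg) deg * pi / 180

# Normalize an angle in degrees to [0, 360)
normAngle360 <- function(deg) ((deg %% 360) + 360) %% 360

# Normalize an angle in degrees to [0, 180)
normAngle180 <- function(deg) ((deg %% 180) + 180) %% 180
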