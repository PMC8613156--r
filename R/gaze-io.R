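#' Read a raw eye-tracker log
#'
#' The log is tabular text with header columns
#' `participant,group,sample_index,x,y`: one row per tracker sample, with
#' monitor-pixel coordinates. Sample indices must be strictly increasing
#' within each participant.
#'
#' @param path file path.
#' @param sep field delimiter.
#' @return data.frame with columns `participant`, `group`, `sampleIndex`,
#'   `xMon`, `yMon`.
#' @export
readGazeLog <- function(path, sep = ",") {
  d <- utils::read.table(path, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE)
  need <- c("participant", "group", "sample_index", "x", "y")
  if (!all(need %in% names(d)))
    stop("gaze log must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  out <- data.frame(participant = as.character(d$participant),
                    group = as.character(d$group),
                    sampleIndex = as.integer(d$sample_index),
                    xMon = as.numeric(d$x), yMon = as.numeric(d$y),
                    stringsAsFactors = FALSE)
  bad <- vapply(split(out$sampleIndex, out$participant),
                function(s) any(diff(s) <= 0), logical(1))
  if (any(bad))
    stop("sample_index not strictly increasing for participant(s): ",
         paste(names(bad)[bad], collapse = ", "), call. = FALSE)
  out
}

#' Read display geometry from a config file
#'
#' Accepts JSON (`{"mon_w": ..., ...}`) or `key=value` lines with keys
#' `mon_w, mon_h, stim_w, stim_h, tracker_hz, refresh_hz`.
#'
#' @param path file path.
#' @return A [StimulusGeometry()].
#' @export
readGeometryConfig <- function(path) {
  txt <- readLines(path, warn = FALSE)
  vals <- if (grepl("^\\s*\\{", paste(txt, collapse = ""))) {
    jsonlite::fromJSON(paste(txt, collapse = "\n"))
  } else {
    kv <- txt[grepl("=", txt, fixed = TRUE)]
    parts <- strsplit(kv, "=", fixed = TRUE)
    stats::setNames(lapply(parts, function(p) as.numeric(trimws(p[2]))),
                    trimws(vapply(parts, `[`, "", 1)))
  }
  need <- c("mon_w", "mon_h", "stim_w", "stim_h", "tracker_hz", "refresh_hz")
  if (!all(need %in% names(vals)))
    stop("geometry config must define ", paste(need, collapse = ", "),
         call. = FALSE)
  StimulusGeometry(vals$mon_w, vals$mon_h, vals$stim_w, vals$stim_h,
                   vals$tracker_hz, vals$refresh_hz)
}

#' Truncate all participants to the minimum record count
#'
#' Eye trackers lose slightly different numbers of samples per participant;
#' since the log does not say where losses occurred, every participant's
#' record is shortened by discarding trailing samples down to the minimum
#' count available across participants.
#'
#' @param logs raw gaze log data.frame (see [readGazeLog()]).
#' @return Truncated log.
#' @export
truncateToMin <- function(logs) {
  if (!nrow(logs)) stop("empty gaze log collection", call. = FALSE)
  counts <- table(logs$participant)
  nmin <- min(counts)
  keep <- unlist(lapply(split(seq_len(nrow(logs)), logs$participant),
                        function(idx) {
                          idx[order(logs$sampleIndex[idx])][seq_len(nmin)]
                        }), use.names = FALSE)
  out <- logs[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Remove untrackable and off-stimulus samples
#'
#' Drops exact `(0, 0)` samples (the tracker's code for lost gaze) and
#' samples landing outside the displayed stimulus area: `xMon` outside the
#' half-open band `[sideBar, monW - sideBar)` (the black side bars) or
#' `yMon` outside `[0, monH)`.
#'
#' @param logs raw gaze log data.frame.
#' @param geom a [StimulusGeometry()].
#' @return Filtered log.
#' @export
dropInvalid <- function(logs, geom) {
  bar <- sideBarWidth(geom)
  lost <- logs$xMon == 0 & logs$yMon == 0
  off <- logs$xMon < bar | logs$xMon >= geom@monW - bar |
         logs$yMon < 0 | logs$yMon >= geom@monH
  out <- logs[!(lost | off), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Map monitor coordinates to stimulus coordinates
#'
#' Inverts the display scaling: the stimulus was enlarged to full monitor
#' height (scale `monH / stimH`) and centered horizontally between black
#' side bars, so `xStim = (xMon - sideBar) / scale`,
#' `yStim = yMon / scale`.
#'
#' @param xMon,yMon monitor coordinates (vectors).
#' @param geom a [StimulusGeometry()].
#' @return List with components `x` and `y` in stimulus pixels.
#' @export
monitorToStimulus <- function(xMon, yMon, geom) {
  s <- scaleFactor(geom)
  list(x = (xMon - sideBarWidth(geom)) / s, y = yMon / s)
}

#' Inverse of [monitorToStimulus()]
#' @param xStim,yStim stimulus coordinates.
#' @param geom a [StimulusGeometry()].
#' @return List with components `x` and `y` in monitor pixels.
#' @export
stimulusToMonitor <- function(xStim, yStim, geom) {
  s <- scaleFactor(geom)
  list(x = xStim * s + sideBarWidth(geom), y = yStim * s)
}

## 1-based sample indices whose tracker interval [ (s-1)/tracker, s/tracker )
## lies entirely inside frame f's interval [ (f-1)/refresh, f/refresh ).
## Returns, for each sample index, the frame it fully belongs to (NA if it
## straddles a frame boundary). Comparison is done on the common time scale
## multiplied out to avoid float division.
frameForSample <- function(s, trackerHz, refreshHz, tol = 1e-9) {
  ## candidate frame: smallest f with f >= s * refresh / tracker
  f <- ceiling(s * refreshHz / trackerHz - tol)
  ok <- (s - 1) * refreshHz >= (f - 1) * trackerHz - tol
  f[!ok] <- NA_integer_
  as.integer(f)
}

#' Align tracker samples to video frames
#'
#' The tracker samples faster than the video refreshes (for example 60 Hz
#' against 25 Hz, 2.4 samples per frame), so one coordinate per participant
#' per frame is chosen: the first remaining sample whose tracker interval
#' lies entirely within the frame's display interval. At 60/25 Hz this
#' selects 1-based samples 1, 4, 6, 9, 11, 13, ... Samples straddling a
#' frame boundary never qualify. If no remaining sample qualifies for a
#' (participant, frame) pair, that pair is absent from the result.
#'
#' @param logs raw gaze log (already truncated and cleaned).
#' @param geom a [StimulusGeometry()] carrying `trackerHz` and `refreshHz`.
#' @param nFrames number of stimulus frames.
#' @return data.frame with columns `participant`, `group`, `frameIndex`,
#'   `sampleIndex`, `xMon`, `yMon`; at most one row per participant and
#'   frame.
#' @export
alignToFrames <- function(logs, geom, nFrames) {
  if (geom@trackerHz < geom@refreshHz)
    stop("tracker rate below refresh rate: cannot align", call. = FALSE)
  f <- frameForSample(logs$sampleIndex, geom@trackerHz, geom@refreshHz)
  keep <- !is.na(f) & f >= 1L & f <= nFrames
  d <- logs[keep, , drop = FALSE]
  d$frameIndex <- f[keep]
  ## first qualifying sample per participant per frame
  o <- order(d$participant, d$frameIndex, d$sampleIndex)
  d <- d[o, , drop = FALSE]
  first <- !duplicated(d[, c("participant", "frameIndex")])
  out <- d[first, c("participant", "group", "frameIndex", "sampleIndex",
                    "xMon", "yMon")]
  rownames(out) <- NULL
  out
}

#' Full gaze preprocessing pipeline
#'
#' Applies, in order: truncation of every participant to the minimum record
#' count, removal of `(0,0)` and off-stimulus samples, alignment of tracker
#' samples to frames, and the monitor-to-stimulus coordinate mapping. The
#' result is a gaze table with at most one stimulus-coordinate fixation per
#' participant per frame.
#'
#' @param logs raw gaze log data.frame (see [readGazeLog()]).
#' @param geom a [StimulusGeometry()].
#' @param nFrames number of stimulus frames.
#' @return data.frame (gaze table) with columns `participant`, `group`,
#'   `frameIndex`, `xStim`, `yStim`.
#' @export
preprocessGaze <- function(logs, geom, nFrames) {
  logs <- truncateToMin(logs)
  logs <- dropInvalid(logs, geom)
  al <- alignToFrames(logs, geom, nFrames)
  st <- monitorToStimulus(al$xMon, al$yMon, geom)
  out <- data.frame(participant = al$participant, group = al$group,
                    frameIndex = al$frameIndex,
                    xStim = st$x, yStim = st$y, stringsAsFactors = FALSE)
  ## numerically clamp the half-open box (drop_invalid guarantees this up
  ## to float error at the boundary)
  out$xStim <- pmin(pmax(out$xStim, 0), geom@stimW - 1e-9)
  out$yStim <- pmin(pmax(out$yStim, 0), geom@stimH - 1e-9)
  assertGazeTable(out)
  out
}
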