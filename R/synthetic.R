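#' Synthetic experiment scenario
#'
#' Describes a fully synthetic eye-tracking experiment with known ground
#' truth: a stimulus with one moving object (the dynamic AoI) travelling
#' linearly toward a static target region (the static AoI) over a textured
#' background, and two groups of participants whose fixations are drawn
#' per frame from a known mixture of the feature maps. The sampler also
#' emulates the tracker's artifacts: a faster sampling rate than the video
#' refresh, `(0,0)` dropout samples, off-stimulus samples in the black
#' side bars, and ragged per-participant record counts.
#'
#' Defaults emulate the reference experiment at 1/8 linear scale (stimulus
#' 90 x 72 px inside a 240 x 135 monitor, 60 Hz tracker against 25 Hz
#' video) so the full pipeline runs quickly at full fidelity of structure.
#'
#' @param grid a [GridSpec()]; default 90 x 72 px, 25 fps, 30 frames.
#' @param geometry a [StimulusGeometry()]; default scales the grid to full
#'   monitor height with black side bars, 60 Hz tracker.
#' @param nPerGroup named integer vector `c(treatment = , control = )`.
#' @param weightCurves named list of two `nFrames x K` matrices of
#'   per-frame mixture weights (each row sums to 1); default curves put
#'   most weight on the moving object, with the target share rising over
#'   time.
#' @param objectStart,objectVelocity object center at frame 1 and its
#'   per-frame displacement (stimulus px).
#' @param objectHalf half-width of the (square) moving object in px.
#' @param staticAoi vertex matrix of the static AoI polygon.
#' @param dropoutProb probability a tracker sample is lost and recorded as
#'   `(0, 0)`.
#' @param offStimulusProb probability a sample lands in a black side bar.
#' @param seed RNG seed for the gaze sampler.
#' @return A list of class `"ScenarioSpec"`.
#' @export
scenarioSpec <- function(grid = GridSpec(90, 72, fps = 25, nFrames = 30),
                         geometry = StimulusGeometry(240, 135, grid@w,
                                                     grid@h, 60, grid@fps),
                         nPerGroup = c(treatment = 25L, control = 25L),
                         weightCurves = NULL,
                         objectStart = c(12, 46),
                         objectVelocity = c(1.7, -0.8),
                         objectHalf = 5,
                         staticAoi = rbind(c(64, 8), c(84, 8),
                                           c(84, 28), c(64, 28)),
                         dropoutProb = 0.05, offStimulusProb = 0.02,
                         seed = 1L) {
  if (is.null(weightCurves))
    weightCurves <- list(treatment = defaultWeightCurves(grid@nFrames),
                         control = defaultWeightCurves(grid@nFrames))
  spec <- list(grid = grid, geometry = geometry,
               nPerGroup = nPerGroup, weightCurves = weightCurves,
               objectStart = objectStart, objectVelocity = objectVelocity,
               objectHalf = objectHalf, staticAoi = staticAoi,
               dropoutProb = dropoutProb,
               offStimulusProb = offStimulusProb, seed = as.integer(seed))
  class(spec) <- "ScenarioSpec"
  validateScenario(spec)
  spec
}

scenarioFeatures <- c("uniform", "center_bias", "static_saliency",
                      "dynamic_saliency", "aoi:object", "aoi:target")

## Control-group weight curves: object-driven attention dominating, target
## share rising linearly as the object approaches it.
defaultWeightCurves <- function(nFrames) {
  t01 <- if (nFrames > 1) (seq_len(nFrames) - 1) / (nFrames - 1) else 0
  w <- cbind(uniform = rep(0.05, nFrames),
             center_bias = rep(0.20, nFrames),
             static_saliency = rep(0.10, nFrames),
             dynamic_saliency = rep(0.10, nFrames),
             `aoi:object` = 0.40 - 0.10 * t01,
             `aoi:target` = 0.15 + 0.10 * t01)
  w
}

validateScenario <- function(spec) {
  g <- spec$grid
  for (gname in names(spec$weightCurves)) {
    w <- spec$weightCurves[[gname]]
    if (nrow(w) != g@nFrames)
      stop("weight curves must have one row per frame", call. = FALSE)
    if (any(w < 0) || any(abs(rowSums(w) - 1) > .NORM_TOL))
      stop(sprintf(
        "weight curves for '%s' must be nonnegative and sum to 1 per frame",
        gname), call. = FALSE)
  }
  if (any(spec$nPerGroup < 1L)) stop("need >= 1 participant per group",
                                     call. = FALSE)
  for (p in c("dropoutProb", "offStimulusProb"))
    if (spec[[p]] < 0 || spec[[p]] > 1)
      stop(p, " must be in [0, 1]", call. = FALSE)
  ctr <- objectCenter(spec, c(1, g@nFrames))
  half <- spec$objectHalf
  if (any(ctr[, 1] < half) || any(ctr[, 1] > g@w - half) ||
      any(ctr[, 2] < half) || any(ctr[, 2] > g@h - half))
    stop("object trajectory leaves the stimulus frame", call. = FALSE)
  invisible(spec)
}

#' Moving-object center at given frames
#'
#' Linear trajectory: `start + (frame - 1) * velocity`, exact.
#'
#' @param spec a [scenarioSpec()].
#' @param frames 1-based frame indices.
#' @return Matrix with columns x, y.
#' @export
objectCenter <- function(spec, frames) {
  cbind(spec$objectStart[1] + (frames - 1) * spec$objectVelocity[1],
        spec$objectStart[2] + (frames - 1) * spec$objectVelocity[2])
}

#' Render the synthetic stimulus
#'
#' Deterministic luminance frames: a smooth sinusoidal background texture,
#' a mid-gray static target region with a darker border (the static AoI),
#' and a bright square moving along the linear trajectory (the dynamic
#' AoI). Also returns the per-frame AoI polygons consistent with the
#' rendered object.
#'
#' @param spec a [scenarioSpec()].
#' @return List with `frames` (list of `h x w` matrices in `[0, 1]`) and
#'   `aois` (records with `label`, `frameIndex`, `vertices`; the static
#'   AoI has `frameIndex = NA`).
#' @export
renderStimulus <- function(spec) {
  g <- spec$grid
  cx <- pixelCentersX(g); cy <- pixelCentersY(g)
  tex <- 0.35 + 0.06 * outer(sin(2 * pi * cy / 9), cos(2 * pi * cx / 13))
  ## static target: filled region with a darker border for static contrast
  sx <- range(spec$staticAoi[, 1]); sy <- range(spec$staticAoi[, 2])
  inX <- cx >= sx[1] & cx <= sx[2]
  inY <- cy >= sy[1] & cy <= sy[2]
  borderX <- inX & (cx < sx[1] + 2 | cx > sx[2] - 2)
  borderY <- inY & (cy < sy[1] + 2 | cy > sy[2] - 2)
  base <- tex
  base[inY, inX] <- 0.62
  base[inY, borderX] <- 0.15
  base[borderY, inX] <- 0.15
  half <- spec$objectHalf
  frames <- vector("list", g@nFrames)
  aois <- list()
  for (f in seq_len(g@nFrames)) {
    ctr <- objectCenter(spec, f)
    fx <- cx >= ctr[1] - half & cx <= ctr[1] + half
    fy <- cy >= ctr[2] - half & cy <= ctr[2] + half
    img <- base
    img[fy, fx] <- 0.97
    frames[[f]] <- img
    aois[[length(aois) + 1L]] <- list(
      label = "object", frameIndex = f,
      vertices = rbind(c(ctr[1] - half, ctr[2] - half),
                       c(ctr[1] + half, ctr[2] - half),
                       c(ctr[1] + half, ctr[2] + half),
                       c(ctr[1] - half, ctr[2] + half)))
  }
  aois[[length(aois) + 1L]] <- list(label = "target",
                                    frameIndex = NA_integer_,
                                    vertices = spec$staticAoi)
  list(frames = frames, aois = aois)
}

#' Feature maps for a scenario
#'
#' Builds the full per-frame map set (uniform, center bias, static and
#' dynamic saliency computed from the rendered frames, and the two AoI
#' maps). Frame 1 has no dynamic map, so its entry is `NULL`: the frame is
#' skipped by the model unless refitted without dynamic features.
#'
#' @param spec a [scenarioSpec()].
#' @param stimulus optional pre-rendered result of [renderStimulus()].
#' @param frames frames to build (default all).
#' @return List indexed by frame: each entry a list of [FeatureMap()]s or
#'   `NULL`.
#' @export
buildScenarioMaps <- function(spec, stimulus = renderStimulus(spec),
                              frames = seq_len(spec$grid@nFrames)) {
  g <- spec$grid
  uni <- uniformMap(g)
  cb <- centerBiasMap(g)
  tgt <- aoiMap(spec$staticAoi, g, "target")
  out <- vector("list", g@nFrames)
  for (f in frames) {
    if (f == 1L) next  # dynamic map undefined: leave NULL
    objA <- stimulus$aois[[f]]
    out[[f]] <- list(
      uni, cb,
      staticSaliencyMap(stimulus$frames[[f]], g, f),
      dynamicSaliencyMap(stimulus$frames[[f]], stimulus$frames[[f - 1]],
                         g, f),
      aoiMap(objA$vertices, g, "object", f),
      FeatureMap(mapName(tgt), mapValues(tgt), f))
  }
  out
}

## Draw n fixation coordinates from a pixel-level mixture density: sample
## a pixel by its mass, then jitter uniformly within the pixel, so the
## continuous density is piecewise constant and matches the map exactly.
samplePixelMixture <- function(mixture, n) {
  h <- nrow(mixture); w <- ncol(mixture)
  idx <- sample.int(h * w, n, replace = TRUE, prob = as.vector(mixture))
  row <- (idx - 1L) %% h + 1L
  col <- (idx - 1L) %/% h + 1L
  cbind(x = col - 1 + stats::runif(n), y = row - 1 + stats::runif(n))
}

## Mixture density for one group and frame; drops features whose maps are
## unavailable on that frame (dynamic saliency on frame 1) and
## renormalizes the remaining weights.
frameMixture <- function(weights, maps) {
  nm <- vapply(maps, mapName, "")
  w <- weights[nm[nm %in% names(weights)]]
  w <- w / sum(w)
  acc <- 0
  for (k in seq_along(maps)) acc <- acc + w[[mapName(maps[[k]])]] *
    mapValues(maps[[k]])
  acc
}

#' Sample a synthetic raw gaze log
#'
#' Per participant and frame, one fixation is drawn from the group's known
#' mixture `sum_k w_k(t) M_k(t)` over the frame's feature maps (frame 1
#' omits the dynamic map and renormalizes). Fixations are mapped to
#' monitor coordinates, emitted at the tracker rate (every tracker sample
#' within a frame repeats that frame's fixation), and corrupted per the
#' scenario: dropout samples become `(0, 0)`, off-stimulus samples land in
#' a black side bar, and a random number of trailing samples is appended
#' per participant so record counts are ragged. Deterministic for the
#' scenario seed.
#'
#' @param spec a [scenarioSpec()].
#' @param mapsByFrame per-frame feature maps, see [buildScenarioMaps()].
#' @return Raw gaze log data.frame (`participant`, `group`, `sampleIndex`,
#'   `xMon`, `yMon`).
#' @export
sampleGaze <- function(spec, mapsByFrame = buildScenarioMaps(spec)) {
  g <- spec$grid; geom <- spec$geometry
  nF <- g@nFrames
  set.seed(spec$seed)
  ## mixture per group per frame (frame 1 uses the frame-2 map set minus
  ## the dynamic map so the generator is defined on every frame)
  groups <- names(spec$nPerGroup)
  mix <- lapply(groups, function(gr) {
    lapply(seq_len(nF), function(f) {
      maps <- mapsByFrame[[f]]
      if (is.null(maps) && f == 1L)
        maps <- Filter(function(m) mapName(m) != "dynamic_saliency",
                       mapsByFrame[[2L]])
      frameMixture(spec$weightCurves[[gr]][f, ], maps)
    })
  })
  names(mix) <- groups
  nominal <- floor(nF * geom@trackerHz / geom@refreshHz)
  sFrame <- pmin(pmax(floor((seq_len(nominal) - 1) * geom@refreshHz /
                              geom@trackerHz) + 1L, 1L), nF)
  bar <- sideBarWidth(geom)
  rows <- list()
  for (gr in groups) {
    nP <- spec$nPerGroup[[gr]]
    ## one draw per participant per frame, vectorized over participants
    fxm <- matrix(0, nP, nF); fym <- matrix(0, nP, nF)
    for (f in seq_len(nF)) {
      pt <- samplePixelMixture(mix[[gr]][[f]], nP)
      fxm[, f] <- pt[, "x"]; fym[, f] <- pt[, "y"]
    }
    for (p in seq_len(nP)) {
      pid <- sprintf("%s%02d", toupper(substr(gr, 1, 1)), p)
      fx <- fxm[p, ]; fy <- fym[p, ]
      extra <- sample(0:12, 1)
      sIdx <- seq_len(nominal + extra)
      fIdx <- c(sFrame, rep(nF, extra))[sIdx]
      mon <- stimulusToMonitor(fx[fIdx], fy[fIdx], geom)
      xm <- mon$x; ym <- mon$y
      u <- stats::runif(length(sIdx))
      off <- u >= spec$dropoutProb &
             u < spec$dropoutProb + spec$offStimulusProb
      nOff <- sum(off)
      if (nOff) {
        left <- stats::runif(nOff) < 0.5
        xm[off] <- ifelse(left, stats::runif(nOff, 0, bar * 0.95),
                          stats::runif(nOff, geom@monW - bar * 0.95,
                                       geom@monW))
        ym[off] <- stats::runif(nOff, 0, geom@monH)
      }
      drop <- u < spec$dropoutProb
      xm[drop] <- 0; ym[drop] <- 0
      rows[[length(rows) + 1L]] <- data.frame(
        participant = pid, group = gr, sampleIndex = sIdx,
        xMon = xm, yMon = ym, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Two-group scenario with an injected effect
#'
#' The control group uses the base weight curves; the treatment group
#' shifts `delta` of mixture weight onto the named feature, scaling the
#' remaining features down proportionally so each frame's weights still
#' sum to 1 (the treatment weight on `effect` exceeds the control weight
#' by exactly `delta` at every frame). `delta = 0` gives the null
#' scenario of identically distributed groups.
#'
#' @param effect feature name (one of the scenario's features).
#' @param delta weight shift; must keep all weights in `[0, 1]`.
#' @param ... passed to [scenarioSpec()].
#' @return A [scenarioSpec()].
#' @export
makeTwoGroupScenario <- function(effect = "aoi:target", delta = 0, ...) {
  spec <- scenarioSpec(...)
  base <- spec$weightCurves$control
  if (!effect %in% colnames(base))
    stop("unknown feature '", effect, "'", call. = FALSE)
  shifted <- base
  we <- base[, effect]
  if (any(we + delta < 0) || any(we + delta > 1))
    stop("delta pushes '", effect, "' weight outside [0, 1]",
         call. = FALSE)
  others <- setdiff(colnames(base), effect)
  scl <- (1 - we - delta) / (1 - we)
  shifted[, others] <- base[, others] * scl
  shifted[, effect] <- we + delta
  spec$weightCurves$treatment <- shifted
  validateScenario(spec)
  spec
}
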