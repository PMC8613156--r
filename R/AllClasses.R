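#' @include AllGenerics.R
NULL

#' Pixel grid and timing of a stimulus
#'
#' A `GridSpec` describes the stimulus raster on which all feature maps and
#' eye-position density maps live: its width `w` and height `h` in pixels,
#' the video refresh rate `fps` (frames per second) and the number of frames
#' `nFrames`. All maps in a model must share one `GridSpec`.
#'
#' The package uses image conventions throughout: x runs rightward in
#' `[0, w)`, y runs downward in `[0, h)`, and the pixel stored at matrix
#' entry `[i, j]` (1-based row `i`, column `j`) has continuous center
#' `(j - 0.5, i - 0.5)`.
#'
#' @param w,h stimulus width and height in pixels (integers `>= 2`).
#' @param fps video refresh rate in frames per second.
#' @param nFrames number of frames in the stimulus.
#' @return A `GridSpec` object.
#' @examples
#' GridSpec(720, 576, fps = 25, nFrames = 174)
#' @export
GridSpec <- function(w, h, fps = 25, nFrames = 1L) {
  new("GridSpec", w = as.integer(w), h = as.integer(h),
      fps = as.numeric(fps), nFrames = as.integer(nFrames))
}

#' @rdname GridSpec
#' @export
setClass("GridSpec",
  representation(w = "integer", h = "integer", fps = "numeric",
                 nFrames = "integer"),
  validity = function(object) {
    msg <- character(0)
    if (length(object@w) != 1L || is.na(object@w) || object@w < 2L)
      msg <- c(msg, "'w' must be a single integer >= 2")
    if (length(object@h) != 1L || is.na(object@h) || object@h < 2L)
      msg <- c(msg, "'h' must be a single integer >= 2")
    if (length(object@fps) != 1L || !is.finite(object@fps) || object@fps <= 0)
      msg <- c(msg, "'fps' must be a single positive number")
    if (length(object@nFrames) != 1L || is.na(object@nFrames) ||
        object@nFrames < 1L)
      msg <- c(msg, "'nFrames' must be a single integer >= 1")
    if (length(msg)) msg else TRUE
  })

setMethod("show", "GridSpec", function(object) {
  cat(sprintf("GridSpec: %d x %d px, %g fps, %d frame(s)\n",
              object@w, object@h, object@fps, object@nFrames))
})

## tolerance used by all density-normalization validity checks
.NORM_TOL <- 1e-9

#' Density-normalized feature map for one frame
#'
#' A `FeatureMap` holds one named, density-normalized `h x w` grid: one
#' candidate driver of visual attention evaluated on one stimulus frame.
#' Entries are nonnegative and sum to 1, so the map is a probability mass
#' function over pixels. Canonical names are `"uniform"`, `"center_bias"`,
#' `"static_saliency"`, `"dynamic_saliency"`, `"aoi:<label>"` and
#' `"custom:<label>"`.
#'
#' @param name feature identifier.
#' @param values nonnegative numeric matrix (`h` rows, `w` columns) summing
#'   to 1 within `1e-9`.
#' @param frameIndex 1-based frame number, or `NA` for a time-independent
#'   map that applies to every frame.
#' @return A `FeatureMap` object.
#' @seealso [uniformMap()], [centerBiasMap()], [aoiMap()],
#'   [staticSaliencyMap()], [dynamicSaliencyMap()]
#' @export
FeatureMap <- function(name, values, frameIndex = NA_integer_) {
  new("FeatureMap", name = as.character(name),
      frameIndex = as.integer(frameIndex),
      values = values)
}

#' @rdname FeatureMap
#' @export
setClass("FeatureMap",
  representation(name = "character", frameIndex = "integer",
                 values = "matrix"),
  validity = function(object) {
    msg <- character(0)
    if (length(object@name) != 1L || !nzchar(object@name))
      msg <- c(msg, "'name' must be a single non-empty string")
    v <- object@values
    if (!is.numeric(v))
      msg <- c(msg, "'values' must be a numeric matrix")
    else {
      if (anyNA(v)) msg <- c(msg, "'values' contains NA")
      else {
        if (min(v) < 0) msg <- c(msg, "'values' has negative entries")
        if (abs(sum(v) - 1) > .NORM_TOL)
          msg <- c(msg, sprintf("'values' sums to %.12g, not 1", sum(v)))
      }
    }
    if (length(msg)) msg else TRUE
  })

setMethod("show", "FeatureMap", function(object) {
  d <- dim(object@values)
  cat(sprintf("FeatureMap '%s' (frame %s): %d x %d px, max %.3g\n",
              object@name,
              if (is.na(object@frameIndex)) "any" else object@frameIndex,
              d[2], d[1], max(object@values)))
})

#' @rdname FeatureMap
#' @export
setMethod("mapValues", "FeatureMap", function(x) x@values)

#' @rdname FeatureMap
#' @export
setMethod("mapName", "FeatureMap", function(x) x@name)

#' @rdname FeatureMap
#' @export
setMethod("frameIndex", "FeatureMap", function(x) x@frameIndex)

#' Monitor/stimulus display geometry
#'
#' Records how the stimulus was displayed on the eye-tracker monitor: the
#' stimulus is enlarged to full monitor height and proportionally in width,
#' leaving black side bars. The scale factor is `monH / stimH`, the scaled
#' stimulus width is `stimW * scale` and each side bar is
#' `(monW - stimW * scale) / 2` pixels wide. Also carries the tracker
#' sampling rate and the video refresh rate used for frame alignment.
#'
#' @param monW,monH monitor resolution in pixels.
#' @param stimW,stimH stimulus resolution in pixels.
#' @param trackerHz eye-tracker sampling rate in Hz.
#' @param refreshHz video refresh rate in Hz.
#' @return A `StimulusGeometry` object.
#' @examples
#' g <- StimulusGeometry(1920, 1080, 720, 576, trackerHz = 60, refreshHz = 25)
#' scaledStimWidth(g)  # 1350
#' sideBarWidth(g)     # 258
#' @export
StimulusGeometry <- function(monW, monH, stimW, stimH,
                             trackerHz = 60, refreshHz = 25) {
  new("StimulusGeometry", monW = as.numeric(monW), monH = as.numeric(monH),
      stimW = as.numeric(stimW), stimH = as.numeric(stimH),
      trackerHz = as.numeric(trackerHz), refreshHz = as.numeric(refreshHz))
}

#' @rdname StimulusGeometry
#' @export
setClass("StimulusGeometry",
  representation(monW = "numeric", monH = "numeric", stimW = "numeric",
                 stimH = "numeric", trackerHz = "numeric",
                 refreshHz = "numeric"),
  validity = function(object) {
    msg <- character(0)
    for (s in c("monW", "monH", "stimW", "stimH", "trackerHz", "refreshHz")) {
      v <- slot(object, s)
      if (length(v) != 1L || !is.finite(v) || v <= 0)
        msg <- c(msg, sprintf("'%s' must be a single positive number", s))
    }
    if (!length(msg)) {
      scale <- object@monH / object@stimH
      if (object@stimW * scale > object@monW + 1e-9)
        msg <- c(msg, "scaled stimulus width exceeds monitor width")
    }
    if (length(msg)) msg else TRUE
  })

#' @rdname StimulusGeometry
#' @export
scaleFactor <- function(geom) geom@monH / geom@stimH

#' @rdname StimulusGeometry
#' @export
scaledStimWidth <- function(geom) geom@stimW * scaleFactor(geom)

#' @rdname StimulusGeometry
#' @export
sideBarWidth <- function(geom) (geom@monW - scaledStimWidth(geom)) / 2

setMethod("show", "StimulusGeometry", function(object) {
  cat(sprintf(
    "StimulusGeometry: monitor %g x %g, stimulus %g x %g (scale %.4g, side bars %.4g px)\n  tracker %g Hz, refresh %g Hz\n",
    object@monW, object@monH, object@stimW, object@stimH,
    scaleFactor(object), sideBarWidth(object),
    object@trackerHz, object@refreshHz))
})

#' Kernel-density eye-position map for one frame and group
#'
#' Holds the bivariate kernel density estimate of one group's fixation
#' locations on one frame, evaluated at pixel centers, together with the
#' number of fixations used and the selected bandwidth matrix. When built
#' for modeling the grid is renormalized to sum to 1 (mass falling off the
#' stimulus is folded back by renormalization).
#'
#' @param frameIndex 1-based frame number.
#' @param group group label.
#' @param values nonnegative `h x w` density grid.
#' @param nPoints number of fixations behind the estimate.
#' @param bandwidth 2x2 symmetric positive-definite bandwidth matrix
#'   (pixels^2).
#' @return An `EyeDensityMap` object.
#' @export
EyeDensityMap <- function(frameIndex, group, values, nPoints, bandwidth) {
  new("EyeDensityMap", frameIndex = as.integer(frameIndex),
      group = as.character(group), values = values,
      nPoints = as.integer(nPoints), bandwidth = bandwidth)
}

#' @rdname EyeDensityMap
#' @export
setClass("EyeDensityMap",
  representation(frameIndex = "integer", group = "character",
                 values = "matrix", nPoints = "integer",
                 bandwidth = "matrix"),
  validity = function(object) {
    msg <- character(0)
    if (!is.numeric(object@values) || anyNA(object@values))
      msg <- c(msg, "'values' must be a numeric matrix without NA")
    else if (min(object@values) < 0)
      msg <- c(msg, "'values' has negative entries")
    bw <- object@bandwidth
    if (!identical(dim(bw), c(2L, 2L)))
      msg <- c(msg, "'bandwidth' must be a 2x2 matrix")
    else {
      if (abs(bw[1, 2] - bw[2, 1]) > 1e-12)
        msg <- c(msg, "'bandwidth' must be symmetric")
      else if (any(eigen(bw, symmetric = TRUE,
                         only.values = TRUE)$values <= 0))
        msg <- c(msg, "'bandwidth' must be positive definite")
    }
    if (object@nPoints < 1L) msg <- c(msg, "'nPoints' must be >= 1")
    if (length(msg)) msg else TRUE
  })

setMethod("show", "EyeDensityMap", function(object) {
  d <- dim(object@values)
  cat(sprintf(
    "EyeDensityMap frame %d, group '%s': %d x %d px, N = %d, bw diag (%.3g, %.3g)\n",
    object@frameIndex, object@group, d[2], d[1], object@nPoints,
    object@bandwidth[1, 1], object@bandwidth[2, 2]))
})

#' @rdname EyeDensityMap
#' @export
setMethod("mapValues", "EyeDensityMap", function(x) x@values)

#' @rdname EyeDensityMap
#' @export
setMethod("frameIndex", "EyeDensityMap", function(x) x@frameIndex)

#' @rdname EyeDensityMap
#' @export
setMethod("groupLabel", "EyeDensityMap", function(x) x@group)

#' @rdname EyeDensityMap
#' @export
setMethod("nPoints", "EyeDensityMap", function(x) x@nPoints)

#' @rdname EyeDensityMap
#' @export
setMethod("bandwidthMatrix", "EyeDensityMap", function(x) x@bandwidth)

#' Per-frame model fit
#'
#' Result of fitting the master-saliency decomposition for one frame:
#' selected feature-map weights on the standardized scale (`beta`), the
#' weights mapped back to the raw density scale (`betaRaw`, including the
#' uniform map's weight recovered from the intercept), the selected penalty
#' `lambda`, the BIC of the selected fit, the adjusted coefficient of
#' determination and the number of nonzero weights. Two-group fits carry
#' interaction coefficients suffixed `":G"`. Skipped frames are explicit
#' records with `skipped = TRUE` and a reason.
#'
#' @export
setClass("FrameFit",
  representation(frameIndex = "integer", beta = "numeric",
                 betaRaw = "numeric", lambda = "numeric", bic = "numeric",
                 r2Adj = "numeric", nNonzero = "integer",
                 groups = "character", skipped = "logical",
                 reason = "character"),
  validity = function(object) {
    msg <- character(0)
    if (length(object@skipped) != 1L)
      msg <- c(msg, "'skipped' must be a single logical")
    else if (!object@skipped) {
      if (is.null(names(object@beta)))
        msg <- c(msg, "'beta' must be named")
      if (length(object@nNonzero) == 1L &&
          object@nNonzero != sum(abs(object@beta) > 0))
        msg <- c(msg, "'nNonzero' does not match count of nonzero betas")
    }
    if (length(msg)) msg else TRUE
  })

setMethod("show", "FrameFit", function(object) {
  if (object@skipped) {
    cat(sprintf("FrameFit frame %d: skipped (%s)\n",
                object@frameIndex, object@reason))
  } else {
    cat(sprintf(
      "FrameFit frame %d [%s]: lambda %.4g, BIC %.6g, adj R2 %.3f, %d nonzero\n",
      object@frameIndex, paste(object@groups, collapse = " vs "),
      object@lambda, object@bic, object@r2Adj, object@nNonzero))
    print(round(object@beta, 4))
  }
})

#' @rdname FrameFit-class
#' @export
setMethod("frameIndex", "FrameFit", function(x) x@frameIndex)

#' Accessors for FrameFit
#'
#' `fitBeta` returns the standardized-scale weights, `fitBetaRaw` the
#' raw-scale weights, `fitLambda`, `fitBic`, `fitR2Adj` the selection
#' summaries, and `isSkipped` whether the frame was skipped.
#'
#' @param x a `FrameFit`.
#' @name FrameFit-accessors
NULL

#' @rdname FrameFit-accessors
#' @export
fitBeta <- function(x) x@beta

#' @rdname FrameFit-accessors
#' @export
fitBetaRaw <- function(x) x@betaRaw

#' @rdname FrameFit-accessors
#' @export
fitLambda <- function(x) x@lambda

#' @rdname FrameFit-accessors
#' @export
fitBic <- function(x) x@bic

#' @rdname FrameFit-accessors
#' @export
fitR2Adj <- function(x) x@r2Adj

#' @rdname FrameFit-accessors
#' @export
isSkipped <- function(x) x@skipped

#' Permutation-test result for one frame
#'
#' For each feature, the observed group-difference coefficient (the
#' interaction weight), its distribution over `P` participant-label
#' permutations, and the two-sided p-value
#' `(1 + #\{|permuted| >= |observed|\}) / (P + 1)`.
#'
#' @export
setClass("PermutationResult",
  representation(frameIndex = "integer", observed = "numeric",
                 permuted = "matrix", pValues = "numeric",
                 seed = "integer"),
  validity = function(object) {
    msg <- character(0)
    K <- length(object@observed)
    if (ncol(object@permuted) != K)
      msg <- c(msg, "'permuted' must have one column per feature")
    if (length(object@pValues) != K)
      msg <- c(msg, "'pValues' must have one entry per feature")
    P <- nrow(object@permuted)
    if (P >= 1L && K >= 1L) {
      expect <- (1 + colSums(abs(object@permuted) >=
                             matrix(abs(object@observed), P, K,
                                    byrow = TRUE))) / (P + 1)
      if (any(abs(expect - object@pValues) > 1e-12))
        msg <- c(msg, "'pValues' inconsistent with permuted distribution")
    }
    if (any(object@pValues <= 0 | object@pValues > 1))
      msg <- c(msg, "p-values must lie in (0, 1]")
    if (length(msg)) msg else TRUE
  })

setMethod("show", "PermutationResult", function(object) {
  cat(sprintf("PermutationResult frame %d (%d permutations):\n",
              object@frameIndex, nrow(object@permuted)))
  print(data.frame(observed = round(object@observed, 4),
                   p = round(object@pValues, 4)))
})

#' @rdname PermutationResult-class
#' @export
setMethod("frameIndex", "PermutationResult", function(x) x@frameIndex)

#' Accessors for PermutationResult
#' @param x a `PermutationResult`.
#' @name PermutationResult-accessors
NULL

#' @rdname PermutationResult-accessors
#' @export
observedDiff <- function(x) x@observed

#' @rdname PermutationResult-accessors
#' @export
permutedDiffs <- function(x) x@permuted

#' @rdname PermutationResult-accessors
#' @export
pValues <- function(x) x@pValues
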