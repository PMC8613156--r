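#' Normalize a nonnegative grid to a density map
#'
#' Divides each entry by the sum of all entries, so the result is a
#' probability mass function over pixels. All feature maps and
#' (renormalized) eye-position density maps go through this rule.
#'
#' @param raw nonnegative numeric matrix.
#' @param what label used in error messages (map name / frame).
#' @return Matrix of the same shape summing to 1.
#' @examples
#' normalizeMap(matrix(c(2, 0, 0, 2), 2))
#' @export
normalizeMap <- function(raw, what = "map") {
  if (!is.numeric(raw) || anyNA(raw))
    stop(sprintf("%s: values must be numeric and non-missing", what),
         call. = FALSE)
  if (min(raw) < 0)
    stop(sprintf("%s: negative entries cannot be density-normalized", what),
         call. = FALSE)
  s <- sum(raw)
  if (s <= 0)
    stop(sprintf("degenerate map: %s is all zero", what), call. = FALSE)
  raw / s
}

#' Uniform feature map
#'
#' The catch-all hypothesis: every pixel equally likely, value
#' `1 / (w * h)` everywhere. Time-independent.
#'
#' @param grid a [GridSpec()].
#' @return A [FeatureMap()] named `"uniform"`.
#' @examples
#' m <- uniformMap(GridSpec(4, 3))
#' sum(mapValues(m))  # 1
#' @export
uniformMap <- function(grid) {
  v <- matrix(1 / (grid@w * grid@h), nrow = grid@h, ncol = grid@w)
  FeatureMap("uniform", v)
}

#' Center-bias feature map
#'
#' The tendency to look near the stimulus center, modeled as a bivariate
#' Gaussian with diagonal covariance evaluated at pixel centers and
#' normalized over the grid. Defaults follow the convention of dividing
#' stimulus width and height by 12 for the standard deviations, centered at
#' the stimulus center. Time-independent.
#'
#' @param grid a [GridSpec()].
#' @param sigmaX,sigmaY standard deviations in pixels; defaults `w/12` and
#'   `h/12`.
#' @param center length-2 numeric `(x, y)` in continuous stimulus
#'   coordinates; default the stimulus center `(w/2, h/2)`.
#' @return A [FeatureMap()] named `"center_bias"`.
#' @examples
#' centerBiasMap(GridSpec(720, 576))  # sigmas 60 and 48 px
#' @export
centerBiasMap <- function(grid, sigmaX = grid@w / 12, sigmaY = grid@h / 12,
                          center = c(grid@w / 2, grid@h / 2)) {
  if (!is.finite(sigmaX) || sigmaX <= 0 || !is.finite(sigmaY) || sigmaY <= 0)
    stop("center bias standard deviations must be positive", call. = FALSE)
  dx2 <- ((pixelCentersX(grid) - center[1]) / sigmaX)^2
  dy2 <- ((pixelCentersY(grid) - center[2]) / sigmaY)^2
  v <- exp(-0.5 * outer(dy2, dx2, "+"))
  FeatureMap("center_bias", normalizeMap(v, "center_bias"))
}

#' Point-in-polygon test (even-odd rule, inclusive boundary)
#'
#' Even-odd ray casting; points exactly on a polygon edge or vertex count
#' as inside (closed polygon).
#'
#' @param px,py point coordinates (vectors of equal length).
#' @param vx,vy polygon vertex coordinates in order (not repeated at end).
#' @return Logical vector.
#' @export
pointInPolygon <- function(px, py, vx, vy) {
  n <- length(vx)
  stopifnot(n >= 3L, length(vy) == n, length(px) == length(py))
  inside <- logical(length(px))
  onEdge <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    x1 <- vx[j]; y1 <- vy[j]; x2 <- vx[i]; y2 <- vy[i]
    ## exact on-segment check
    cross <- (px - x1) * (y2 - y1) - (py - y1) * (x2 - x1)
    within <- px >= pmin(x1, x2) - 1e-12 & px <= pmax(x1, x2) + 1e-12 &
              py >= pmin(y1, y2) - 1e-12 & py <= pmax(y1, y2) + 1e-12
    onEdge <- onEdge | (abs(cross) < 1e-9 & within)
    ## crossing test: half-open in y to count each crossing once
    crosses <- ((y1 > py) != (y2 > py)) &
               (px < (x2 - x1) * (py - y1) / (y2 - y1) + x1)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside | onEdge
}

#' Area-of-interest feature map
#'
#' Rasterizes a polygon to a binary grid (1 on pixels whose centers fall
#' inside the polygon, boundary inclusive; 0 otherwise) and
#' density-normalizes it. Vertices outside `[0, w] x [0, h]` are clipped to
#' the grid box.
#'
#' @param vertices numeric matrix with columns x, y (>= 3 rows), in
#'   continuous stimulus coordinates.
#' @param grid a [GridSpec()].
#' @param label AoI label; the map is named `"aoi:<label>"`.
#' @param frameIndex 1-based frame, or `NA` for a static AoI.
#' @return A [FeatureMap()].
#' @examples
#' sq <- rbind(c(1, 1), c(3, 1), c(3, 3), c(1, 3))
#' aoiMap(sq, GridSpec(6, 6), "target")
#' @export
aoiMap <- function(vertices, grid, label = "aoi", frameIndex = NA_integer_) {
  vertices <- as.matrix(vertices)
  if (nrow(vertices) < 3L || ncol(vertices) != 2L)
    stop("AoI polygon needs >= 3 (x, y) vertices", call. = FALSE)
  vx <- pmin(pmax(vertices[, 1], 0), grid@w)
  vy <- pmin(pmax(vertices[, 2], 0), grid@h)
  cx <- pixelCentersX(grid)
  cy <- pixelCentersY(grid)
  pts <- expand.grid(y = cy, x = cx)  # column-major over h x w matrix
  inside <- pointInPolygon(pts$x, pts$y, vx, vy)
  v <- matrix(as.numeric(inside), nrow = grid@h, ncol = grid@w)
  name <- paste0("aoi:", label)
  FeatureMap(name,
             normalizeMap(v, sprintf("%s (frame %s)", name, frameIndex)),
             frameIndex)
}

## Odd-sized, zero-mean (even) Gabor kernel.
gaborKernel <- function(wavelength, theta, sigma, halfSize) {
  idx <- -halfSize:halfSize
  xg <- outer(rep(1, length(idx)), idx)
  yg <- outer(idx, rep(1, length(idx)))
  xr <- xg * cos(theta) + yg * sin(theta)
  env <- exp(-(xg^2 + yg^2) / (2 * sigma^2))
  k <- env * cos(2 * pi * xr / wavelength)
  k - mean(k)  # zero DC response
}

#' Static saliency feature map
#'
#' A simplified luminance-contrast operator: the frame is passed through a
#' bank of even Gabor filters (4 orientations x 2 scales), responses are
#' rectified, each channel is divided by its maximum, and channels are
#' summed and density-normalized. Deterministic for fixed input. A
#' constant-luminance frame has no contrast anywhere, so the operator
#' returns the uniform map. The operator is deliberately simple and
#' swappable: precomputed maps from any external saliency model can be
#' injected via [loadExternalSaliency()].
#'
#' @param frame numeric `h x w` luminance matrix.
#' @param grid a [GridSpec()].
#' @param frameIndex 1-based frame number.
#' @param wavelengths Gabor wavelengths in pixels (the two scales).
#' @return A [FeatureMap()] named `"static_saliency"`.
#' @export
staticSaliencyMap <- function(frame, grid, frameIndex = NA_integer_,
                              wavelengths = c(4, 8)) {
  assertGrid(frame, grid, "static saliency input frame")
  thetas <- pi * (0:3) / 4
  acc <- matrix(0, grid@h, grid@w)
  any_live <- FALSE
  for (wl in wavelengths) {
    sigma <- wl / 2
    half <- min(ceiling(2.5 * sigma),
                floor((min(grid@h, grid@w) - 1) / 2))
    for (th in thetas) {
      k <- gaborKernel(wl, th, sigma, half)
      resp <- abs(EBImage::filter2(frame, k, boundary = "replicate"))
      m <- max(resp)
      if (m > 1e-9) {        # dead channel: no contrast at this band
        acc <- acc + resp / m
        any_live <- TRUE
      }
    }
  }
  if (!any_live)
    return(FeatureMap("static_saliency",
                      mapValues(uniformMap(grid)), frameIndex))
  FeatureMap("static_saliency", normalizeMap(acc, "static_saliency"),
             frameIndex)
}

#' Dynamic saliency feature map
#'
#' A simplified motion-energy operator built from the previous frame: both
#' frames are Gaussian-blurred (sigma 2 px, suppressing fine spatial
#' detail), the absolute luminance difference is taken and smoothed again
#' (sigma 3 px), then density-normalized. There is no previous frame for
#' the first frame, so this map is undefined there and requesting it is an
#' error.
#'
#' @param frame,framePrev numeric `h x w` luminance matrices for the
#'   current and previous frame.
#' @param grid a [GridSpec()].
#' @param frameIndex 1-based frame number; must be `>= 2`.
#' @param onStatic policy when the two frames are identical (all-zero raw
#'   map): `"error"` (default) or `"uniform"` (substitute the uniform map
#'   with a warning).
#' @param blurSigma,smoothSigma pre-difference and post-difference Gaussian
#'   widths in pixels.
#' @return A [FeatureMap()] named `"dynamic_saliency"`.
#' @export
dynamicSaliencyMap <- function(frame, framePrev, grid,
                               frameIndex = NA_integer_,
                               onStatic = c("error", "uniform"),
                               blurSigma = 2, smoothSigma = 3) {
  onStatic <- match.arg(onStatic)
  if (!is.na(frameIndex) && frameIndex < 2L)
    stop("dynamic saliency is undefined for the first frame", call. = FALSE)
  assertGrid(frame, grid, "dynamic saliency current frame")
  assertGrid(framePrev, grid, "dynamic saliency previous frame")
  b1 <- EBImage::gblur(frame, sigma = blurSigma, boundary = "replicate")
  b0 <- EBImage::gblur(framePrev, sigma = blurSigma, boundary = "replicate")
  d <- abs(b1 - b0)
  d <- EBImage::gblur(d, sigma = smoothSigma, boundary = "replicate")
  d[d < 0] <- 0  # clip FFT roundoff
  if (sum(d) <= 1e-12) {
    if (onStatic == "uniform") {
      warning(sprintf(
        "frames %s and %s identical: substituting uniform dynamic map",
        frameIndex, if (is.na(frameIndex)) NA else frameIndex - 1L))
      return(FeatureMap("dynamic_saliency", mapValues(uniformMap(grid)),
                        frameIndex))
    }
    stop(sprintf("degenerate map: dynamic_saliency (frame %s) is all zero",
                 frameIndex), call. = FALSE)
  }
  FeatureMap("dynamic_saliency", normalizeMap(d, "dynamic_saliency"),
             frameIndex)
}

#' Load a precomputed saliency grid
#'
#' Reads a dense `h x w` numeric grid from a headerless CSV file (one row
#' per pixel row), clips negative entries to zero with a warning,
#' density-normalizes and labels it `"custom:<name>"`. This is the entry
#' point for substituting the output of any external saliency model for
#' the built-in operators.
#'
#' @param path CSV file path.
#' @param grid a [GridSpec()].
#' @param name label for the map.
#' @param frameIndex 1-based frame number.
#' @return A [FeatureMap()].
#' @export
loadExternalSaliency <- function(path, grid, name,
                                 frameIndex = NA_integer_) {
  v <- as.matrix(utils::read.csv(path, header = FALSE))
  dimnames(v) <- NULL
  storage.mode(v) <- "double"
  if (anyNA(v))
    stop(sprintf("external saliency '%s': non-numeric or missing entries",
                 path), call. = FALSE)
  if (nrow(v) != grid@h || ncol(v) != grid@w)
    stop(sprintf("external saliency '%s' is %d x %d, expected %d x %d (h x w)",
                 path, nrow(v), ncol(v), grid@h, grid@w), call. = FALSE)
  if (min(v) < 0) {
    warning(sprintf("external saliency '%s': negative entries clipped to 0",
                    path))
    v[v < 0] <- 0
  }
  nm <- paste0("custom:", name)
  FeatureMap(nm, normalizeMap(v, nm), frameIndex)
}

#' Smooth a feature map with a KDE kernel
#'
#' Convolves a feature map with the Gaussian kernel of a (diagonal)
#' bandwidth matrix, by normalized convolution: each output pixel is the
#' kernel-weighted average of the input restricted to the grid, so
#' constant maps stay exactly constant and no phantom boundary structure
#' appears. The result is renormalized to sum to 1.
#'
#' Rationale: the regression response is a kernel-smoothed density, so
#' comparing it against feature maps smoothed with the same kernel makes
#' the mixture-weight regression consistent; see the methods vignette.
#'
#' @param map a [FeatureMap()].
#' @param H 2x2 bandwidth matrix (off-diagonal ignored; the bandwidth
#'   search family is diagonal).
#' @param grid a [GridSpec()].
#' @return A [FeatureMap()] with the same name and frame.
#' @export
smoothFeatureMap <- function(map, H, grid) {
  v <- mapValues(map)
  assertGrid(v, grid, mapName(map))
  hx <- sqrt(H[1, 1]); hy <- sqrt(H[2, 2])
  cx <- pixelCentersX(grid); cy <- pixelCentersY(grid)
  kx <- stats::dnorm(outer(cx, cx, "-"), sd = hx)
  ky <- stats::dnorm(outer(cy, cy, "-"), sd = hy)
  kx <- kx / rowSums(kx)
  ky <- ky / rowSums(ky)
  sm <- ky %*% v %*% t(kx)
  FeatureMap(mapName(map), normalizeMap(sm, mapName(map)),
             frameIndex(map))
}

#' Read a stimulus frame sequence
#'
#' Reads a lexicographically ordered sequence of PNG (or TIFF) images and
#' converts them to luminance by the ITU-R BT.601 weights
#' `0.299 R + 0.587 G + 0.114 B`. Grayscale images are used as-is.
#'
#' @param paths character vector of image paths, or a directory containing
#'   the frames.
#' @param grid optional [GridSpec()] to validate shapes against.
#' @return List of `h x w` luminance matrices in `[0, 1]`.
#' @export
readFrameSequence <- function(paths, grid = NULL) {
  if (length(paths) == 1L && dir.exists(paths))
    paths <- sort(list.files(paths, pattern = "\\.(png|tif|tiff)$",
                             ignore.case = TRUE, full.names = TRUE))
  if (!length(paths)) stop("no frame images found", call. = FALSE)
  frames <- lapply(paths, function(p) {
    img <- if (grepl("\\.png$", p, ignore.case = TRUE)) png::readPNG(p)
           else tiff::readTIFF(p)
    lum <- if (length(dim(img)) == 3L && dim(img)[3] >= 3L)
      0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
    else if (length(dim(img)) == 3L) img[, , 1]
    else img
    if (!is.null(grid)) assertGrid(lum, grid, p)
    lum
  })
  frames
}

#' Read AoI polygon definitions from JSON
#'
#' The file holds a list of records `{label, frame_index, vertices}` with
#' `vertices` a list of `[x, y]` pairs; `frame_index` is 1-based, and
#' `null` means the AoI is static and applies to every frame.
#'
#' @param path JSON file path.
#' @return List of records with elements `label`, `frameIndex`
#'   (`NA` if static) and `vertices` (matrix).
#' @export
readAoiJson <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  lapply(raw, function(r) {
    v <- do.call(rbind, lapply(r$vertices, unlist))
    list(label = r$label,
         frameIndex = if (is.null(r$frame_index)) NA_integer_
                      else as.integer(r$frame_index),
         vertices = v)
  })
}
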