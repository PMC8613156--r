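## Bivariate kernel density estimation of eye-position density maps, with
## least-squares cross-validation (LSCV) bandwidth selection per frame and
## group.

## Scaled Gaussian kernel K_H evaluated at displacement rows of `d` (n x 2).
kernelAtDisplacements <- function(d, H) {
  Hi <- solve(H)
  q <- d[, 1]^2 * Hi[1, 1] + 2 * d[, 1] * d[, 2] * Hi[1, 2] +
       d[, 2]^2 * Hi[2, 2]
  exp(-0.5 * q) / (2 * pi * sqrt(det(H)))
}

## Density surface at arbitrary grid axes (vectors of x and y evaluation
## coordinates); returns length(ys) x length(xs) matrix. Separable fast
## path for diagonal H; exact dense computation otherwise.
kdeOnAxes <- function(points, H, xs, ys) {
  N <- nrow(points)
  if (abs(H[1, 2]) < 1e-14) {
    sx <- sqrt(H[1, 1]); sy <- sqrt(H[2, 2])
    Gx <- exp(-0.5 * (outer(xs, points[, 1], "-") / sx)^2) /
      (sqrt(2 * pi) * sx)                       # |xs| x N
    Gy <- exp(-0.5 * (outer(ys, points[, 2], "-") / sy)^2) /
      (sqrt(2 * pi) * sy)                       # |ys| x N
    (Gy %*% t(Gx)) / N
  } else {
    out <- matrix(0, length(ys), length(xs))
    for (k in seq_len(N)) {
      d <- cbind(rep(xs, each = length(ys)) - points[k, 1],
                 rep(ys, times = length(xs)) - points[k, 2])
      out <- out + matrix(kernelAtDisplacements(d, H), length(ys))
    }
    out / N
  }
}

#' Bivariate Gaussian kernel density estimate on the pixel grid
#'
#' Evaluates `f(x; H) = N^-1 sum_i K_H(x - X_i)` at every pixel center,
#' with the scaled Gaussian kernel
#' `K_H(x) = (2 pi)^-1 |H|^-1/2 exp(-x' H^-1 x / 2)`.
#'
#' @param points numeric `N x 2` matrix of fixation coordinates (x, y) in
#'   stimulus pixels.
#' @param H 2x2 symmetric positive-definite bandwidth matrix (pixels^2).
#' @param grid a [GridSpec()].
#' @param frameIndex,group metadata carried into the result.
#' @param renormalize if `TRUE`, rescale the grid to sum to 1 (the form
#'   used as the regression response); if `FALSE`, return raw density
#'   values per px^2.
#' @return An [EyeDensityMap()].
#' @export
gaussianKde <- function(points, H, grid, frameIndex = NA_integer_,
                        group = "all", renormalize = FALSE) {
  points <- as.matrix(points)
  if (!nrow(points)) stop("no fixation points: KDE undefined", call. = FALSE)
  checkBandwidth(H)
  v <- kdeOnAxes(points, H, pixelCentersX(grid), pixelCentersY(grid))
  v[v < 0] <- 0
  if (renormalize) v <- normalizeMap(v, "eye-position density")
  EyeDensityMap(frameIndex, group, v, nrow(points), H)
}

checkBandwidth <- function(H) {
  if (!is.matrix(H) || !identical(dim(H), c(2L, 2L)))
    stop("bandwidth must be a 2x2 matrix", call. = FALSE)
  if (abs(H[1, 2] - H[2, 1]) > 1e-12)
    stop("bandwidth matrix must be symmetric", call. = FALSE)
  ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0))
    stop("bandwidth matrix must be positive definite", call. = FALSE)
  invisible(TRUE)
}

## Axes of the integration grid: extended `extendSd` standard deviations
## beyond the stimulus box so boundary mass is not lost. The per-axis step
## tracks the kernel scale: never larger than the axis SD (a Gaussian
## sampled at its own SD is already integrated to ~1e-9 relative error),
## refined below one pixel for sub-pixel kernels and widened to SD/4 for
## very smooth ones, so both ends of the candidate range stay accurate
## and affordable. Each grid point represents a cell of `stepx * stepy`.
lscvAxes <- function(grid, H, extendSd = 3) {
  stepFor <- function(sd) if (sd >= 4) floor(sd / 4) else min(1, sd)
  sx <- sqrt(H[1, 1]); sy <- sqrt(H[2, 2])
  mx <- ceiling(extendSd * sx); my <- ceiling(extendSd * sy)
  stx <- stepFor(sx); sty <- stepFor(sy)
  list(xs = seq(-mx + stx / 2, grid@w + mx, by = stx),
       ys = seq(-my + sty / 2, grid@h + my, by = sty),
       area = stx * sty)
}

#' Least-squares cross-validation criterion
#'
#' `LSCV(H) = int f(x; H)^2 dx - 2 N^-1 sum_i f_{-i}(X_i; H)`, where
#' `f_{-i}` is the leave-one-out estimator. The integral is approximated by
#' a Riemann sum on the pixel-spaced grid extended three (maximal)
#' bandwidth standard deviations beyond the stimulus box; the leave-one-out
#' term is exact.
#'
#' @inheritParams gaussianKde
#' @param extendSd how many bandwidth standard deviations to extend the
#'   integration grid beyond the stimulus box.
#' @return The criterion value (scalar).
#' @export
lscvCriterion <- function(points, H, grid, extendSd = 3) {
  points <- as.matrix(points)
  N <- nrow(points)
  if (N < 2L) stop("LSCV needs at least 2 points (leave-one-out undefined)",
                   call. = FALSE)
  checkBandwidth(H)
  ax <- lscvAxes(grid, H, extendSd)
  fhat <- kdeOnAxes(points, H, ax$xs, ax$ys)
  intf2 <- sum(fhat^2) * ax$area
  loo <- looTerm(points, H)
  intf2 - 2 * mean(loo)
}

## Leave-one-out estimates f_{-i}(X_i); optionally reuses precomputed
## squared pairwise differences (for the diagonal-H search loop).
looTerm <- function(points, H, pre = NULL) {
  N <- nrow(points)
  if (abs(H[1, 2]) < 1e-14) {
    if (is.null(pre)) pre <- pairwiseSq(points)
    K <- exp(-0.5 * (pre$dx2 / H[1, 1] + pre$dy2 / H[2, 2])) /
      (2 * pi * sqrt(H[1, 1] * H[2, 2]))
  } else {
    dx <- outer(points[, 1], points[, 1], "-")
    dy <- outer(points[, 2], points[, 2], "-")
    K <- matrix(kernelAtDisplacements(cbind(as.vector(dx), as.vector(dy)),
                                      H), N)
  }
  k0 <- 1 / (2 * pi * sqrt(det(H)))
  (rowSums(K) - k0) / (N - 1)
}

pairwiseSq <- function(points) {
  list(dx2 = outer(points[, 1], points[, 1], "-")^2,
       dy2 = outer(points[, 2], points[, 2], "-")^2)
}

## LSCV for diagonal H parameterized by SDs (hx, hy), reusing pairwise
## squares across the candidate search.
lscvDiag <- function(points, hx, hy, grid, pre, extendSd = 3) {
  H <- diag(c(hx^2, hy^2))
  ax <- lscvAxes(grid, H, extendSd)
  fhat <- kdeOnAxes(points, H, ax$xs, ax$ys)
  sum(fhat^2) * ax$area - 2 * mean(looTerm(points, H, pre))
}

#' Select a KDE bandwidth by LSCV
#'
#' Minimizes the LSCV criterion over diagonal bandwidth matrices: a
#' log-spaced `nCandidates x nCandidates` grid of per-axis standard
#' deviations spanning `range` times a plug-in pilot bandwidth
#' (`sd * N^(-1/6)` per axis, the normal-scale rule for two dimensions),
#' followed by Nelder--Mead refinement from the grid minimum.
#' Deterministic: no randomness is involved.
#'
#' @param points `N x 2` matrix of fixations (N >= 2).
#' @param grid a [GridSpec()].
#' @param nCandidates candidates per axis in the search grid.
#' @param range multiplier range around the pilot bandwidth.
#' @param refine run Nelder--Mead refinement after the grid search.
#' @param extendSd integration-grid extension, see [lscvCriterion()].
#' @return 2x2 diagonal bandwidth matrix (pixels^2).
#' @export
selectBandwidth <- function(points, grid, nCandidates = 15,
                            range = c(0.25, 4), refine = TRUE,
                            extendSd = 3) {
  points <- as.matrix(points)
  N <- nrow(points)
  if (N < 2L) stop("bandwidth selection needs at least 2 points",
                   call. = FALSE)
  sx <- stats::sd(points[, 1]); sy <- stats::sd(points[, 2])
  if (sx == 0 || sy == 0)
    stop(paste("degenerate point set (zero variance on an axis);",
               "use a fixed bandwidth instead of LSCV selection"),
         call. = FALSE)
  pilot <- c(sx, sy) * N^(-1 / 6)
  mult <- exp(seq(log(range[1]), log(range[2]), length.out = nCandidates))
  pre <- pairwiseSq(points)
  best <- NULL; bestVal <- Inf
  for (mx in mult) for (my in mult) {
    hx <- max(mx * pilot[1], 0.3)  # sub-pixel floor, as in refinement
    hy <- max(my * pilot[2], 0.3)
    val <- lscvDiag(points, hx, hy, grid, pre, extendSd)
    if (val < bestVal - 1e-15) { bestVal <- val; best <- c(hx, hy) }
  }
  h <- best
  if (refine) {
    opt <- stats::optim(log(h), function(lh) {
      hh <- exp(lh)
      ## bandwidths below ~1/3 px are not identifiable from lattice data
      if (any(hh < 0.3)) return(Inf)
      lscvDiag(points, hh[1], hh[2], grid, pre, extendSd)
    }, method = "Nelder-Mead", control = list(maxit = 60, reltol = 1e-8))
    if (opt$value < bestVal) h <- exp(opt$par)
  }
  diag(h^2)
}

#' Eye-position density map for one frame and group
#'
#' Gathers the fixations of `group` on frame `frameIndex` from a gaze
#' table, selects an LSCV bandwidth for that frame and group independently
#' (unless a bandwidth is supplied), and returns the renormalized density
#' map. Frames with fewer than two usable fixations are handled per
#' `policy`: skipped (returns `NULL`) or estimated with a fixed fallback
#' bandwidth.
#'
#' @param gaze gaze table (see [preprocessGaze()]).
#' @param frameIdx 1-based frame.
#' @param group group label.
#' @param grid a [GridSpec()].
#' @param policy `"skip"` (default) or `"fixed"` for under-populated
#'   frames.
#' @param fixedBandwidth 2x2 matrix used when `policy = "fixed"`, or to
#'   force a bandwidth for all frames (set `bandwidth`).
#' @param bandwidth optional 2x2 matrix: reuse this bandwidth instead of
#'   selecting by LSCV (used, e.g., to hold bandwidths fixed across
#'   permutations).
#' @param ... passed to [selectBandwidth()].
#' @return An [EyeDensityMap()] (renormalized to sum 1), or `NULL` if the
#'   frame is skipped.
#' @export
densityForGroup <- function(gaze, frameIdx, group, grid,
                            policy = c("skip", "fixed"),
                            fixedBandwidth = NULL, bandwidth = NULL, ...) {
  policy <- match.arg(policy)
  assertGazeTable(gaze)
  rows <- gaze$frameIndex == frameIdx & gaze$group == group
  pts <- as.matrix(gaze[rows, c("xStim", "yStim")])
  if (nrow(pts) < 2L) {
    if (policy == "skip" || nrow(pts) == 0L) return(NULL)
    return(gaussianKde(pts, fixedBandwidth, grid, frameIdx, group,
                       renormalize = TRUE))
  }
  H <- if (!is.null(bandwidth)) bandwidth
       else tryCatch(selectBandwidth(pts, grid, ...),
                     error = function(e) {
                       if (!is.null(fixedBandwidth)) fixedBandwidth
                       else stop(e)
                     })
  gaussianKde(pts, H, grid, frameIdx, group, renormalize = TRUE)
}
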