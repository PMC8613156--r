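## Shared fixtures, built in code.

## Paper-scale display geometry: 1920x1080 monitor, 720x576 stimulus,
## 60 Hz tracker, 25 Hz video.
referenceGeometry <- function() {
  StimulusGeometry(1920, 1080, 720, 576, trackerHz = 60, refreshHz = 25)
}

## Small random nonnegative map, normalized.
randomFeatureMap <- function(grid, name = "custom:test") {
  v <- matrix(stats::rexp(grid@w * grid@h), grid@h, grid@w)
  FeatureMap(name, v / sum(v))
}

## Raw gaze log with given per-participant sample counts; coordinates
## drawn inside the displayed stimulus area.
randomGazeLog <- function(counts, geom, groups = NULL, seed = 1) {
  set.seed(seed)
  bar <- sideBarWidth(geom)
  if (is.null(groups))
    groups <- rep(c("treatment", "control"), length.out = length(counts))
  do.call(rbind, lapply(seq_along(counts), function(i) {
    n <- counts[i]
    data.frame(participant = sprintf("P%02d", i), group = groups[i],
               sampleIndex = seq_len(n),
               xMon = runif(n, bar, geom@monW - bar - 1e-6),
               yMon = runif(n, 0, geom@monH - 1e-6),
               stringsAsFactors = FALSE)
  }))
}

## Tiny two-group gaze table with fixations drawn from given mixtures.
mixtureGazeTable <- function(mixT, mixC, nPerGroup, frameIdx = 2L,
                             seed = 1) {
  set.seed(seed)
  ptsT <- gazeRI:::samplePixelMixture(mixT, nPerGroup)
  ptsC <- gazeRI:::samplePixelMixture(mixC, nPerGroup)
  data.frame(
    participant = c(sprintf("T%04d", seq_len(nPerGroup)),
                    sprintf("C%04d", seq_len(nPerGroup))),
    group = rep(c("treatment", "control"), each = nPerGroup),
    frameIndex = frameIdx,
    xStim = c(ptsT[, "x"], ptsC[, "x"]),
    yStim = c(ptsT[, "y"], ptsC[, "y"]),
    stringsAsFactors = FALSE)
}

## Brute-force KDE: per-pixel, per-point double loop (independent oracle).
naiveKde <- function(points, H, xs, ys) {
  Hi <- solve(H)
  cst <- 1 / (2 * pi * sqrt(det(H)))
  out <- matrix(0, length(ys), length(xs))
  for (i in seq_along(ys)) for (j in seq_along(xs)) {
    s <- 0
    for (k in seq_len(nrow(points))) {
      d <- c(xs[j] - points[k, 1], ys[i] - points[k, 2])
      s <- s + cst * exp(-0.5 * sum(d * (Hi %*% d)))
    }
    out[i, j] <- s / nrow(points)
  }
  out
}

## Brute-force LSCV: Riemann sum over the same axes, plus explicit
## leave-one-out double loop.
naiveLscv <- function(points, H, grid, extendSd = 3) {
  ax <- gazeRI:::lscvAxes(grid, H, extendSd)
  fhat <- naiveKde(points, H, ax$xs, ax$ys)
  intf2 <- sum(fhat^2) * ax$area
  N <- nrow(points)
  Hi <- solve(H)
  cst <- 1 / (2 * pi * sqrt(det(H)))
  loo <- numeric(N)
  for (i in seq_len(N)) {
    s <- 0
    for (j in seq_len(N)) {
      if (j == i) next
      d <- points[i, ] - points[j, ]
      s <- s + cst * exp(-0.5 * sum(d * (Hi %*% d)))
    }
    loo[i] <- s / (N - 1)
  }
  intf2 - 2 * mean(loo)
}
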