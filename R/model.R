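## Master-saliency decomposition: per frame, the group-level eye-position
## density map is regressed on the feature maps, Y ~ sum_k beta_k M_k, by
## L1-penalized least squares with BIC selection. The two-group model
## stacks both groups' responses and adds dummy-coded interaction columns,
## so interaction weights measure group differences in feature importance.

#' Stack feature maps and a density map into a regression design
#'
#' Maps are vectorized in row-major pixel order (row 1 left-to-right, then
#' row 2, ...) so that each pixel is one observation: the response is the
#' eye-position density and each feature map contributes one column.
#'
#' @param maps list of [FeatureMap()]s sharing one grid.
#' @param Y an [EyeDensityMap()] (or `h x w` matrix) on the same grid.
#' @param grid a [GridSpec()].
#' @return List with `y` (length `w*h` response), `X` (`w*h x K` matrix
#'   with feature-name columns), and `features`.
#' @export
stackMaps <- function(maps, Y, grid) {
  yv <- if (is(Y, "EyeDensityMap")) mapValues(Y) else Y
  assertGrid(yv, grid, "response density map")
  X <- vapply(maps, function(m) {
    assertGrid(mapValues(m), grid, mapName(m))
    vecRowMajor(mapValues(m))
  }, numeric(grid@w * grid@h))
  colnames(X) <- vapply(maps, mapName, "")
  list(y = vecRowMajor(yv), X = X, features = colnames(X))
}

#' Stack a two-group design with dummy-coded interactions
#'
#' The response is the treatment density stacked over the control density
#' (`2*w*h` rows, treatment block first). A group dummy (1 on the
#' treatment block, 0 on the control block) is interacted elementwise with
#' every feature column, giving `K` main-effect plus `K` interaction
#' columns (suffixed `":G"`). At an interaction weight of zero the two
#' blocks share one coefficient; otherwise the treatment block's effective
#' weight is main + interaction.
#'
#' @param mapsT,mapsC feature maps for the treatment and control group
#'   (usually identical: the stimulus is shared).
#' @param Yt,Yc the groups' [EyeDensityMap()]s.
#' @param grid a [GridSpec()].
#' @return List with `y`, `X`, `dummy`, `features` (main-effect names),
#'   `blocks` (row indices per block).
#' @export
stackMultigroup <- function(mapsT, mapsC, Yt, Yc, grid) {
  ft <- vapply(mapsT, mapName, "")
  fc <- vapply(mapsC, mapName, "")
  if (!identical(ft, fc))
    stop("treatment and control feature labels differ", call. = FALSE)
  st <- stackMaps(mapsT, Yt, grid)
  sc <- stackMaps(mapsC, Yc, grid)
  n <- length(st$y)
  y <- c(st$y, sc$y)
  dummy <- rep(c(1, 0), each = n)
  main <- rbind(st$X, sc$X)
  inter <- main * dummy
  colnames(inter) <- paste0(ft, ":G")
  list(y = y, X = cbind(main, inter), dummy = dummy, features = ft,
       blocks = list(treatment = seq_len(n), control = n + seq_len(n)))
}

#' Center and standardize a design per group
#'
#' Within each group block, every main-effect column and the response are
#' centered and scaled to unit standard deviation; interaction columns are
#' rebuilt from the standardized main columns afterwards. Standardizing
#' per group (rather than pooled) prevents a group with a stronger density
#' peak from dominating the shared scale. The uniform map is constant, so
#' after centering it carries no information: it is removed from the
#' penalized design and its weight is recovered from the fit's intercept
#' on the raw scale (see [fitFrame()]). Any other zero-variance column is
#' dropped with a warning.
#'
#' @param design result of [stackMaps()] or [stackMultigroup()].
#' @return List with standardized `y` and `X`, `features` kept, `scaling`
#'   (per block: means and SDs of response and kept columns), `dropped`.
#' @export
standardizeDesign <- function(design) {
  twoGroup <- !is.null(design$dummy)
  blocks <- if (twoGroup) design$blocks
            else list(all = seq_along(design$y))
  feats <- design$features
  keep <- setdiff(feats, "uniform")
  X <- design$X[, keep, drop = FALSE]
  if (twoGroup) {
    ## recover raw main columns (interaction cols are rebuilt below)
    X <- design$X[, keep, drop = FALSE]
  }
  y <- design$y
  scaling <- list()
  for (b in names(blocks)) {
    idx <- blocks[[b]]
    my <- mean(y[idx]); sy <- stats::sd(y[idx])
    ## a perfectly uniform response centers to all-zero; scale by 1 so the
    ## fit degenerates gracefully to zero weights
    y[idx] <- if (sy == 0) y[idx] - my else (y[idx] - my) / sy
    mM <- colMeans(X[idx, , drop = FALSE])
    sM <- apply(X[idx, , drop = FALSE], 2, stats::sd)
    for (k in seq_along(keep))
      if (sM[k] > 0) X[idx, k] <- (X[idx, k] - mM[k]) / sM[k]
    scaling[[b]] <- list(meanY = my, sdY = sy, meanM = mM, sdM = sM)
  }
  dropped <- character(0)
  zv <- vapply(seq_along(keep), function(k)
    any(vapply(names(blocks), function(b)
      scaling[[b]]$sdM[k] == 0, logical(1))), logical(1))
  if (any(zv)) {
    dropped <- keep[zv]
    warning("zero-variance feature column(s) dropped: ",
            paste(dropped, collapse = ", "))
    keep <- keep[!zv]
    X <- X[, keep, drop = FALSE]
  }
  if (twoGroup) {
    inter <- X * design$dummy
    colnames(inter) <- paste0(keep, ":G")
    X <- cbind(X, inter)
  }
  list(y = y, X = X, features = keep, scaling = scaling,
       dropped = dropped, twoGroup = twoGroup,
       blocks = blocks, hasUniform = "uniform" %in% feats)
}

#' L1-penalized least-squares path (coordinate descent)
#'
#' Solves `argmin_beta { ||y - X beta||^2 + lambda * sum |beta_k| }` for a
#' descending sequence of penalties, by cyclic coordinate descent on the
#' Gram matrix with warm starts. At `lambda = 0` the solution is the
#' ordinary least-squares estimate; at
#' `lambda >= 2 * max |X'y|` all weights are zero.
#'
#' @param X design matrix (standardized).
#' @param y response vector.
#' @param lambdas strictly descending penalty values (the final value may
#'   be 0).
#' @param tol convergence tolerance on coefficient updates.
#' @param maxit maximum coordinate-descent sweeps per penalty.
#' @return Matrix with one row per penalty and one column per feature;
#'   attribute `"lambdas"`.
#' @export
lassoPath <- function(X, y, lambdas, tol = 1e-12, maxit = 10000L) {
  if (is.unsorted(rev(lambdas), strictly = TRUE))
    stop("'lambdas' must be strictly descending", call. = FALSE)
  G <- crossprod(X)
  b <- drop(crossprod(X, y))
  K <- length(b)
  Gd <- diag(G)
  beta <- numeric(K)
  out <- matrix(0, length(lambdas), K,
                dimnames = list(NULL, colnames(X)))
  scaleRef <- max(abs(b) / Gd, 1e-300)
  Gb <- drop(G %*% beta)
  for (li in seq_along(lambdas)) {
    lam <- lambdas[li]
    if (lam == 0) {
      beta <- drop(solve(G, b))
      Gb <- drop(G %*% beta)
    } else {
      g <- lam / 2
      for (it in seq_len(maxit)) {
        delta <- 0
        for (k in seq_len(K)) {
          ## soft-threshold update; Gb tracks G %*% beta incrementally
          r <- b[k] - Gb[k] + Gd[k] * beta[k]
          newb <- if (r > g) (r - g) / Gd[k]
                  else if (r < -g) (r + g) / Gd[k] else 0
          d <- newb - beta[k]
          if (d != 0) {
            Gb <- Gb + G[, k] * d
            beta[k] <- newb
            d <- abs(d)
            if (d > delta) delta <- d
          }
        }
        if (delta < tol * scaleRef) break
      }
    }
    out[li, ] <- beta
  }
  attr(out, "lambdas") <- lambdas
  out
}

#' Penalty grid for the LASSO path
#'
#' 100 log-spaced values from `lambda_max` (the smallest penalty with an
#' all-zero solution, `2 * max |X'y|`) down to `lambda_max * 1e-4`, with 0
#' appended so the least-squares limit is always on the path.
#'
#' @param X,y standardized design and response.
#' @param nLambda number of log-spaced values.
#' @param ratio smallest-to-largest penalty ratio.
#' @return Descending numeric vector.
#' @export
lambdaGrid <- function(X, y, nLambda = 100, ratio = 1e-4) {
  lmax <- 2 * max(abs(crossprod(X, y)))
  if (lmax == 0) return(0)  # degenerate response: OLS solution is 0 anyway
  c(exp(seq(log(lmax), log(lmax * ratio), length.out = nLambda)), 0)
}

## Gaussian BIC of a fitted coefficient vector: -2 logL + K log n with
## sigma^2 = RSS / n and K = number of nonzero weights.
bicOf <- function(beta, X, y) {
  n <- length(y)
  rss <- sum((y - drop(X %*% beta))^2)
  K <- sum(abs(beta) > 0)
  n * log(2 * pi * rss / n) + n + K * log(n)
}

#' Select one fit from a LASSO path by BIC
#'
#' Computes, for every point on the path, the Gaussian BIC
#' `-2 log L + K log n` with error variance `RSS / n` and `K` the number
#' of nonzero weights (the unbiased LASSO degrees of freedom), and returns
#' the minimizer. Ties are broken toward the larger penalty (the sparser
#' model).
#'
#' @param path result of [lassoPath()].
#' @param X,y the design and response the path was fitted on.
#' @return List with `beta`, `lambda`, `bic`, `index`, and the full `bics`
#'   vector.
#' @export
selectByBic <- function(path, X, y) {
  lambdas <- attr(path, "lambdas")
  bics <- vapply(seq_len(nrow(path)),
                 function(i) bicOf(path[i, ], X, y), numeric(1))
  best <- which.min(bics)  # first minimum = largest lambda on ties
  list(beta = path[best, ], lambda = lambdas[best], bic = bics[best],
       index = best, bics = bics)
}

## Map standardized betas back to the raw density scale and recover the
## uniform map's weight from the per-block intercept. Returns a named
## vector matching the standardized naming (":G" = treatment - control on
## the raw scale).
rawScaleBetas <- function(beta, std, grid) {
  npx <- grid@w * grid@h
  feats <- std$features
  blocks <- names(std$scaling)
  rawPerBlock <- list()
  for (b in blocks) {
    sc <- std$scaling[[b]]
    bstd <- beta[feats]
    if (std$twoGroup && b == "treatment")
      bstd <- bstd + beta[paste0(feats, ":G")]
    braw <- bstd * sc$sdY / sc$sdM[feats]
    intercept <- sc$meanY - sum(braw * sc$meanM[feats])
    rawPerBlock[[b]] <- c(braw, uniform = unname(intercept * npx))
  }
  if (!std$twoGroup) return(rawPerBlock[[1]])
  con <- rawPerBlock$control
  tre <- rawPerBlock$treatment
  diffs <- tre - con
  names(diffs) <- paste0(names(con), ":G")
  c(con, diffs)
}

#' Fit the master-saliency model for one frame
#'
#' Builds the (single- or two-group) design from the frame's feature maps
#' and eye-position density map(s), standardizes per group, fits the LASSO
#' path and selects the penalty by BIC. Returns the selected weights on
#' the standardized scale, the raw-scale weights (with the uniform map's
#' weight recovered from the intercept), the penalty, BIC, and adjusted
#' R-squared with `p` equal to the number of nonzero weights.
#'
#' @param maps list of [FeatureMap()]s for this frame (include the uniform
#'   map to have its raw-scale weight reported).
#' @param Y the (treatment) group's [EyeDensityMap()].
#' @param grid a [GridSpec()].
#' @param Ycontrol optional control-group [EyeDensityMap()]; when present
#'   the two-group interaction model is fitted (treatment block first).
#' @param mapsControl optional control-group maps (e.g. smoothed with the
#'   control group's kernel); defaults to `maps`.
#' @param lambdas optional penalty sequence; default [lambdaGrid()].
#' @param nLambda,lambdaRatio passed to [lambdaGrid()].
#' @return A [FrameFit-class] object.
#' @examples
#' grid <- GridSpec(24, 18)
#' cb <- centerBiasMap(grid)
#' maps <- list(uniformMap(grid), cb)
#' Y <- EyeDensityMap(1, "all", mapValues(cb), 10L, diag(2))
#' fitFrame(maps, Y, grid)
#' @export
fitFrame <- function(maps, Y, grid, Ycontrol = NULL, mapsControl = NULL,
                     lambdas = NULL, nLambda = 100, lambdaRatio = 1e-4) {
  twoGroup <- !is.null(Ycontrol)
  design <- if (twoGroup)
    stackMultigroup(maps, mapsControl %||% maps, Y, Ycontrol, grid)
  else
    stackMaps(maps, Y, grid)
  std <- standardizeDesign(design)
  if (is.null(lambdas)) lambdas <- lambdaGrid(std$X, std$y, nLambda,
                                              lambdaRatio)
  path <- lassoPath(std$X, std$y, lambdas)
  sel <- selectByBic(path, std$X, std$y)
  n <- length(std$y)
  rss <- sum((std$y - drop(std$X %*% sel$beta))^2)
  tss <- sum((std$y - mean(std$y))^2)
  r2 <- if (tss == 0) 0 else 1 - rss / tss
  p <- sum(abs(sel$beta) > 0)
  r2adj <- 1 - (1 - r2) * (n - 1) / (n - p - 1)
  groups <- if (twoGroup) c(groupLabel(Y), groupLabel(Ycontrol))
            else groupLabel(Y)
  new("FrameFit",
      frameIndex = frameIndex(Y), beta = sel$beta,
      betaRaw = rawScaleBetas(sel$beta, std, grid),
      lambda = sel$lambda, bic = sel$bic, r2Adj = r2adj,
      nNonzero = as.integer(p), groups = groups, skipped = FALSE,
      reason = NA_character_)
}

## Explicit skip record.
skippedFrameFit <- function(frameIdx, reason, groups = character(0)) {
  new("FrameFit", frameIndex = as.integer(frameIdx),
      beta = numeric(0), betaRaw = numeric(0), lambda = NA_real_,
      bic = NA_real_, r2Adj = NA_real_, nNonzero = 0L,
      groups = groups, skipped = TRUE, reason = reason)
}

#' Fit the model over a sequence of frames
#'
#' Orchestrates the per-frame pipeline: estimate each group's eye-position
#' density map (LSCV bandwidth per frame and group, see
#' [densityForGroup()]), then fit the single- or two-group model. Frames
#' with too few fixations in any group, and frames whose required dynamic
#' maps are unavailable, become explicit skip records.
#'
#' @param gaze gaze table (see [preprocessGaze()]).
#' @param mapsByFrame list indexed by frame of lists of [FeatureMap()]s
#'   (entries may be `NULL` to request a skip, e.g. frame 1 when dynamic
#'   maps are in the model).
#' @param grid a [GridSpec()].
#' @param groups group labels; for two groups, treatment first. Default:
#'   sorted unique labels in `gaze`.
#' @param frames frames to fit (default: all with non-`NULL` maps).
#' @param bandwidths optional list `bandwidths[[frame]][[group]]` of 2x2
#'   matrices to reuse instead of LSCV selection.
#' @param kdeOptions list of arguments passed on to [densityForGroup()]
#'   (e.g. `nCandidates`, `policy`).
#' @param matchKernel smooth each group's feature maps with that group's
#'   selected KDE kernel before stacking (see [smoothFeatureMap()]); the
#'   default. `FALSE` regresses the smoothed density on the raw maps.
#' @param smoothedMaps optional precomputed kernel-matched maps,
#'   `smoothedMaps[[as.character(frame)]][[group]]`; used (with
#'   `bandwidths`) to avoid re-smoothing identical maps across
#'   permutations.
#' @param ... passed to [fitFrame()].
#' @return List with `fits` (list of [FrameFit-class]), `bandwidths`
#'   (list per frame per group), `groups`.
#' @export
fitFrames <- function(gaze, mapsByFrame, grid, groups = NULL,
                      frames = NULL, bandwidths = NULL,
                      kdeOptions = list(), matchKernel = TRUE,
                      smoothedMaps = NULL, ...) {
  assertGazeTable(gaze)
  if (is.null(groups)) groups <- defaultGroupOrder(unique(gaze$group))
  if (length(groups) > 2L)
    stop("at most two groups per fit; dummy-code additional groups pairwise",
         call. = FALSE)
  if (is.null(frames))
    frames <- which(!vapply(mapsByFrame, is.null, logical(1)))
  fits <- vector("list", length(frames))
  bwRec <- vector("list", length(frames))
  names(bwRec) <- as.character(frames)
  for (i in seq_along(frames)) {
    f <- frames[i]
    maps <- if (f <= length(mapsByFrame)) mapsByFrame[[f]] else NULL
    if (is.null(maps)) {
      fits[[i]] <- skippedFrameFit(f, "no feature maps for frame", groups)
      next
    }
    dens <- list()
    ok <- TRUE
    for (g in groups) {
      bw <- if (!is.null(bandwidths)) bandwidths[[as.character(f)]][[g]]
      d <- do.call(densityForGroup,
                   c(list(gaze = gaze, frameIdx = f, group = g,
                          grid = grid, bandwidth = bw), kdeOptions))
      if (is.null(d)) { ok <- FALSE; break }
      dens[[g]] <- d
    }
    if (!ok) {
      fits[[i]] <- skippedFrameFit(f, sprintf(
        "fewer than 2 fixations for group '%s'", g), groups)
      next
    }
    bwRec[[as.character(f)]] <- lapply(dens, bandwidthMatrix)
    gmaps <- if (!is.null(smoothedMaps) &&
                 !is.null(smoothedMaps[[as.character(f)]]))
      smoothedMaps[[as.character(f)]]
    else if (matchKernel)
      lapply(dens, function(d) lapply(maps, smoothFeatureMap,
                                      H = bandwidthMatrix(d), grid = grid))
    else
      stats::setNames(rep(list(maps), length(groups)), groups)
    fits[[i]] <- if (length(groups) == 2L)
      fitFrame(gmaps[[groups[1]]], dens[[groups[1]]], grid,
               Ycontrol = dens[[groups[2]]],
               mapsControl = gmaps[[groups[2]]], ...)
    else
      fitFrame(gmaps[[groups[1]]], dens[[groups[1]]], grid, ...)
  }
  list(fits = fits, bandwidths = bwRec, groups = groups)
}

#' Relative-importance curves from per-frame fits
#'
#' Collects each feature's weight over frames into per-group time series.
#' The control curve is the main-effect weight; the treatment curve is
#' main effect + interaction. Optional normalization divides each frame's
#' weight vector by the sum of its absolute values, so magnitudes are
#' comparable across frames.
#'
#' @param fits list of [FrameFit-class] objects (skips allowed).
#' @param normalize divide each frame's weights by `sum(|beta|)`.
#' @param scale `"standardized"` (default) or `"raw"` weights.
#' @return List with `frames`, `features`, `curves` (named list of
#'   frame-by-feature matrices, one per group), `skipped` (logical).
#' @export
riCurves <- function(fits, normalize = FALSE,
                     scale = c("standardized", "raw")) {
  scale <- match.arg(scale)
  skipped <- vapply(fits, isSkipped, logical(1))
  frames <- vapply(fits, frameIndex, integer(1))
  live <- fits[!skipped]
  if (!length(live)) stop("all frames skipped", call. = FALSE)
  b1 <- if (scale == "standardized") fitBeta(live[[1]])
        else fitBetaRaw(live[[1]])
  nm <- names(b1)
  feats <- nm[!grepl(":G$", nm)]
  twoGroup <- any(grepl(":G$", nm))
  groups <- live[[1]]@groups
  getb <- function(f) if (scale == "standardized") fitBeta(f)
                      else fitBetaRaw(f)
  liveFrames <- frames[!skipped]
  mk <- function(which) {
    m <- matrix(NA_real_, length(live), length(feats),
                dimnames = list(liveFrames, feats))
    for (i in seq_along(live)) {
      b <- getb(live[[i]])
      v <- if (which == "control") b[feats]
           else b[feats] + b[paste0(feats, ":G")]
      if (normalize) {
        s <- sum(abs(v))
        if (s > 0) v <- v / s
      }
      m[i, ] <- v
    }
    m
  }
  curves <- if (twoGroup)
    stats::setNames(list(mk("treatment"), mk("control")),
                    c(groups[1], groups[2]))
  else
    stats::setNames(list(mk("control")), groups[1])
  list(frames = liveFrames, features = feats, curves = curves,
       skipped = stats::setNames(skipped, frames))
}
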