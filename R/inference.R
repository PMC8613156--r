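#' Permute participant group labels
#'
#' Randomly reassigns the group labels of participants while preserving the
#' group sizes; all of a participant's samples keep moving together (the
#' participant is the exchangeable unit — permuting individual samples or
#' frames would break within-participant dependence). Uses the current RNG
#' state; seed via [set.seed()] or let [permutationTest()] drive it.
#'
#' @param gaze gaze table (see [preprocessGaze()]).
#' @return Gaze table with permuted group labels.
#' @export
permuteGroups <- function(gaze) {
  assertGazeTable(gaze)
  pg <- unique(gaze[, c("participant", "group")])
  newg <- sample(pg$group)
  names(newg) <- pg$participant
  gaze$group <- unname(newg[gaze$participant])
  gaze
}

#' Equidistant frame subset
#'
#' Evenly spaced 1-based frame indices over the modelable frames
#' (`firstFrame` to `nFrames`; the first stimulus frame is excluded by
#' default because dynamic maps are undefined there). With `count = 1` the
#' middle frame is returned.
#'
#' @param nFrames total number of frames.
#' @param count how many frames to select.
#' @param firstFrame first modelable frame (default 2).
#' @return Integer vector of length `count`; consecutive spacings differ
#'   by at most 1.
#' @export
equidistantFrames <- function(nFrames, count, firstFrame = 2L) {
  avail <- nFrames - firstFrame + 1L
  if (count > avail)
    stop(sprintf("requested %d frames but only %d available", count, avail),
         call. = FALSE)
  if (count == 1L) return(as.integer(round((firstFrame + nFrames) / 2)))
  as.integer(round(seq(firstFrame, nFrames, length.out = count)))
}

#' Permutation test for group-difference coefficients
#'
#' For each selected frame, fits the two-group model on the observed group
#' labels, then re-runs the full pipeline (density estimation,
#' standardization, penalized fit) under `P` random reassignments of
#' participants to groups, recording the interaction coefficients each
#' time. Two-sided p-values use the add-one correction
#' `(1 + #\{|permuted| >= |observed|\}) / (P + 1)`, so they lie in
#' `(0, 1]` and are never exactly zero. Deterministic for a fixed seed.
#'
#' By default each permutation re-selects KDE bandwidths and the penalty
#' exactly as the observed fit does (full pipeline symmetry). For large
#' `P` the selection steps can be frozen at their observed values with
#' `reuseBandwidths` / `freezeLambda`, a standard shortcut that permutes
#' only the group assignment.
#'
#' @param gaze gaze table with exactly two groups.
#' @param mapsByFrame per-frame lists of [FeatureMap()]s (see
#'   [fitFrames()]).
#' @param grid a [GridSpec()].
#' @param frames frames to test (e.g. [equidistantFrames()]).
#' @param P number of permutations.
#' @param seed RNG seed driving all permutations.
#' @param groups group labels, treatment first; default sorted unique.
#' @param reuseBandwidths reuse the observed fit's per-frame, per-group
#'   bandwidths inside permutations instead of re-selecting by LSCV.
#' @param freezeLambda refit permutations at the observed frame's selected
#'   penalty instead of re-running BIC selection.
#' @param kdeOptions,... passed to [fitFrames()].
#' @return List with `results` (one [PermutationResult-class] per
#'   non-skipped frame), `observedFits`, `skippedFrames`.
#' @export
permutationTest <- function(gaze, mapsByFrame, grid, frames, P = 1000,
                            seed = 1, groups = NULL,
                            reuseBandwidths = FALSE, freezeLambda = FALSE,
                            kdeOptions = list(), ...) {
  assertGazeTable(gaze)
  if (is.null(groups)) groups <- defaultGroupOrder(unique(gaze$group))
  if (length(groups) != 2L)
    stop("permutation test needs exactly two groups", call. = FALSE)
  if (P < 1L || !length(frames)) stop("P >= 1 and non-empty frames required",
                                      call. = FALSE)
  ## only the tested frames' samples matter; participants' group labels
  ## are shared across frames, so permuting the subset is equivalent
  gaze <- gaze[gaze$frameIndex %in% frames, , drop = FALSE]
  obs <- fitFrames(gaze, mapsByFrame, grid, groups = groups,
                   frames = frames, kdeOptions = kdeOptions, ...)
  skipped <- vapply(obs$fits, isSkipped, logical(1))
  liveIdx <- which(!skipped)
  if (!length(liveIdx))
    return(list(results = list(), observedFits = obs$fits,
                skippedFrames = frames[skipped]))
  interNames <- grep(":G$", names(fitBeta(obs$fits[[liveIdx[1]]])),
                     value = TRUE)
  K <- length(interNames)
  ## with frozen bandwidths the kernel-matched maps are identical across
  ## permutations: compute them once
  preSmoothed <- NULL
  if (reuseBandwidths) {
    preSmoothed <- lapply(as.character(frames[liveIdx]), function(fc) {
      maps <- mapsByFrame[[as.integer(fc)]]
      lapply(obs$bandwidths[[fc]], function(H)
        lapply(maps, smoothFeatureMap, H = H, grid = grid))
    })
    names(preSmoothed) <- as.character(frames[liveIdx])
  }
  perm <- lapply(liveIdx, function(i) matrix(
    NA_real_, P, K, dimnames = list(NULL, interNames)))
  names(perm) <- as.character(frames[liveIdx])
  set.seed(seed)
  for (p in seq_len(P)) {
    gp <- permuteGroups(gaze)
    for (j in seq_along(liveIdx)) {
      i <- liveIdx[j]
      f <- frames[i]
      lam <- if (freezeLambda) fitLambda(obs$fits[[i]]) else NULL
      pf <- fitFrames(gp, mapsByFrame, grid, groups = groups, frames = f,
                      bandwidths = if (reuseBandwidths) obs$bandwidths,
                      smoothedMaps = preSmoothed,
                      kdeOptions = kdeOptions,
                      lambdas = if (!is.null(lam))
                        sort(unique(c(lam)), decreasing = TRUE),
                      ...)$fits[[1]]
      if (!isSkipped(pf))
        perm[[j]][p, ] <- fitBeta(pf)[interNames]
    }
  }
  results <- lapply(seq_along(liveIdx), function(j) {
    i <- liveIdx[j]
    pm <- perm[[j]][stats::complete.cases(perm[[j]]), , drop = FALSE]
    obsB <- fitBeta(obs$fits[[i]])[interNames]
    pv <- vapply(seq_len(K), function(k) {
      (1 + sum(abs(pm[, k]) >= abs(obsB[k]))) / (nrow(pm) + 1)
    }, numeric(1))
    names(pv) <- interNames
    new("PermutationResult", frameIndex = as.integer(frames[i]),
        observed = obsB, permuted = pm, pValues = pv,
        seed = as.integer(seed))
  })
  names(results) <- as.character(frames[liveIdx])
  list(results = results, observedFits = obs$fits,
       skippedFrames = frames[skipped])
}

#' Quartile summary of permutation distributions
#'
#' Per frame and feature: quartiles of the permuted group-difference
#' coefficients plus the observed value and p-value, the numbers behind a
#' box-plot display of the test.
#'
#' @param results list component `results` of [permutationTest()].
#' @return data.frame with one row per frame and feature.
#' @export
permutationSummary <- function(results) {
  do.call(rbind, lapply(results, function(r) {
    q <- apply(permutedDiffs(r), 2, stats::quantile,
               probs = c(0.25, 0.5, 0.75))
    data.frame(frameIndex = frameIndex(r),
               feature = sub(":G$", "", colnames(permutedDiffs(r))),
               q25 = q[1, ], q50 = q[2, ], q75 = q[3, ],
               observed = observedDiff(r), pValue = pValues(r),
               row.names = NULL)
  }))
}
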