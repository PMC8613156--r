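## Small design fixture: K maps on a small grid plus a response built as a
## known mixture.
modelFixture <- function(seed = 1, w = 24, h = 18) {
  set.seed(seed)
  grid <- GridSpec(w, h)
  maps <- list(uniformMap(grid), centerBiasMap(grid),
               aoiMap(rbind(c(2, 2), c(10, 2), c(10, 9), c(2, 9)),
                      grid, "one"),
               aoiMap(rbind(c(14, 10), c(22, 10), c(22, 16), c(14, 16)),
                      grid, "two"),
               randomFeatureMap(grid, "custom:tex"))
  list(grid = grid, maps = maps)
}

densityFrom <- function(values, frameIdx = 2L, group = "g", n = 50L) {
  EyeDensityMap(frameIdx, group, values, n, diag(c(4, 4)))
}

test_that("stacking vectorizes maps in row-major pixel order", {
  fx <- modelFixture()
  Y <- densityFrom(mapValues(fx$maps[[2]]))
  s <- stackMaps(fx$maps, Y, fx$grid)
  expect_equal(dim(s$X), c(24 * 18, 5))
  expect_equal(s$features, vapply(fx$maps, mapName, ""))
  ## row-major: first w entries are the first pixel row
  expect_equal(s$y[1:24], mapValues(Y)[1, ])
  ## unstack then restack is the identity
  expect_equal(gazeRI:::unvecRowMajor(s$y, fx$grid), mapValues(Y))
  expect_error(stackMaps(fx$maps, matrix(1, 5, 5), fx$grid), "shape")
})

test_that("reference-resolution designs have the expected row counts", {
  grid <- GridSpec(720, 576)
  u <- uniformMap(grid)
  cb <- centerBiasMap(grid)
  Y <- densityFrom(mapValues(cb), group = "treatment")
  s1 <- stackMaps(list(u, cb), Y, grid)
  expect_equal(nrow(s1$X), 414720)
  Yc <- densityFrom(mapValues(u), group = "control")
  s2 <- stackMultigroup(list(u, cb), list(u, cb), Y, Yc, grid)
  expect_equal(nrow(s2$X), 829440)
  expect_equal(length(s2$y), 2 * 414720)
  expect_equal(colnames(s2$X),
               c("uniform", "center_bias", "uniform:G", "center_bias:G"))
  ## dummy: treatment block first
  expect_equal(unique(s2$dummy[1:414720]), 1)
  expect_equal(unique(s2$dummy[414721:829440]), 0)
})

test_that("standardization gives zero-mean unit-SD columns per block", {
  fx <- modelFixture(2)
  set.seed(2)
  vT <- normalizeMap(0.6 * mapValues(fx$maps[[3]]) +
                     0.4 * mapValues(fx$maps[[2]]))
  vC <- normalizeMap(0.3 * mapValues(fx$maps[[3]]) +
                     0.7 * mapValues(fx$maps[[2]]))
  s <- stackMultigroup(fx$maps, fx$maps,
                       densityFrom(vT, group = "treatment"),
                       densityFrom(vC, group = "control"), fx$grid)
  std <- standardizeDesign(s)
  for (b in std$blocks) {
    expect_equal(mean(std$y[b]), 0, tolerance = 1e-12)
    expect_equal(sd(std$y[b]), 1, tolerance = 1e-12)
    for (k in std$features) {
      expect_equal(mean(std$X[b, k]), 0, tolerance = 1e-12)
      expect_equal(sd(std$X[b, k]), 1, tolerance = 1e-12)
    }
  }
  ## uniform is removed from the penalized design (intercept policy)
  expect_false("uniform" %in% colnames(std$X))
  ## interactions are the standardized main columns gated by the dummy
  expect_equal(std$X[, "center_bias:G"], std$X[, "center_bias"] * s$dummy)
})

test_that("lasso path reduces to soft-thresholding on orthonormal designs", {
  set.seed(4)
  for (rep in 1:100) {
    n <- sample(20:60, 1); K <- sample(2:6, 1)
    X <- qr.Q(qr(matrix(rnorm(n * K), n, K)))
    y <- rnorm(n)
    ols <- drop(crossprod(X, y))
    lambdas <- sort(runif(4, 0.01, 2 * max(abs(ols))), decreasing = TRUE)
    path <- lassoPath(X, y, lambdas)
    for (i in seq_along(lambdas)) {
      thr <- sign(ols) * pmax(abs(ols) - lambdas[i] / 2, 0)
      expect_lt(max(abs(path[i, ] - thr)), 1e-8)
    }
  }
})

test_that("lasso limits: lambda 0 is OLS, lambda above the KKT bound is zero", {
  set.seed(6)
  n <- 200; K <- 5
  X <- scale(matrix(rnorm(n * K), n, K))
  y <- drop(X %*% c(2, -1, 0, 0.5, 0)) + rnorm(n)
  y <- y - mean(y)
  lmax <- 2 * max(abs(crossprod(X, y)))
  path <- lassoPath(X, y, c(2 * lmax, lmax, 1, 0))
  ols <- drop(solve(crossprod(X), crossprod(X, y)))
  expect_lt(max(abs(path[4, ] - ols)), 1e-8)
  expect_equal(unname(path[1, ]), rep(0, K))
  expect_equal(unname(path[2, ]), rep(0, K))
  expect_error(lassoPath(X, y, c(1, 2)), "descending")
})

test_that("lasso path agrees with glmnet on a correlated design", {
  skip_if_not_installed("glmnet")
  set.seed(14)
  n <- 500; K <- 6
  Z <- matrix(rnorm(n * K), n, K)
  X <- scale(Z %*% chol(0.5 * diag(K) + 0.5))
  y <- drop(scale(drop(X %*% c(1.5, 0, -0.8, 0, 0.3, 0)) + rnorm(n)))
  lam <- c(40, 10, 2)
  mine <- lassoPath(X, y, lam)
  ## glmnet objective is (1/2n)||y - Xb||^2 + lambda |b|, so the penalty
  ## scale differs by 2n from ||y - Xb||^2 + lambda |b|
  gn <- glmnet::glmnet(X, y, lambda = lam / (2 * n), standardize = FALSE,
                       intercept = FALSE, thresh = 1e-14)
  expect_lt(max(abs(t(as.matrix(gn$beta)) - mine)), 1e-6)
})

test_that("BIC prefers the sparse truth over an overfit model", {
  set.seed(10)
  hits <- 0
  for (rep in 1:20) {
    n <- 400; K <- 6
    X <- scale(matrix(rnorm(n * K), n, K))
    beta0 <- c(1.2, 0, 0, -0.9, 0, 0)
    y <- drop(X %*% beta0) + rnorm(n, sd = 0.5)
    y <- y - mean(y)
    ## path holding the true-support OLS fit and the overfit full OLS fit
    sparse <- numeric(K)
    sparse[c(1, 4)] <- drop(solve(crossprod(X[, c(1, 4)]),
                                  crossprod(X[, c(1, 4)], y)))
    full <- drop(solve(crossprod(X), crossprod(X, y)))
    path <- rbind(sparse, full)
    attr(path, "lambdas") <- c(1, 0)
    sel <- selectByBic(path, X, y)
    if (sel$index == 1) hits <- hits + 1
    ## independent BIC formula via dnorm log-likelihood
    rss <- sum((y - drop(X %*% sel$beta))^2)
    s2 <- rss / n
    ll <- sum(stats::dnorm(y, drop(X %*% sel$beta), sqrt(s2), log = TRUE))
    bicOracle <- -2 * ll + sum(abs(sel$beta) > 0) * log(n)
    expect_lt(abs(sel$bic - bicOracle), 1e-8)
  }
  expect_gte(hits, 18)
  ## single-element path returned unchanged
  p1 <- lassoPath(diag(3), c(1, 2, 3), 0.5)
  s1 <- selectByBic(p1, diag(3), c(1, 2, 3))
  expect_equal(s1$beta, p1[1, ])
  expect_equal(s1$lambda, 0.5)
})

test_that("irrelevant features are zeroed monotonically along the path", {
  set.seed(12)
  n <- 300; K <- 6
  irrelevant <- 3:6
  zeroCounts <- replicate(20, {
    X <- scale(matrix(rnorm(n * K), n, K))
    y <- drop(X %*% c(1.5, -1, 0, 0, 0, 0)) + rnorm(n)
    y <- y - mean(y)
    lambdas <- lambdaGrid(X, y, nLambda = 30)
    path <- lassoPath(X, y, lambdas)
    ## lambdas descend along the path: zeroed-irrelevant counts must be
    ## non-increasing down the path (non-decreasing in lambda)
    rowSums(path[, irrelevant, drop = FALSE] == 0)
  })
  expect_true(all(apply(zeroCounts, 2, function(z) all(diff(z) <= 0))))
})

test_that("two-group OLS fit decomposes into the per-group OLS fits", {
  fx <- modelFixture(20)
  set.seed(20)
  noiseT <- matrix(rexp(24 * 18), 18, 24)
  noiseC <- matrix(rexp(24 * 18), 18, 24)
  vT <- normalizeMap(0.5 * mapValues(fx$maps[[3]]) +
                     0.3 * mapValues(fx$maps[[2]]) + 0.2 * noiseT / sum(noiseT))
  vC <- normalizeMap(0.6 * mapValues(fx$maps[[2]]) +
                     0.4 * mapValues(fx$maps[[4]]) + 0.2 * noiseC / sum(noiseC))
  Yt <- densityFrom(vT, group = "treatment")
  Yc <- densityFrom(vC, group = "control")
  ## stacked fit at lambda = 0
  both <- fitFrame(fx$maps, Yt, fx$grid, Ycontrol = Yc, lambdas = 0)
  ## separate per-group OLS oracles via lm() on standardized columns
  sepFit <- function(Y) {
    s <- stackMaps(fx$maps, Y, fx$grid)
    std <- standardizeDesign(s)
    coef(stats::lm(std$y ~ std$X - 1))
  }
  bT <- sepFit(Yt); bC <- sepFit(Yc)
  feats <- names(fitBeta(both))
  main <- feats[!grepl(":G$", feats)]
  expect_lt(max(abs(fitBeta(both)[main] - bC)), 1e-8)
  expect_lt(max(abs((fitBeta(both)[main] +
                     fitBeta(both)[paste0(main, ":G")]) - bT)), 1e-8)
})

test_that("noiseless mixtures are recovered exactly", {
  fx <- modelFixture(30)
  v <- 0.7 * mapValues(fx$maps[[3]]) + 0.3 * mapValues(fx$maps[[2]])
  fit <- fitFrame(fx$maps, densityFrom(v), fx$grid)
  expect_gt(fitR2Adj(fit), 1 - 1e-6)
  raw <- fitBetaRaw(fit)
  expect_equal(unname(raw["aoi:one"]), 0.7, tolerance = 1e-6)
  expect_equal(unname(raw["center_bias"]), 0.3, tolerance = 1e-6)
  expect_equal(unname(abs(raw[c("aoi:two", "custom:tex")])), c(0, 0),
               tolerance = 1e-6)
})

test_that("a uniform response yields zero weights and zero R2", {
  fx <- modelFixture(31)
  fit <- fitFrame(fx$maps, densityFrom(mapValues(fx$maps[[1]])), fx$grid)
  expect_equal(unname(fitBeta(fit)), rep(0, length(fitBeta(fit))))
  expect_equal(fitR2Adj(fit), 0, tolerance = 1e-9)
})

test_that("raw-scale weights reproduce the standardized fit's predictions", {
  fx <- modelFixture(32)
  set.seed(32)
  noise <- matrix(rexp(24 * 18), 18, 24)
  v <- normalizeMap(0.55 * mapValues(fx$maps[[4]]) +
                    0.25 * mapValues(fx$maps[[2]]) + 0.2 * noise / sum(noise))
  fit <- fitFrame(fx$maps, densityFrom(v), fx$grid)
  raw <- fitBetaRaw(fit)
  pred <- raw["uniform"] * gazeRI:::vecRowMajor(mapValues(fx$maps[[1]]))
  for (m in fx$maps[-1])
    pred <- pred + raw[mapName(m)] * gazeRI:::vecRowMajor(mapValues(m))
  ## compare to the standardized prediction mapped back to the raw scale
  s <- stackMaps(fx$maps, densityFrom(v), fx$grid)
  std <- standardizeDesign(s)
  predStd <- drop(std$X %*% fitBeta(fit)) * std$scaling[[1]]$sdY +
    std$scaling[[1]]$meanY
  expect_lt(max(abs(pred - predStd)), 1e-8)
})

test_that("irrelevant features are shrunk away on estimated densities", {
  ## fixations from 2 of 5 maps; support of the BIC-selected fit should
  ## recover the true pair in most replicates
  fx <- modelFixture(40)
  hits <- 0
  reps <- 10
  for (rep in seq_len(reps)) {
    set.seed(100 + rep)
    mix <- 0.6 * mapValues(fx$maps[[3]]) + 0.4 * mapValues(fx$maps[[2]])
    pts <- gazeRI:::samplePixelMixture(mix, 2000)
    H <- selectBandwidth(pts, fx$grid, nCandidates = 9)
    Y <- gaussianKde(pts, H, fx$grid, 2L, "g", renormalize = TRUE)
    fit <- fitFrame(fx$maps, Y, fx$grid)
    supp <- names(which(abs(fitBeta(fit)) > 0))
    if (setequal(supp, c("aoi:one", "center_bias"))) hits <- hits + 1
  }
  expect_gte(hits, 0.8 * reps)
})

test_that("ri curves assemble group weights over frames", {
  fx <- modelFixture(50)
  set.seed(50)
  fits <- list()
  for (f in 2:4) {
    noise <- matrix(rexp(24 * 18), 18, 24)
    vT <- normalizeMap(0.6 * mapValues(fx$maps[[3]]) + 0.3 * mapValues(fx$maps[[2]]) +
                       0.1 * noise / sum(noise))
    vC <- normalizeMap(0.5 * mapValues(fx$maps[[2]]) + 0.5 * mapValues(fx$maps[[4]]))
    fits[[length(fits) + 1]] <-
      fitFrame(fx$maps, densityFrom(vT, f, "treatment"), fx$grid,
               Ycontrol = densityFrom(vC, f, "control"), lambdas = 0)
  }
  fits <- c(fits, list(gazeRI:::skippedFrameFit(5L, "test skip",
                                                c("treatment", "control"))))
  ri <- riCurves(fits)
  expect_equal(ri$frames, c(2L, 3L, 4L))
  expect_true(all(c("treatment", "control") %in% names(ri$curves)))
  ## control curve equals main-effect betas verbatim
  feats <- ri$features
  expect_equal(unname(ri$curves$control[1, ]),
               unname(fitBeta(fits[[1]])[feats]))
  expect_equal(unname(ri$curves$treatment[2, ]),
               unname(fitBeta(fits[[2]])[feats] +
                      fitBeta(fits[[2]])[paste0(feats, ":G")]))
  expect_equal(unname(ri$skipped), c(FALSE, FALSE, FALSE, TRUE))
  ## treatment curve equals the treatment-only OLS fit at lambda 0
  vT1 <- normalizeMap(0.6 * mapValues(fx$maps[[3]]) + 0.4 * mapValues(fx$maps[[2]]))
  only <- fitFrame(fx$maps, densityFrom(vT1, 2L, "treatment"), fx$grid,
                   lambdas = 0)
  both <- fitFrame(fx$maps, densityFrom(vT1, 2L, "treatment"), fx$grid,
                   Ycontrol = densityFrom(
                     mapValues(fx$maps[[2]]), 2L, "control"), lambdas = 0)
  riB <- riCurves(list(both))
  expect_lt(max(abs(riB$curves$treatment[1, ] - fitBeta(only)[feats])),
            1e-8)
  ## normalization divides by the absolute weight sum
  rn <- riCurves(list(both), normalize = TRUE)
  expect_equal(sum(abs(rn$curves$treatment[1, ])), 1)
})

test_that("normalized single-frame weights split proportionally", {
  ## betas (1, 1) normalize to (0.5, 0.5)
  f <- new("FrameFit", frameIndex = 2L,
           beta = c(a = 1, b = 1), betaRaw = c(a = 1, b = 1, uniform = 0),
           lambda = 0, bic = 0, r2Adj = 0.5, nNonzero = 2L,
           groups = "g", skipped = FALSE, reason = NA_character_)
  ri <- riCurves(list(f), normalize = TRUE)
  expect_equal(unname(ri$curves$g[1, ]), c(0.5, 0.5))
})
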