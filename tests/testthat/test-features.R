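test_that("normalizeMap rescales proportionally and rejects degenerate input", {
  expect_equal(normalizeMap(matrix(1, 2, 2)), matrix(0.25, 2, 2))
  expect_equal(normalizeMap(matrix(c(2, 0, 0, 2), 2)),
               matrix(c(0.5, 0, 0, 0.5), 2))
  expect_error(normalizeMap(matrix(0, 2, 2)), "degenerate")
  expect_error(normalizeMap(matrix(c(-1, 2, 2, 2), 2)), "negative")
})

test_that("uniform map puts 1/(w*h) everywhere", {
  m <- uniformMap(GridSpec(2, 2))
  expect_equal(mapValues(m), matrix(0.25, 2, 2))
  expect_equal(sum(mapValues(m)), 1)
  big <- uniformMap(GridSpec(720, 576))
  expect_equal(mapValues(big)[1, 1], 1 / 414720)
  expect_equal(sum(mapValues(big)), 1, tolerance = 1e-12)
})

test_that("center bias is a symmetric Gaussian peaked at the center", {
  grid <- GridSpec(20, 14)
  v <- mapValues(centerBiasMap(grid))
  expect_equal(v, v[, ncol(v):1], tolerance = 1e-12)  # horizontal mirror
  expect_equal(v, v[nrow(v):1, ], tolerance = 1e-12)  # vertical mirror
  am <- which(v == max(v), arr.ind = TRUE)
  ## 4-fold tie at the exact center of an even grid
  expect_true(all(am[, "row"] %in% c(7, 8)) && all(am[, "col"] %in% c(10, 11)))
  expect_error(centerBiasMap(grid, sigmaX = -1), "positive")
})

test_that("center bias defaults divide stimulus dimensions by 12", {
  grid <- GridSpec(720, 576)
  expect_equal(mapValues(centerBiasMap(grid)),
               mapValues(centerBiasMap(grid, sigmaX = 60, sigmaY = 48)))
})

test_that("aoi map rasterizes polygons at pixel centers", {
  grid <- GridSpec(6, 6)
  sq <- rbind(c(1, 1), c(3, 1), c(3, 3), c(1, 3))
  v <- mapValues(aoiMap(sq, grid, "sq"))
  expect_equal(sum(v > 0), 4)
  expect_equal(v[2:3, 2:3], matrix(0.25, 2, 2))
  full <- rbind(c(0, 0), c(6, 0), c(6, 6), c(0, 6))
  expect_equal(mapValues(aoiMap(full, grid, "all")),
               mapValues(uniformMap(grid)))
  expect_error(aoiMap(rbind(c(0, 0), c(0.2, 0), c(0.1, 0.2)),
                      GridSpec(50, 50), "tiny"), "degenerate")
  expect_error(aoiMap(sq[1:2, ], grid), "vertices")
})

test_that("aoi rasterization agrees with an independent point-in-polygon test", {
  skip_if_not_installed("mgcv")
  set.seed(42)
  for (rep in 1:100) {
    w <- sample(5:50, 1); h <- sample(5:50, 1)
    grid <- GridSpec(w, h)
    nv <- sample(3:8, 1)
    ## star-shaped polygon: random radii around a random center
    cx <- runif(1, w * 0.3, w * 0.7); cy <- runif(1, h * 0.3, h * 0.7)
    ang <- sort(runif(nv, 0, 2 * pi))
    rad <- runif(nv, 0.15, 0.45)
    vx <- pmin(pmax(cx + rad * w * cos(ang), 0), w)  # pre-clip to the
    vy <- pmin(pmax(cy + rad * h * sin(ang), 0), h)  # grid box
    memb <- matrix(FALSE, h, w)
    ok <- tryCatch({
      memb <- mapValues(aoiMap(cbind(vx, vy), grid, "r")) > 0
      TRUE
    }, error = function(e) FALSE)  # polygon may cover zero pixels
    pts <- expand.grid(y = seq_len(h) - 0.5, x = seq_len(w) - 0.5)
    oracle <- mgcv::in.out(cbind(c(vx, vx[1]), c(vy, vy[1])),
                           cbind(pts$x, pts$y))
    if (!ok) {
      expect_equal(sum(oracle), 0)
    } else {
      expect_equal(as.vector(memb), as.vector(oracle))
    }
  }
})

test_that("static saliency is deterministic, normalized, and contrast-seeking", {
  grid <- GridSpec(48, 36)
  flat <- matrix(0.5, 36, 48)
  expect_equal(mapValues(staticSaliencyMap(flat, grid)),
               mapValues(uniformMap(grid)), tolerance = 1e-9)
  img <- matrix(0.3, 36, 48)
  img[15:22, 20:27] <- 0.95
  m1 <- staticSaliencyMap(img, grid)
  m2 <- staticSaliencyMap(img, grid)
  expect_identical(mapValues(m1), mapValues(m2))
  expect_equal(sum(mapValues(m1)), 1, tolerance = 1e-9)
  am <- which(mapValues(m1) == max(mapValues(m1)), arr.ind = TRUE)[1, ]
  expect_true(am["row"] >= 12 && am["row"] <= 25 &&
              am["col"] >= 17 && am["col"] <= 30)
  expect_error(staticSaliencyMap(matrix(0.5, 10, 10), grid), "shape")
})

test_that("dynamic saliency highlights inter-frame motion", {
  grid <- GridSpec(48, 36)
  bg <- matrix(0.3, 36, 48)
  f0 <- bg; f0[10:17, 8:15] <- 0.9
  f1 <- bg; f1[10:17, 13:20] <- 0.9   # translated 5 px right
  m <- dynamicSaliencyMap(f1, f0, grid, frameIndex = 2L)
  expect_equal(sum(mapValues(m)), 1, tolerance = 1e-9)
  am <- which(mapValues(m) == max(mapValues(m)), arr.ind = TRUE)[1, ]
  ## union bbox rows 10:17, cols 8:20, dilated by the smoothing radius
  expect_true(am["row"] >= 5 && am["row"] <= 22 &&
              am["col"] >= 3 && am["col"] <= 25)
  expect_error(dynamicSaliencyMap(f1, f1, grid, frameIndex = 2L),
               "degenerate")
  expect_warning(
    u <- dynamicSaliencyMap(f1, f1, grid, frameIndex = 2L,
                            onStatic = "uniform"), "uniform")
  expect_equal(mapValues(u), mapValues(uniformMap(grid)))
  expect_error(dynamicSaliencyMap(f1, f0, grid, frameIndex = 1L), "first")
})

test_that("external saliency grids load, clip, and validate shape", {
  grid <- GridSpec(8, 5)
  tmp <- withr::local_tempfile(fileext = ".csv")
  u <- matrix(1 / 40, 5, 8)
  write.table(u, tmp, sep = ",", row.names = FALSE, col.names = FALSE)
  m <- loadExternalSaliency(tmp, grid, "ext")
  expect_equal(mapValues(m), mapValues(uniformMap(grid)))
  expect_equal(mapName(m), "custom:ext")
  neg <- u; neg[1, 1] <- -0.5
  write.table(neg, tmp, sep = ",", row.names = FALSE, col.names = FALSE)
  expect_warning(m2 <- loadExternalSaliency(tmp, grid, "ext"), "clipped")
  expect_equal(mapValues(m2)[1, 1], 0)
  expect_equal(sum(mapValues(m2)), 1, tolerance = 1e-12)
  write.table(u[, 1:5], tmp, sep = ",", row.names = FALSE,
              col.names = FALSE)
  expect_error(loadExternalSaliency(tmp, grid, "ext"), "expected")
})

test_that("every constructed feature map is a density", {
  set.seed(7)
  grid <- GridSpec(30, 24)
  img1 <- matrix(runif(24 * 30), 24, 30)
  img2 <- img1 + matrix(rnorm(24 * 30, sd = 0.05), 24, 30)
  img2 <- pmin(pmax(img2, 0), 1)
  maps <- list(uniformMap(grid), centerBiasMap(grid),
               staticSaliencyMap(img1, grid),
               dynamicSaliencyMap(img2, img1, grid, frameIndex = 2L),
               aoiMap(rbind(c(3, 3), c(20, 5), c(12, 18)), grid, "t"))
  for (i in 1:20) maps <- c(maps, list(randomFeatureMap(grid)))
  for (m in maps) {
    expect_gte(min(mapValues(m)), 0)
    expect_equal(sum(mapValues(m)), 1, tolerance = 1e-9)
  }
})
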