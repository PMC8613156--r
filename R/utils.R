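## Internal helpers shared across modules.

## Continuous centers of pixel columns (x) and rows (y); 1-based matrix
## entry [i, j] has center (j - 0.5, i - 0.5).
pixelCentersX <- function(grid) seq_len(grid@w) - 0.5
pixelCentersY <- function(grid) seq_len(grid@h) - 0.5

assertGrid <- function(values, grid, what = "grid") {
  d <- dim(values)
  if (is.null(d) || d[1] != grid@h || d[2] != grid@w)
    stop(sprintf("%s has shape %s, expected %d x %d (h x w)", what,
                 paste(d, collapse = " x "), grid@h, grid@w), call. = FALSE)
  invisible(TRUE)
}

## Vectorize an h x w map in row-major pixel order (row 1 left-to-right,
## then row 2, ...). This order is the package-wide stacking convention.
vecRowMajor <- function(m) as.vector(t(m))

## Inverse of vecRowMajor.
unvecRowMajor <- function(v, grid) matrix(v, nrow = grid@h, ncol = grid@w,
                                          byrow = TRUE)

## Treatment-first ordering for group labels: the first group occupies the
## dummy = 1 block of the two-group design. A label literally named
## "treatment" is put first; otherwise labels are sorted.
defaultGroupOrder <- function(groups) {
  groups <- sort(groups)
  if ("treatment" %in% groups)
    groups <- c("treatment", setdiff(groups, "treatment"))
  groups
}

## Columns of a gaze table; validator used at module boundaries.
assertGazeTable <- function(gaze) {
  need <- c("participant", "group", "frameIndex", "xStim", "yStim")
  if (!is.data.frame(gaze) || !all(need %in% names(gaze)))
    stop("gaze table must be a data.frame with columns ",
         paste(need, collapse = ", "), call. = FALSE)
  dup <- anyDuplicated(gaze[, c("participant", "frameIndex")])
  if (dup)
    stop("gaze table has more than one row per participant per frame",
         call. = FALSE)
  invisible(TRUE)
}
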