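# Quantitative evaluation of reconstructed parameter maps.

#' Mean relative absolute error (percent)
#'
#' `100 * mean(|rec - ref| / ref)` over the mask.  By default the mask is
#' every voxel with positive reference value (background excluded).
#'
#' @param rec,ref maps of identical shape (magnitudes are taken).
#' @param mask logical array selecting the evaluated voxels.
#' @return percent error (scalar).
#' @export
mrae <- function(rec, ref, mask = Re(ref) > 0) {
  rec <- abs(rec); ref <- abs(ref)
  stopifnot(all(dim(rec) == dim(ref)))
  if (!any(mask)) stop("empty evaluation mask")
  if (any(ref[mask] <= 0)) stop("reference must be positive on the mask")
  100 * mean(abs(rec[mask] - ref[mask]) / ref[mask])
}

# 2D moving-average over w x w windows, valid region only, via cumulated
# sums; x is a numeric matrix
box_mean2d <- function(x, w) {
  n1 <- nrow(x); n2 <- ncol(x)
  cs <- apply(apply(x, 2, cumsum), 1, cumsum)  # transposed cumulative sums
  cs <- t(cs)
  csp <- matrix(0, n1 + 1, n2 + 1)
  csp[-1, -1] <- cs
  i <- seq_len(n1 - w + 1); j <- seq_len(n2 - w + 1)
  (csp[i + w, j + w, drop = FALSE] - csp[i, j + w, drop = FALSE] -
     csp[i + w, j, drop = FALSE] + csp[i, j, drop = FALSE]) / (w * w)
}

ssim_slice <- function(a, b, w, c1, c2) {
  n <- w * w
  covn <- n / (n - 1)               # sample-covariance normalization
  ua <- box_mean2d(a, w); ub <- box_mean2d(b, w)
  uaa <- box_mean2d(a * a, w); ubb <- box_mean2d(b * b, w)
  uab <- box_mean2d(a * b, w)
  va <- covn * (uaa - ua^2); vb <- covn * (ubb - ub^2)
  vab <- covn * (uab - ua * ub)
  mean(((2 * ua * ub + c1) * (2 * vab + c2)) /
         ((ua^2 + ub^2 + c1) * (va + vb + c2)))
}

#' Structural similarity index of volumes
#'
#' Mean SSIM with a uniform `7 x 7` window and the standard stabilizing
#' constants `C1 = (0.01 L)^2`, `C2 = (0.03 L)^2`, computed per slice over
#' the valid window positions and averaged over slices; matches the
#' conventional reference implementation with uniform (non-Gaussian)
#' weighting and sample covariances.  The dynamic range L defaults to the
#' maximum of the reference map, i.e. both maps are compared on the
#' reference's scale.
#'
#' @param rec,ref real-valued volumes of identical shape.
#' @param data_range dynamic range L (default `max(ref)`).
#' @param win_size odd window size (default 7).
#' @return SSIM in [-1, 1].
#' @export
ssim <- function(rec, ref, data_range = max(ref), win_size = 7) {
  stopifnot(all(dim(rec) == dim(ref)))
  d <- dim(ref)
  if (length(d) == 2L) { dim(rec) <- c(d, 1L); dim(ref) <- c(d, 1L); d <- dim(ref) }
  if (min(d[1:2]) < win_size)
    stop("image smaller than the SSIM window")
  c1 <- (0.01 * data_range)^2
  c2 <- (0.03 * data_range)^2
  vals <- vapply(seq_len(d[3]), function(z)
    ssim_slice(rec[, , z], ref[, , z], win_size, c1, c2), numeric(1))
  mean(vals)
}

#' Per-region statistics of a parameter map
#'
#' Mean, population standard deviation and voxel count of the map over
#' every positive label.  Labels present in the volume but empty after
#' masking are warned about and omitted.
#'
#' @param map numeric volume (e.g. T1 in ms).
#' @param labels integer label volume aligned with `map`; label 0 is
#'   background and ignored.
#' @return data frame with columns `label`, `mean`, `sd`, `n`.
#' @export
roi_stats <- function(map, labels) {
  stopifnot(all(dim(map) == dim(labels)))
  lv <- sort(unique(labels[labels > 0]))
  rows <- lapply(lv, function(l) {
    v <- Re(map[labels == l])
    if (!length(v)) {
      warning(sprintf("label %d has no voxels; omitted", l))
      return(NULL)
    }
    data.frame(label = l, mean = mean(v),
               sd = sqrt(mean((v - mean(v))^2)), n = length(v))
  })
  do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
}

#' Joint histogram and Pearson correlation of two maps
#'
#' 2D histogram of paired voxel values over a common mask, with the
#' Pearson correlation coefficient of the pairs.
#'
#' @param rec,ref maps of identical shape.
#' @param bins number of bins per axis.
#' @param mask logical array selecting pairs (default: reference > 0).
#' @return list with `counts` (bins x bins matrix), `breaks_rec`,
#'   `breaks_ref`, and `r` (Pearson correlation).
#' @export
joint_histogram <- function(rec, ref, bins = 64, mask = Re(ref) > 0) {
  stopifnot(all(dim(rec) == dim(ref)))
  x <- Re(rec[mask]); y <- Re(ref[mask])
  if (length(x) < 2) stop("need at least two paired voxels")
  bx <- seq(min(x), max(x), length.out = bins + 1)
  by <- seq(min(y), max(y), length.out = bins + 1)
  ix <- pmin(pmax(findInterval(x, bx, rightmost.closed = TRUE), 1), bins)
  iy <- pmin(pmax(findInterval(y, by, rightmost.closed = TRUE), 1), bins)
  counts <- matrix(0L, bins, bins)
  tb <- table(factor(ix, levels = seq_len(bins)),
              factor(iy, levels = seq_len(bins)))
  counts[] <- as.integer(tb)
  list(counts = counts, breaks_rec = bx, breaks_ref = by,
       r = stats::cor(x, y))
}
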