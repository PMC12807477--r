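#' Otsu threshold of an intensity sample
#'
#' Classic between-class-variance maximization on a fixed-width histogram.
#' Operates on an arbitrary pixel sample (e.g. the pixels inside one
#' nucleus ROI), which is what the per-ROI "relative" thresholding of the
#' bright-compartment mask requires.
#'
#' @param values numeric vector of intensities.
#' @param levels number of histogram bins (default 256).
#' @return threshold value; pixels `> threshold` are foreground.  `NA` with
#'   a warning-free degenerate result if all values are equal.
#' @export
otsu_threshold <- function(values, levels = 256L) {
  values <- values[is.finite(values)]
  rng <- range(values)
  if (diff(rng) == 0) return(NA_real_)
  breaks <- seq(rng[1], rng[2], length.out = levels + 1L)
  h <- tabulate(findInterval(values, breaks, rightmost.closed = TRUE),
                nbins = levels)
  mids <- (breaks[-1] + breaks[-(levels + 1L)]) / 2
  w <- cumsum(h); total <- w[levels]
  mu <- cumsum(h * mids); mu_t <- mu[levels]
  w1 <- w[-levels]; w2 <- total - w1
  valid <- w1 > 0 & w2 > 0
  bcv <- rep(-Inf, levels - 1L)
  bcv[valid] <- (mu_t * w1[valid] - total * mu[-levels][valid])^2 /
    (w1[valid] * w2[valid])
  # the criterion is flat across empty histogram gaps; take the plateau
  # midpoint so the threshold sits centrally between the classes
  best <- which(bcv >= max(bcv) - 1e-12 * abs(max(bcv)))
  breaks[floor(stats::median(best)) + 1L]
}

#' Segment nuclei from a DAPI channel
#'
#' Global Otsu threshold, hole filling, connected components, minimum-area
#' filter.
#'
#' @param dapi numeric intensity matrix.
#' @param min_area minimum ROI area in pixels (default 50).
#' @return list of `nucleus_roi` objects: list(mask, label, area).
#' @export
segment_nuclei <- function(dapi, min_area = 50) {
  stopifnot(is.matrix(dapi))
  thr <- otsu_threshold(as.numeric(dapi))
  if (is.na(thr)) return(list())
  fg <- dapi > thr
  if (!any(fg)) return(list())
  filled <- EBImage::fillHull(matrix(as.numeric(fg), nrow(dapi)))
  lab <- EBImage::bwlabel(filled)
  rois <- list()
  for (l in seq_len(max(lab))) {
    m <- lab == l
    a <- sum(m)
    if (a >= min_area)
      rois[[length(rois) + 1L]] <-
        structure(list(mask = m, label = length(rois) + 1L, area = a),
                  class = "nucleus_roi")
  }
  rois
}

#' Bright/dim compartment masks within a nucleus ROI
#'
#' The Otsu threshold is computed from the pixels inside the ROI only
#' ("relative" thresholding); the bright mask is the above-threshold subset
#' of the ROI and the dim mask its complement within the ROI, so
#' bright and dim always partition the ROI exactly.
#'
#' @param channel numeric intensity matrix (e.g. NPM1).
#' @param roi a `nucleus_roi`.
#' @return list(bright, dim, threshold, degenerate); `degenerate = TRUE`
#'   (with an empty bright mask) when the ROI intensities are uniform.
#' @export
bright_mask <- function(channel, roi) {
  stopifnot(inherits(roi, "nucleus_roi"), all(dim(channel) == dim(roi$mask)))
  vals <- channel[roi$mask]
  thr <- otsu_threshold(vals)
  if (is.na(thr)) {
    empty <- matrix(FALSE, nrow(channel), ncol(channel))
    return(list(bright = empty, dim = roi$mask, threshold = NA_real_,
                degenerate = TRUE))
  }
  bright <- roi$mask & channel > thr
  list(bright = bright, dim = roi$mask & !bright, threshold = thr,
       degenerate = FALSE)
}

# Crofton perimeter estimate from boundary intercept counts in the four
# directions 0/45/90/135 degrees; line spacings 1, 1/sqrt(2).
crofton_perimeter <- function(mask) {
  m <- matrix(as.integer(mask), nrow(mask))
  transitions <- function(v) sum(abs(diff(c(0L, v, 0L))))
  n0 <- sum(apply(m, 1, transitions))   # horizontal scan lines
  n90 <- sum(apply(m, 2, transitions))  # vertical
  diag_trans <- function(m) {
    h <- nrow(m); w <- ncol(m); tot <- 0L
    for (d in seq(-(h - 1L), w - 1L)) {
      r <- seq_len(h); c <- r + d
      ok <- c >= 1L & c <= w
      if (sum(ok) == 0) next
      tot <- tot + transitions(m[cbind(r[ok], c[ok])])
    }
    tot
  }
  n45 <- diag_trans(m)
  n135 <- diag_trans(m[, rev(seq_len(ncol(m))), drop = FALSE])
  (pi / 8) * (n0 + n90 + (n45 + n135) / sqrt(2))
}

# Min/max Feret (caliper) diameters over the convex hull of the pixel
# corner points, scanned at angular steps of at most 1 degree.
feret_diameters <- function(rows, cols, step_deg = 1) {
  corners <- cbind(
    x = c(cols - 0.5, cols + 0.5, cols - 0.5, cols + 0.5),
    y = c(rows - 0.5, rows - 0.5, rows + 0.5, rows + 0.5))
  hull <- corners[grDevices::chull(corners), , drop = FALSE]
  ang <- seq(0, pi, by = step_deg * pi / 180)
  ang <- ang[ang < pi]
  widths <- vapply(ang, function(t) {
    proj <- hull[, 1] * cos(t) + hull[, 2] * sin(t)
    max(proj) - min(proj)
  }, numeric(1))
  c(min = min(widths), max = max(widths))
}

#' Shape descriptors of bright objects
#'
#' Connected components of a boolean mask, with per-object area, Crofton
#' perimeter, circularity `4*pi*A/P^2` (clamped at 1, since the digital
#' perimeter estimate can underestimate slightly for small discs), and
#' aspect ratio `minFeret / maxFeret` from rotating calipers over the
#' component's convex hull at 1-degree steps.
#'
#' @param mask logical matrix.
#' @param min_area drop components smaller than this (default 1).
#' @return data frame: label, area, perimeter, circularity, aspect_ratio,
#'   centroid_row, centroid_col; zero rows for an empty mask.
#' @export
object_shapes <- function(mask, min_area = 1) {
  stopifnot(is.matrix(mask))
  empty <- data.frame(label = integer(), area = numeric(),
                      perimeter = numeric(), circularity = numeric(),
                      aspect_ratio = numeric(), centroid_row = numeric(),
                      centroid_col = numeric())
  if (!any(mask)) return(empty)
  lab <- EBImage::bwlabel(matrix(as.numeric(mask), nrow(mask)))
  out <- empty
  for (l in seq_len(max(lab))) {
    idx <- which(lab == l, arr.ind = TRUE)
    a <- nrow(idx)
    if (a < min_area) next
    comp <- lab == l
    per <- crofton_perimeter(comp)
    fer <- feret_diameters(idx[, 1], idx[, 2])
    out <- rbind(out, data.frame(
      label = nrow(out) + 1L, area = a, perimeter = per,
      circularity = min(1, 4 * pi * a / per^2),
      aspect_ratio = fer[["min"]] / fer[["max"]],
      centroid_row = mean(idx[, 1]), centroid_col = mean(idx[, 2])))
  }
  rownames(out) <- NULL
  out
}

#' Compartmental Pearson colocalization
#'
#' Pearson correlation of two channels over the pixels of the bright and
#' dim compartment masks separately.
#'
#' @param ch_a,ch_b intensity matrices of equal shape.
#' @param bright,dim logical compartment masks.
#' @return named numeric `c(r_bright, r_dim)`; a compartment with fewer
#'   than 3 pixels or zero variance in either channel yields `NA`.
#' @export
compartment_pearson <- function(ch_a, ch_b, bright, dim) {
  stopifnot(all(dim(ch_a) == dim(ch_b)))
  one <- function(mask) {
    if (sum(mask) < 3) return(NA_real_)
    a <- ch_a[mask]; b <- ch_b[mask]
    if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
    stats::cor(a, b)
  }
  c(r_bright = one(bright), r_dim = one(dim))
}

#' Per-nucleus intensity statistics
#'
#' Mean fluorescence intensity and population standard deviation of a
#' channel over one nucleus ROI.
#'
#' @param channel intensity matrix.
#' @param roi a `nucleus_roi`.
#' @return named numeric `c(mfi, sd)`.
#' @export
nucleus_intensity_stats <- function(channel, roi) {
  stopifnot(inherits(roi, "nucleus_roi"))
  v <- channel[roi$mask]
  m <- mean(v)
  c(mfi = m, sd = sqrt(mean((v - m)^2)))
}

#' Relative mean fluorescence intensity
#'
#' Normalizes per-cell MFI values by the mean of the control group, the
#' usual way "relative MFI" panels are scaled.
#'
#' @param values numeric MFI values to normalize.
#' @param control MFI values of the control group.
#' @return `values / mean(control)`.
#' @export
relative_mfi <- function(values, control) {
  m <- mean(control, na.rm = TRUE)
  assert_that(is.finite(m) && m > 0, "imaging",
              "control group mean must be positive")
  values / m
}

#' Write a segmentation QC overlay
#'
#' Renders one channel in grayscale with the bright-object mask in red and
#' the nucleus outline in blue, as a PNG.
#'
#' @param channel intensity matrix in [0, 1].
#' @param bright logical bright-object mask.
#' @param roi_mask logical nucleus mask.
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
write_overlay_png <- function(channel, bright, roi_mask, path) {
  g <- pmin(pmax(channel, 0), 1)  # matrix first: keeps dim attributes
  edge <- roi_mask & !(EBImage::erode(matrix(as.numeric(roi_mask),
                                             nrow(roi_mask)),
                                      EBImage::makeBrush(3, "box")) > 0)
  r_ch <- g; g_ch <- g; b_ch <- g
  r_ch[bright] <- 1;   g_ch[bright] <- 0.2; b_ch[bright] <- 0.2
  r_ch[edge] <- 0.2;   b_ch[edge] <- 1
  out <- array(c(r_ch, g_ch, b_ch), dim = c(nrow(g), ncol(g), 3))
  png::writePNG(out, path)
  invisible(path)
}

#' Quantify one multi-channel nucleus image
#'
#' Runs segmentation, per-ROI bright/dim masking, object morphometry,
#' compartmental colocalization and intensity statistics.
#'
#' @param img list(dapi, npm1, fbxo11) of matrices.
#' @param min_area minimum nucleus area (px).
#' @param min_object_area minimum bright-object area (px).
#' @return list with `nuclei` (per-nucleus data frame: n_objects, MFI, SD,
#'   r_bright, r_dim) and `objects` (per-object shape data frame with
#'   nucleus label).
#' @export
quantify_nucleus_image <- function(img, min_area = 200, min_object_area = 10) {
  rois <- segment_nuclei(img$dapi, min_area = min_area)
  nuclei <- data.frame()
  objects <- data.frame()
  for (roi in rois) {
    bm <- bright_mask(img$npm1, roi)
    sh <- object_shapes(bm$bright, min_area = min_object_area)
    if (nrow(sh)) objects <- rbind(objects, cbind(nucleus = roi$label, sh))
    coloc <- if (!is.null(img$fbxo11))
      compartment_pearson(img$npm1, img$fbxo11, bm$bright, bm$dim)
    else c(r_bright = NA_real_, r_dim = NA_real_)
    st_npm1 <- nucleus_intensity_stats(img$npm1, roi)
    st_fbx <- if (!is.null(img$fbxo11))
      nucleus_intensity_stats(img$fbxo11, roi)
    else c(mfi = NA_real_, sd = NA_real_)
    nuclei <- rbind(nuclei, data.frame(
      nucleus = roi$label, area = roi$area, n_objects = nrow(sh),
      npm1_mfi = st_npm1[["mfi"]], npm1_sd = st_npm1[["sd"]],
      fbxo11_mfi = st_fbx[["mfi"]], fbxo11_sd = st_fbx[["sd"]],
      r_bright = coloc[["r_bright"]], r_dim = coloc[["r_dim"]]))
  }
  list(nuclei = nuclei, objects = objects)
}
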