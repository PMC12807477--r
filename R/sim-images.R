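#' Rasterize a (rotated) ellipse mask
#'
#' Pixel (r, c) is inside when its center lies within the ellipse of
#' semi-axes `a` (along the rotated x axis) and `b`, centred at
#' `(cx, cy)` (column, row), rotated by `theta` radians.
#'
#' @param height,width image dimensions in pixels.
#' @param cx,cy centre (column, row), 1-based pixel coordinates.
#' @param a,b semi-axes in pixels.
#' @param theta rotation in radians (default 0).
#' @return logical matrix `height x width`.
#' @export
ellipse_mask <- function(height, width, cx, cy, a, b, theta = 0) {
  stopifnot(a > 0, b > 0)
  col <- matrix(rep(seq_len(width), each = height), nrow = height)
  row <- matrix(rep(seq_len(height), times = width), nrow = height)
  dx <- col - cx; dy <- row - cy
  u <- cos(theta) * dx + sin(theta) * dy
  v <- -sin(theta) * dx + cos(theta) * dy
  (u / a)^2 + (v / b)^2 <= 1
}

#' Simulate multi-channel nucleus images
#'
#' Each image holds one nucleus: the DAPI channel is a filled ellipse; the
#' NPM1 channel is a nucleoplasmic base level plus `n_objects` bright
#' elliptical nucleolus-like objects; the FBXO11 channel tracks the NPM1
#' signal in the NPM1-dim compartment (correlated) but not inside the
#' bright objects.  Gaussian noise with `image$noise_sd` is added to all
#' channels and intensities are clipped to [0, 1].
#'
#' Two condition presets are configured: `"control"` (few, larger,
#' elongated objects) and `"low"` (more, smaller, rounder objects),
#' emulating the ligase-suppressed phenotype.
#'
#' @param cfg a [sim_config()].
#' @param condition `"control"` or `"low"` (a name of
#'   `cfg$image$conditions`).
#' @return list with `images` (list per nucleus of list(dapi, npm1,
#'   fbxo11) matrices) and `truth` (per-nucleus object count, semi-axes,
#'   centres, angles).
#' @export
gen_nucleus_images <- function(cfg, condition = "control") {
  stopifnot(inherits(cfg, "ub_sim_config"))
  p <- cfg$image
  cond <- p$conditions[[condition]]
  assert_that(!is.null(cond), "gen_nucleus_images",
              paste0("unknown condition: ", condition))
  set.seed(stream_seed(cfg$seed, "nucleus_images") +
             match(condition, names(p$conditions)))
  h <- p$height; w <- p$width
  a_nuc <- p$nucleus_axes[1]; b_nuc <- p$nucleus_axes[2]
  images <- vector("list", p$n_nuclei)
  truth <- vector("list", p$n_nuclei)
  for (i in seq_len(p$n_nuclei)) {
    cx <- w / 2 + stats::runif(1, -5, 5)
    cy <- h / 2 + stats::runif(1, -5, 5)
    nuc <- ellipse_mask(h, w, cx, cy, a_nuc, b_nuc)
    k <- cond$n_objects
    # deterministic polar placement keeps objects inside and disjoint
    ang <- 2 * pi * (seq_len(k) - 1) / k + stats::runif(1, 0, 2 * pi)
    rad <- 0.55 * pmin(a_nuc, b_nuc)
    ocx <- cx + rad * cos(ang) * a_nuc / max(a_nuc, b_nuc)
    ocy <- cy + rad * sin(ang) * b_nuc / max(a_nuc, b_nuc)
    oth <- stats::runif(k, 0, pi)
    npm1 <- matrix(0, h, w)
    npm1[nuc] <- 0.25
    objs <- matrix(FALSE, h, w)
    for (jj in seq_len(k)) {
      om <- ellipse_mask(h, w, ocx[jj], ocy[jj],
                         cond$object_axes[1], cond$object_axes[2], oth[jj])
      objs <- objs | om
    }
    objs <- objs & nuc
    npm1[objs] <- 0.85
    dapi <- matrix(0, h, w); dapi[nuc] <- 0.7
    nz <- function(m) if (p$noise_sd > 0)
      matrix(pmin(1, pmax(0, m + stats::rnorm(length(m), 0, p$noise_sd))),
             h, w) else m
    dapi <- nz(dapi); npm1 <- nz(npm1)
    # FBXO11 tracks the (noisy) NPM1 signal in the nucleoplasm but is flat
    # inside the bright bodies, so colocalization is dim-compartment biased
    fbx <- matrix(0, h, w)
    dim_part <- nuc & !objs
    fbx[dim_part] <- 0.1 + 0.5 * npm1[dim_part]
    fbx[objs] <- 0.22
    fbx <- nz(fbx)
    images[[i]] <- list(dapi = dapi, npm1 = npm1, fbxo11 = fbx)
    truth[[i]] <- list(n_objects = k, object_axes = cond$object_axes,
                       centres = cbind(cx = ocx, cy = ocy), angles = oth)
  }
  list(images = images,
       truth = list(planted_objects_per_nucleus = truth,
                    condition = condition))
}

#' Write / read a nucleus image as multi-channel 16-bit TIFF
#'
#' Channel order is DAPI, NPM1, FBXO11 (one TIFF page per channel).
#'
#' @param img list(dapi, npm1, fbxo11) of numeric matrices in [0, 1].
#' @param path TIFF path.
#' @return `read_nucleus_tiff` returns the channel list.
#' @export
write_nucleus_tiff <- function(img, path) {
  tiff::writeTIFF(list(img$dapi, img$npm1, img$fbxo11), path,
                  bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_nucleus_tiff
#' @export
read_nucleus_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  stats::setNames(pages[1:3], c("dapi", "npm1", "fbxo11"))
}
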