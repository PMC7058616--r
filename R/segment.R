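#' Segment a single-channel image
#'
#' Standard mask creation for fluorescence channels: global Otsu threshold
#' (or a fixed threshold), morphological closing, hole filling, and removal
#' of components smaller than `min_area` pixels. Deterministic.
#'
#' @param image numeric/integer matrix (rows = y, cols = x).
#' @param method `"otsu"` (default) or `"fixed"`.
#' @param threshold intensity threshold when `method = "fixed"`.
#' @param min_area minimum component size \[pixels\].
#' @param closing_radius radius of the closing brush \[pixels\]; 0 disables.
#' @return object of class `viffi_segmentation`: list with `mask` (logical
#'   matrix), `labels` (integer matrix, labels contiguous from 1), `sizes`
#'   (pixel counts per label).
#' @export
segment <- function(image, method = c("otsu", "fixed"), threshold = NULL,
                    min_area = 20, closing_radius = 1) {
  method <- match.arg(method)
  stopifnot(is.matrix(image))
  rng <- range(image)
  if (rng[1] == rng[2]) {  # all-constant image: empty mask is valid
    return(structure(list(mask = matrix(FALSE, nrow(image), ncol(image)),
                          labels = matrix(0L, nrow(image), ncol(image)),
                          sizes = integer(0)),
                     class = "viffi_segmentation"))
  }
  norm <- (image - rng[1]) / (rng[2] - rng[1])
  thr <- if (method == "otsu") {
    EBImage::otsu(EBImage::Image(norm), range = c(0, 1))
  } else {
    if (is.null(threshold)) stop("'threshold' required for method = 'fixed'", call. = FALSE)
    (threshold - rng[1]) / (rng[2] - rng[1])
  }
  mask <- EBImage::Image(norm > thr)
  if (closing_radius > 0) {
    brush <- EBImage::makeBrush(2 * closing_radius + 1, shape = "disc")
    mask <- EBImage::closing(mask, brush)
  }
  mask <- EBImage::fillHull(mask)
  lab <- EBImage::bwlabel(mask)
  labm <- matrix(as.integer(EBImage::imageData(lab)), nrow(image), ncol(image))
  sizes <- tabulate(labm[labm > 0])
  keep <- which(sizes >= min_area)
  relab <- integer(length(sizes))
  relab[keep] <- seq_along(keep)
  labm[labm > 0] <- relab[labm[labm > 0]]
  structure(list(mask = labm > 0, labels = labm, sizes = sizes[keep]),
            class = "viffi_segmentation")
}

#' Minimum-area enclosing rectangle of a point set
#'
#' Convex hull plus rotating calipers: the minimum-area enclosing rectangle
#' of a convex polygon has one side collinear with a hull edge, so scanning
#' hull-edge orientations finds the global optimum exactly.
#'
#' @param pts two-column matrix of (x, y) points.
#' @return list with `area`, `angle` \[radians\], `width`, `height`.
#' @export
min_area_rect <- function(pts) {
  stopifnot(is.matrix(pts), ncol(pts) == 2, nrow(pts) >= 1)
  if (nrow(pts) == 1) return(list(area = 0, angle = 0, width = 0, height = 0))
  h <- grDevices::chull(pts)
  hp <- pts[h, , drop = FALSE]
  n <- nrow(hp)
  if (n == 1) return(list(area = 0, angle = 0, width = 0, height = 0))
  if (n == 2) {
    d <- sqrt(sum((hp[2, ] - hp[1, ])^2))
    return(list(area = 0, angle = atan2(hp[2, 2] - hp[1, 2], hp[2, 1] - hp[1, 1]),
                width = d, height = 0))
  }
  best <- list(area = Inf, angle = 0, width = 0, height = 0)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    e <- hp[j, ] - hp[i, ]
    th <- atan2(e[2], e[1])
    ct <- cos(-th); st <- sin(-th)
    xr <- hp[, 1] * ct - hp[, 2] * st
    yr <- hp[, 1] * st + hp[, 2] * ct
    w <- max(xr) - min(xr)
    hgt <- max(yr) - min(yr)
    if (w * hgt < best$area) best <- list(area = w * hgt, angle = th, width = w, height = hgt)
  }
  best
}

# internal: pixel-corner point set of a logical mask; pixel (r, c) 1-based
# occupies [c-1, c] x [r-1, r] in pixel units
mask_corners <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("empty mask", call. = FALSE)
  r <- idx[, 1]; c <- idx[, 2]
  pts <- rbind(cbind(c - 1, r - 1), cbind(c, r - 1), cbind(c - 1, r), cbind(c, r))
  unique(pts)
}

#' Nucleus / enclosing-box area ratio
#'
#' The area of a mask divided by the area of its minimum-area *rotated*
#' enclosing rectangle (computed on the pixel-corner point set). A filled
#' convex round nucleus approaches pi/4 ~ 0.785; lobulated (neutrophil-like)
#' nuclei give systematically lower values, which is what makes this a
#' lobulation statistic.
#'
#' @param mask logical matrix (single nucleus), or a `viffi_segmentation`
#'   whose mask is used.
#' @return ratio in (0, 1\]; the rectangle is attached as attribute `"rect"`.
#' @export
enclosing_box_ratio <- function(mask) {
  if (inherits(mask, "viffi_segmentation")) mask <- mask$mask
  stopifnot(is.logical(mask) || all(mask %in% c(0, 1)))
  mask <- mask > 0
  npx <- sum(mask)
  if (npx == 0) stop("empty mask", call. = FALSE)
  rect <- min_area_rect(mask_corners(mask))
  ratio <- npx / rect$area
  attr(ratio, "rect") <- rect
  ratio
}

#' Morphometric features of one labeled component
#'
#' Area (pixel count times pixel area), perimeter (length of the traced
#' boundary polygon), aspect ratio (major/minor axis of the second-moment
#' ellipse) and centroid.
#'
#' @param mask logical matrix containing exactly one connected component.
#' @param pixel_size object-plane pixel size \[µm\].
#' @return list with `area_um2`, `perimeter_um`, `aspect_ratio`,
#'   `centroid_um` (x, y), `area_px`.
#' @export
cell_features <- function(mask, pixel_size = 1) {
  if (inherits(mask, "viffi_segmentation")) mask <- mask$mask
  mask <- mask > 0
  npx <- sum(mask)
  if (npx == 0) stop("empty component", call. = FALSE)
  idx <- which(mask, arr.ind = TRUE)
  # pixel centers: 0-based pixel j has center (j + 0.5); 1-based row/col r, c
  # -> (c - 0.5, r - 0.5) pixel units
  x <- idx[, 2] - 0.5
  y <- idx[, 1] - 0.5
  ctr <- c(mean(x), mean(y))
  # second-moment ellipse (add the pixel's own 1/12 variance)
  cv <- stats::cov(cbind(x, y)) * (npx - 1) / npx + diag(2) / 12
  ev <- eigen(cv, symmetric = TRUE, only.values = TRUE)$values
  aspect <- sqrt(max(ev) / max(min(ev), .Machine$double.eps))
  # boundary: traced contour polygon (closed)
  oc <- EBImage::ocontour(EBImage::Image(mask * 1))[[1]]
  dxy <- diff(rbind(oc, oc[1, , drop = FALSE]))
  per_px <- sum(sqrt(rowSums(dxy^2)))
  list(area_um2 = npx * pixel_size^2,
       perimeter_um = per_px * pixel_size,
       aspect_ratio = aspect,
       centroid_um = ctr * pixel_size,
       area_px = npx)
}
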