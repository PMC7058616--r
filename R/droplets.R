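# internal: square max/min filter of radius r (window side 2r+1), separable,
# edges padded with the identity element
window_filter <- function(m, r, op = pmax, pad) {
  shift_cols <- function(mm, d) {
    nc <- ncol(mm)
    out <- matrix(pad, nrow(mm), nc)
    if (d >= 0) out[, (1 + d):nc] <- mm[, 1:(nc - d), drop = FALSE]
    else out[, 1:(nc + d)] <- mm[, (1 - d):nc, drop = FALSE]
    out
  }
  h <- m
  for (d in seq_len(r)) h <- op(h, shift_cols(m, d), shift_cols(m, -d))
  v <- h
  th <- t(h)
  for (d in seq_len(r)) v <- op(v, t(shift_cols(th, d)), t(shift_cols(th, -d)))
  v
}

#' Count bright sub-resolution spots by local-extrema contrast
#'
#' The lipid-droplet enumeration rule: local intensity maxima are located in
#' a square window whose side matches the approximate droplet size; each
#' maximum is kept only if its intensity exceeds the minimum intensity in the
#' surrounding annulus (between one and two window sizes) by more than
#' `contrast_threshold`. Plateaus of equal-valued maxima are merged and
#' resolved to their centroid. The counting is invariant under a uniform
#' intensity offset.
#'
#' @param image numeric matrix.
#' @param droplet_size approximate droplet size; in µm if `pixel_size` is
#'   given, else in pixels. Must be >= 2 pixels.
#' @param contrast_threshold minimum (max - surrounding min) intensity
#'   difference.
#' @param pixel_size optional object-plane pixel size \[µm\]; converts
#'   `droplet_size` and the returned positions to µm.
#' @return list with `count` and `positions` (two-column matrix of (x, y)
#'   centroids, µm if `pixel_size` given, else pixel units).
#' @export
count_droplets <- function(image, droplet_size, contrast_threshold,
                           pixel_size = NULL) {
  stopifnot(is.matrix(image))
  size_px <- if (is.null(pixel_size)) droplet_size else droplet_size / pixel_size
  if (size_px < 2) stop("'droplet_size' must be at least 2 pixels", call. = FALSE)
  r <- max(1L, round((size_px - 1) / 2))
  mx <- window_filter(image, r, pmax, -Inf)
  cand <- image >= mx  # local maxima (plateaus included)
  if (!any(cand)) return(list(count = 0L, positions = matrix(numeric(0), 0, 2)))
  # merge adjacent equal-valued candidate pixels into plateau components
  lab <- EBImage::bwlabel(EBImage::Image(cand * 1))
  labm <- matrix(as.integer(EBImage::imageData(lab)), nrow(image), ncol(image))
  n_lab <- max(labm)
  keep <- logical(n_lab)
  cx <- numeric(n_lab); cy <- numeric(n_lab)
  nr <- nrow(image); nc <- ncol(image)
  for (l in seq_len(n_lab)) {
    idx <- which(labm == l, arr.ind = TRUE)
    peak <- max(image[labm == l])
    pr <- round(mean(idx[, 1])); pc <- round(mean(idx[, 2]))
    # annulus between 1x and 2x the window around the plateau centroid
    rr <- max(1, pr - 2 * r):min(nr, pr + 2 * r)
    cc <- max(1, pc - 2 * r):min(nc, pc + 2 * r)
    outer_w <- image[rr, cc, drop = FALSE]
    ann_mask <- !(outer(abs(rr - pr) <= r, abs(cc - pc) <= r, `&`))
    if (!any(ann_mask)) next
    ann_min <- min(outer_w[ann_mask])
    if (peak - ann_min > contrast_threshold) {
      keep[l] <- TRUE
      cx[l] <- mean(idx[, 2]) - 0.5  # 0-based pixel-center coordinates
      cy[l] <- mean(idx[, 1]) - 0.5
    }
  }
  pos <- cbind(cx[keep], cy[keep])
  # positions at pixel centers: 0-based pixel j has center (j + 0.5) p
  if (!is.null(pixel_size)) pos <- (pos + 0.5) * pixel_size
  colnames(pos) <- c("x", "y")
  list(count = sum(keep), positions = pos)
}

#' Per-cell droplet-area statistics
#'
#' Mean droplet area per cell from per-cell droplet segmentations. Cells with
#' zero droplets get `NA` (missing), never 0: an absent droplet has no area.
#'
#' @param droplet_areas list (one element per cell) of numeric vectors of
#'   droplet areas \[µm²\].
#' @return data.frame with `cell`, `droplet_count`, `mean_droplet_area_um2`.
#' @export
droplet_area_stats <- function(droplet_areas) {
  stopifnot(is.list(droplet_areas))
  data.frame(
    cell = seq_along(droplet_areas),
    droplet_count = vapply(droplet_areas, length, integer(1)),
    mean_droplet_area_um2 = vapply(droplet_areas, function(a) {
      if (length(a) == 0) NA_real_ else mean(a)
    }, numeric(1)))
}
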