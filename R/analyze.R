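#' Run the per-cell analysis pipeline on one frame
#'
#' Channel extraction, per-channel segmentation, and per-cell morphometry:
#' cell body features from `cell_channel`, nuclear area and enclosing-box
#' ratio from `nucleus_channel` (nucleus assigned to the cell whose centroid
#' is nearest), droplet count and mean droplet area from `droplet_channel`
#' within each cell's bounding box.
#'
#' @param frame a `viffi_frame` (or path to a written frame).
#' @param droplet_size approximate droplet size \[µm\].
#' @param droplet_threshold contrast threshold for droplet counting (DN);
#'   `NULL` disables droplet counting.
#' @param cell_channel channel defining the cell body (default 2, the
#'   cytoplasm stain).
#' @param nucleus_channel channel of the nuclear stain (default 1).
#' @param droplet_channel channel of the droplet stain (default 1).
#' @param min_area minimum component area \[px\] for segmentation.
#' @param frame_id identifier written to the `frame` column.
#' @return data.frame in the fixed export column order (see
#'   [export_features()]).
#' @export
analyze_frame <- function(frame, droplet_size = 0.8, droplet_threshold = NULL,
                          cell_channel = 2, nucleus_channel = 1,
                          droplet_channel = 1, min_area = 20, frame_id = 1L) {
  if (is.character(frame)) frame <- read_frame(frame)
  stopifnot(inherits(frame, "viffi_frame"))
  p <- frame$pixel_size
  chans <- split_channels(frame)
  seg_cell <- segment(chans[[cell_channel]], min_area = min_area)
  n_cells <- length(seg_cell$sizes)
  if (n_cells == 0) return(empty_records())
  seg_nuc <- segment(chans[[nucleus_channel]], min_area = min_area)
  nuc_centroids <- component_centroids(seg_nuc$labels)
  rows <- vector("list", n_cells)
  for (i in seq_len(n_cells)) {
    cmask <- seg_cell$labels == i
    feat <- cell_features(cmask, p)
    # nucleus: nearest nuclear component centroid (within the cell radius)
    nuc_area <- NA_real_; box_area <- NA_real_; box_ratio <- NA_real_
    if (nrow(nuc_centroids) > 0) {
      d2 <- (nuc_centroids$x - feat$centroid_um[1] / p)^2 +
            (nuc_centroids$y - feat$centroid_um[2] / p)^2
      j <- which.min(d2)
      if (sqrt(d2[j]) * p < 2 * sqrt(feat$area_um2 / pi)) {
        nmask <- seg_nuc$labels == nuc_centroids$label[j]
        br <- enclosing_box_ratio(nmask)
        nuc_area <- sum(nmask) * p^2
        box_area <- attr(br, "rect")$area * p^2
        box_ratio <- as.numeric(br)
      }
    }
    # droplets: counted inside the cell's bounding box (padded)
    dcount <- NA_integer_; darea <- NA_real_
    if (!is.null(droplet_threshold)) {
      idx <- which(cmask, arr.ind = TRUE)
      rr <- max(1, min(idx[, 1]) - 2):min(nrow(cmask), max(idx[, 1]) + 2)
      cc <- max(1, min(idx[, 2]) - 2):min(ncol(cmask), max(idx[, 2]) + 2)
      dimg <- chans[[droplet_channel]][rr, cc, drop = FALSE]
      cd <- count_droplets(dimg, droplet_size, droplet_threshold, pixel_size = p)
      dcount <- cd$count
      if (cd$count > 0) {
        dseg <- segment(dimg, min_area = 2)
        darea <- if (length(dseg$sizes) > 0) mean(dseg$sizes) * p^2 else NA_real_
      }
    }
    rows[[i]] <- data.frame(
      frame = frame_id, cell_id = i,
      x_um = feat$centroid_um[1], y_um = feat$centroid_um[2],
      area_um2 = feat$area_um2, perimeter_um = feat$perimeter_um,
      aspect_ratio = feat$aspect_ratio,
      nucleus_area_um2 = nuc_area, box_area_um2 = box_area,
      box_ratio = box_ratio, droplet_count = dcount,
      mean_droplet_area_um2 = darea)
  }
  do.call(rbind, rows)
}

# internal: centroids (pixel-center 1-based units) of labeled components
component_centroids <- function(labels) {
  n <- max(labels)
  if (n == 0) return(data.frame(label = integer(0), x = numeric(0), y = numeric(0)))
  do.call(rbind, lapply(seq_len(n), function(l) {
    idx <- which(labels == l, arr.ind = TRUE)
    data.frame(label = l, x = mean(idx[, 2]) - 0.5, y = mean(idx[, 1]) - 0.5)
  }))
}

empty_records <- function() {
  data.frame(frame = integer(0), cell_id = integer(0), x_um = numeric(0),
             y_um = numeric(0), area_um2 = numeric(0), perimeter_um = numeric(0),
             aspect_ratio = numeric(0), nucleus_area_um2 = numeric(0),
             box_area_um2 = numeric(0), box_ratio = numeric(0),
             droplet_count = integer(0), mean_droplet_area_um2 = numeric(0))
}

#' Export per-cell feature records as CSV
#'
#' Writes one row per cell with a stable column order:
#' `frame, cell_id, x_um, y_um, area_um2, perimeter_um, aspect_ratio,
#' nucleus_area_um2, box_area_um2, box_ratio, droplet_count,
#' mean_droplet_area_um2`. A round-trip read reproduces the records.
#'
#' @param records data.frame as produced by [analyze_frame()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
export_features <- function(records, path) {
  cols <- names(empty_records())
  missing <- setdiff(cols, names(records))
  if (length(missing) > 0) {
    stop("records are missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  ok <- tryCatch({
    utils::write.csv(records[, cols], path, row.names = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop(sprintf("failed to write '%s': %s", path, conditionMessage(ok)),
                        call. = FALSE)
  invisible(path)
}

#' Export fixed-size per-cell image crops
#'
#' Cuts a square crop (16-bit TIFF) centered on each cell centroid from a
#' channel image, e.g. to feed an off-the-shelf CNN classifier. Crops at the
#' frame edge are zero-padded so every crop has the same size.
#'
#' @param image numeric matrix (one channel).
#' @param records data.frame with `cell_id`, `x_um`, `y_um`.
#' @param pixel_size object-plane pixel size \[µm\].
#' @param dir output directory (created if needed).
#' @param size crop side \[px\] (default 64).
#' @return character vector of written file paths, invisibly.
#' @export
export_crops <- function(image, records, pixel_size, dir, size = 64) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  half <- size %/% 2
  paths <- character(nrow(records))
  for (i in seq_len(nrow(records))) {
    # centroid in 1-based pixel indices (pixel centers at (j + 0.5) p)
    pc <- round(records$x_um[i] / pixel_size + 0.5)
    pr <- round(records$y_um[i] / pixel_size + 0.5)
    crop <- matrix(0, size, size)
    rr <- (pr - half):(pr + half - 1L)
    cc <- (pc - half):(pc + half - 1L)
    rok <- rr >= 1 & rr <= nrow(image)
    cok <- cc >= 1 & cc <= ncol(image)
    crop[which(rok), which(cok)] <- image[rr[rok], cc[cok], drop = FALSE]
    paths[i] <- file.path(dir, sprintf("cell_%04d.tif", records$cell_id[i]))
    tiff::writeTIFF(pmin(pmax(crop, 0), 65535) / 65535, paths[i],
                    bits.per.sample = 16, compression = "none")
  }
  invisible(paths)
}
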