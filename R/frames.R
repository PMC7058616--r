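#' @export
print.viffi_frame <- function(x, ...) {
  cat(sprintf("<viffi_frame> %d x %d px (%d channels of %d lines), pixel %g um, mode %s\n",
              nrow(x$data), ncol(x$data), x$layout$n_channels, x$layout$n_y,
              x$pixel_size, x$mode))
  invisible(x)
}

#' Write / read a rendered frame as 16-bit TIFF plus JSON sidecar
#'
#' The frame is written as a multi-page 16-bit grayscale TIFF (one page per
#' channel) and a JSON sidecar carrying the pixel size, acquisition mode,
#' seed, channel layout and any ground-truth emitter positions, so a frame
#' directory is self-describing and reproducible.
#'
#' @param frame a `viffi_frame` (see [render_frame()]).
#' @param path output path; `".tif"` is appended if missing, and the sidecar
#'   is written next to it as `<path>.json`.
#' @return `write_frame` returns the TIFF path invisibly; `read_frame`
#'   returns a `viffi_frame`.
#' @export
write_frame <- function(frame, path) {
  stopifnot(inherits(frame, "viffi_frame"))
  if (!grepl("\\.tiff?$", path)) path <- paste0(path, ".tif")
  chans <- split_channels(frame)
  pages <- lapply(chans, function(m) pmin(pmax(m, 0), 65535) / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16, compression = "none")
  side <- list(pixel_size_um = frame$pixel_size, mode = frame$mode,
               seed = frame$seed, layout = frame$layout,
               truth = frame$truth)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_frame
#' @export
read_frame <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  mats <- lapply(pages, function(pg) {
    m <- round(pg * 65535)
    matrix(as.integer(m), nrow(m), ncol(m))
  })
  data <- do.call(rbind, mats)
  layout <- side$layout
  layout$n_channels <- as.integer(layout$n_channels)
  layout$n_y <- as.integer(layout$n_y)
  layout$y_offsets <- as.integer(layout$y_offsets)
  layout$x_shift <- as.integer(layout$x_shift)
  structure(list(data = data, pixel_size = side$pixel_size_um, mode = side$mode,
                 seed = side$seed, layout = layout,
                 truth = if (is.null(side$truth) || length(side$truth) == 0) NULL
                         else as.data.frame(side$truth)),
            class = "viffi_frame")
}

#' Extract per-channel images from a frame
#'
#' The two color channels of the split-image sensor layout occupy disjoint
#' row bands of one frame; this extracts each band (applying the layout's
#' registration shift along the flow axis, wrapping at the frame edge) and
#' returns one matrix per channel.
#'
#' @param frame a `viffi_frame`, or a plain matrix (then `layout` is
#'   required).
#' @param layout overriding layout: list with `n_channels`, `n_y`,
#'   `y_offsets` (0-based row offsets of each band) and `x_shift`
#'   (registration shift in pixels applied to channels after the first).
#' @return list of per-channel matrices (`n_y` rows each).
#' @export
split_channels <- function(frame, layout = NULL) {
  if (inherits(frame, "viffi_frame")) {
    data <- frame$data
    if (is.null(layout)) layout <- frame$layout
  } else {
    data <- frame
    if (is.null(layout)) stop("'layout' is required for plain matrices", call. = FALSE)
  }
  n_y <- layout$n_y
  out <- vector("list", layout$n_channels)
  for (ci in seq_len(layout$n_channels)) {
    r0 <- layout$y_offsets[ci] + 1L
    r1 <- r0 + n_y - 1L
    if (r0 < 1 || r1 > nrow(data)) {
      stop(sprintf("channel %d band [%d, %d] outside frame of %d rows",
                   ci, r0, r1, nrow(data)), call. = FALSE)
    }
    m <- data[r0:r1, , drop = FALSE]
    sh <- layout$x_shift
    if (ci > 1 && !is.null(sh) && sh != 0) {
      if (abs(sh) >= ncol(m)) stop("'x_shift' exceeds frame width", call. = FALSE)
      idx <- ((seq_len(ncol(m)) - 1L + sh) %% ncol(m)) + 1L
      m <- m[, idx, drop = FALSE]
    }
    out[[ci]] <- m
  }
  out
}
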