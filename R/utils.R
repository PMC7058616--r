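#' Round half away from zero
#'
#' Base `round()` rounds half to even; reported design numbers follow the
#' half-up convention instead so that e.g. 25.5 reports as 26.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Round to a number of significant figures, half away from zero
#'
#' @param x numeric vector.
#' @param digits significant figures (default 2, the convention used for
#'   reported design values).
#' @return rounded numeric vector.
#' @export
signif_half_up <- function(x, digits = 2) {
  out <- x
  nz <- is.finite(x) & x != 0
  mag <- floor(log10(abs(x[nz])))
  out[nz] <- round_half_up(x[nz] / 10^(mag - digits + 1)) * 10^(mag - digits + 1)
  out
}

#' Round to the nearest multiple
#'
#' @param x numeric vector.
#' @param to multiple to round to (e.g. 10 for "nearest 10 microseconds").
#' @return rounded numeric vector.
#' @export
round_to <- function(x, to) round_half_up(x / to) * to

# internal: stop unless all values strictly positive
check_positive <- function(...) {
  vals <- list(...)
  nms <- names(vals)
  for (i in seq_along(vals)) {
    if (!is.numeric(vals[[i]]) || any(!is.finite(vals[[i]])) || any(vals[[i]] <= 0)) {
      stop(sprintf("'%s' must be strictly positive and finite", nms[i]), call. = FALSE)
    }
  }
  invisible(TRUE)
}

deg2rad <- function(deg) deg * pi / 180
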