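# Shared fixtures and independent oracles, all built in code.

# discrete disk mask: pixels whose center lies within radius r of (cx, cy)
disk_mask <- function(n, cx, cy, r) {
  xs <- matrix(rep(seq_len(n) - 0.5, each = n), n, n)
  ys <- matrix(rep(seq_len(n) - 0.5, times = n), n, n)
  (xs - cx)^2 + (ys - cy)^2 <= r^2
}

# union-of-disks mask (lobulated nucleus analogue)
lobed_mask <- function(n, cx, cy, r_outer, k, angle = 0) {
  r_l <- r_outer * 0.55
  off <- r_outer - r_l
  m <- matrix(FALSE, n, n)
  for (i in seq_len(k)) {
    a <- angle + 2 * pi * (i - 1) / k
    m <- m | disk_mask(n, cx + off * cos(a), cy + off * sin(a), r_l)
  }
  m
}

# brute-force minimum-area enclosing rectangle: exhaustive rotation search
brute_min_rect_area <- function(pts, step_deg = 0.1) {
  angles <- seq(0, 180 - step_deg, by = step_deg) * pi / 180
  best <- Inf
  for (th in angles) {
    ct <- cos(th); st <- sin(th)
    xr <- pts[, 1] * ct + pts[, 2] * st
    yr <- -pts[, 1] * st + pts[, 2] * ct
    a <- (max(xr) - min(xr)) * (max(yr) - min(yr))
    if (a < best) best <- a
  }
  best
}

# rotate a mask about its centroid by 'deg' degrees (nearest-neighbour)
rotate_mask <- function(mask, deg) {
  idx <- which(mask, arr.ind = TRUE)
  cy <- mean(idx[, 1]); cx <- mean(idx[, 2])
  th <- deg * pi / 180
  n <- nrow(mask) # assume square
  out <- matrix(FALSE, n, n)
  # inverse map output pixels to input
  oy <- rep(seq_len(n), times = n)
  ox <- rep(seq_len(n), each = n)
  sx <- cx + (ox - cx) * cos(-th) - (oy - cy) * sin(-th)
  sy <- cy + (ox - cx) * sin(-th) + (oy - cy) * cos(-th)
  # bilinear interpolation of the binary mask, thresholded at 0.5, which
  # keeps the rotated boundary smooth
  r0 <- floor(sy); c0 <- floor(sx)
  fy <- sy - r0; fx <- sx - c0
  val <- function(ri, ci) {
    ok <- ri >= 1 & ri <= n & ci >= 1 & ci <= n
    v <- numeric(length(ri))
    v[ok] <- mask[cbind(ri[ok], ci[ok])]
    v
  }
  v <- val(r0, c0) * (1 - fy) * (1 - fx) + val(r0 + 1, c0) * fy * (1 - fx) +
    val(r0, c0 + 1) * (1 - fy) * fx + val(r0 + 1, c0 + 1) * fy * fx
  out[cbind(oy, ox)] <- v >= 0.5
  out
}

# synthetic droplet crop: flat background + k Gaussian spots with known
# centers, pairwise separation > min_sep pixels
make_spot_image <- function(n = 48, k = 3, amp = 600, background = 100,
                            sigma = 0.8, min_sep = 8, seed = 1, margin = 6) {
  set.seed(seed)
  centers <- matrix(numeric(0), 0, 2)
  guard <- 0
  while (nrow(centers) < k && guard < 2000) {
    cand <- runif(2, margin, n - margin)
    if (nrow(centers) == 0 ||
        min(sqrt(rowSums((centers - matrix(cand, nrow(centers), 2,
                                           byrow = TRUE))^2))) > min_sep) {
      centers <- rbind(centers, cand)
    }
    guard <- guard + 1
  }
  img <- matrix(background, n, n)
  xs <- matrix(rep(seq_len(n) - 0.5, each = n), n, n)
  ys <- matrix(rep(seq_len(n) - 0.5, times = n), n, n)
  for (i in seq_len(nrow(centers))) {
    img <- img + amp * exp(-((xs - centers[i, 1])^2 + (ys - centers[i, 2])^2) /
                             (2 * sigma^2))
  }
  list(image = img, centers = centers)
}

# crop a bead image around its detected local peak (as the analysis pipeline
# does); NULL if too close to the frame edge
crop_at_peak <- function(ch, x_um, y_um, p, half = 8, search = 12) {
  pc <- round(x_um / p + 0.5); pr <- round(y_um / p + 0.5)
  rr <- max(1, pr - search):min(nrow(ch), pr + search)
  cc <- max(1, pc - search):min(ncol(ch), pc + search)
  w <- ch[rr, cc]
  pk <- which(w == max(w), arr.ind = TRUE)[1, ]
  pr2 <- rr[pk[1]]; pc2 <- cc[pk[2]]
  if (pc2 <= half || pc2 > ncol(ch) - half ||
      pr2 <= half || pr2 > nrow(ch) - half) return(NULL)
  list(crop = ch[(pr2 - half):(pr2 + half), (pc2 - half):(pc2 + half)],
       pr = pr2, pc = pc2)
}

# render a bead field with enforced pairwise isolation (re-draw clustered
# beads), returning frame + truth of isolated beads only
isolated_bead_field <- function(n_beads, design, mode, noise, seed,
                                min_sep_px = 20, ...) {
  fr <- render_bead_field(n_beads, design, mode, noise = noise, seed = seed, ...)
  tr <- fr$truth
  p <- fr$pixel_size
  keep <- rep(TRUE, nrow(tr))
  d2 <- as.matrix(stats::dist(cbind(tr$x, tr$y) / p))
  diag(d2) <- Inf
  keep <- apply(d2, 1, min) > min_sep_px
  fr$truth <- tr[keep, ]
  fr
}

# per-bead integrated signal (electrons above offset) in a window
bead_total_signal <- function(ch, x_um, y_um, p, noise, half = 10) {
  pc <- round(x_um / p + 0.5); pr <- round(y_um / p + 0.5)
  if (pc <= half || pc > ncol(ch) - half ||
      pr <= half || pr > nrow(ch) - half) return(NA_real_)
  w <- ch[(pr - half):(pr + half), (pc - half):(pc + half)]
  sum(w - noise$offset) * noise$gain
}

paper_design <- function() viffi_design()
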