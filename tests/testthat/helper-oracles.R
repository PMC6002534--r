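# Independent oracles and small fixture builders used across the suite.

# Lossless 90-degree rotation (counter-clockwise) of a matrix.
rot90_lossless <- function(m) t(m)[, nrow(m):1]

# Brute-force convex-hull pixel count: a candidate pixel is outside the
# hull iff some all-points-on-one-side supporting line (through a pair of
# set pixels) strictly separates it. Integer arithmetic, exact. O(n^2 * c).
oracle_hull_count <- function(pts) {
  pts <- unique(pts[, 1:2, drop = FALSE])
  n <- nrow(pts)
  if (n == 1L) return(1L)
  rr <- range(pts[, 1]); cc <- range(pts[, 2])
  cand <- as.matrix(expand.grid(r = rr[1]:rr[2], c = cc[1]:cc[2]))
  collin <- TRUE
  if (n > 2L) {
    a <- pts[1, ]; b <- pts[2, ]
    collin <- all((b[1] - a[1]) * (pts[, 2] - a[2]) -
                  (b[2] - a[2]) * (pts[, 1] - a[1]) == 0)
  }
  if (collin) {
    o <- order(pts[, 1], pts[, 2])
    a <- pts[o[1], ]; b <- pts[o[n], ]
    cr <- (b[1] - a[1]) * (cand[, 2] - a[2]) -
          (b[2] - a[2]) * (cand[, 1] - a[1])
    return(sum(cr == 0 &
               cand[, 1] >= rr[1] & cand[, 1] <= rr[2] &
               cand[, 2] >= cc[1] & cand[, 2] <= cc[2]))
  }
  outside <- rep(FALSE, nrow(cand))
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      a <- pts[i, ]; b <- pts[j, ]
      cr_pts <- (b[1] - a[1]) * (pts[, 2] - a[2]) -
                (b[2] - a[2]) * (pts[, 1] - a[1])
      cr_cand <- NULL
      if (all(cr_pts >= 0)) {
        cr_cand <- (b[1] - a[1]) * (cand[, 2] - a[2]) -
                   (b[2] - a[2]) * (cand[, 1] - a[1])
        outside <- outside | (cr_cand < 0)
      }
      if (all(cr_pts <= 0)) {
        if (is.null(cr_cand)) {
          cr_cand <- (b[1] - a[1]) * (cand[, 2] - a[2]) -
                     (b[2] - a[2]) * (cand[, 1] - a[1])
        }
        outside <- outside | (cr_cand > 0)
      }
    }
  }
  sum(!outside)
}

# Direct erosion-then-dilation white top-hat oracle with a disk element:
# brute-force min/max filters over the kernel support, border handled by
# restricting the window to the image (matching EBImage's behaviour on
# interior pixels; comparisons use interior regions only).
oracle_white_tophat <- function(img, radius) {
  # disk support of a radius-r element rasterized over a (2r+1)^2 grid:
  # centers within r + 0.5 of the origin
  offs <- expand.grid(dr = -radius:radius, dc = -radius:radius)
  offs <- offs[offs$dr^2 + offs$dc^2 <= (radius + 0.5)^2, ]
  nr <- nrow(img); nc <- ncol(img)
  filt <- function(m, f) {
    out <- matrix(0, nr, nc)
    for (r in seq_len(nr)) {
      for (c in seq_len(nc)) {
        rs <- r + offs$dr; cs <- c + offs$dc
        ok <- rs >= 1 & rs <= nr & cs >= 1 & cs <= nc
        out[r, c] <- f(m[cbind(rs[ok], cs[ok])])
      }
    }
    out
  }
  img - filt(filt(img, min), max)
}

# Smooth Gaussian blob fixture (possibly anisotropic), centered.
gaussian_blob <- function(size, sd_col, sd_row = sd_col, height = 100) {
  ctr <- (size + 1) / 2
  g <- expand.grid(r = seq_len(size), c = seq_len(size))
  matrix(height * exp(-((g$c - ctr)^2 / (2 * sd_col^2) +
                        (g$r - ctr)^2 / (2 * sd_row^2))), size, size)
}

# Hard-edged disk image on a square grid (centered by default).
disk_image <- function(size, radius, height = 1,
                       center = rep((size + 1) / 2, 2)) {
  g <- expand.grid(r = seq_len(size), c = seq_len(size))
  m <- matrix(0, size, size)
  m[(g$r - center[1])^2 + (g$c - center[2])^2 <= radius^2] <- height
  m
}

# Small fast colony parameter set for scoring tests.
small_colony_params <- function(..., seed = 1) {
  colony_sim_params(n_cells = 40, dispersion_sigma = 12, cell_radius = 3,
                    image_size = 128, seed = seed, ...)
}
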