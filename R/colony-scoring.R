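#' Colony image container
#'
#' A light wrapper pairing a preprocessed single-channel intensity matrix
#' with its binary cell mask and a preprocessing log. One colony per image
#' is assumed (colonies are cut out upstream).
#'
#' @param intensity Numeric matrix `[row, col]`, non-negative. After
#'   preprocessing this is the top-hat-corrected field used for the radial
#'   profile.
#' @param mask Optional logical matrix of cell pixels (same shape).
#' @param detection Optional numeric matrix: the background-subtracted
#'   (pre-top-hat) intensity used for cell detection and centroiding.
#' @param provenance Character vector of processing-log entries.
#' @return A `colony_image` object.
#' @export
colony_image <- function(intensity, mask = NULL, detection = NULL,
                         provenance = character()) {
  stopifnot(is.matrix(intensity), is.numeric(intensity))
  if (any(intensity < 0)) abort("intensity must be non-negative")
  if (!is.null(mask)) {
    stopifnot(is.logical(mask), identical(dim(mask), dim(intensity)))
  }
  if (!is.null(detection)) {
    stopifnot(is.matrix(detection), identical(dim(detection), dim(intensity)))
  }
  structure(list(intensity = intensity, mask = mask, detection = detection,
                 provenance = provenance),
            class = "colony_image")
}

#' @export
print.colony_image <- function(x, ...) {
  cat("<colony_image> ", paste(dim(x$intensity), collapse = " x "),
      " px; mask: ",
      if (is.null(x$mask)) "none" else paste0(sum(x$mask), " px"),
      "\n", sep = "")
  if (length(x$provenance)) cat(paste0("  - ", x$provenance, "\n"), sep = "")
  invisible(x)
}

as_colony_image <- function(x) {
  if (inherits(x, "colony_image")) return(x)
  if (inherits(x, "colony_sim")) {
    return(colony_image(x$image, provenance = "simulated"))
  }
  if (is.matrix(x)) return(colony_image(x))
  if (is.character(x) && length(x) == 1L) {
    return(colony_image(read_colony_image(x), provenance = paste0("read ", x)))
  }
  abort("cannot interpret input as a colony image")
}

#' Preprocess a colony image: luminance, background subtraction, top-hat
#'
#' Subtracts a global background estimate (the mode of the nonzero-support
#' intensity histogram; zero when most of the frame is empty) with
#' clipping at zero, then applies a morphological
#' white top-hat with a disk structuring element to correct uneven
#' illumination. Features smaller than the disk (cells) pass through; the
#' smooth background, including linear ramps, is removed.
#'
#' @param x A `colony_image`, intensity matrix, or image path (RGB files
#'   are collapsed to luminance on read).
#' @param tophat_radius Disk radius in pixels (default 10).
#' @return A `colony_image` with corrected intensity (mask unset).
#' @export
preprocess_colony <- function(x, tophat_radius = 10) {
  x <- as_colony_image(x)
  tophat_radius <- assert_count(tophat_radius, "tophat_radius")
  img <- x$intensity
  if (all(img == 0)) abort("empty image")
  bg <- histogram_mode(img)
  img <- pmax(img - bg, 0)
  detection <- img
  kern <- EBImage::makeBrush(2L * tophat_radius + 1L, shape = "disc")
  # EBImage works on [x, y] and its grayscale morphology assumes [0, 1],
  # so scale intensities in and out; the symmetric disk kernel makes the
  # transposition harmless for our [row, col] convention.
  mx <- max(img)
  if (mx > 0) {
    img <- t(EBImage::whiteTopHat(EBImage::Image(t(img) / mx), kern)) * mx
  }
  img <- pmax(img, 0)
  colony_image(img, detection = detection, provenance = c(
    x$provenance,
    sprintf("background mode %.4g subtracted", bg),
    sprintf("white top-hat, disk radius %d", tophat_radius)))
}

# Background level estimate: mode of the nonzero-support intensity
# histogram. Zero pixels are excluded so that black padding (from
# cropping/translation) cannot drag the estimate down; when the frame is
# mostly empty (zeros in the majority) the background IS zero and nothing
# is subtracted. Quantized images (<= 256 distinct levels) use the exact
# most frequent level (ties to the lowest), continuous ones the fullest of
# 256 equal bins.
histogram_mode <- function(img) {
  v <- as.vector(img)
  nz <- v[v > 0]
  if (length(nz) < length(v) / 2) return(0)
  rng <- range(nz)
  if (diff(rng) == 0) return(rng[1L])
  lv <- sort(unique(nz))
  if (length(lv) <= 256L) {
    return(lv[which.max(tabulate(match(nz, lv)))])
  }
  h <- graphics::hist(nz, breaks = seq(rng[1L], rng[2L], length.out = 257L),
                      plot = FALSE)
  h$mids[which.max(h$counts)]
}

#' Threshold a preprocessed colony image into a cell mask
#'
#' Default is Otsu's method on the background-subtracted detection image
#' (the pre-top-hat field kept by [preprocess_colony()]); a fixed
#' threshold can be supplied instead. Thresholding the top-hat output is
#' available via `on = "tophat"`, but note that the top-hat suppresses
#' bright regions larger than its structuring element, which hollows out
#' densely fused compact colonies and inverts the density attribute —
#' the detection image keeps solid colony cores solid.
#'
#' @param x A `colony_image` (preprocessed).
#' @param method `"otsu"` or `"fixed"`.
#' @param fixed_threshold Intensity cutoff when `method = "fixed"`.
#' @param on `"detection"` (default) or `"tophat"`: which field to
#'   threshold. Falls back to the top-hat intensity when no detection
#'   field is present (e.g. a raw matrix wrapped directly).
#' @return The `colony_image` with its `mask` set.
#' @export
binarize_colony <- function(x, method = c("otsu", "fixed"),
                            fixed_threshold = NULL,
                            on = c("detection", "tophat")) {
  x <- as_colony_image(x)
  method <- match.arg(method)
  on <- match.arg(on)
  img <- if (on == "detection") x$detection %||% x$intensity else x$intensity
  th <- if (method == "otsu") {
    mx <- max(img)
    if (mx == 0) abort("no cells detected")
    EBImage::otsu(EBImage::Image(t(img) / mx), range = c(0, 1)) * mx
  } else {
    assert_scalar_number(fixed_threshold, "fixed_threshold")
    fixed_threshold
  }
  mask <- img > th
  if (!any(mask)) abort("no cells detected")
  colony_image(x$intensity, mask, detection = x$detection,
               provenance = c(x$provenance,
                              sprintf("binarized (%s on %s, threshold %.4g)",
                                      method, on, th)))
}

#' Translate a colony so its centroid sits at the image center
#'
#' The centroid is intensity-weighted over the mask region; the translation
#' is rounded to whole pixels and vacated pixels are zero-filled.
#'
#' @param x A `colony_image` with a mask.
#' @return The recentered `colony_image`.
#' @export
recenter_colony <- function(x) {
  x <- as_colony_image(x)
  if (is.null(x$mask) || !any(x$mask)) abort("mask required for recentering")
  w <- (x$detection %||% x$intensity) * x$mask
  if (sum(w) == 0) w <- x$mask * 1
  idx <- which(x$mask, arr.ind = TRUE)
  wts <- w[x$mask]
  cen <- c(sum(idx[, 1L] * wts), sum(idx[, 2L] * wts)) / sum(wts)
  target <- (dim(x$intensity) + 1) / 2
  shift <- round(target - cen)
  colony_image(shift_matrix(x$intensity, shift),
               shift_matrix(x$mask, shift) > 0,
               detection = if (!is.null(x$detection))
                 shift_matrix(x$detection, shift),
               provenance = c(x$provenance,
                 sprintf("recentered by (%d, %d)", shift[1L], shift[2L])))
}

# Integer-shift a matrix with zero fill.
shift_matrix <- function(m, shift) {
  out <- matrix(0, nrow(m), ncol(m))
  r <- seq_len(nrow(m)) - shift[1L]
  c <- seq_len(ncol(m)) - shift[2L]
  ok_r <- r >= 1 & r <= nrow(m)
  ok_c <- c >= 1 & c <= ncol(m)
  out[ok_r, ok_c] <- m[r[ok_r], c[ok_c]]
  out
}

# Rotate a matrix about its center (pixel-center of ((n+1)/2, (n+1)/2)) by
# `deg` degrees, bilinear interpolation, zero fill outside the frame.
rotate_bilinear <- function(m, deg) {
  if (deg %% 360 == 0) return(m)
  th <- deg * pi / 180
  nr <- nrow(m); nc <- ncol(m)
  ctr <- c((nr + 1) / 2, (nc + 1) / 2)
  g <- expand.grid(r = seq_len(nr), c = seq_len(nc))
  dr <- g$r - ctr[1L]; dc <- g$c - ctr[2L]
  # inverse mapping: sample the source at the back-rotated position
  sr <- ctr[1L] + cos(th) * dr - sin(th) * dc
  sc <- ctr[2L] + sin(th) * dr + cos(th) * dc
  r0 <- floor(sr); c0 <- floor(sc)
  fr <- sr - r0; fc <- sc - c0
  val <- function(ri, ci) {
    ok <- ri >= 1 & ri <= nr & ci >= 1 & ci <= nc
    v <- numeric(length(ri))
    v[ok] <- m[cbind(ri[ok], ci[ok])]
    v
  }
  out <- (1 - fr) * (1 - fc) * val(r0, c0) +
         (1 - fr) * fc       * val(r0, c0 + 1L) +
         fr       * (1 - fc) * val(r0 + 1L, c0) +
         fr       * fc       * val(r0 + 1L, c0 + 1L)
  matrix(out, nr, nc)
}

#' Rotation-averaged row intensity profile
#'
#' For each of `n_rotations` copies of the (recentered) image rotated by
#' multiples of `step_deg` about the image center, the per-row intensity
#' line plots are averaged over rows; the profiles of all rotations are
#' then averaged into a single 1D profile of length equal to the image
#' width. With the default 18 x 20 degrees the profile covers a full 360
#' degree sweep.
#'
#' @param x A `colony_image` (recentered) or intensity matrix.
#' @param n_rotations Number of rotated copies (default 18).
#' @param step_deg Rotation increment in degrees (default 20).
#' @return Numeric vector of length `ncol(intensity)`.
#' @export
average_row_profile <- function(x, n_rotations = 18, step_deg = 20) {
  img <- if (is.matrix(x)) x else as_colony_image(x)$intensity
  n_rotations <- assert_count(n_rotations, "n_rotations")
  assert_scalar_number(step_deg, "step_deg")
  if (abs(n_rotations * step_deg - 360) > 1e-8) {
    warn(sprintf("n_rotations * step_deg = %g does not cover 360 degrees",
                 n_rotations * step_deg))
  }
  acc <- numeric(ncol(img))
  for (k in seq_len(n_rotations) - 1L) {
    acc <- acc + colMeans(rotate_bilinear(img, k * step_deg))
  }
  acc / n_rotations
}

#' Fit a Gaussian to an intensity profile and return its SD
#'
#' Nonlinear least squares of `a * exp(-(x - mu)^2 / (2 sigma^2)) (+ c)`
#' initialized from the profile (amplitude = max, center = argmax, sigma
#' from the half-width at half-maximum / 1.177, offset = min). The fitted
#' `sigma` (pixels) is the cell-distribution measure.
#'
#' @param profile Numeric vector with a positive maximum.
#' @param allow_offset Include the additive offset `c` (default `TRUE`).
#' @return A `profile_fit` object; use `$sigma` or [tidy()] for the
#'   coefficients.
#' @export
fit_profile_sigma <- function(profile, allow_offset = TRUE) {
  stopifnot(is.numeric(profile))
  n <- length(profile)
  if (n < 4 || !any(is.finite(profile)) || max(profile) <= 0 ||
      diff(range(profile)) == 0) {
    abort("unfittable profile")
  }
  x <- seq_len(n)
  a0 <- max(profile)
  mu0 <- which.max(profile)
  c0 <- min(profile)
  half <- c0 + (a0 - c0) / 2
  s0 <- max(sum(profile >= half) / 2, 1) / 1.177
  df <- data.frame(x = x, y = profile)
  fit <- tryCatch({
    if (allow_offset) {
      minpack.lm::nlsLM(y ~ a * exp(-(x - mu)^2 / (2 * sigma^2)) + c,
                        data = df,
                        start = list(a = a0 - c0, mu = mu0, sigma = s0, c = c0),
                        lower = c(0, -Inf, 1e-6, -Inf),
                        control = minpack.lm::nls.lm.control(maxiter = 200))
    } else {
      minpack.lm::nlsLM(y ~ a * exp(-(x - mu)^2 / (2 * sigma^2)),
                        data = df,
                        start = list(a = a0, mu = mu0, sigma = s0),
                        lower = c(0, -Inf, 1e-6),
                        control = minpack.lm::nls.lm.control(maxiter = 200))
    }
  }, error = function(e) abort("unfittable profile"))
  cf <- coef(fit)
  sigma <- abs(unname(cf["sigma"]))
  if (!is.finite(sigma) || sigma <= 0 || sigma > n) abort("unfittable profile")
  structure(list(sigma = sigma, coefficients = cf,
                 fitted = stats::fitted(fit), profile = profile,
                 allow_offset = allow_offset),
            class = "profile_fit")
}

#' @export
print.profile_fit <- function(x, ...) {
  cat("<profile_fit> sigma =", format(x$sigma, digits = 5), "px\n")
  invisible(x)
}

#' Convex-hull pixel area of a binary mask
#'
#' Counts the pixels whose centers lie inside or on the convex hull of the
#' set pixels (integer arithmetic, so the count is exact). A single pixel
#' has area 1; collinear masks count the lattice pixels on the segment.
#'
#' @param mask Logical matrix with at least one set pixel.
#' @return Hull pixel count.
#' @export
hull_area <- function(mask) {
  stopifnot(is.logical(mask))
  pts <- which(mask, arr.ind = TRUE)
  if (nrow(pts) == 0) abort("empty mask")
  sum(hull_membership(pts))
}

# Logical vector/total count support: returns logical matrix over the
# bounding box is not needed; we just count candidate pixels inside hull.
# pts: integer matrix [n, 2] of (row, col).
hull_membership <- function(pts) {
  pts <- unique(pts[, 1:2, drop = FALSE])
  storage.mode(pts) <- "integer"
  n <- nrow(pts)
  if (n == 1L) return(TRUE)
  rr <- range(pts[, 1L]); cc <- range(pts[, 2L])
  cand <- as.matrix(expand.grid(r = rr[1L]:rr[2L], c = cc[1L]:cc[2L]))
  h <- chull(pts[, 2L], pts[, 1L])  # (x = col, y = row)
  hp <- pts[h, , drop = FALSE]
  if (nrow(hp) <= 2L || all_collinear(pts)) {
    # degenerate hull: pixels whose centers lie exactly on the segment
    a <- pts[which.min(pts[, 1L] * 1e6 + pts[, 2L]), ]
    b <- pts[which.max(pts[, 1L] * 1e6 + pts[, 2L]), ]
    cross <- (b[1L] - a[1L]) * (cand[, 2L] - a[2L]) -
             (b[2L] - a[2L]) * (cand[, 1L] - a[1L])
    on <- cross == 0 &
      cand[, 1L] >= min(a[1L], b[1L]) & cand[, 1L] <= max(a[1L], b[1L]) &
      cand[, 2L] >= min(a[2L], b[2L]) & cand[, 2L] <= max(a[2L], b[2L])
    return(on)
  }
  # chull returns vertices clockwise in (x, y); in (row, col) with row
  # increasing downwards this is counter-clockwise. Test all edges with a
  # consistent orientation sign.
  m <- nrow(hp)
  inside <- rep(TRUE, nrow(cand))
  # determine orientation once from the polygon's signed area
  nxt <- c(2:m, 1L)
  area2 <- sum(hp[, 2L] * hp[nxt, 1L] - hp[nxt, 2L] * hp[, 1L])
  s <- if (area2 >= 0) 1L else -1L
  for (i in seq_len(m)) {
    a <- hp[i, ]; b <- hp[nxt[i], ]
    cross <- (b[2L] - a[2L]) * (cand[, 1L] - a[1L]) -
             (b[1L] - a[1L]) * (cand[, 2L] - a[2L])
    inside <- inside & (s * cross >= 0)
    if (!any(inside)) break
  }
  inside
}

all_collinear <- function(pts) {
  if (nrow(pts) <= 2L) return(TRUE)
  a <- pts[1L, ]; b <- pts[2L, ]
  cross <- (b[1L] - a[1L]) * (pts[, 2L] - a[2L]) -
           (b[2L] - a[2L]) * (pts[, 1L] - a[1L])
  all(cross == 0)
}

#' In-hull cell density of a binary mask
#'
#' Fraction of the convex-hull pixels that contain cells.
#'
#' @param mask Logical matrix with at least one set pixel.
#' @param hull_px Optional precomputed [hull_area()] count.
#' @return Density in `(0, 1]`.
#' @export
hull_density <- function(mask, hull_px = NULL) {
  stopifnot(is.logical(mask))
  n_set <- sum(mask)
  if (n_set == 0) abort("empty mask")
  hull_px <- hull_px %||% hull_area(mask)
  if (hull_px < n_set) abort("hull_area smaller than mask pixel count")
  n_set / hull_px
}

#' Score one colony image
#'
#' Runs the full per-colony pipeline: preprocessing (background
#' subtraction + top-hat), binarization, centroid recentering, the
#' rotation-averaged row profile with its Gaussian fit, and the convex-hull
#' area and in-hull density of the mask.
#'
#' @param x A `colony_image`, `colony_sim`, intensity matrix, or image
#'   path.
#' @param tophat_radius Disk radius for the top-hat stage.
#' @param binarize_method,fixed_threshold,binarize_on Passed to
#'   [binarize_colony()].
#' @param n_rotations,step_deg Passed to [average_row_profile()].
#' @param allow_offset Passed to [fit_profile_sigma()].
#' @param preprocess Set `FALSE` if `x` is already background-corrected.
#' @return A one-row tibble: `sigma_px` (Gaussian SD of the averaged
#'   profile), `hull_area_px`, `density`, `mask_px`, `n_rotations`,
#'   `on_border` (mask touches the frame; hull and sigma are then lower
#'   bounds).
#' @export
score_colony <- function(x, tophat_radius = 10,
                         binarize_method = c("otsu", "fixed"),
                         fixed_threshold = NULL,
                         binarize_on = c("detection", "tophat"),
                         n_rotations = 18, step_deg = 20,
                         allow_offset = TRUE, preprocess = TRUE) {
  binarize_method <- match.arg(binarize_method)
  binarize_on <- match.arg(binarize_on)
  stage <- "preprocess"
  res <- tryCatch({
    ci <- as_colony_image(x)
    if (preprocess) ci <- preprocess_colony(ci, tophat_radius)
    stage <- "binarize"
    ci <- binarize_colony(ci, binarize_method, fixed_threshold, binarize_on)
    stage <- "recenter"
    ci <- recenter_colony(ci)
    stage <- "profile"
    prof <- average_row_profile(ci, n_rotations, step_deg)
    stage <- "fit"
    fit <- fit_profile_sigma(prof, allow_offset)
    stage <- "hull"
    hull_px <- hull_area(ci$mask)
    border <- any(ci$mask[1L, ]) || any(ci$mask[nrow(ci$mask), ]) ||
      any(ci$mask[, 1L]) || any(ci$mask[, ncol(ci$mask)])
    tibble::tibble(sigma_px = fit$sigma,
                   hull_area_px = hull_px,
                   density = hull_density(ci$mask, hull_px),
                   mask_px = sum(ci$mask),
                   n_rotations = as.integer(n_rotations),
                   on_border = border)
  }, error = function(e) {
    abort(sprintf("colony scoring failed at stage '%s': %s",
                  stage, conditionMessage(e)))
  })
  res
}

#' Score a batch of colony images
#'
#' @param x A tibble with a `sim` or `image` list-column or a `path`
#'   column (e.g. from [simulate_colony_set()]), a character vector of
#'   image paths, or a list of images. Identifier columns (`image_id`,
#'   `clone_id`, `role`) are carried through; rows keep their input order.
#' @param ... Passed to [score_colony()].
#' @return A tibble of per-colony features, one row per input image.
#' @export
score_colonies <- function(x, ...) {
  if (is.character(x)) x <- tibble::tibble(path = x)
  if (!is.data.frame(x)) x <- tibble::tibble(image = as.list(x))
  inputs <- if ("sim" %in% names(x)) x$sim
    else if ("image" %in% names(x)) x$image
    else if ("path" %in% names(x)) as.list(x$path)
    else abort("need a `sim`, `image` or `path` column")
  feats <- purrr::map_dfr(inputs, score_colony, ...)
  keep <- intersect(c("image_id", "clone_id", "role", "path",
                      "dispersion_sigma", "n_cells"), names(x))
  dplyr::bind_cols(x[keep], feats)
}

#' Averaged profile and Gaussian fit of one colony, for inspection
#'
#' Convenience wrapper that runs the scoring pipeline up to the profile
#' fit and returns the `profile_fit` object, whose [autoplot()] overlays
#' the fitted Gaussian on the profile.
#'
#' @inheritParams score_colony
#' @return A `profile_fit`.
#' @export
colony_profile <- function(x, tophat_radius = 10,
                           binarize_method = c("otsu", "fixed"),
                           fixed_threshold = NULL,
                           binarize_on = c("detection", "tophat"),
                           n_rotations = 18, step_deg = 20,
                           allow_offset = TRUE, preprocess = TRUE) {
  binarize_method <- match.arg(binarize_method)
  binarize_on <- match.arg(binarize_on)
  ci <- as_colony_image(x)
  if (preprocess) ci <- preprocess_colony(ci, tophat_radius)
  ci <- binarize_colony(ci, binarize_method, fixed_threshold, binarize_on)
  ci <- recenter_colony(ci)
  fit_profile_sigma(average_row_profile(ci, n_rotations, step_deg),
                    allow_offset)
}
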