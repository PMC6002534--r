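#' Parameters for a simulated metastatic colony image
#'
#' Bundles the tunable settings of the colony image generator. The defaults
#' emulate a single CAM metastatic colony as seen by fluorescence
#' stereomicroscopy: 50--100 GFP-labelled cells (default 75) scattered
#' about the extravasation point, rendered on an uneven background.
#'
#' @param n_cells Number of cells in the colony (>= 1).
#' @param dispersion_sigma Positional standard deviation of cell centers, in
#'   pixels. Cell centers are drawn i.i.d. from an isotropic bivariate
#'   normal about the image center; larger values give more "spread out"
#'   (motile) colonies.
#' @param cell_radius Radius of the uniform-intensity disk rendered for each
#'   cell, pixels.
#' @param cell_intensity Fluorescence added on cell pixels, arbitrary units.
#' @param background_level Flat background level, intensity units.
#' @param background_gradient Amplitude of a linear illumination ramp across
#'   columns, intensity units per pixel. Exercises the top-hat correction.
#' @param noise_sd Standard deviation of i.i.d. Gaussian pixel noise.
#' @param image_size Side length of the square image, pixels.
#' @param seed Optional integer seed; identical parameters + seed give a
#'   bit-identical image, mask and truth table.
#'
#' @return A `colony_sim_params` list.
#' @seealso [simulate_colony()], [simulate_colony_set()]
#' @export
#' @examples
#' p <- colony_sim_params(n_cells = 10, dispersion_sigma = 5,
#'                        image_size = 101, seed = 1)
#' sim <- simulate_colony(p)
#' dim(sim$image)
colony_sim_params <- function(n_cells = 75,
                              dispersion_sigma = 40,
                              cell_radius = 5,
                              cell_intensity = 1000,
                              background_level = 100,
                              background_gradient = 0.2,
                              noise_sd = 20,
                              image_size = 256,
                              seed = NULL) {
  n_cells <- assert_count(n_cells, "n_cells")
  assert_scalar_number(dispersion_sigma, "dispersion_sigma", lower = 0)
  assert_scalar_number(cell_radius, "cell_radius", lower = 0.5)
  assert_scalar_number(cell_intensity, "cell_intensity", lower = 0)
  assert_scalar_number(background_level, "background_level", lower = 0)
  assert_scalar_number(background_gradient, "background_gradient", lower = 0)
  assert_scalar_number(noise_sd, "noise_sd", lower = 0)
  image_size <- assert_count(image_size, "image_size", lower = 3)
  p <- list(n_cells = n_cells, dispersion_sigma = dispersion_sigma,
            cell_radius = cell_radius, cell_intensity = cell_intensity,
            background_level = background_level,
            background_gradient = background_gradient,
            noise_sd = noise_sd, image_size = image_size, seed = seed)
  # Frame must hold >= 99% of the center distribution (per axis squared).
  half <- image_size / 2 - cell_radius
  p_in <- if (dispersion_sigma == 0) 1 else
    (pnorm(half / dispersion_sigma) - pnorm(-half / dispersion_sigma))^2
  if (half <= 0 || p_in < 0.99) {
    abort(paste0("image_size ", image_size, " too small to contain the ",
                 "colony core at dispersion_sigma ", dispersion_sigma))
  }
  structure(p, class = "colony_sim_params")
}

#' Simulate one colony image with ground truth
#'
#' Draws cell centers from an isotropic bivariate normal about the image
#' center, renders each cell as a filled disk of uniform intensity, and adds
#' a flat background, a linear illumination ramp along columns, and Gaussian
#' noise (clipped at zero). The returned truth mask marks cell pixels only.
#'
#' @param params A [colony_sim_params()] object.
#' @return A list of class `colony_sim`:
#'   \describe{
#'     \item{image}{numeric matrix `[row, col]` of intensities (>= 0).}
#'     \item{mask}{logical matrix marking cell pixels.}
#'     \item{centers}{tibble of true cell centers (`row`, `col`).}
#'     \item{params}{the generating parameters.}
#'   }
#' @export
simulate_colony <- function(params) {
  stopifnot(inherits(params, "colony_sim_params"))
  with_seed_maybe(params$seed, {
    n <- params$image_size
    ctr <- (n + 1) / 2
    rows <- rnorm(params$n_cells, ctr, params$dispersion_sigma)
    cols <- rnorm(params$n_cells, ctr, params$dispersion_sigma)

    mask <- matrix(FALSE, n, n)
    rad <- params$cell_radius
    w <- ceiling(rad)
    for (i in seq_len(params$n_cells)) {
      r_lo <- max(1, floor(rows[i] - w)); r_hi <- min(n, ceiling(rows[i] + w))
      c_lo <- max(1, floor(cols[i] - w)); c_hi <- min(n, ceiling(cols[i] + w))
      if (r_lo > r_hi || c_lo > c_hi) next  # center fell outside the frame
      rr <- r_lo:r_hi
      cc <- c_lo:c_hi
      d2 <- outer((rr - rows[i])^2, (cc - cols[i])^2, `+`)
      mask[rr, cc] <- mask[rr, cc] | (d2 <= rad^2)
    }

    ramp <- matrix(params$background_gradient * (seq_len(n) - 1),
                   n, n, byrow = TRUE)
    img <- params$background_level + ramp
    if (params$noise_sd > 0) img <- img + rnorm(n * n, 0, params$noise_sd)
    img[mask] <- img[mask] + params$cell_intensity
    img <- pmax(img, 0)

    structure(list(image = img, mask = mask,
                   centers = tibble::tibble(row = rows, col = cols),
                   params = params),
              class = "colony_sim")
  })
}

#' Simulate a control/clone pair of colony image sets
#'
#' Emulates a colony re-injection experiment: `n_colonies` scramble-control
#' colonies at `control_sigma` and `n_colonies` clone colonies at
#' `clone_sigma`, with per-colony jitter in cell number (uniform within
#' +/- 25% of the base count, the 50--100 cells-per-colony regime at the
#' default base of 75). A smaller `clone_sigma` emulates a compact,
#' motility-inhibited clone.
#'
#' @param control_sigma,clone_sigma Positional dispersion (pixels) of the
#'   control and the clone colonies.
#' @param n_colonies Colonies per group (>= 2).
#' @param base A [colony_sim_params()] supplying all other settings.
#' @param clone_id,control_id Labels used in the grouping table.
#' @param out_dir Optional directory; when given, each image is written as a
#'   16-bit grayscale TIFF (intensities rounded to integer counts) and a
#'   grouping CSV `grouping.csv` (image_path, clone_id, role) is written
#'   alongside.
#' @param seed Optional master seed; per-colony seeds are derived from it,
#'   so a fixed seed reproduces the set (and the files) exactly.
#' @return A tibble with one row per colony: `image_id`, `clone_id`, `role`
#'   (`"control"`/`"clone"`), `dispersion_sigma`, `n_cells`, `seed`, a
#'   `sim` list-column of `colony_sim` objects, and `path` when `out_dir`
#'   is given.
#' @export
simulate_colony_set <- function(control_sigma, clone_sigma, n_colonies = 10,
                                base = colony_sim_params(),
                                clone_id = "clone", control_id = "scramble",
                                out_dir = NULL, seed = NULL) {
  n_colonies <- assert_count(n_colonies, "n_colonies", lower = 2)
  with_seed_maybe(seed, {
    plan <- tibble::tibble(
      clone_id = rep(c(control_id, clone_id), each = n_colonies),
      role = rep(c("control", "clone"), each = n_colonies),
      dispersion_sigma = rep(c(control_sigma, clone_sigma), each = n_colonies)
    )
    m <- nrow(plan)
    lo <- max(1L, round(base$n_cells * 0.75))
    hi <- round(base$n_cells * 1.25)
    plan$n_cells <- sample(lo:hi, m, replace = TRUE)
    plan$seed <- sample.int(2147483646L, m)
    plan$image_id <- sprintf("%s_%02d", plan$clone_id,
                             stats::ave(seq_len(m), plan$clone_id, FUN = seq_along))
    plan$sim <- purrr::pmap(
      list(plan$dispersion_sigma, plan$n_cells, plan$seed),
      function(sig, nc, sd_i) {
        p <- base
        p$dispersion_sigma <- sig
        p$n_cells <- nc
        p$seed <- sd_i
        class(p) <- "colony_sim_params"
        simulate_colony(p)
      })
    out <- dplyr::relocate(plan, "image_id")
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      out$path <- file.path(out_dir, paste0(out$image_id, ".tif"))
      purrr::walk2(out$sim, out$path,
                   function(s, f) write_colony_image(s$image, f))
      utils::write.csv(
        data.frame(image_path = out$path, clone_id = out$clone_id,
                   role = out$role),
        file.path(out_dir, "grouping.csv"), row.names = FALSE)
    }
    out
  })
}

#' Write a colony intensity matrix as a 16-bit grayscale TIFF
#'
#' Intensities are rounded to integer counts and stored on the 16-bit
#' scale; [read_colony_image()] inverts the scaling, so integer-valued
#' images round-trip exactly.
#'
#' @param image Numeric matrix of non-negative intensities (< 65536).
#' @param path Output file (`.tif` or `.png`).
#' @return `path`, invisibly.
#' @export
write_colony_image <- function(image, path) {
  stopifnot(is.matrix(image), all(image >= 0))
  counts <- round(image)
  if (max(counts) > 65535) abort("intensities exceed the 16-bit range")
  type <- if (grepl("\\.png$", path, ignore.case = TRUE)) "png" else "tiff"
  # EBImage stores [x, y]; transpose from our [row, col] convention.
  EBImage::writeImage(t(counts) / 65535, path, type = type,
                      bits.per.sample = 16L)
  invisible(path)
}

#' Read a colony image from TIFF or PNG
#'
#' RGB images are collapsed to luminance (0.2989 R + 0.5870 G + 0.1140 B).
#' Pixel values are returned on the 16-bit count scale, matching
#' [write_colony_image()].
#'
#' @param path Image file.
#' @return A numeric intensity matrix `[row, col]`.
#' @export
read_colony_image <- function(path) {
  img <- EBImage::readImage(path)
  dat <- EBImage::imageData(img)
  if (length(dim(dat)) == 3L) {
    wt <- c(0.2989, 0.5870, 0.1140)[seq_len(dim(dat)[3L])]
    wt <- wt / sum(wt)
    dat <- apply(sweep(dat, 3L, wt, `*`), c(1L, 2L), sum)
  }
  t(dat) * 65535
}
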