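# Per-colony attribute computation: preprocessing, masking, profile,
# Gaussian fit, hull and density.

test_that("preprocessing removes flat and ramped background, keeps cells", {
  # constant field is pure background
  flat <- matrix(37, 64, 64)
  out <- preprocess_colony(flat, tophat_radius = 10)
  expect_equal(max(out$intensity), 0)

  expect_error(preprocess_colony(matrix(0, 16, 16)), "empty image")

  # small bright disk on zero background passes through intact
  img <- disk_image(64, 3, height = 500)
  out2 <- preprocess_colony(img, tophat_radius = 10)
  inner <- disk_image(64, 2) > 0   # interior, away from rasterized rim
  expect_true(all(abs(out2$intensity[inner] - 500) < 1e-6))

  # disk on a linear ramp: peak recovered within 10% of its height,
  # matching a direct erosion/dilation top-hat oracle
  ramp <- matrix(rep(0.5 * (0:63), each = 64), 64, 64, byrow = FALSE)
  img3 <- ramp + disk_image(64, 3, height = 200)
  out3 <- preprocess_colony(img3, tophat_radius = 10)
  peak <- max(out3$intensity)
  expect_lt(abs(peak - 200) / 200, 0.10)
  # oracle agreement away from the border (opening propagates border
  # handling up to 2 * radius inwards)
  oracle <- oracle_white_tophat(img3, 10)
  interior <- matrix(FALSE, 64, 64); interior[22:43, 22:43] <- TRUE
  expect_lt(max(abs((out3$intensity - pmax(oracle, 0)) * interior)), 1e-6)
})

test_that("binarization separates clean classes and fails on empty masks", {
  img <- disk_image(64, 5, height = 1000) +
    matrix(runif(64 * 64, 0, 50), 64, 64)
  ci <- binarize_colony(colony_image(img))
  expect_identical(ci$mask, img >= 950)

  expect_error(binarize_colony(colony_image(img), method = "fixed",
                               fixed_threshold = max(img) + 1),
               "no cells detected")
})

test_that("binarized masks recover generator truth on noisy colonies", {
  s <- simulate_colony(colony_sim_params(n_cells = 60, dispersion_sigma = 20,
                                         noise_sd = 20, seed = 21))
  ci <- binarize_colony(preprocess_colony(s$image))
  jac <- sum(ci$mask & s$mask) / sum(ci$mask | s$mask)
  expect_gte(jac, 0.9)
})

test_that("recentering puts the mask centroid at the image center", {
  img <- disk_image(101, 6, height = 100, center = c(58, 47)) # offset blob
  ci <- recenter_colony(binarize_colony(colony_image(img)))
  idx <- which(ci$mask, arr.ind = TRUE)
  cen <- colMeans(idx)
  expect_lt(max(abs(cen - 51)), 1)

  # already centered: identity
  img0 <- disk_image(101, 6, height = 100)
  ci0 <- recenter_colony(binarize_colony(colony_image(img0)))
  expect_identical(ci0$intensity, img0)

  # offset by (+7, -4) is undone: recentered copies agree exactly
  imgS <- disk_image(101, 6, height = 100, center = c(51 + 7, 51 - 4))
  ciS <- recenter_colony(binarize_colony(colony_image(imgS)))
  expect_identical(ciS$intensity, ci0$intensity)
})

test_that("rotation-averaged profile respects symmetry", {
  iso <- gaussian_blob(101, 12)
  p1 <- average_row_profile(iso, 1, 360)
  p18 <- average_row_profile(iso, 18, 20)
  expect_lt(max(abs(p1 - p18)) / max(p1), 0.01)

  # smooth anisotropic bar vs its lossless 90-degree rotation
  bar <- gaussian_blob(101, sd_col = 15, sd_row = 4)
  pa <- average_row_profile(bar)
  pb <- average_row_profile(rot90_lossless(bar))
  expect_lt(max(abs(pa - pb)) / max(pa), 0.01)

  expect_identical(average_row_profile(matrix(0, 32, 32)), numeric(32))

  expect_warning(average_row_profile(iso, 5, 20), "360")
})

test_that("Gaussian profile fit recovers known parameters", {
  x <- 1:200
  for (sig in c(5, 10, 25)) {
    prof <- 80 * exp(-(x - 100)^2 / (2 * sig^2))
    fit <- fit_profile_sigma(prof)
    expect_lt(abs(fit$sigma - sig), 0.1)
  }
  # with additive offset
  prof <- 80 * exp(-(x - 90)^2 / (2 * 25^2)) + 5
  fit <- fit_profile_sigma(prof, allow_offset = TRUE)
  expect_lt(abs(fit$sigma - 25) / 25, 0.02)

  expect_error(fit_profile_sigma(numeric(50)), "unfittable profile")
  expect_error(fit_profile_sigma(rep(3, 50)), "unfittable profile")
})

test_that("hull area matches direct counts on canonical masks", {
  m <- matrix(FALSE, 20, 20); m[6:15, 6:15] <- TRUE    # filled square
  expect_equal(hull_area(m), 100)
  corners <- matrix(FALSE, 20, 20)
  corners[cbind(c(6, 6, 15, 15), c(6, 15, 6, 15))] <- TRUE
  expect_equal(hull_area(corners), 100)               # hull of the corners
  expect_equal(hull_density(corners), 4 / 100)
  expect_equal(hull_density(m), 1.0)

  single <- matrix(FALSE, 5, 5); single[3, 3] <- TRUE
  expect_equal(hull_area(single), 1)

  seg <- matrix(FALSE, 10, 10); seg[cbind(2:7, 2:7)] <- TRUE
  expect_equal(hull_area(seg), 6)                     # rasterized diagonal
  seg2 <- matrix(FALSE, 10, 10); seg2[3, c(2, 9)] <- TRUE
  expect_equal(hull_area(seg2), 8)                    # horizontal segment

  expect_error(hull_area(matrix(FALSE, 4, 4)), "empty mask")
})

test_that("hull area equals the brute-force half-plane oracle", {
  set.seed(42)
  for (k in 1:30) {
    npts <- sample(1:50, 1)
    m <- matrix(FALSE, 64, 64)
    m[cbind(sample(64, npts, TRUE), sample(64, npts, TRUE))] <- TRUE
    pts <- which(m, arr.ind = TRUE)
    expect_identical(as.integer(hull_area(m)),
                     as.integer(oracle_hull_count(pts)))
  }
})

test_that("adding an interior pixel raises density, keeps the hull", {
  corners <- matrix(FALSE, 20, 20)
  corners[cbind(c(6, 6, 15, 15), c(6, 15, 6, 15))] <- TRUE
  h0 <- hull_area(corners); d0 <- hull_density(corners)
  corners[10, 10] <- TRUE
  expect_equal(hull_area(corners), h0)
  expect_gt(hull_density(corners), d0)
})

test_that("score_colony is deterministic and satisfies the feature contract", {
  s <- simulate_colony(small_colony_params(seed = 31))
  f1 <- score_colony(s)
  f2 <- score_colony(s)
  expect_identical(f1, f2)
  expect_gt(f1$sigma_px, 0)
  expect_gte(f1$hull_area_px, f1$mask_px)
  expect_true(f1$density > 0 && f1$density <= 1)
  expect_error(score_colony(matrix(0, 32, 32)), "stage 'preprocess'")
})

test_that("score_colonies keeps input order and identifiers", {
  set <- simulate_colony_set(15, 6, 2, small_colony_params(), seed = 12)
  feats <- score_colonies(set)
  expect_equal(nrow(feats), 4L)
  expect_identical(feats$image_id, set$image_id)
  expect_identical(feats$clone_id, set$clone_id)
  # compact clone is denser and smaller than the dispersed control
  m <- tapply(feats$density, feats$role, mean)
  expect_gt(m[["clone"]], m[["control"]])
})

test_that("features are invariant under integer translation of the input", {
  s <- simulate_colony(small_colony_params(seed = 41))
  f0 <- score_colony(s$image)
  shifted <- matrix(0, 128, 128)
  shifted[1:119, 6:128] <- s$image[10:128, 1:123]
  f1 <- score_colony(shifted)
  expect_lt(abs(f1$sigma_px - f0$sigma_px) / f0$sigma_px, 0.01)
  expect_equal(f1$hull_area_px, f0$hull_area_px)
  expect_equal(f1$density, f0$density)
})

test_that("features are robust to lossless 90-degree rotation", {
  s <- simulate_colony(small_colony_params(seed = 51))
  f0 <- score_colony(s$image)
  f1 <- score_colony(rot90_lossless(s$image))
  expect_lt(abs(f1$sigma_px - f0$sigma_px) / f0$sigma_px, 0.02)
  expect_lt(abs(f1$hull_area_px - f0$hull_area_px) / f0$hull_area_px, 0.02)
})

test_that("attributes respond monotonically to colony dispersion", {
  base <- colony_sim_params(n_cells = 50, cell_radius = 4,
                            dispersion_sigma = 30, image_size = 192)
  sigmas <- c(5, 15, 30)
  means <- purrr::map_dfr(sigmas, function(sg) {
    set <- simulate_colony_set(30, sg, 5, base, seed = 60 + sg)
    f <- score_colonies(dplyr::filter(set, role == "clone"))
    tibble::tibble(sigma = sg, m_sigma = mean(f$sigma_px),
                   m_hull = mean(f$hull_area_px), m_dens = mean(f$density))
  })
  expect_true(all(diff(means$m_sigma) > 0))
  expect_true(all(diff(means$m_hull) > 0))
  expect_true(all(diff(means$m_dens) < 0))
})
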