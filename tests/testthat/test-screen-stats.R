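# Z-scores, the composite Compactness Index, hit calling, ANOVA/LSD, and
# the screen-design Poisson calculators.

fake_features <- function(clone_id, sigma, hull, dens) {
  tibble::tibble(clone_id = clone_id, sigma_px = sigma,
                 hull_area_px = hull, density = dens)
}

test_that("reference statistics use the n-1 sample SD", {
  f <- fake_features("ctrl", c(10, 12), c(100, 140), c(0.2, 0.4))
  ref <- reference_stats(f)
  d <- tidy(ref)
  expect_equal(d$mean[d$attribute == "density"], 0.3)
  expect_equal(d$sd[d$attribute == "density"], sd(c(0.2, 0.4)))
  expect_equal(d$sd[d$attribute == "density"], 0.1414214, tolerance = 1e-6)

  ident <- fake_features("ctrl", c(10, 10), c(100, 100), c(0.2, 0.2))
  expect_error(reference_stats(ident), "degenerate control")
  expect_error(reference_stats(f[1, ]), "at least 2")
})

test_that("z-scores and the compactness index follow the defining formulas", {
  expect_equal(z_score(5, 5, 2), 0)
  expect_equal(z_score(5 + 2 * 1.5, 5, 1.5), 2)
  expect_equal(z_score(7.5, 5.0, 1.25), 2.0)
  expect_error(z_score(1, 0, 0), "positive")

  expect_equal(compactness_index(0, 0, 0), 0)
  expect_equal(compactness_index(2, -1, -1), 4)
  expect_equal(compactness_index(1, 2, 3), -4)  # dispersed scores negative
})

test_that("a clone scored against its own reference gets exactly zero", {
  set.seed(8)
  f <- fake_features(rep("scramble", 12), rnorm(12, 20, 3),
                     rnorm(12, 5000, 600), runif(12, 0.3, 0.6))
  sc <- score_clones(f, control = "scramble")
  expect_identical(sc$ci, 0)
  expect_identical(sc$z_density + sc$z_distribution + sc$z_area, 0)
})

test_that("z-scores are invariant under common positive affine transforms", {
  set.seed(9)
  f <- dplyr::bind_rows(
    fake_features(rep("scramble", 10), rnorm(10, 20, 3),
                  rnorm(10, 5000, 600), runif(10, 0.3, 0.6)),
    fake_features(rep("cloneA", 10), rnorm(10, 12, 3),
                  rnorm(10, 3000, 600), runif(10, 0.5, 0.8)))
  sc1 <- score_clones(f, control = "scramble")
  f2 <- dplyr::mutate(f, sigma_px = 3.7 * sigma_px + 11)
  sc2 <- score_clones(f2, control = "scramble")
  expect_equal(sc2$z_distribution, sc1$z_distribution, tolerance = 1e-10)
  expect_equal(sc2$z_density, sc1$z_density)
})

test_that("LSD with two groups reduces to the pooled-variance t-test", {
  set.seed(10)
  d <- tibble::tibble(v = rnorm(24), g = rep(c("ctrl", "a"), each = 12))
  res <- lsd_compare(d, "v", "g", control = "ctrl")
  tt <- t.test(v ~ g, data = d, var.equal = TRUE)
  expect_lt(abs(res$p_lsd - tt$p.value), 1e-12)
  expect_lt(abs(res$p_omnibus - tt$p.value), 1e-12)  # F = t^2
})

test_that("LSD detects a strongly shifted clone", {
  set.seed(11)
  d <- tibble::tibble(
    v = c(rnorm(10), rnorm(10), rnorm(10) + 5),
    g = rep(c("ctrl", "a", "b"), each = 10))
  res <- lsd_compare(d, "v", "g", control = "ctrl")
  expect_lt(res$p_lsd[res$group == "b"], 0.001)
  expect_true(res$significant[res$group == "b"])
})

test_that("undersized groups are dropped with a warning", {
  d <- tibble::tibble(v = c(rnorm(10), rnorm(10), 1.3),
                      g = c(rep("ctrl", 10), rep("a", 10), "tiny"))
  expect_warning(res <- lsd_compare(d, "v", "g", control = "ctrl"), "tiny")
  expect_identical(res$group, "a")
})

test_that("null-calibrated LSD p-values have nominal type-I behaviour", {
  # 400 null replicates, 3 groups of 8: unadjusted LSD rejections at 5%
  # should be near nominal; the protected flag can only be rarer.
  set.seed(12)
  rej_p <- 0; rej_flag <- 0; tot <- 0
  for (r in 1:400) {
    d <- tibble::tibble(v = rnorm(24), g = rep(c("ctrl", "a", "b"), each = 8))
    res <- lsd_compare(d, "v", "g", control = "ctrl")
    rej_p <- rej_p + sum(res$p_lsd <= 0.05)
    rej_flag <- rej_flag + sum(res$significant)
    tot <- tot + nrow(res)
  }
  expect_gt(rej_p / tot, 0.03)
  expect_lt(rej_p / tot, 0.07)
  expect_lte(rej_flag, rej_p)
})

test_that("hit calling applies the C.I., p and single-shRNA gates", {
  scores <- tibble::tibble(
    clone_id = c("kif3b_like", "border", "ns", "multi"),
    ci = c(12.4, 4.9, 9.0, 20),
    p_vs_control = c(0.001, 0.001, 0.2, 0.001),
    single_shrna = c(TRUE, TRUE, TRUE, FALSE))
  hits <- call_hits(scores, ci_threshold = 5.0, alpha = 0.05)
  expect_true(hits$hit[hits$clone_id == "kif3b_like"])
  expect_false(hits$hit[hits$clone_id == "border"])
  expect_false(hits$hit[hits$clone_id == "ns"])
  expect_false(hits$hit[hits$clone_id == "multi"])
  # ranked by ci descending
  expect_identical(hits$clone_id, scores$clone_id[order(-scores$ci)])
})

test_that("single-integration probability follows the Poisson form", {
  expect_equal(moi_single_fraction(1e-9), 1, tolerance = 1e-6)
  expect_equal(moi_single_fraction(0.2), 0.2 * exp(-0.2) / (1 - exp(-0.2)))
  expect_equal(moi_single_fraction(0.2), 0.9033, tolerance = 1e-4)
  expect_equal(moi_single_fraction(1), exp(-1) / (1 - exp(-1)),
               tolerance = 1e-12)
  expect_error(moi_single_fraction(0), "positive")
  # Monte-Carlo cross-check of the conditional probability at MOI 0.2
  set.seed(13)
  k <- rpois(2e5, 0.2)
  mc <- mean(k[k >= 1] == 1)
  expect_lt(abs(mc - moi_single_fraction(0.2)), 0.01)
})

test_that("embryo coverage calculator matches the exact Poisson scan", {
  brute <- function(n_shrnas, cpe, min_copies, conf) {
    for (E in 1:10000) {
      lam <- E * cpe / n_shrnas
      if (ppois(min_copies - 1, lam, lower.tail = FALSE) >= conf) return(E)
    }
    NA_integer_
  }
  cases <- list(c(10, 100, 3, 0.99), c(1000, 50, 3, 0.99),
                c(500, 20, 1, 0.95), c(79805, 2500, 3, 0.5))
  for (cs in cases) {
    expect_equal(
      embryos_for_coverage(cs[1], cs[2], cs[3], cs[4]),
      brute(cs[1], cs[2], cs[3], cs[4]))
  }
  # trivial and monotone behaviour
  expect_equal(embryos_for_coverage(10, 100, 1, 1e-9), 1L)
  e1 <- embryos_for_coverage(1000, 50, 3, 0.99)
  e2 <- embryos_for_coverage(1000, 100, 3, 0.99)
  expect_lte(e2, e1)
  # whole-library mode demands at least as many embryos
  expect_gte(embryos_for_coverage(1000, 50, 3, 0.99, mode = "library"), e1)
})

test_that("score_clones integrates features into scored, tested clones", {
  set.seed(14)
  f <- dplyr::bind_rows(
    fake_features(rep("scramble", 10), rnorm(10, 25, 2),
                  rnorm(10, 9000, 500), rnorm(10, 0.35, 0.03)),
    fake_features(rep("compact", 10), rnorm(10, 12, 2),
                  rnorm(10, 3000, 500), rnorm(10, 0.7, 0.03)))
  meta <- tibble::tibble(clone_id = c("scramble", "compact"),
                         single_shrna = TRUE)
  sc <- score_clones(f, control = "scramble", clone_meta = meta)
  row <- dplyr::filter(sc, clone_id == "compact")
  expect_equal(row$ci,
               row$z_density - row$z_distribution - row$z_area)
  expect_gt(row$ci, 5)
  expect_lt(row$p_vs_control, 0.001)
  expect_true(is.na(sc$p_vs_control[sc$clone_id == "scramble"]))
  hits <- call_hits(sc)
  expect_true(hits$hit[hits$clone_id == "compact"])
})
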