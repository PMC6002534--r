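#' Simulate cell tracks as persistent random walks
#'
#' Each track takes steps of constant length `speed * dt`; at every step
#' the previous heading is kept with probability `persistence`, otherwise a
#' new heading is drawn uniformly. `persistence = 1` gives ballistic
#' (straight-line) motion, `persistence = 0` an uncorrelated random walk.
#' Defaults emulate intravital time-lapse tracking: frames every 15 min
#' over ~7 h, at least 20 cells per condition.
#'
#' @param n_tracks Number of tracks.
#' @param n_steps Steps per track (a track has `n_steps + 1` samples).
#' @param dt Sampling interval, minutes.
#' @param speed Step speed, pixels (or microns) per minute.
#' @param persistence Probability of keeping the previous heading, `[0, 1]`.
#' @param seed Optional seed.
#' @return A tibble with columns `track_id`, `t` (minutes), `x`, `y`.
#' @export
#' @examples
#' tr <- simulate_tracks(n_tracks = 2, n_steps = 4, seed = 1)
#' track_stats(tr)
simulate_tracks <- function(n_tracks = 20, n_steps = 28, dt = 15,
                            speed = 1, persistence = 0.8, seed = NULL) {
  n_tracks <- assert_count(n_tracks, "n_tracks")
  n_steps <- assert_count(n_steps, "n_steps")
  assert_scalar_number(dt, "dt", lower = 1e-9)
  assert_scalar_number(speed, "speed", lower = 0)
  assert_scalar_number(persistence, "persistence", 0, 1)
  with_seed_maybe(seed, {
    step_len <- speed * dt
    purrr::map_dfr(seq_len(n_tracks), function(i) {
      theta <- numeric(n_steps)
      theta[1L] <- runif(1, 0, 2 * pi)
      if (n_steps > 1) {
        for (k in 2:n_steps) {
          theta[k] <- if (runif(1) < persistence) theta[k - 1L] else
            runif(1, 0, 2 * pi)
        }
      }
      tibble::tibble(
        track_id = sprintf("track%03d", i),
        t = seq(0, n_steps) * dt,
        x = c(0, cumsum(step_len * cos(theta))),
        y = c(0, cumsum(step_len * sin(theta)))
      )
    })
  })
}

#' Simulate a qPCR Ct table with a known standard curve
#'
#' Builds a serial-dilution standard series from an idealized amplification
#' line `Ct = intercept + slope * log10(cells)` (default slope is the 100%
#' efficiency value, -1/log10(2) ~ -3.32 Ct per 10-fold), plus sample wells
#' whose Cts are generated from true cell numbers, and normalizer wells.
#'
#' @param true_cells Named numeric vector of true cell numbers per sample.
#' @param groups Optional character vector (same length) of group labels;
#'   defaults to the sample names.
#' @param standards Cell numbers of the dilution series.
#' @param slope,intercept Standard-curve parameters.
#' @param normalizer_ct Baseline normalizer (tissue input) Ct.
#' @param normalizer_shift Optional per-sample shift of the normalizer Ct,
#'   emulating unequal tissue input; the target Ct is shifted identically
#'   so that delta-Ct correction recovers the true cell numbers.
#' @param noise_sd Gaussian noise added to every Ct.
#' @param seed Optional seed.
#' @return A tidy Ct table: `sample`, `group`, `role`
#'   (`"standard"`/`"sample"`/`"normalizer"`), `ct`, `cells` (known for
#'   standards, `NA` otherwise).
#' @export
simulate_qpcr_table <- function(true_cells,
                                groups = NULL,
                                standards = 10^(2:6),
                                slope = -1 / log10(2),
                                intercept = 40,
                                normalizer_ct = 20,
                                normalizer_shift = 0,
                                noise_sd = 0, seed = NULL) {
  stopifnot(is.numeric(true_cells), length(true_cells) > 0,
            !is.null(names(true_cells)))
  groups <- groups %||% names(true_cells)
  shift <- rep_len(normalizer_shift, length(true_cells))
  with_seed_maybe(seed, {
    std <- tibble::tibble(
      sample = sprintf("std_%g", standards),
      group = "standard", role = "standard",
      ct = intercept + slope * log10(standards), cells = standards)
    smp <- tibble::tibble(
      sample = names(true_cells), group = groups, role = "sample",
      ct = unname(intercept + slope * log10(true_cells) + shift),
      cells = NA_real_)
    nrm <- tibble::tibble(
      sample = names(true_cells), group = groups, role = "normalizer",
      ct = normalizer_ct + shift, cells = NA_real_)
    out <- dplyr::bind_rows(std, smp, nrm)
    if (noise_sd > 0) out$ct <- out$ct + rnorm(nrow(out), 0, noise_sd)
    out
  })
}
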