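#' Per-track velocity and displacement-rate statistics
#'
#' For each track: `velocity` is the average speed of the track (total
#' path length divided by total time; identical to the mean per-step speed
#' at a fixed sampling interval), and `displacement_rate` (productive
#' migration) is the straight-line distance from the first to the last
#' position divided by the track time. `displacement_rate <= velocity`
#' always, with equality only for straight monotone motion.
#'
#' @param tracks Tibble with `track_id`, `t` (minutes), `x`, `y` (pixels
#'   or microns, one consistent unit).
#' @return A tibble with one row per track: `track_id`, `n_points`,
#'   `duration`, `path_length`, `displacement`, `velocity`,
#'   `displacement_rate`.
#' @export
track_stats <- function(tracks) {
  need <- c("track_id", "t", "x", "y")
  if (!all(need %in% names(tracks))) {
    abort("tracks need columns track_id, t, x, y")
  }
  tracks |>
    dplyr::group_by(.data$track_id) |>
    dplyr::group_modify(function(d, key) {
      d <- dplyr::arrange(d, .data$t)
      if (nrow(d) < 2) abort("each track needs at least 2 samples")
      if (any(duplicated(d$t))) abort("duplicate timestamps in a track")
      dt <- diff(d$t)
      steps <- sqrt(diff(d$x)^2 + diff(d$y)^2)
      total_t <- d$t[nrow(d)] - d$t[1L]
      disp <- sqrt((d$x[nrow(d)] - d$x[1L])^2 + (d$y[nrow(d)] - d$y[1L])^2)
      tibble::tibble(
        n_points = nrow(d),
        duration = total_t,
        path_length = sum(steps),
        displacement = disp,
        velocity = sum(steps) / total_t,
        displacement_rate = disp / total_t)
    }) |>
    dplyr::ungroup()
}

#' Compare a motility statistic across groups
#'
#' Group means with standard errors plus one-way ANOVA and Fisher's LSD
#' comparisons against the control group (see [lsd_compare()]).
#'
#' @param stats Per-track statistics (from [track_stats()]) with a group
#'   column, or any tidy table of per-observation values.
#' @param value Column to compare (e.g. `"displacement_rate"`).
#' @param group Grouping column (default `"group"`).
#' @param control Control group label.
#' @param alpha Significance level.
#' @return The [lsd_compare()] tibble.
#' @export
compare_groups <- function(stats, value, group = "group", control,
                           alpha = 0.05) {
  lsd_compare(stats, value = value, group = group, control = control,
              alpha = alpha)
}

#' Map angles to their acute equivalent
#'
#' Every angle is reduced to the sharper of the two angles its line makes,
#' i.e. into `[0, 90]` degrees: `min(a mod 180, 180 - a mod 180)`. The
#' mapping is idempotent.
#'
#' @param angles Angles in degrees.
#' @return Acute angles in `[0, 90]`.
#' @export
acute_angle <- function(angles) {
  m <- angles %% 180
  pmin(m, 180 - m)
}

#' Acute-angle frequency distribution
#'
#' Bins the acute equivalents of the input angles into half-open bins of
#' `bin` degrees over `[0, 90]`; the top bin is closed at 90.
#'
#' @param angles Angles in degrees (any range; mapped via [acute_angle()]).
#' @param bin Bin width in degrees (default 10).
#' @return An `angle_distribution` tibble: `bin_start`, `bin_end`,
#'   `count`, `frequency`; `n` and `bin_width` as attributes.
#' @export
angle_histogram <- function(angles, bin = 10) {
  stopifnot(is.numeric(angles), all(is.finite(angles)))
  assert_scalar_number(bin, "bin", lower = 1e-9, upper = 90)
  a <- acute_angle(angles)
  starts <- seq(0, 90 - bin, by = bin)
  idx <- pmin(floor(a / bin), length(starts) - 1L)  # 90 falls in the top bin
  counts <- tabulate(idx + 1L, nbins = length(starts))
  out <- tibble::tibble(
    bin_start = starts,
    bin_end = starts + bin,
    count = counts,
    frequency = counts / length(a))
  structure(out, n = length(a), bin_width = bin,
            class = c("angle_distribution", class(out)))
}

#' Fit a qPCR standard curve
#'
#' Least-squares line `Ct = slope * log10(cells) + intercept` through the
#' dilution standards. A valid amplification series has a negative slope
#' (about -3.32 Ct per 10-fold dilution at 100% efficiency); a
#' non-negative slope triggers a warning.
#'
#' @param standards Tibble with `cells` and `ct` columns, or a full qPCR
#'   table (with a `role` column) from which `role == "standard"` rows are
#'   taken.
#' @return A `standard_curve` object with `slope`, `intercept`,
#'   `r_squared`, and the Ct `dynamic_range`; see [tidy()] / [glance()].
#' @export
fit_standard_curve <- function(standards) {
  if ("role" %in% names(standards)) {
    standards <- dplyr::filter(standards, .data$role == "standard")
  }
  if (!all(c("cells", "ct") %in% names(standards))) {
    abort("standards need `cells` and `ct` columns")
  }
  standards <- dplyr::filter(standards, is.finite(.data$cells),
                             .data$cells > 0, is.finite(.data$ct))
  if (length(unique(standards$cells)) < 3) {
    abort("need at least 3 distinct dilution levels")
  }
  fit <- lm(ct ~ log10(cells), data = standards)
  slope <- unname(coef(fit)[2L])
  if (slope >= 0) warn("invalid amplification: non-negative slope")
  sst <- sum((standards$ct - mean(standards$ct))^2)
  r2 <- if (sst > 0) 1 - sum(resid(fit)^2) / sst else NA_real_
  structure(list(
    slope = slope,
    intercept = unname(coef(fit)[1L]),
    r_squared = r2,
    dynamic_range = range(standards$ct),
    efficiency = 10^(-1 / slope) - 1,
    n = nrow(standards),
    standards = tibble::as_tibble(standards[c("cells", "ct")])),
    class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat("<standard_curve> Ct =", format(x$slope, digits = 5),
      "* log10(cells) +", format(x$intercept, digits = 5),
      "\n  R^2 =", format(x$r_squared, digits = 4),
      "; efficiency =", format(100 * x$efficiency, digits = 4),
      "%; Ct range", format(x$dynamic_range[1L], digits = 4), "-",
      format(x$dynamic_range[2L], digits = 4), "\n")
  invisible(x)
}

#' @rdname fit_standard_curve
#' @param x A `standard_curve`.
#' @param ... Unused.
#' @export
tidy.standard_curve <- function(x, ...) {
  tibble::tibble(term = c("intercept", "slope"),
                 estimate = c(x$intercept, x$slope))
}

#' @rdname fit_standard_curve
#' @export
glance.standard_curve <- function(x, ...) {
  tibble::tibble(r_squared = x$r_squared, efficiency = x$efficiency,
                 n_standards = x$n,
                 ct_min = x$dynamic_range[1L], ct_max = x$dynamic_range[2L])
}

#' Absolute cell numbers from a Ct via the standard curve
#'
#' @param ct Ct values.
#' @param curve A `standard_curve`.
#' @return Estimated cell numbers, `10^((ct - intercept)/slope)`.
#' @export
cells_from_ct <- function(ct, curve) {
  stopifnot(inherits(curve, "standard_curve"))
  10^((ct - curve$intercept) / curve$slope)
}

#' Quantify metastatic burden from a qPCR table
#'
#' Converts target Cts to absolute cell numbers via the standard curve
#' after delta-Ct normalization for tissue input: each sample's target Ct
#' is corrected by the deviation of its normalizer Ct from the run-mean
#' normalizer Ct. Group burdens are expressed relative to the control
#' group mean (control = 100%).
#'
#' @param qpcr Tidy Ct table with columns `sample`, `role`
#'   (`"sample"`/`"normalizer"`; `"standard"` rows are ignored here),
#'   `ct`, and optionally `group` (defaults to the sample name).
#' @param curve A `standard_curve` (from [fit_standard_curve()], possibly
#'   on the same table).
#' @param control Control group label.
#' @return A list with `samples` (per-sample tibble: `sample`, `group`,
#'   `ct`, `ct_adjusted`, `cells`, `extrapolated` — Ct outside the curve's
#'   dynamic range) and `groups` (per-group tibble: `group`, `n`,
#'   `mean_cells`, `relative_burden_pct`).
#' @export
quantify_burden <- function(qpcr, curve, control) {
  stopifnot(inherits(curve, "standard_curve"))
  need <- c("sample", "role", "ct")
  if (!all(need %in% names(qpcr))) {
    abort("qpcr table needs sample, role and ct columns")
  }
  if (!"group" %in% names(qpcr)) qpcr$group <- qpcr$sample
  smp <- dplyr::filter(qpcr, .data$role == "sample")
  nrm <- dplyr::filter(qpcr, .data$role == "normalizer")
  if (nrow(smp) == 0) abort("no sample rows")
  dct <- 0
  if (nrow(nrm) > 0) {
    nrm_mean <- mean(nrm$ct)
    nmap <- setNames(nrm$ct - nrm_mean, nrm$sample)
    dct <- unname(nmap[smp$sample])
    dct[is.na(dct)] <- 0
  }
  samples <- smp |>
    dplyr::mutate(
      ct_adjusted = .data$ct - dct,
      cells = cells_from_ct(.data$ct_adjusted, curve),
      extrapolated = .data$ct_adjusted < curve$dynamic_range[1L] |
        .data$ct_adjusted > curve$dynamic_range[2L]) |>
    dplyr::select("sample", "group", "ct", "ct_adjusted", "cells",
                  "extrapolated")
  groups <- samples |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(n = dplyr::n(), mean_cells = mean(.data$cells),
                     .groups = "drop")
  if (!control %in% groups$group) abort("control group missing from samples")
  ctrl_mean <- groups$mean_cells[groups$group == control]
  groups$relative_burden_pct <- 100 * groups$mean_cells / ctrl_mean
  list(samples = samples, groups = groups)
}
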