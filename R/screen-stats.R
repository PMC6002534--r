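#' Control reference statistics for the compactness attributes
#'
#' Computes, per colony attribute (`sigma_px`, `hull_area_px`, `density`),
#' the sample mean and sample standard deviation (n - 1 denominator) across
#' the control colonies. These define the Z-score scale for every clone.
#'
#' @param control_features A features tibble (as from [score_colonies()])
#'   containing the control colonies only.
#' @return A `ref_stats` tibble with columns `attribute`, `mean`, `sd` and
#'   an `n_control` attribute.
#' @export
reference_stats <- function(control_features) {
  attrs <- c("sigma_px", "hull_area_px", "density")
  if (!all(attrs %in% names(control_features))) {
    abort("control features need sigma_px, hull_area_px and density columns")
  }
  n <- nrow(control_features)
  if (n < 2) abort("need at least 2 control colonies")
  out <- tibble::tibble(
    attribute = attrs,
    mean = unname(vapply(attrs, function(a) mean(control_features[[a]]), 0)),
    sd = unname(vapply(attrs, function(a) sd(control_features[[a]]), 0)))
  if (any(out$sd <= 0)) abort("degenerate control: zero spread in an attribute")
  structure(out, n_control = n, class = c("ref_stats", class(out)))
}

#' @export
print.ref_stats <- function(x, ...) {
  cat("<ref_stats> control reference from", attr(x, "n_control"),
      "colonies\n")
  NextMethod()
}

#' @rdname reference_stats
#' @param x A `ref_stats` object.
#' @param ... Unused.
#' @export
tidy.ref_stats <- function(x, ...) {
  tibble::as_tibble(x)
}

#' Attribute Z-score against the control reference
#'
#' `Z = (clone attribute mean - control attribute mean) / control attribute
#' SD`.
#'
#' @param clone_mean Clone attribute mean (vectorized).
#' @param ref_mean,ref_sd Control mean and standard deviation.
#' @return Dimensionless Z-score(s).
#' @export
z_score <- function(clone_mean, ref_mean, ref_sd) {
  if (any(ref_sd <= 0)) abort("reference SD must be positive")
  unname((clone_mean - ref_mean) / ref_sd)
}

#' Composite Compactness Index
#'
#' `C.I. = Z(density) - Z(cell distribution) - Z(area)`. Density rises in
#' compact colonies while spread and area fall, so all three terms push the
#' C.I. of a compact (motility-inhibited) clone positive; dispersed, motile
#' colonies score negative.
#'
#' @param z_density,z_distribution,z_area Attribute Z-scores (vectorized).
#' @return The composite index.
#' @export
compactness_index <- function(z_density, z_distribution, z_area) {
  z_density - z_distribution - z_area
}

#' Score clones against a control reference
#'
#' Builds the control reference, computes per-clone attribute means and
#' Z-scores, the clone-level Compactness Index, and per-clone significance
#' against the control via one-way ANOVA with Fisher's LSD on per-colony
#' C.I. values (each colony Z-scored individually against the reference).
#'
#' @param features Per-colony features (from [score_colonies()]) with a
#'   `clone_id` column.
#' @param control Clone id of the scramble/negative control.
#' @param clone_meta Optional tibble (`clone_id`, `single_shrna`) merged
#'   into the result.
#' @param alpha Omnibus gate for the protected LSD comparisons.
#' @return A `clone_scores` tibble: one row per clone with attribute means,
#'   `z_density`, `z_distribution`, `z_area`, `ci`, `n_colonies`,
#'   `p_vs_control` (`NA` for the control itself) and, when provided,
#'   `single_shrna`. The per-colony C.I. table is attached as attribute
#'   `"colony_ci"`; the reference as `"reference"`.
#' @export
score_clones <- function(features, control, clone_meta = NULL,
                         alpha = 0.05) {
  if (!"clone_id" %in% names(features)) abort("features need a clone_id column")
  if (!control %in% features$clone_id) {
    abort(sprintf("control clone '%s' not present", control))
  }
  ref <- reference_stats(dplyr::filter(features, .data$clone_id == control))
  rs <- setNames(ref$sd, ref$attribute)
  rm_ <- setNames(ref$mean, ref$attribute)

  colony_ci <- features |>
    dplyr::mutate(
      ci = compactness_index(
        z_score(.data$density, rm_["density"], rs["density"]),
        z_score(.data$sigma_px, rm_["sigma_px"], rs["sigma_px"]),
        z_score(.data$hull_area_px, rm_["hull_area_px"], rs["hull_area_px"]))) |>
    dplyr::select("clone_id", "ci")

  lsd <- if (length(unique(features$clone_id)) >= 2) {
    lsd_compare(colony_ci, value = "ci", group = "clone_id",
                control = control, alpha = alpha)
  } else {
    tibble::tibble(group = character(), p_lsd = numeric())
  }

  scores <- features |>
    dplyr::group_by(.data$clone_id) |>
    dplyr::summarise(
      n_colonies = dplyr::n(),
      mean_sigma_px = mean(.data$sigma_px),
      mean_hull_area_px = mean(.data$hull_area_px),
      mean_density = mean(.data$density),
      .groups = "drop") |>
    dplyr::mutate(
      z_density = z_score(.data$mean_density, rm_["density"], rs["density"]),
      z_distribution = z_score(.data$mean_sigma_px, rm_["sigma_px"],
                               rs["sigma_px"]),
      z_area = z_score(.data$mean_hull_area_px, rm_["hull_area_px"],
                       rs["hull_area_px"]),
      ci = compactness_index(.data$z_density, .data$z_distribution,
                             .data$z_area)) |>
    dplyr::left_join(dplyr::select(lsd, clone_id = "group",
                                   p_vs_control = "p_lsd"),
                     by = "clone_id")
  scores$p_vs_control[scores$clone_id == control] <- NA_real_
  if (!is.null(clone_meta)) {
    scores <- dplyr::left_join(scores, clone_meta, by = "clone_id")
  }
  structure(scores, reference = ref, colony_ci = colony_ci,
            control = control,
            class = c("clone_scores", class(scores)))
}

#' One-way ANOVA with Fisher's LSD comparisons against a control
#'
#' Classical protected LSD: a one-way ANOVA across all groups, then
#' unadjusted pairwise comparisons of each group against the control using
#' the pooled within-group variance (`t` on the residual degrees of
#' freedom, two-sided). The `significant` flag gates the per-comparison
#' test on the omnibus ANOVA at `alpha`; the unadjusted LSD p-values are
#' reported either way. Groups with fewer than 2 observations are dropped
#' with a warning.
#'
#' @param data Tibble in long form.
#' @param value,group Column names of the response and the grouping factor.
#' @param control Group label of the control.
#' @param alpha Significance level for the omnibus gate and the flag.
#' @return A tibble with one row per non-control group: `group`, `n`,
#'   `mean`, `sem`, `diff` (group - control), `t`, `p_lsd`, `p_omnibus`,
#'   `significant`.
#' @export
lsd_compare <- function(data, value, group, control, alpha = 0.05) {
  v <- data[[value]]
  g <- as.character(data[[group]])
  ok <- is.finite(v) & !is.na(g)
  v <- v[ok]; g <- g[ok]
  sizes <- table(g)
  small <- names(sizes)[sizes < 2]
  if (length(small)) {
    warn(paste("dropping groups with < 2 observations:",
               paste(small, collapse = ", ")))
    keep <- !(g %in% small)
    v <- v[keep]; g <- g[keep]
  }
  if (!control %in% g) abort("control group missing (or has < 2 observations)")
  if (length(unique(g)) < 2) abort("need at least 2 groups")

  fit <- aov(v ~ factor(g))
  p_omni <- summary(fit)[[1]][["Pr(>F)"]][1]
  mse <- sum(resid(fit)^2) / fit$df.residual
  df_res <- fit$df.residual

  means <- tapply(v, g, mean)
  ns <- tapply(v, g, length)
  others <- setdiff(names(means), control)
  tval <- (means[others] - means[control]) /
    sqrt(mse * (1 / ns[others] + 1 / ns[control]))
  p <- 2 * pt(-abs(tval), df_res)
  tibble::tibble(
    group = others,
    n = as.integer(ns[others]),
    mean = unname(means[others]),
    sem = unname(tapply(v, g, sd)[others] / sqrt(ns[others])),
    diff = unname(means[others] - means[control]),
    t = unname(tval),
    p_lsd = unname(p),
    p_omnibus = p_omni,
    significant = p_omni <= alpha & p <= alpha)
}

#' Call screen hits from clone scores
#'
#' A clone is a hit when its LSD p-value is at most `alpha`, its
#' Compactness Index is at least `ci_threshold`, and (optionally) it
#' carries a single shRNA. For example, a single-shRNA clone with
#' C.I. = 12.4 and p < 0.001 is a hit at the default threshold of 5.0.
#'
#' @param scores A `clone_scores` tibble (from [score_clones()]).
#' @param ci_threshold Minimum C.I. (default 5.0).
#' @param alpha Maximum p-value (default 0.05).
#' @param require_single_shrna Require the `single_shrna` flag (default
#'   `TRUE` when the column is present).
#' @return The scores with a `hit` flag, control row dropped, sorted by
#'   `ci` descending (ties broken by `clone_id`).
#' @export
call_hits <- function(scores, ci_threshold = 5.0, alpha = 0.05,
                      require_single_shrna = "single_shrna" %in% names(scores)) {
  control <- attr(scores, "control")
  out <- tibble::as_tibble(scores)
  if (!is.null(control)) out <- dplyr::filter(out, .data$clone_id != control)
  hit <- !is.na(out$p_vs_control) & out$p_vs_control <= alpha &
    out$ci >= ci_threshold
  if (require_single_shrna) {
    if (!"single_shrna" %in% names(out)) {
      abort("single_shrna column required (supply clone_meta to score_clones)")
    }
    hit <- hit & out$single_shrna %in% TRUE
  }
  out$hit <- hit
  dplyr::arrange(out, dplyr::desc(.data$ci), .data$clone_id)
}

#' Probability of a single lentiviral integration at a given MOI
#'
#' Under Poisson integration statistics, the probability that a transduced
#' cell (>= 1 integration) carries exactly one integration:
#' `moi * exp(-moi) / (1 - exp(-moi))`. At the screen's MOI of 0.2 this is
#' about 0.90, which is why low-MOI transduction favors single-shRNA
#' clones.
#'
#' @param moi Multiplicity of infection (> 0, vectorized).
#' @return Probability of exactly one integration given at least one.
#' @export
moi_single_fraction <- function(moi) {
  if (any(moi <= 0)) abort("moi must be positive")
  moi * exp(-moi) / (1 - exp(-moi))
}

#' Embryos needed for library coverage
#'
#' Smallest number of embryos `E` such that, with each shRNA's colony count
#' Poisson with mean `lambda = E * colonies_per_embryo / n_shrnas`, the
#' coverage requirement holds at the given confidence. Two interpretations
#' are exposed: `"per_shrna"` (default) requires
#' `P(X >= min_copies) >= confidence` for one shRNA; `"library"` requires
#' it jointly for all `n_shrnas` hairpins (independence approximation).
#'
#' @param n_shrnas Library size.
#' @param colonies_per_embryo Scored colonies contributed per embryo.
#' @param min_copies Required representation per shRNA (e.g. 3 for 3x).
#' @param confidence Required probability, in (0, 1).
#' @param mode `"per_shrna"` or `"library"`.
#' @return Integer embryo count.
#' @export
embryos_for_coverage <- function(n_shrnas, colonies_per_embryo,
                                 min_copies = 3, confidence = 0.99,
                                 mode = c("per_shrna", "library")) {
  mode <- match.arg(mode)
  n_shrnas <- assert_count(n_shrnas, "n_shrnas")
  assert_scalar_number(colonies_per_embryo, "colonies_per_embryo", lower = 1e-9)
  min_copies <- assert_count(min_copies, "min_copies")
  assert_scalar_number(confidence, "confidence", lower = 1e-12, upper = 1 - 1e-12)
  conf <- if (mode == "library") confidence^(1 / n_shrnas) else confidence
  ok <- function(E) {
    lambda <- E * colonies_per_embryo / n_shrnas
    ppois(min_copies - 1, lambda, lower.tail = FALSE) >= conf
  }
  if (!ok(1e6)) abort("coverage unsatisfiable with <= 1e6 embryos")
  lo <- 1; hi <- 1e6
  while (hi > lo) {
    mid <- floor((lo + hi) / 2)
    if (ok(mid)) hi <- mid else lo <- mid + 1
  }
  as.integer(lo)
}
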