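#' Convert sediment depth to age under a constant sedimentation rate
#'
#' `age (yr) = 10 * depth_cm / omega_mm_yr` — depth in cm, lead-210-derived
#' sedimentation rate in mm/yr.
#'
#' @param depth_cm Depth(s) below the sediment surface, cm, `>= 0`.
#' @param omega_mm_yr Sedimentation rate, mm/yr, `> 0`.
#' @return Age(s) in years.
#' @examples
#' depth_to_age(1.4, 0.76)  # ~18.4 yr
#' @export
depth_to_age <- function(depth_cm, omega_mm_yr) {
  if (any(omega_mm_yr <= 0)) rlang::abort("depth_to_age: omega_mm_yr must be > 0")
  if (any(depth_cm < 0)) rlang::abort("depth_to_age: depth_cm must be >= 0")
  10 * depth_cm / omega_mm_yr
}

#' Time for a population doubling every `distance_cm` of burial
#'
#' The depth-to-time conversion for a growth trend expressed per cm of
#' sediment: numerically identical to [depth_to_age()], exposed under the name
#' used in the worked example (a guild doubling every 1.4 cm at sedimentation
#' rates of 0.76 and 0.29 mm/yr doubles every ~18 and ~48 years).
#'
#' @param distance_cm Doubling distance, cm, `> 0`.
#' @param omega_mm_yr Sedimentation rate, mm/yr, `> 0`.
#' @return Doubling time in years.
#' @export
doubling_from_distance <- function(distance_cm, omega_mm_yr) {
  if (any(distance_cm <= 0)) {
    rlang::abort("doubling_from_distance: distance_cm must be > 0")
  }
  depth_to_age(distance_cm, omega_mm_yr)
}

#' Fit an exponential decay or growth to (age, abundance) points
#'
#' Ordinary least squares on `ln(abundance)` versus age; the rate constant is
#' the negated slope for decay and the slope for growth, and
#' `half_life = ln(2) / rate` is the half-life (decay) or doubling time
#' (growth). Zero abundances cannot enter the log fit: they are dropped and
#' counted, and if more than half of the points are zero the fit is refused.
#' A fitted slope whose sign contradicts `direction` is returned flagged
#' (`converged = FALSE`), not raised. `method = "nls"` refines the OLS
#' solution by nonlinear least squares on the natural scale
#' (`a * exp(s * age)`); both methods coincide on noise-free input.
#'
#' @param age Ages in years, strictly increasing.
#' @param abundance Non-negative abundances (same length).
#' @param direction `"decay"` or `"growth"`.
#' @param method `"ols"` (default) or `"nls"`.
#' @return One-row tibble: direction, rate_constant (1/yr), half_life (yr),
#'   intercept (log-abundance at the first age), r_squared, n_points,
#'   n_zero_dropped, converged.
#' @export
fit_exponential <- function(age, abundance, direction = c("decay", "growth"),
                            method = c("ols", "nls")) {
  direction <- match.arg(direction)
  method <- match.arg(method)
  if (length(age) != length(abundance)) {
    rlang::abort("fit_exponential: age and abundance lengths differ")
  }
  if (any(diff(age) <= 0)) {
    rlang::abort("fit_exponential: ages must be strictly increasing")
  }
  if (any(abundance < 0)) rlang::abort("fit_exponential: negative abundance")
  zero <- abundance == 0
  n_zero <- sum(zero)
  if (n_zero > length(abundance) / 2) {
    rlang::abort(paste0("fit_exponential: ", n_zero, "/", length(abundance),
                        " zero abundances in the window; fit refused"),
                 class = "hadalguilds_insufficient_data")
  }
  a <- age[!zero]
  y <- abundance[!zero]
  if (length(a) < 3L) {
    rlang::abort("fit_exponential: fewer than 3 usable points",
                 class = "hadalguilds_insufficient_data")
  }
  fit <- stats::lm(log(y) ~ a)
  slope <- unname(stats::coef(fit)[2])
  intercept0 <- unname(stats::coef(fit)[1])
  if (method == "nls") {
    nl <- tryCatch(
      stats::nls(y ~ A * exp(s * a),
                 start = list(A = exp(intercept0), s = slope),
                 control = stats::nls.control(maxiter = 200, warnOnly = TRUE,
                                              scaleOffset = 1)),
      error = function(e) NULL)
    if (!is.null(nl)) {
      cf <- stats::coef(nl)
      slope <- unname(cf["s"])
      intercept0 <- log(unname(cf["A"]))
    }
  }
  # summary.lm warns on an exactly collinear (noise-free) series; that case is
  # legitimate here and simply yields r2 = 1
  r2 <- suppressWarnings(summary(fit)$r.squared)
  rate <- if (direction == "decay") -slope else slope
  converged <- is.finite(rate) && rate > 0
  tibble::tibble(
    direction = direction,
    rate_constant = rate,
    half_life = if (converged) log(2) / rate else NA_real_,
    intercept = intercept0 + slope * a[1],
    r_squared = r2,
    n_points = length(a),
    n_zero_dropped = n_zero,
    converged = converged
  )
}

#' Per-site exponential kinetics of guild abundance profiles
#'
#' For each site and group, converts horizon midpoints to ages with that
#' site's sedimentation rate and fits [fit_exponential()] inside a depth
#' window. The decay window defaults to the ferruginous zone (NO3 penetration
#' depth down to the deepest horizon); growth fits (e.g. putative fermenters)
#' use an explicit window, by default 6.5-9.5 cm. The cross-site summary is
#' the (min, max) of the per-site half-lives/doubling times, no pooling.
#'
#' @param group_abund Matrix, groups x samples.
#' @param metadata `sample_metadata` tibble (zone column not required; the
#'   window derives from the NO3 penetration depth).
#' @param groups Character vector of group rows to fit; default all rows.
#' @param direction `"decay"` or `"growth"`.
#' @param window `NULL` for the per-site default, or `c(top_cm, bottom_cm)`.
#' @param method Passed to [fit_exponential()].
#' @param min_points Minimum usable horizons per site (default 3); sites with
#'   fewer are skipped with a warning.
#' @return List with `fits` (tibble: site_id, group, window, fit columns) and
#'   `range` (tibble: group, half_life_min, half_life_max over converged
#'   fits).
#' @export
fit_guild_kinetics <- function(group_abund, metadata, groups = NULL,
                               direction = c("decay", "growth"),
                               window = NULL, method = "ols",
                               min_points = 3L) {
  direction <- match.arg(direction)
  metadata <- validate_table(metadata, "sample_metadata")
  if (is.null(groups)) groups <- rownames(group_abund)
  if (direction == "growth" && is.null(window)) window <- c(6.5, 9.5)
  metadata <- metadata[metadata$sample_id %in% colnames(group_abund), ]
  mid <- (metadata$depth_top_cm + metadata$depth_bottom_cm) / 2

  fits <- list()
  for (s in unique(metadata$site_id)) {
    in_site <- metadata$site_id == s
    omega <- metadata$sedimentation_rate_mm_yr[in_site][1]
    win <- if (is.null(window)) {
      c(metadata$no3_penetration_cm[in_site][1], Inf)
    } else {
      window
    }
    sel <- in_site & mid >= win[1] & mid <= win[2]
    if (sum(sel) < min_points) {
      rlang::warn(paste0("fit_guild_kinetics: site '", s, "' has ", sum(sel),
                         " horizon(s) in window [", win[1], ", ", win[2],
                         "] cm; skipped"))
      next
    }
    ord <- order(mid[sel])
    ages <- depth_to_age(mid[sel][ord], omega)
    samp <- metadata$sample_id[sel][ord]
    for (g in groups) {
      fit <- tryCatch(
        fit_exponential(ages, group_abund[g, samp], direction, method),
        hadalguilds_insufficient_data = function(e) NULL)
      if (is.null(fit)) {
        rlang::warn(paste0("fit_guild_kinetics: insufficient data for group '",
                           g, "' at site '", s, "'"))
        next
      }
      fits[[length(fits) + 1L]] <- dplyr::bind_cols(
        tibble::tibble(site_id = s, group = g,
                       window_top_cm = win[1],
                       window_bottom_cm = if (is.finite(win[2])) win[2]
                                          else max(mid[sel])),
        fit)
    }
  }
  if (length(fits) == 0L) {
    rlang::abort("fit_guild_kinetics: no site had enough horizons in the window")
  }
  fits <- dplyr::bind_rows(fits)
  ok <- fits[fits$converged, ]
  range_tbl <- dplyr::summarise(
    dplyr::group_by(ok, .data$group),
    half_life_min = min(.data$half_life),
    half_life_max = max(.data$half_life),
    n_sites = dplyr::n(),
    .groups = "drop")
  list(fits = fits, range = range_tbl)
}
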