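#' Box-counting configuration
#'
#' Controls the dyadic grid used by [box_counting_dimension()]. Box sides
#' are `eps = 2^-k` on the unit square for each exponent `k`; the dimension
#' is the regression slope over `fit_range` only, excluding the coarsest
#' and finest exponents where counts saturate.
#'
#' @param box_exponents Integer exponents `k` to evaluate (default `2:9`).
#' @param fit_range Exponents used for the log-log slope (default `3:8`;
#'   at least 3 values, all contained in `box_exponents`).
#' @return A `box_count_config` list.
#' @export
box_count_config <- function(box_exponents = 2:9, fit_range = 3:8) {
  box_exponents <- sort(unique(as.integer(box_exponents)))
  fit_range <- sort(unique(as.integer(fit_range)))
  if (!all(fit_range %in% box_exponents)) {
    abort("fit_range must be a subset of box_exponents")
  }
  if (length(fit_range) < 3) {
    abort("fit_range needs at least 3 exponents")
  }
  structure(list(box_exponents = box_exponents, fit_range = fit_range),
            class = "box_count_config")
}

#' Sample standard deviation of a channel
#'
#' Magnitude of gait fluctuations: the plain sample standard deviation
#' (denominator `N - 1`) of one channel over the full recording.
#'
#' @param x Numeric samples in channel units.
#' @return Scalar SD, same units as `x`.
#' @export
channel_sd <- function(x) {
  if (length(x) < 2) abort("channel_sd needs at least 2 samples")
  sd(x)
}

# Grid-cell counts of the normalized graph covering, one count per box
# exponent. The series is mapped to the unit square by min-max
# normalization of both axes; within each time column the piecewise-linear
# graph covers the vertical interval between its column minimum and
# maximum (including interpolated values at column boundaries). The count
# per column is the number of grid lines crossed by that interval
# (floor(ymax/eps) - floor(ymin/eps)), whose expectation under a uniform
# grid offset is exactly span/eps: counting occupied cells instead (one
# more per column) inflates coarse-scale counts and biases the slope low.
box_counts_normalized <- function(y, tt, exponents) {
  map_dbl(exponents, function(k) {
    nb <- 2L^k
    # interpolated graph values at interior column boundaries
    vb <- if (nb > 1) approx(tt, y, xout = (1:(nb - 1)) / nb)$y else numeric()
    lef <- c(NA_real_, vb)
    rig <- c(vb, NA_real_)
    ymin <- pmin(lef, rig, na.rm = TRUE)
    ymax <- pmax(lef, rig, na.rm = TRUE)
    if (nb == 1) ymin <- ymax <- y[1]
    # per-column extremes over the samples; columns are contiguous runs
    col <- pmin(floor(tt * nb), nb - 1L) + 1L
    starts <- which(c(TRUE, diff(col) > 0))
    ends <- c(starts[-1] - 1L, length(col))
    rc <- col[starts]
    rmin <- vapply(seq_along(starts),
                   function(i) min(y[starts[i]:ends[i]]), 0)
    rmax <- vapply(seq_along(starts),
                   function(i) max(y[starts[i]:ends[i]]), 0)
    ymin[rc] <- pmin(ymin[rc], rmin, na.rm = TRUE)
    ymax[rc] <- pmax(ymax[rc], rmax, na.rm = TRUE)
    keep <- is.finite(ymin) & is.finite(ymax)
    lo <- floor(ymin[keep] * nb)
    hi <- pmin(floor(ymax[keep] * nb), nb - 1)
    max(sum(hi - lo), 1)
  })
}

#' Box-counting fractal dimension of a time series graph
#'
#' Estimates the box-counting dimension `D` of the graph `{(t_i, x_i)}`:
#' the graph is mapped to the unit square by min-max normalization of both
#' axes (making the estimate invariant under affine amplitude transforms),
#' covered by dyadic grids of side `eps = 2^-k`, and `D` is the
#' least-squares slope of `log N(eps)` versus `log(1/eps)` over the
#' configured fit range. `N(eps)` counts, per time column, the grid lines
#' crossed by the vertical extent of the interpolated graph, a
#' grid-phase-unbiased covering count (see [box_count_config()]).
#'
#' Values near 1 indicate a smooth trace; values near 2 an extremely
#' irregular one. A fractional Brownian path with Hurst exponent `H` has
#' graph dimension `2 - H`, the reference used to validate this estimator.
#'
#' @param x Numeric samples.
#' @param t Optional time stamps (defaults to equally spaced).
#' @param config A [box_count_config()].
#' @return Scalar dimension estimate. Constant input returns 1 (flat line)
#'   with a warning; estimates outside `[0.95, 2.05]` warn.
#' @export
#' @examples
#' box_counting_dimension(seq(0, 1, length.out = 4096))   # ~1
box_counting_dimension <- function(x, t = NULL, config = box_count_config()) {
  if (length(x) < 2) abort("need at least 2 samples")
  if (is.null(t)) t <- seq_along(x) - 1
  if (length(t) != length(x)) abort("t and x lengths differ")
  rx <- range(x)
  if (diff(rx) == 0) {
    warn("constant signal: box-counting dimension defined as 1 (flat line)")
    return(1.0)
  }
  kmax <- max(config$box_exponents)
  if (length(x) < 2^kmax) {
    warn(sprintf(paste0("only %d samples for box exponents up to %d ",
                        "(>= %d recommended)"), length(x), kmax, 2^kmax))
  }
  y <- (x - rx[1]) / diff(rx)
  tt <- (t - t[1]) / (t[length(t)] - t[1])
  counts <- box_counts_normalized(y, tt, config$box_exponents)
  sel <- match(config$fit_range, config$box_exponents)
  lk <- config$box_exponents[sel] * log(2)
  d <- unname(coef(lm(log(counts[sel]) ~ lk))[2])
  if (d < 0.95 || d > 2.05) {
    warn(sprintf("dimension estimate %.3f outside [1, 2] by more than 0.05", d))
  }
  d
}

#' Variability profile of a six-channel recording
#'
#' The twelve variability indices of a walking recording: per-channel
#' sample standard deviation ([channel_sd()], fluctuation magnitude) and
#' box-counting fractal dimension ([box_counting_dimension()], fluctuation
#' complexity), computed on the full recording including turnarounds.
#'
#' @param series An [imu_series()].
#' @param config A [box_count_config()].
#' @return A tibble with one row per channel: `channel`, `sd`, `d`.
#' @export
variability_profile <- function(series, config = box_count_config()) {
  validate_imu_series(series)
  tt <- series$t
  tibble(channel = imu_channels(),
         sd = map_dbl(imu_channels(), ~ channel_sd(series[[.x]])),
         d = map_dbl(imu_channels(),
                     ~ box_counting_dimension(series[[.x]], t = tt,
                                              config = config)))
}

#' Per-participant variability index table for a cohort
#'
#' Computes the twelve indices for every participant and lays them out one
#' row per participant with columns `sd_<channel>` and `d_<channel>`, plus
#' the TUG time and faller label - the table all threshold classifiers are
#' fitted on.
#'
#' @param cohort Cohort tibble with `participant_id`, `tug_s`, `faller`
#'   and a `series` list column (see [load_cohort()], [generate_cohort()]).
#' @param config A [box_count_config()].
#' @return A tibble with columns `participant_id`, `sd_a_ml`, ...,
#'   `d_w_ap`, `tug_s`, `faller`.
#' @export
cohort_indices <- function(cohort, config = box_count_config()) {
  prof <- cohort %>%
    mutate(profile = map(.data$series, variability_profile, config = config)) %>%
    select("participant_id", "tug_s", "faller", "profile") %>%
    tidyr::unnest("profile") %>%
    tidyr::pivot_wider(names_from = "channel", values_from = c("sd", "d"))
  prof %>% select("participant_id",
                  tidyr::starts_with("sd_"), tidyr::starts_with("d_"),
                  "tug_s", "faller")
}
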