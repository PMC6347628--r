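#' Detect modes of a 4DTv distribution by Gaussian kernel density
#'
#' A Gaussian KDE is evaluated on a regular grid over `[0, 1]`; modes are
#' grid points strictly greater than both neighbours whose density reaches
#' at least `min_density_frac` of the global maximum. `bandwidth = "auto"`
#' uses Silverman's rule of thumb ([stats::bw.nrd0()]).
#'
#' @param values Numeric vector of 4DTv values in `[0, 1]` (non-finite
#'   values are dropped); at least 10 finite values are required.
#' @param bandwidth Positive bandwidth or `"auto"`.
#' @param grid_step Grid spacing over `[0, 1]` (default 0.001).
#' @param min_density_frac Minimum mode density as a fraction of the maximum
#'   density (default 0.05).
#' @return A tibble of class `fourdtv_peaks` with columns `location`,
#'   `density`, `bandwidth`, `n`, sorted by location; the full density curve
#'   is attached as attribute `"curve"` (tibble `grid`, `density`).
#' @export
kde_modes <- function(values, bandwidth = "auto", grid_step = 0.001,
                      min_density_frac = 0.05) {
  values <- values[is.finite(values)]
  if (length(values) < 10L) {
    abort("insufficient data: at least 10 finite 4DTv values are required")
  }
  if (any(values < 0 | values > 1)) abort("4DTv values must lie in [0, 1]")
  if (grid_step <= 0 || grid_step >= 1) abort("grid_step must lie in (0, 1)")
  bw <- if (identical(bandwidth, "auto")) bw.nrd0(values) else bandwidth
  if (!is.finite(bw) || bw <= 0) bw <- grid_step
  n_grid <- round(1 / grid_step) + 1L
  d <- density(values, bw = bw, kernel = "gaussian", from = 0, to = 1, n = n_grid)
  y <- d$y
  k <- length(y)
  is_mode <- c(FALSE, y[2:(k - 1)] > y[1:(k - 2)] & y[2:(k - 1)] > y[3:k], FALSE)
  is_mode <- is_mode & y >= min_density_frac * max(y)
  out <- tibble::tibble(location = d$x[is_mode], density = y[is_mode],
                        bandwidth = bw, n = length(values))
  out <- dplyr::arrange(out, .data$location)
  attr(out, "curve") <- tibble::tibble(grid = d$x, density = y)
  class(out) <- c("fourdtv_peaks", class(out))
  out
}

#' Calibration anchor converting 4DTv to million years
#'
#' Strict linear molecular-clock scaling through the origin: an event of
#' known age (by default the grass rho WGD, 4DTv 0.38 at ~70 MYA) fixes the
#' rate, and any other peak dates as `location * anchor_time / anchor_4dtv`.
#'
#' @param anchor_4dtv 4DTv of the reference event (> 0; default 0.38).
#' @param anchor_time Age of the reference event in MY (> 0; default 70).
#' @return A named list of class `fourdtv_calibration` with fields
#'   `anchor_4dtv`, `anchor_time`, `rate` (4DTv units per MY).
#' @export
calibration <- function(anchor_4dtv = 0.38, anchor_time = 70) {
  if (anchor_4dtv <= 0 || anchor_time <= 0) {
    abort("calibration anchors must be strictly positive")
  }
  structure(list(anchor_4dtv = anchor_4dtv, anchor_time = anchor_time,
                 rate = anchor_4dtv / anchor_time),
            class = "fourdtv_calibration")
}

#' Convert 4DTv peaks to divergence dates
#'
#' @param peaks A [kde_modes()] result (or any tibble with a `location`
#'   column).
#' @param cal A [calibration()].
#' @return The peaks tibble with a `time_mya` column appended.
#' @export
date_from_peak <- function(peaks, cal = calibration()) {
  stopifnot(inherits(cal, "fourdtv_calibration"))
  dplyr::mutate(tibble::as_tibble(peaks),
                time_mya = .data$location * cal$anchor_time / cal$anchor_4dtv)
}

#' Run the peak-detection and dating pipeline per pair class
#'
#' Groups a [fourdtv()] result table by `class_col`, drops undefined values
#' (zero scorable sites) with a logged count, detects modes per class and
#' converts them to dates. Classes with fewer than 10 defined values are
#' omitted with a warning.
#'
#' @param results A [fourdtv()] result tibble.
#' @param class_col Name of the class label column (default `"cohort"`).
#' @param cal A [calibration()].
#' @param bandwidth,grid_step,min_density_frac Passed to [kde_modes()].
#' @return Tibble of class `wgd_dating` with one row per (class, mode):
#'   `class`, `n`, `mode_index`, `is_major` (the class's highest-density
#'   mode, its headline estimate), `location`, `density`, `bandwidth`,
#'   `time_mya`. Per-class density curves are attached as attribute
#'   `"curves"`.
#' @export
run_dating_pipeline <- function(results, class_col = "cohort", cal = calibration(),
                                bandwidth = "auto", grid_step = 0.001,
                                min_density_frac = 0.05) {
  results <- tibble::as_tibble(results)
  if (!class_col %in% names(results)) {
    abort(paste0("unknown class column: ", class_col))
  }
  n_undef <- sum(!results$defined)
  if (n_undef > 0) {
    inform(paste0("excluded ", n_undef, " pair(s) with no scorable fourfold sites"))
  }
  results <- results[results$defined, , drop = FALSE]
  curves <- list()
  rows <- list()
  for (cls in sort(unique(results[[class_col]]))) {
    vals <- results$fourdtv[results[[class_col]] == cls]
    if (length(vals) < 10L) {
      warn(paste0("class '", cls, "' has fewer than 10 pairs; omitted"))
      next
    }
    pk <- kde_modes(vals, bandwidth = bandwidth, grid_step = grid_step,
                    min_density_frac = min_density_frac)
    curves[[cls]] <- attr(pk, "curve")
    dated <- date_from_peak(pk, cal)
    if (nrow(dated)) {
      rows[[cls]] <- dplyr::mutate(dated, class = cls,
                                   mode_index = dplyr::row_number(),
                                   is_major = .data$density == max(.data$density),
                                   .before = 1L)
    }
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out)) out <- dplyr::relocate(out, "class", "n", "mode_index")
  attr(out, "curves") <- curves
  attr(out, "calibration") <- cal
  class(out) <- c("wgd_dating", class(out))
  out
}

#' @export
tidy.wgd_dating <- function(x, ...) {
  out <- tibble::as_tibble(x)
  attr(out, "curves") <- NULL
  attr(out, "calibration") <- NULL
  class(out) <- setdiff(class(out), "wgd_dating")
  out
}

#' @export
glance.wgd_dating <- function(x, ...) {
  cal <- attr(x, "calibration")
  tibble::tibble(n_classes = length(unique(x$class)),
                 n_modes = nrow(x),
                 anchor_4dtv = cal$anchor_4dtv,
                 anchor_time = cal$anchor_time)
}

#' Plot per-class 4DTv density curves with detected modes
#'
#' @param x A [run_dating_pipeline()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.wgd_dating <- function(x, ...) {
  curves <- attr(x, "curves")
  curve_df <- dplyr::bind_rows(purrr::imap(curves, ~dplyr::mutate(.x, class = .y)))
  ggplot2::ggplot(curve_df, ggplot2::aes(x = .data$grid, y = .data$density,
                                         colour = .data$class)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(data = tibble::as_tibble(x),
                        ggplot2::aes(xintercept = .data$location,
                                     colour = .data$class),
                        linetype = "dashed", show.legend = FALSE) +
    ggplot2::labs(x = "4DTv", y = "density", colour = "pair class") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.wgd_dating
#' @param dating A [run_dating_pipeline()] result.
#' @export
plot_fourdtv_density <- function(dating, ...) autoplot.wgd_dating(dating, ...)
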