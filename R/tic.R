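## Moving-average smoothing with truncated (renormalized) edges, columnwise.
## Y: n x p matrix (n samples per column). window must be odd.
ma_truncated <- function(Y, window) {
  if (window <= 1) return(Y)
  if (window %% 2 == 0) stop("smoothing window must be odd", call. = FALSE)
  Y <- as.matrix(Y)
  n <- nrow(Y)
  h <- (window - 1) / 2
  cs <- rbind(0, apply(Y, 2, cumsum))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L, , drop = FALSE] - cs[lo, , drop = FALSE]) / (hi - lo + 1L)
}

#' Detect TIC landmarks on a raw trace
#'
#' Landmarks of the wash-in phase: the baseline (mean of an initial
#' pre-arrival window of `max(3, ceil(0.05 n))` samples), the peak (earliest
#' global maximum of the smoothed trace), and the enhancement start — the
#' first time the smoothed trace crosses
#' `baseline + threshold_frac * (y_peak - baseline)`, linearly interpolated
#' between samples. A trace whose enhancement `y_peak - baseline` does not
#' exceed `noise_floor` is flagged `no_enhancement`; a peak on the final frame
#' (washout not observed) is flagged `censored_peak`.
#'
#' @param y raw intensity samples (`>= 4`).
#' @param t times, seconds, strictly increasing, same length as `y`.
#' @param smooth_window centered moving-average window in frames (odd; edges
#'   use a truncated window). Default 5.
#' @param threshold_frac enhancement-start threshold as a fraction of peak
#'   enhancement above baseline, in (0, 1). Default 0.05.
#' @param noise_floor minimum enhancement (intensity units) to count as a
#'   perfused pixel. Default 0.
#' @return A list: `baseline`, `t_start`, `t_peak`, `y_peak`, `y_start`
#'   (smoothed intensity at `t_start`), and `quality` in
#'   `"ok"`, `"no_enhancement"`, `"censored_peak"`, `"degenerate"`.
#' @export
detect_landmarks <- function(y, t, smooth_window = 5, threshold_frac = 0.05,
                             noise_floor = 0) {
  if (length(y) < 4) stop("need at least 4 samples", call. = FALSE)
  stopifnot(length(t) == length(y), threshold_frac > 0, threshold_frac < 1)
  lm <- landmarks_matrix(matrix(y, ncol = 1), t, smooth_window,
                         threshold_frac, noise_floor)
  lapply(lm, `[`, 1)
}

# Vectorized landmark detection over columns of the trace matrix Y (T x N).
landmarks_matrix <- function(Y, t, smooth_window, threshold_frac, noise_floor) {
  n <- nrow(Y); N <- ncol(Y)
  Ys <- ma_truncated(Y, smooth_window)
  m <- max(3L, ceiling(0.05 * n))
  baseline <- colMeans(Ys[seq_len(m), , drop = FALSE])
  ipk <- max.col(t(Ys), ties.method = "first")  # earliest global max
  y_peak <- Ys[cbind(ipk, seq_len(N))]
  enh <- y_peak - baseline

  quality <- rep("ok", N)
  quality[enh <= noise_floor] <- "no_enhancement"
  quality[quality == "ok" & ipk == n] <- "censored_peak"

  thr <- baseline + threshold_frac * enh
  t_start <- y_start <- rep(NA_real_, N)
  ok <- quality == "ok"
  for (j in which(ok)) {
    above <- Ys[seq_len(ipk[j]), j] >= thr[j]
    i <- which.max(above)           # first TRUE
    if (!above[i]) i <- ipk[j]      # numerically possible only at the peak
    if (i == 1L) {
      t_start[j] <- t[1L]
      y_start[j] <- Ys[1L, j]
    } else {
      f <- (thr[j] - Ys[i - 1L, j]) / (Ys[i, j] - Ys[i - 1L, j])
      t_start[j] <- t[i - 1L] + f * (t[i] - t[i - 1L])
      y_start[j] <- thr[j]          # crossing level by construction
    }
  }
  t_peak <- ifelse(ok, t[ipk], NA_real_)
  quality[ok & t_peak <= t_start] <- "degenerate"
  list(baseline = baseline, t_start = t_start, t_peak = t_peak,
       y_peak = ifelse(quality %in% c("ok", "censored_peak"), y_peak, NA_real_),
       y_start = y_start, i_peak = ipk, quality = quality)
}

#' Extract one pixel's time-intensity curve
#'
#' @param loop a [cineloop()] (motion-corrected upstream).
#' @param row,col pixel indices (1-based, row 1 at the top).
#' @param smooth_window,threshold_frac,noise_floor see [detect_landmarks()].
#' @return A tibble of class `tic_curve` with columns `t`, `y` (raw),
#'   `y_smooth`; landmark fields are attached as attribute `landmarks`.
#' @export
extract_tic <- function(loop, row, col, smooth_window = 5,
                        threshold_frac = 0.05, noise_floor = 0) {
  stopifnot(inherits(loop, "cineloop"))
  fd <- frame_dim(loop)
  if (row < 1 || row > fd[1] || col < 1 || col > fd[2]) {
    stop("pixel (", row, ", ", col, ") outside frame bounds ",
         fd[1], " x ", fd[2], call. = FALSE)
  }
  y <- loop$frames[, row, col]
  ys <- as.vector(ma_truncated(matrix(y, ncol = 1), smooth_window))
  lm <- detect_landmarks(y, loop$times, smooth_window, threshold_frac,
                         noise_floor)
  structure(
    tibble::tibble(t = loop$times, y = y, y_smooth = ys),
    class = c("tic_curve", class(tibble::tibble())),
    landmarks = lm, pixel = c(row = row, col = col)
  )
}

#' @export
print.tic_curve <- function(x, ...) {
  lm <- attr(x, "landmarks")
  cat(sprintf("<tic_curve> pixel (%d, %d), %d samples, quality: %s\n",
              attr(x, "pixel")[1], attr(x, "pixel")[2], nrow(x), lm$quality))
  if (lm$quality %in% c("ok", "censored_peak")) {
    cat(sprintf("  baseline %.3f | start %.2f s | peak %.2f s (y = %.3f)\n",
                lm$baseline, lm$t_start, lm$t_peak, lm$y_peak))
  }
  NextMethod()
}

#' Mean gradient to peak of a TIC
#'
#' The average slope of the TIC over the wash-in phase, from the start of
#' enhancement to the point of peak intensity. Because the mean of a
#' derivative over an interval is the endpoint difference divided by the
#' interval length, this is
#' `(y_peak - y(t_start)) / (t_peak - t_start)` (with `gradient_from =
#' "baseline"`, the lower endpoint is the baseline instead of the
#' threshold-crossing intensity).
#'
#' @param curve a `tic_curve` from [extract_tic()] with quality `"ok"`.
#' @param gradient_from lower endpoint of the wash-in interval:
#'   `"start_intensity"` (default) or `"baseline"`.
#' @return intensity/s (`>= 0` for an ok-quality curve).
#' @export
mean_gradient_to_peak <- function(curve,
                                  gradient_from = c("start_intensity",
                                                    "baseline")) {
  gradient_from <- match.arg(gradient_from)
  lm <- attr(curve, "landmarks")
  if (is.null(lm)) stop("curve has no landmarks; use extract_tic()", call. = FALSE)
  if (lm$quality != "ok") {
    stop("mean gradient undefined for quality '", lm$quality, "'", call. = FALSE)
  }
  lower <- if (gradient_from == "baseline") lm$baseline else lm$y_start
  (lm$y_peak - lower) / (lm$t_peak - lm$t_start)
}

## ---- parametric map ---------------------------------------------------------

#' Configuration for pixel-wise map computation
#'
#' @param smooth_window temporal moving-average window, frames (odd).
#' @param threshold_frac enhancement-start threshold fraction.
#' @param noise_floor minimum enhancement counting as perfusion.
#' @param gradient_from lower endpoint for the mean gradient
#'   (`"start_intensity"` or `"baseline"`).
#' @return A named list of class `map_config`.
#' @export
map_config <- function(smooth_window = 5, threshold_frac = 0.05,
                       noise_floor = 0,
                       gradient_from = c("start_intensity", "baseline")) {
  gradient_from <- match.arg(gradient_from)
  stopifnot(smooth_window >= 1, smooth_window %% 2 == 1,
            threshold_frac > 0, threshold_frac < 1, noise_floor >= 0)
  structure(list(smooth_window = smooth_window, threshold_frac = threshold_frac,
                 noise_floor = noise_floor, gradient_from = gradient_from),
            class = "map_config")
}

#' Compute a pixel-wise perfusion parameter map
#'
#' Runs TIC landmark detection on every pixel inside the ROI and evaluates the
#' requested parameter. Values are finite exactly where the mask is `TRUE` and
#' the pixel quality is `"ok"`; everywhere else the value is `NA` and the
#' quality grid says why (`outside`, `no_enhancement`, `censored_peak`,
#' `degenerate`).
#'
#' @param loop a [cineloop()] — motion-corrected upstream (the caller's
#'   responsibility; a note is recorded if `meta$motion_corrected` is absent).
#' @param mask an [roi_mask()] congruent with the frames.
#' @param parameter `"mean_gradient_to_peak"` (intensity/s),
#'   `"peak_enhancement"` (intensity above baseline), or `"time_to_peak"`
#'   (s from enhancement start to peak).
#' @param config a [map_config()].
#' @return A `parametric_map`: list with `values` (rows x cols, `NA` off the
#'   ok set), `quality` (character grid), `parameter`, `mask`, `config`.
#' @export
compute_map <- function(loop, mask,
                        parameter = c("mean_gradient_to_peak",
                                      "peak_enhancement", "time_to_peak"),
                        config = map_config()) {
  parameter <- match.arg(parameter)
  stopifnot(inherits(loop, "cineloop"), inherits(mask, "roi_mask"))
  check_congruent(loop, mask)

  idx <- which(mask)                      # column-major pixel index
  nf <- n_frames(loop)
  fd <- frame_dim(loop)
  # (time, row, col) array in column-major order: columns are pixels in
  # column-major order, matching which(mask)
  Y <- matrix(loop$frames, nf, prod(fd))[, idx, drop = FALSE]
  lm <- landmarks_matrix(Y, loop$times, config$smooth_window,
                         config$threshold_frac, config$noise_floor)

  ok <- lm$quality == "ok"
  vals <- rep(NA_real_, length(idx))
  if (parameter == "mean_gradient_to_peak") {
    lower <- if (config$gradient_from == "baseline") lm$baseline else lm$y_start
    vals[ok] <- (lm$y_peak[ok] - lower[ok]) / (lm$t_peak[ok] - lm$t_start[ok])
  } else if (parameter == "peak_enhancement") {
    vals[ok] <- lm$y_peak[ok] - lm$baseline[ok]
  } else {
    vals[ok] <- lm$t_peak[ok] - lm$t_start[ok]
  }

  values <- matrix(NA_real_, fd[1], fd[2])
  values[idx] <- vals
  quality <- matrix("outside", fd[1], fd[2])
  quality[idx] <- lm$quality

  structure(list(values = values, quality = quality, parameter = parameter,
                 mask = mask, config = config,
                 motion_corrected = isTRUE(loop$meta$motion_corrected)),
            class = "parametric_map")
}

#' @export
print.parametric_map <- function(x, ...) {
  okv <- x$values[x$quality == "ok"]
  cat(sprintf("<parametric_map> %s, %d x %d px, %d ok / %d in ROI\n",
              x$parameter, nrow(x$values), ncol(x$values), length(okv),
              attr(x$mask, "n_pixels")))
  if (length(okv)) {
    cat(sprintf("  range [%.4g, %.4g], median %.4g\n",
                min(okv), max(okv), stats::median(okv)))
  }
  invisible(x)
}

#' Tidy a parametric map into a long tibble
#'
#' @param x a `parametric_map`.
#' @param ... unused.
#' @return Tibble with columns `row`, `col`, `value`, `quality`, rows for
#'   every in-ROI pixel.
#' @export
tidy.parametric_map <- function(x, ...) {
  idx <- which(matrix(x$mask, nrow(x$mask), ncol(x$mask)), arr.ind = TRUE)
  tibble::tibble(row = idx[, 1], col = idx[, 2],
                 value = x$values[idx], quality = x$quality[idx])
}

#' @export
autoplot.parametric_map <- function(object, ...) {
  df <- tidy.parametric_map(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradientn(
      colours = perfusion_palette(256), na.value = "grey20",
      name = object$parameter) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

perfusion_palette <- function(n) {
  grDevices::colorRampPalette(c("#00004B", "#0000FF", "#00CFFF", "#00FF66",
                                "#FFFF00", "#FF8000", "#FF0000"))(n)
}
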