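#' Gamma-variate bolus transit model
#'
#' Standard indicator-dilution kinetics for a contrast bolus:
#' \deqn{y(t) = b + y_{max} \tau^\alpha e^{\alpha(1-\tau)}, \quad
#'       \tau = (t - t_0)/(t_{pk} - t_0)}
#' for `t > t0`, and `y(t) = b` for `t <= t0`. The curve is continuous, equals
#' the baseline before bolus arrival, and attains its global maximum
#' `baseline + ymax` exactly at `t = tpk`.
#'
#' @param t0 bolus arrival time, s (`>= 0`).
#' @param tpk time of peak, s (`> t0`).
#' @param ymax peak enhancement above baseline, intensity units (`> 0`).
#' @param alpha gamma-variate shape (dimensionless, `> 0`).
#' @param baseline pre-arrival intensity (`>= 0`).
#' @return An object of class `bolus_model`.
#' @export
bolus_model <- function(t0, tpk, ymax, alpha = 2, baseline = 0) {
  stopifnot(t0 >= 0, tpk > t0, ymax > 0, alpha > 0, baseline >= 0)
  structure(list(t0 = t0, tpk = tpk, ymax = ymax, alpha = alpha,
                 baseline = baseline),
            class = "bolus_model")
}

#' Evaluate a gamma-variate bolus curve
#'
#' @param t times in seconds (vectorized).
#' @param model a [bolus_model()].
#' @return Intensities at `t`.
#' @export
gamma_variate <- function(t, model) {
  stopifnot(inherits(model, "bolus_model"))
  tau <- (t - model$t0) / (model$tpk - model$t0)
  y <- rep(model$baseline, length(t))
  up <- tau > 0
  y[up] <- model$baseline +
    model$ymax * tau[up]^model$alpha * exp(model$alpha * (1 - tau[up]))
  y
}

#' Analytic mean gradient to peak of a bolus model
#'
#' The mean slope of the noiseless curve from bolus arrival to peak:
#' `ymax / (tpk - t0)`. This is the ground truth the pixel-wise estimator
#' targets.
#'
#' @param model a [bolus_model()].
#' @return intensity/s.
#' @export
bolus_mgp <- function(model) model$ymax / (model$tpk - model$t0)

## ---- phantom ----------------------------------------------------------------

# Elliptical "prostate" ROI centred in the frame.
default_roi <- function(shape, fill = 0.42) {
  r <- seq_len(shape[1]); c <- seq_len(shape[2])
  cr <- (shape[1] + 1) / 2; cc <- (shape[2] + 1) / 2
  a <- fill * shape[1]; b <- fill * shape[2]
  roi_mask(outer(r, c, function(i, j) ((i - cr) / a)^2 + ((j - cc) / b)^2 <= 1))
}

# Relative areas of the hot components for each archetype. The hot set totals
# ~25% of the ROI so that a 75th-percentile threshold separates it cleanly.
archetype_areas <- function(lesion_type) {
  switch(as.character(lesion_type),
    "1" = 1,                                  # single focal area
    "2" = c(0.82, 0.06, 0.06, 0.06),          # dominant + small satellites
    "3" = rep(0.25, 4),                       # several distinct areas
    "4" = rep(1 / 7, 7),                      # numerous scattered foci
    stop("lesion_type must be 1, 2, 3, 4 or 'none'", call. = FALSE)
  )
}

# Seeded placement of non-overlapping discs inside the ROI: deterministic
# ring layouts (jittered by the phantom's RNG) so every archetype fits even
# in small frames. A dominant first component sits at the centre with its
# satellites on an outer ring; otherwise components share a ring, with the
# first moved to the centre when there are many.
place_components <- function(roi, radii) {
  shape <- dim(roi)
  cr <- (shape[1] + 1) / 2; cc <- (shape[2] + 1) / 2
  a <- 0.42 * shape[1]; b <- 0.42 * shape[2]
  n <- length(radii)
  centers <- matrix(0, n, 2)
  jit_th <- stats::runif(n, -0.12, 0.12)
  jit_rho <- stats::runif(n, 0.96, 1.04)
  rot <- stats::runif(1, 0, 2 * pi)
  ring <- function(i, k, m, rho_frac, rho_abs = NULL) {
    # place component i as the k-th of m points on a ring
    th <- rot + 2 * pi * (k - 1) / m + jit_th[i]
    avail_r <- a - radii[i] - 2
    avail_c <- b - radii[i] - 2
    rho_r <- if (is.null(rho_abs)) rho_frac * avail_r else min(rho_abs, avail_r)
    rho_c <- if (is.null(rho_abs)) rho_frac * avail_c else min(rho_abs, avail_c)
    f <- min(jit_rho[i], 1)
    c(cr + f * rho_r * cos(th), cc + f * rho_c * sin(th))
  }
  dominant <- n >= 2 && radii[1] >= 2 * radii[2]
  if (n == 1) {
    centers[1, ] <- c(cr, cc) + stats::runif(2, -0.06, 0.06) * c(a, b)
  } else if (dominant) {
    centers[1, ] <- c(cr, cc)
    need <- radii[1] + radii[-1] + 2  # clearance from the dominant disc
    for (i in 2:n) {
      centers[i, ] <- ring(i, i - 1, n - 1, 0.8,
                           rho_abs = max(0.8 * (a - radii[i] - 2), need[i - 1]))
    }
  } else if (n <= 5) {
    for (i in seq_len(n)) centers[i, ] <- ring(i, i, n, 0.62)
  } else {
    centers[1, ] <- c(cr, cc) + stats::runif(2, -0.03, 0.03) * c(a, b)
    for (i in 2:n) centers[i, ] <- ring(i, i - 1, n - 1, 0.75)
  }
  d <- as.matrix(stats::dist(centers))
  sep <- outer(radii, radii, `+`)
  if (any(d[upper.tri(d)] < sep[upper.tri(sep)])) {
    stop("could not place lesion components inside the ROI; ",
         "reduce their number or size", call. = FALSE)
  }
  centers
}

# Static echotexture field in [-1, 1], box-blurred white noise with a grain
# of a few pixels (fine enough to anchor speckle tracking, coarse enough to
# survive bilinear resampling).
texture_field <- function(shape, blur = 1) {
  f <- matrix(stats::rnorm(prod(shape)), shape[1], shape[2])
  k <- rep(1, 2 * blur + 1)
  for (pass in 1:2) {
    f <- apply(f, 2, function(v) stats::filter(c(rev(v[seq_len(blur)]), v,
                                                 rev(v[length(v) - seq_len(blur) + 1])),
                                               k / length(k), sides = 2)[blur + seq_along(v)])
    f <- t(apply(f, 1, function(v) stats::filter(c(rev(v[seq_len(blur)]), v,
                                                   rev(v[length(v) - seq_len(blur) + 1])),
                                                 k / length(k), sides = 2)[blur + seq_along(v)]))
  }
  f / max(abs(f))
}

# Bilinear sample of image at (r + dr, c + dc), edge-clamped.
shift_image <- function(img, dr, dc, method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  R <- nrow(img); C <- ncol(img)
  if (method == "nearest") { dr <- round(dr); dc <- round(dc) }
  r <- seq_len(R) + dr; c <- seq_len(C) + dc
  if (method == "nearest" || (dr == round(dr) && dc == round(dc))) {
    ri <- pmin(pmax(as.integer(round(r)), 1L), R)
    ci <- pmin(pmax(as.integer(round(c)), 1L), C)
    return(img[ri, ci, drop = FALSE])
  }
  r0 <- pmin(pmax(floor(r), 1), R); r1 <- pmin(r0 + 1, R)
  c0 <- pmin(pmax(floor(c), 1), C); c1 <- pmin(c0 + 1, C)
  fr <- pmin(pmax(r - r0, 0), 1); fc <- pmin(pmax(c - c0, 0), 1)
  a <- img[r0, c0, drop = FALSE] * (1 - fr) + img[r1, c0, drop = FALSE] * fr
  b <- img[r0, c1, drop = FALSE] * (1 - fr) + img[r1, c1, drop = FALSE] * fr
  a * rep(1 - fc, each = R) + b * rep(fc, each = R)
}

#' Simulate a CEUS cineloop phantom with known ground truth
#'
#' Generates a bolus-transit cineloop over an elliptical "prostate" ROI. Each
#' pixel follows its component's (or the background's) gamma-variate curve,
#' scaled by a static smooth multiplicative echotexture field so frames carry
#' spatial structure at every phase of the transit (which keeps rigid
#' registration well-posed); frame-wise multiplicative speckle and a smooth
#' sinusoidal rigid drift are optional. The per-pixel analytic ground truth
#' carries the texture factor. The four lesion archetypes reproduce the geometry of the
#' perfusion-discreteness grades: a single focal hot area (type 1), one
#' dominant area with small satellites (type 2), several distinct areas
#' (type 3), and numerous scattered foci (type 4).
#'
#' @param shape frame dimensions `(rows, cols)`.
#' @param n_frames number of frames.
#' @param frame_interval seconds between frames (default acquisition: 240
#'   frames at 0.5 s, i.e. 120 s of contrast transit).
#' @param lesion_type `"none"` or 1–4.
#' @param background [bolus_model()] for benign parenchyma.
#' @param lesion [bolus_model()] for lesion pixels; defaults to kinetics twice
#'   as fast and twice as strong as the background (rise time halved, peak
#'   enhancement doubled).
#' @param noise_sigma multiplicative speckle scale: `I * (1 + sigma * eps)`,
#'   `eps ~ N(0,1)`, clipped at 0.
#' @param motion_amplitude max rigid drift in px (sinusoidal, row+column).
#' @param texture_amp relative amplitude of the static multiplicative
#'   echotexture field (0 disables it).
#' @param seed integer seed; the phantom is deterministic given the seed.
#' @return A list with elements `loop` ([cineloop()]), `mask` ([roi_mask()]),
#'   and `truth` (analytic `mgp_map`, component `labels` image, per-component
#'   table, the applied per-frame `shifts`, and `lesion_type`).
#' @export
make_phantom <- function(shape = c(128, 128), n_frames = 240,
                         frame_interval = 0.5,
                         lesion_type = "none",
                         background = bolus_model(t0 = 8, tpk = 28, ymax = 12,
                                                  alpha = 2, baseline = 2),
                         lesion = NULL,
                         noise_sigma = 0, motion_amplitude = 0,
                         texture_amp = 0.4, seed = 1) {
  stopifnot(n_frames >= 2, frame_interval > 0, noise_sigma >= 0,
            motion_amplitude >= 0)
  seed <- as.integer(seed)  # force before saving the caller's RNG state
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)

  roi <- default_roi(shape)
  times <- (seq_len(n_frames) - 1) * frame_interval
  if (is.null(lesion)) {
    rise <- (background$tpk - background$t0) / 2
    lesion <- bolus_model(t0 = background$t0, tpk = background$t0 + rise,
                          ymax = 2 * background$ymax, alpha = background$alpha,
                          baseline = background$baseline)
  }

  labels <- matrix(0L, shape[1], shape[2])
  comps <- tibble::tibble(id = integer(), centroid_r = double(),
                          centroid_c = double(), radius = double(),
                          area = integer())
  if (!identical(lesion_type, "none")) {
    rel <- archetype_areas(lesion_type)
    hot_area <- 0.25 * attr(roi, "n_pixels")
    radii <- pmax(sqrt(rel * hot_area / pi), 1)
    centers <- place_components(roi, radii)
    rr <- row(labels); cc <- col(labels)
    for (i in seq_along(radii)) {
      inside <- (rr - centers[i, 1])^2 + (cc - centers[i, 2])^2 <= radii[i]^2
      inside <- inside & roi
      labels[inside] <- i
      comps <- dplyr::bind_rows(comps, tibble::tibble(
        id = i, centroid_r = centers[i, 1], centroid_c = centers[i, 2],
        radius = radii[i], area = sum(inside)))
    }
  }

  # static echotexture multiplies the whole echo-power signal (speckle is
  # multiplicative); the per-pixel analytic ground truth scales with it
  tex <- 1 + texture_amp * texture_field(shape)
  tex[tex < 0.05] <- 0.05

  bg_curve <- gamma_variate(times, background)
  le_curve <- gamma_variate(times, lesion)

  drift <- matrix(0, n_frames, 2)
  if (motion_amplitude > 0) {
    period <- stats::runif(2, 0.3, 0.6) * times[n_frames]
    phase <- stats::runif(2, 0, 2 * pi)
    amp <- motion_amplitude * c(1, stats::runif(1, 0.5, 1))
    drift[, 1] <- amp[1] * sin(2 * pi * times / period[1] + phase[1])
    drift[, 2] <- amp[2] * sin(2 * pi * times / period[2] + phase[2])
    drift <- sweep(drift, 2, drift[1, ])  # reference frame 1 is unshifted
    # rescale so the max displacement from the reference is the stated amplitude
    peak <- max(abs(drift))
    if (peak > 0) drift <- drift * (motion_amplitude / peak)
  }

  lesion_px <- labels > 0
  frames <- array(0, dim = c(n_frames, shape[1], shape[2]))
  for (f in seq_len(n_frames)) {
    img <- matrix(bg_curve[f], shape[1], shape[2])
    img[lesion_px] <- le_curve[f]
    img <- img * tex
    if (motion_amplitude > 0) {
      # content displaced by +drift: frame(r, c) = scene(r - dr, c - dc)
      img <- shift_image(img, -drift[f, 1], -drift[f, 2])
    }
    if (noise_sigma > 0) {
      img <- img * (1 + noise_sigma *
                      matrix(stats::rnorm(prod(shape)), shape[1], shape[2]))
      img[img < 0] <- 0
    }
    frames[f, , ] <- img
  }

  mgp_map <- matrix(NA_real_, shape[1], shape[2])
  mgp_map[roi] <- bolus_mgp(background) * tex[roi]
  mgp_map[lesion_px] <- bolus_mgp(lesion) * tex[lesion_px]

  loop <- cineloop(frames, times,
                   meta = list(simulated = TRUE, lesion_type = lesion_type,
                               noise_sigma = noise_sigma,
                               motion_amplitude = motion_amplitude,
                               seed = as.integer(seed),
                               duration_s = times[n_frames]))
  list(loop = loop, mask = roi,
       truth = list(mgp_map = mgp_map, labels = labels, components = comps,
                    shifts = drift, texture = tex, lesion_type = lesion_type,
                    background = background, lesion = lesion))
}

# save/restore the global RNG state so seeded generators do not clobber it
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

## ---- synthetic reader ratings ----------------------------------------------

#' Simulate a reader-study ratings table
#'
#' Ground truth for each case is Bernoulli(`prevalence`); each rater's binary
#' call is drawn conditionally on truth with the stated per-rater sensitivity
#' and specificity, independently across raters and cases.
#'
#' @param n_cases,n_raters counts (`>= 1`).
#' @param prevalence probability a case is truly malignant.
#' @param sens,spec per-rater sensitivity/specificity; scalars are recycled to
#'   all raters.
#' @param seed integer seed.
#' @param session_label free-text label stored as an attribute.
#' @return A tibble of class `ratings_table` with columns `case_id`, `truth`
#'   (1 = malignant), and `rater_1` ... `rater_k`.
#' @export
make_ratings <- function(n_cases, n_raters, prevalence, sens, spec, seed = 1,
                         session_label = "simulated") {
  stopifnot(n_cases >= 1, n_raters >= 1,
            all(prevalence >= 0 & prevalence <= 1),
            all(sens >= 0 & sens <= 1), all(spec >= 0 & spec <= 1))
  sens <- rep_len(sens, n_raters)
  spec <- rep_len(spec, n_raters)
  seed <- as.integer(seed)  # force before saving the caller's RNG state
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  truth <- stats::rbinom(n_cases, 1, prevalence)
  ratings <- vapply(seq_len(n_raters), function(j) {
    p_call <- ifelse(truth == 1, sens[j], 1 - spec[j])
    stats::rbinom(n_cases, 1, p_call)
  }, integer(n_cases))
  out <- tibble::as_tibble(stats::setNames(
    as.data.frame(ratings), paste0("rater_", seq_len(n_raters))))
  out <- dplyr::bind_cols(tibble::tibble(case_id = seq_len(n_cases),
                                         truth = truth), out)
  structure(out, class = c("ratings_table", class(out)),
            session_label = session_label)
}

#' Extract the cases x raters matrix from a ratings table
#'
#' @param ratings a `ratings_table` (or any data frame with `rater_*` columns).
#' @return Integer matrix, one row per case, one column per rater.
#' @export
ratings_matrix <- function(ratings) {
  cols <- grep("^rater_", names(ratings), value = TRUE)
  if (!length(cols)) stop("no `rater_*` columns found", call. = FALSE)
  m <- as.matrix(as.data.frame(ratings)[cols])
  if (anyNA(m)) stop("ratings must be complete (no missing cells)", call. = FALSE)
  m
}
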