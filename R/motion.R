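#' Estimate rigid motion across a cineloop
#'
#' Per-frame translation relative to a reference frame, by exhaustive
#' normalized cross-correlation over integer shifts within `±max_shift`,
#' with optional subpixel refinement by a local quadratic fit of the
#' correlation surface. Correlation is computed on a temporally smoothed,
#' spatially high-passed log-intensity copy of the loop: the temporal average
#' damps frame-to-frame speckle, and removing the local spatial mean keeps
#' the stationary echotexture — rather than the transient global enhancement
#' — in charge of the match. Ties in the correlation
#' peak are broken toward the smaller displacement norm, then
#' lexicographically (row, then column), so the estimate is deterministic.
#'
#' The shift convention: `shifts[f] = (dr, dc)` means the content of frame `f`
#' is displaced by `+dr` rows (down) and `+dc` columns (right) relative to the
#' reference, i.e. `frame_f(r, c) ≈ ref(r - dr, c - dc)`.
#'
#' @param loop a [cineloop()].
#' @param reference_index anchor frame (1-based), default 1.
#' @param max_shift search radius in pixels (`>= 1`).
#' @param subpixel refine the integer peak with a separable quadratic fit?
#' @param smooth_frames temporal smoothing window (frames) applied before
#'   correlation; 1 disables.
#' @param highpass_halfwidth half-width (px) of the local-mean box removed
#'   from each frame before correlation; 0 disables.
#' @return A `motion_trace`: tibble with columns `frame`, `dr`, `dc`;
#'   attributes `reference_index`, `max_shift`.
#' @export
estimate_motion <- function(loop, reference_index = 1, max_shift = 5,
                            subpixel = TRUE, smooth_frames = 3,
                            highpass_halfwidth = 2) {
  stopifnot(inherits(loop, "cineloop"), max_shift >= 1)
  nf <- n_frames(loop)
  if (reference_index < 1 || reference_index > nf) {
    stop("reference_index out of range [1, ", nf, "]", call. = FALSE)
  }
  # working copies in high-passed log intensity. The temporally smoothed copy
  # drives the integer search (speckle-robust); the unsmoothed copy drives
  # subpixel refinement, because averaging frames at different displacements
  # would bias the fractional estimate during rapid wash-in.
  raw <- log1p(loop$frames)
  if (highpass_halfwidth > 0) {
    for (f in seq_len(nf)) {
      raw[f, , ] <- raw[f, , ] - box_blur(raw[f, , ], highpass_halfwidth)
    }
  }
  work <- raw
  if (smooth_frames > 1) {
    dim3 <- dim(raw)
    m <- matrix(raw, nf, dim3[2] * dim3[3])
    work <- array(ma_truncated(m, smooth_frames), dim3)
  }
  ref <- work[reference_index, , ]
  ref_raw <- raw[reference_index, , ]
  if (stats::sd(ref) == 0) {
    stop("degenerate reference: frame ", reference_index,
         " has zero variance", call. = FALSE)
  }
  R <- nrow(ref); C <- ncol(ref)
  s <- seq.int(-max_shift, max_shift)
  ncc_at <- function(frm, rf, i, j) {
    # overlap of frame(r, c) with ref(r - i, c - j)
    r1 <- max(1, 1 + i); r2 <- min(R, R + i)
    c1 <- max(1, 1 + j); c2 <- min(C, C + j)
    x <- frm[r1:r2, c1:c2]
    y <- rf[(r1 - i):(r2 - i), (c1 - j):(c2 - j)]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(-Inf)
    stats::cor(as.vector(x), as.vector(y))
  }
  shifts <- matrix(0, nf, 2)
  for (f in seq_len(nf)) {
    if (f == reference_index) next
    frm <- work[f, , ]
    cc <- matrix(-Inf, length(s), length(s))
    for (a in seq_along(s)) {
      for (b in seq_along(s)) {
        cc[a, b] <- ncc_at(frm, ref, s[a], s[b])
      }
    }
    best <- which(cc == max(cc), arr.ind = TRUE)
    if (nrow(best) > 1) {  # tie-break: smaller norm, then (row, col) lexicographic
      dn <- s[best[, 1]]^2 + s[best[, 2]]^2
      best <- best[order(dn, s[best[, 1]], s[best[, 2]]), , drop = FALSE]
    }
    ai <- best[1, 1]; bi <- best[1, 2]
    dr <- s[ai]; dc <- s[bi]
    # a numerically perfect match needs no refinement (and edge asymmetry of
    # the correlation surface would otherwise perturb it)
    if (subpixel && cc[ai, bi] < 1 - 1e-12) {
      frm_raw <- raw[f, , ]
      cc3 <- matrix(-Inf, 3, 3)
      for (a in 1:3) for (b in 1:3) {
        cc3[a, b] <- ncc_at(frm_raw, ref_raw, s[ai] + a - 2L, s[bi] + b - 2L)
      }
      if (all(is.finite(cc3)) && which.max(cc3) == 5L) {
        dr <- dr + quad_refine(cc3, 2L, 2L, axis = 1)
        dc <- dc + quad_refine(cc3, 2L, 2L, axis = 2)
      } else {
        dr <- dr + quad_refine(cc, ai, bi, axis = 1)
        dc <- dc + quad_refine(cc, ai, bi, axis = 2)
      }
    }
    shifts[f, ] <- c(dr, dc)
  }
  structure(
    tibble::tibble(frame = seq_len(nf), dr = shifts[, 1], dc = shifts[, 2]),
    class = c("motion_trace", class(tibble::tibble())),
    reference_index = reference_index, max_shift = max_shift
  )
}

# separable box mean with reflected edges
box_blur <- function(m, h) {
  k <- rep(1 / (2 * h + 1), 2 * h + 1)
  smooth1 <- function(v) {
    p <- c(rev(v[seq_len(h)]), v, rev(v[length(v) - seq_len(h) + 1]))
    stats::filter(p, k, sides = 2)[h + seq_along(v)]
  }
  t(apply(apply(m, 2, smooth1), 1, smooth1))
}

# vertex of the parabola through the three correlation values straddling the
# integer peak along one axis; 0 if the peak sits on the search border
quad_refine <- function(cc, ai, bi, axis) {
  n <- if (axis == 1) nrow(cc) else ncol(cc)
  k <- if (axis == 1) ai else bi
  if (k <= 1 || k >= n) return(0)
  v <- if (axis == 1) cc[(k - 1):(k + 1), bi] else cc[ai, (k - 1):(k + 1)]
  if (any(!is.finite(v))) return(0)
  den <- v[1] - 2 * v[2] + v[3]
  if (den >= 0) return(0)  # not a local max
  d <- 0.5 * (v[1] - v[3]) / den
  max(min(d, 0.5), -0.5)
}

#' Apply (undo) an estimated motion trace
#'
#' Each frame is resampled by the inverse of its estimated shift so that every
#' pixel tracks one anatomical location. Out-of-field samples are filled with
#' edge values; frame times are unchanged.
#'
#' @param loop a [cineloop()].
#' @param trace a `motion_trace` from [estimate_motion()] (frame count must
#'   match).
#' @param method `"bilinear"` (default; exact pass-through for integer shifts)
#'   or `"nearest"`.
#' @return A motion-corrected `cineloop`; `meta$motion_corrected = TRUE`.
#' @export
apply_motion <- function(loop, trace, method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  stopifnot(inherits(loop, "cineloop"))
  nf <- n_frames(loop)
  if (nrow(trace) != nf) {
    stop("motion trace has ", nrow(trace), " entries for ", nf, " frames",
         call. = FALSE)
  }
  out <- loop
  for (f in seq_len(nf)) {
    if (trace$dr[f] == 0 && trace$dc[f] == 0) next
    out$frames[f, , ] <- shift_image(loop$frames[f, , ],
                                     trace$dr[f], trace$dc[f],
                                     method = method)
  }
  out$meta$motion_corrected <- TRUE
  out$meta$motion_reference <- attr(trace, "reference_index")
  out$meta$edge_fill <- "clamp"
  out
}

#' Write / read a motion trace as CSV
#'
#' Columns `frame, dr, dc`; the reference index is recoverable as the frame
#' with zero shift is not guaranteed unique, so it is stored in a comment-free
#' extra column.
#'
#' @param trace a `motion_trace`.
#' @param path CSV path.
#' @return `path` invisibly / a `motion_trace`.
#' @export
write_motion_trace <- function(trace, path) {
  df <- as.data.frame(trace)
  df$reference_index <- attr(trace, "reference_index")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_motion_trace
#' @export
read_motion_trace <- function(path) {
  df <- utils::read.csv(path)
  structure(tibble::as_tibble(df[c("frame", "dr", "dc")]),
            class = c("motion_trace", class(tibble::tibble())),
            reference_index = df$reference_index[1])
}
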