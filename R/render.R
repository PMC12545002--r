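## 3x5 bitmap glyphs for colour-bar tick labels (digits, '.', '-', 'e', '+').
## Each glyph is 15 characters, row-major, '#' = ink.
glyphs <- list(
  "0" = "### #.# #.# #.# ###", "1" = ".#. ##. .#. .#. ###",
  "2" = "### ..# ### #.. ###", "3" = "### ..# .## ..# ###",
  "4" = "#.# #.# ### ..# ..#", "5" = "### #.. ### ..# ###",
  "6" = "### #.. ### #.# ###", "7" = "### ..# ..# ..# ..#",
  "8" = "### #.# ### #.# ###", "9" = "### #.# ### ..# ###",
  "." = "... ... ... ... .#.", "-" = "... ... ### ... ...",
  "+" = "... .#. ### .#. ...", "e" = "... ### ##. #.. .##"
)

draw_text <- function(canvas, text, top, left, scale = 2, ink = 0) {
  chars <- strsplit(text, "")[[1]]
  x <- left
  for (ch in chars) {
    g <- glyphs[[ch]]
    if (!is.null(g)) {
      rows <- strsplit(g, " ")[[1]]
      for (r in 1:5) for (c in 1:3) {
        if (substr(rows[r], c, c) == "#") {
          rr <- top + (r - 1) * scale + seq_len(scale) - 1
          cc <- x + (c - 1) * scale + seq_len(scale) - 1
          rr <- rr[rr <= dim(canvas)[1]]; cc <- cc[cc <= dim(canvas)[2]]
          canvas[rr, cc, ] <- ink
        }
      }
    }
    x <- x + 4 * scale
  }
  canvas
}

#' Render a parametric map to a colour-coded PNG
#'
#' In-ROI pixels of ok quality are coloured on a cool-to-hot scale (blue =
#' slow perfusion through red = rapid perfusion) after min–max or percentile
#' normalization; each map pixel maps to exactly one image pixel, so the
#' rendered colours are a faithful re-encoding of the values. Out-of-ROI
#' pixels show the grayscale reference frame if given, else black. A colour
#' bar with numeric ticks (min / mid / max of the normalization range) is
#' embedded on the right.
#'
#' @param map a `parametric_map` from [compute_map()].
#' @param path output PNG path.
#' @param colormap reserved for alternatives; only the default cool-to-hot
#'   scale is bundled.
#' @param normalization `"minmax"` or `"percentile"`.
#' @param probs percentile normalization bounds (used when
#'   `normalization = "percentile"`).
#' @param reference optional grayscale background matrix (the reference
#'   frame), same dimensions as the map.
#' @return `path`, invisibly. A constant map renders as a single colour with
#'   a warning.
#' @export
render_map <- function(map, path, colormap = "cool_hot",
                       normalization = c("minmax", "percentile"),
                       probs = c(0.02, 0.98), reference = NULL) {
  normalization <- match.arg(normalization)
  stopifnot(inherits(map, "parametric_map"))
  vals <- map$values
  ok <- map$quality == "ok"
  v <- vals[ok]
  if (!length(v)) stop("map has no ok-quality pixels to render", call. = FALSE)
  rng <- if (normalization == "minmax") range(v) else
    stats::quantile(v, probs, names = FALSE)
  if (diff(rng) == 0) {
    warning("constant map: rendering a single colour", call. = FALSE)
    rng[2] <- rng[1] + 1
  }
  pal <- grDevices::col2rgb(perfusion_palette(256)) / 255

  R <- nrow(vals); C <- ncol(vals)
  bar_w <- 14L; gap <- 6L; label_w <- 40L
  W <- C + gap + bar_w + label_w
  img <- array(0, dim = c(R, W, 3))
  if (!is.null(reference)) {
    g <- reference / max(reference)
    for (k in 1:3) img[, seq_len(C), k] <- g
  }
  u <- pmin(pmax((vals - rng[1]) / (rng[2] - rng[1]), 0), 1)
  ci <- as.integer(round(u * 255)) + 1L
  okw <- which(ok)
  for (k in 1:3) {
    plane <- img[, seq_len(C), k]
    plane[okw] <- pal[k, ci[okw]]
    img[, seq_len(C), k] <- plane
  }
  # colour bar (hot at top) + tick labels
  bar_rows <- seq.int(4L, R - 4L)
  bu <- rev(seq(0, 1, length.out = length(bar_rows)))
  bci <- as.integer(round(bu * 255)) + 1L
  for (k in 1:3) {
    img[bar_rows, C + gap + seq_len(bar_w), k] <-
      matrix(pal[k, bci], length(bar_rows), bar_w)
  }
  labs <- formatC(c(rng[2], mean(rng), rng[1]), format = "g", digits = 3)
  at <- c(min(bar_rows), floor(mean(range(bar_rows))), max(bar_rows) - 10L)
  img[, (C + gap + bar_w + 1):W, ] <- 1  # white label strip
  for (i in seq_along(labs)) {
    img <- draw_text(img, labs[i], top = at[i], left = C + gap + bar_w + 4L)
  }
  png::writePNG(img, path)
  invisible(path)
}
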