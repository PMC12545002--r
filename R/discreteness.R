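## 8-connected labeling: EBImage::bwlabel is 4-connected, so labels touching
## diagonally are merged afterwards with a union-find over the label graph.
label_components_8 <- function(binary) {
  lab <- EBImage::bwlabel(binary * 1)
  lab <- matrix(as.integer(lab), nrow(binary), ncol(binary))
  nl <- max(lab)
  if (nl < 2) return(lab)
  R <- nrow(lab); C <- ncol(lab)
  a1 <- lab[-R, -C]; b1 <- lab[-1, -1]   # (r, c) vs (r+1, c+1)
  a2 <- lab[-1, -C]; b2 <- lab[-R, -1]   # (r+1, c) vs (r, c+1)
  pairs <- rbind(cbind(as.vector(a1), as.vector(b1)),
                 cbind(as.vector(a2), as.vector(b2)))
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 & pairs[, 1] != pairs[, 2], ,
                 drop = FALSE]
  parent <- seq_len(nl)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (p in seq_len(nrow(pairs))) {
    ra <- find(pairs[p, 1]); rb <- find(pairs[p, 2])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  root <- vapply(seq_len(nl), find, integer(1))
  dense <- match(root, sort(unique(root)))
  lab[lab > 0] <- dense[lab[lab > 0]]
  lab
}

#' Segment the hyper-perfused (hot) regions of a parametric map
#'
#' Hot pixels are the in-ROI ok-quality pixels whose parameter value is at or
#' above a threshold: a percentile of the in-ROI values (default the 75th) or
#' Otsu's threshold on the in-ROI histogram. Hot pixels are grouped into
#' 8-connected components; components smaller than `min_area` (speckle
#' singletons) are removed.
#'
#' @param map a `parametric_map`.
#' @param threshold_method `"percentile"` or `"otsu"`.
#' @param percentile hot-value percentile in (0, 1), default 0.75.
#' @param min_area minimum component area in px, default 5.
#' @return A `hot_region_set`: `label_image` (0 = cold, k >= 1 = component),
#'   `components` tibble (id, area, centroid, mean value; sorted by
#'   decreasing area), `hot_threshold`, `total_hot_area`, and `empty` flag.
#'   If no pixel exceeds the threshold the set is empty with a warning.
#' @export
segment_hot <- function(map, threshold_method = c("percentile", "otsu"),
                        percentile = 0.75, min_area = 5) {
  threshold_method <- match.arg(threshold_method)
  stopifnot(inherits(map, "parametric_map"))
  ok <- map$quality == "ok"
  v <- map$values[ok]
  if (length(v) < min_area) {
    stop("map has fewer ok-quality pixels (", length(v),
         ") than min_area (", min_area, ")", call. = FALSE)
  }
  thr <- if (threshold_method == "percentile") {
    stats::quantile(v, percentile, names = FALSE)
  } else {
    rng <- range(v)
    if (diff(rng) == 0) rng[2] <- rng[1] + 1
    u <- (v - rng[1]) / (rng[2] - rng[1])
    tho <- EBImage::otsu(EBImage::Image(matrix(u, nrow = 1)), levels = 256)
    rng[1] + tho * diff(rng)
  }
  hot <- ok & !is.na(map$values) & map$values >= thr
  lab <- label_components_8(hot)
  if (max(lab) == 0) {
    warning("no pixel at or above the hot threshold; empty region set",
            call. = FALSE)
    return(empty_hot_set(dim(map$values), thr))
  }
  areas <- tabulate(lab[lab > 0])
  keep <- which(areas >= min_area)
  if (!length(keep)) {
    warning("all hot components below min_area; empty region set",
            call. = FALSE)
    return(empty_hot_set(dim(map$values), thr))
  }
  # relabel surviving components by decreasing area
  ord <- keep[order(areas[keep], decreasing = TRUE)]
  newlab <- matrix(0L, nrow(lab), ncol(lab))
  comps <- purrr::map_dfr(seq_along(ord), function(i) {
    px <- which(lab == ord[i], arr.ind = TRUE)
    newlab[px] <<- i
    tibble::tibble(id = i, area = nrow(px),
                   centroid_r = mean(px[, 1]), centroid_c = mean(px[, 2]),
                   mean_value = mean(map$values[px]))
  })
  structure(list(label_image = newlab, components = comps,
                 hot_threshold = thr, total_hot_area = sum(comps$area),
                 empty = FALSE),
            class = "hot_region_set")
}

empty_hot_set <- function(d, thr) {
  structure(list(label_image = matrix(0L, d[1], d[2]),
                 components = tibble::tibble(id = integer(), area = integer(),
                                             centroid_r = double(),
                                             centroid_c = double(),
                                             mean_value = double()),
                 hot_threshold = thr, total_hot_area = 0L, empty = TRUE),
            class = "hot_region_set")
}

#' @export
print.hot_region_set <- function(x, ...) {
  cat(sprintf("<hot_region_set> %d components, %d hot px, threshold %.4g\n",
              nrow(x$components), x$total_hot_area, x$hot_threshold))
  invisible(x)
}

#' Cutpoints of the discreteness decision rule
#'
#' The four-tier grading of the spatial pattern of hyper-perfused regions is
#' made quantitative by a decision rule on the component count and the
#' dominant-component area fraction. All cutpoints are configurable; the
#' dispersion feature (mean pairwise centroid distance / ROI equivalent
#' diameter) is always reported and an optional rule variant uses it.
#'
#' @param s_max most components still compatible with "one dominant area plus
#'   a few satellites" (grade 2), default 4.
#' @param d2 minimum dominant fraction for grade 2, default 0.70.
#' @param n4 minimum component count for grade 4, default 6.
#' @param d4 maximum dominant fraction for grade 4, default 0.35.
#' @param use_dispersion if `TRUE`, grade 4 additionally requires dispersion
#'   at or above `dispersion_min` (sensitivity-analysis variant).
#' @param dispersion_min dispersion cutpoint for the variant rule.
#' @return A named list of class `discreteness_rule`.
#' @export
discreteness_rule <- function(s_max = 4, d2 = 0.70, n4 = 6, d4 = 0.35,
                              use_dispersion = FALSE, dispersion_min = 0.3) {
  stopifnot(s_max >= 2, d2 > 0, d2 <= 1, n4 > s_max, d4 > 0, d4 < 1)
  structure(list(s_max = s_max, d2 = d2, n4 = n4, d4 = d4,
                 use_dispersion = use_dispersion,
                 dispersion_min = dispersion_min),
            class = "discreteness_rule")
}

#' Grade the spatial discreteness of hyper-perfused regions
#'
#' Grades the hot-region pattern on the four-tier ordinal scale:
#' grade 1 (completely concentrated) — a single contiguous hot area;
#' grade 2 (predominantly concentrated) — one dominant area with a few small
#' satellites; grade 3 (predominantly discrete) — multiple distinct areas;
#' grade 4 (completely discrete) — numerous small foci scattered diffusely.
#' The default decision rule: grade 1 iff one component; grade 2 iff
#' `2 <= n <= s_max` and dominant fraction `>= d2`; grade 4 iff `n >= n4` and
#' dominant fraction `< d4`; grade 3 otherwise.
#'
#' @param regions a `hot_region_set` from [segment_hot()] (non-empty).
#' @param roi the [roi_mask()] the map was computed on (for the dispersion
#'   normalization).
#' @param rule a [discreteness_rule()].
#' @return A `discreteness_result`: `grade` (ordered factor 1–4),
#'   `n_components`, `dominant_fraction`, `dispersion`, and the audit
#'   `features` tibble.
#' @export
classify_discreteness <- function(regions, roi, rule = discreteness_rule()) {
  stopifnot(inherits(regions, "hot_region_set"), inherits(roi, "roi_mask"))
  if (regions$empty || nrow(regions$components) == 0) {
    stop("undefined grade: empty hot-region set", call. = FALSE)
  }
  comps <- regions$components
  n <- nrow(comps)
  dom <- max(comps$area) / regions$total_hot_area
  disp <- 0
  if (n > 1) {
    d <- stats::dist(cbind(comps$centroid_r, comps$centroid_c))
    eq_diam <- 2 * sqrt(attr(roi, "n_pixels") / pi)
    disp <- mean(d) / eq_diam
  }
  grade <- if (n == 1) {
    1L
  } else if (n <= rule$s_max && dom >= rule$d2) {
    2L
  } else if (n >= rule$n4 && dom < rule$d4 &&
             (!rule$use_dispersion || disp >= rule$dispersion_min)) {
    4L
  } else {
    3L
  }
  structure(list(
    grade = grade, n_components = n, dominant_fraction = dom,
    dispersion = disp,
    features = tibble::tibble(n_components = n, dominant_fraction = dom,
                              dispersion = disp,
                              total_hot_area = regions$total_hot_area,
                              hot_threshold = regions$hot_threshold),
    rule = rule, components = comps),
    class = "discreteness_result")
}

#' @export
print.discreteness_result <- function(x, ...) {
  lab <- c("completely concentrated", "predominantly concentrated",
           "predominantly discrete", "completely discrete")
  cat(sprintf("<discreteness_result> grade %d (%s)\n", x$grade, lab[x$grade]))
  cat(sprintf("  %d components, dominant fraction %.2f, dispersion %.2f\n",
              x$n_components, x$dominant_fraction, x$dispersion))
  invisible(x)
}

#' @export
tidy.discreteness_result <- function(x, ...) {
  dplyr::mutate(x$features, grade = x$grade, .before = 1)
}

#' Segment and grade a parametric map in one call
#'
#' @inheritParams segment_hot
#' @param roi the [roi_mask()].
#' @param rule a [discreteness_rule()].
#' @return A `discreteness_result`.
#' @export
classify_map <- function(map, roi = map$mask,
                         threshold_method = c("percentile", "otsu"),
                         percentile = 0.75, min_area = 5,
                         rule = discreteness_rule()) {
  regions <- segment_hot(map, threshold_method, percentile, min_area)
  classify_discreteness(regions, roi, rule)
}

#' Cross-tabulate discreteness grades against pathology
#'
#' Builds the 2 x K contingency table (rows benign/malignant, columns ordinal
#' grades) consumed by [cochran_armitage()].
#'
#' @param grades per-case integer grades in 1..4.
#' @param truth per-case binary pathology (1 = malignant).
#' @param k number of grade levels (default 4).
#' @return A `trend_table`: counts matrix with scores attribute `1..K`.
#' @export
trend_against_truth <- function(grades, truth, k = 4) {
  stopifnot(length(grades) == length(truth))
  if (any(!grades %in% seq_len(k))) {
    stop("grades must lie in 1..", k, call. = FALSE)
  }
  counts <- rbind(
    benign = tabulate(grades[truth == 0], nbins = k),
    malignant = tabulate(grades[truth == 1], nbins = k)
  )
  colnames(counts) <- paste0("grade_", seq_len(k))
  trend_table(counts, scores = seq_len(k))
}

#' Construct a trend table for the Cochran-Armitage test
#'
#' @param counts 2 x K non-negative integer matrix (row 1 benign, row 2
#'   malignant).
#' @param scores K ordinal scores, default `1..K`.
#' @return A `trend_table`.
#' @export
trend_table <- function(counts, scores = seq_len(ncol(counts))) {
  counts <- as.matrix(counts)
  stopifnot(nrow(counts) == 2, all(counts >= 0),
            length(scores) == ncol(counts))
  if (sum(counts) < 2) stop("need at least 2 observations", call. = FALSE)
  structure(counts, scores = as.double(scores),
            class = c("trend_table", "matrix", "array"))
}
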