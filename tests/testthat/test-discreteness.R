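# build a parametric_map directly from a value image (unit-test shortcut)
map_from_values <- function(values, mask) {
  q <- matrix("outside", nrow(values), ncol(values))
  q[mask] <- "ok"
  v <- values
  v[!mask] <- NA_real_
  structure(list(values = v, quality = q,
                 parameter = "mean_gradient_to_peak", mask = mask,
                 config = map_config()),
            class = "parametric_map")
}

disc_image <- function(shape, centers, radii, hot = 10, cold = 1) {
  img <- matrix(cold, shape[1], shape[2])
  rr <- row(img); cc <- col(img)
  for (i in seq_len(nrow(centers))) {
    img[(rr - centers[i, 1])^2 + (cc - centers[i, 2])^2 <= radii[i]^2] <- hot
  }
  img
}

full_mask <- function(shape) roi_mask(matrix(TRUE, shape[1], shape[2]))

test_that("two-level maps segment identically under Otsu and percentile", {
  # hot disc covers > 25% of the mask so the 75th percentile lands on the
  # hot level, same as Otsu
  mask <- full_mask(c(40, 40))
  img <- disc_image(c(40, 40), rbind(c(20, 20)), 12)  # ~450 px disc
  map <- map_from_values(img, mask)
  seg_o <- segment_hot(map, "otsu")
  expect_equal(nrow(seg_o$components), 1)
  expect_equal(seg_o$components$area, sum(img == 10))
  seg_p <- segment_hot(map, "percentile", percentile = 0.75)
  expect_identical(seg_p$label_image, seg_o$label_image)
})

test_that("component table is sorted by area with correct dominant fraction", {
  mask <- full_mask(c(60, 60))
  img <- disc_image(c(60, 60), rbind(c(15, 15), c(45, 45)), c(4.36, 3.55))
  map <- map_from_values(img, mask)
  seg <- segment_hot(map, "otsu")
  expect_equal(nrow(seg$components), 2)
  expect_true(all(diff(seg$components$area) <= 0))
  expect_equal(sum(seg$components$area), seg$total_hot_area)
  res <- classify_discreteness(seg, mask)
  expect_equal(res$dominant_fraction,
               max(seg$components$area) / seg$total_hot_area)
})

test_that("sub-min_area foci are filtered out", {
  mask <- full_mask(c(60, 60))
  # 3 real discs + 2 tiny foci of ~3 px
  img <- disc_image(c(60, 60), rbind(c(15, 15), c(15, 45), c(45, 30),
                                     c(45, 10), c(50, 52)),
                    c(6, 6, 6, 0.9, 0.9))
  map <- map_from_values(img, mask)
  seg <- segment_hot(map, "otsu", min_area = 5)
  expect_equal(nrow(seg$components), 3)
})

test_that("labeling is 8-connected", {
  mask <- full_mask(c(10, 10))
  img <- matrix(1, 10, 10)
  img[3, 3] <- img[4, 4] <- img[5, 5] <- 10   # diagonal chain
  map <- map_from_values(img, mask)
  seg <- segment_hot(map, "otsu", min_area = 1)
  expect_equal(nrow(seg$components), 1)
  expect_equal(seg$components$area, 3)
})

test_that("maps with only sub-min_area hot foci give an empty set and undefined grade", {
  mask <- full_mask(c(20, 20))
  img <- matrix(1, 20, 20)
  img[5, 5] <- img[15, 15] <- img[15, 16] <- 10  # isolated speckle foci
  map <- map_from_values(img, mask)
  expect_warning(seg <- segment_hot(map, "otsu", min_area = 5), "empty")
  expect_true(seg$empty)
  expect_equal(seg$total_hot_area, 0L)
  expect_error(classify_discreteness(seg, mask), "undefined grade")
})

test_that("the decision rule reproduces its defining arithmetic", {
  mask <- full_mask(c(50, 50))
  fake_regions <- function(areas) {
    centers <- cbind(seq(10, 40, length.out = length(areas)),
                     seq(10, 40, length.out = length(areas)))
    comps <- tibble::tibble(id = seq_along(areas), area = as.integer(areas),
                            centroid_r = centers[, 1],
                            centroid_c = centers[, 2],
                            mean_value = 10)
    structure(list(label_image = matrix(0L, 50, 50), components = comps,
                   hot_threshold = 5, total_hot_area = sum(areas),
                   empty = FALSE), class = "hot_region_set")
  }
  # single component -> grade 1 regardless of anything else
  expect_equal(classify_discreteness(fake_regions(100), mask)$grade, 1L)
  # fractions {0.85, 0.08, 0.07}: n = 3 <= 4 and dominant 0.85 >= 0.70 -> 2
  expect_equal(classify_discreteness(fake_regions(c(85, 8, 7)), mask)$grade, 2L)
  # 10 components, max fraction 0.15 -> grade 4
  expect_equal(classify_discreteness(
    fake_regions(c(15, rep(9.44, 9)) * 10), mask)$grade, 4L)
  # middle ground -> grade 3
  expect_equal(classify_discreteness(fake_regions(c(50, 30, 20)), mask)$grade, 3L)
  # cutpoints are configurable
  rule <- discreteness_rule(s_max = 2, d2 = 0.9)
  expect_equal(classify_discreteness(fake_regions(c(85, 8, 7)), mask,
                                     rule)$grade, 3L)
})

test_that("the grade is invariant to component relabeling", {
  mask <- full_mask(c(60, 60))
  img <- disc_image(c(60, 60), rbind(c(15, 15), c(15, 45), c(45, 30)),
                    c(7, 5, 4))
  map <- map_from_values(img, mask)
  seg <- segment_hot(map, "otsu")
  g1 <- classify_discreteness(seg, mask)$grade
  perm <- rev(seq_len(nrow(seg$components)))
  seg2 <- seg
  seg2$components <- seg$components[perm, ]
  seg2$label_image <- matrix(match(seg$label_image, perm, nomatch = 0L),
                             60, 60)
  expect_equal(classify_discreteness(seg2, mask)$grade, g1)
})

test_that("merging two components never increases the grade", {
  mask <- full_mask(c(80, 80))
  set.seed(31)
  for (trial in 1:20) {
    n <- sample(2:8, 1)
    areas <- sample(5:60, n, replace = TRUE)
    comps <- tibble::tibble(id = seq_len(n), area = areas,
                            centroid_r = runif(n, 10, 70),
                            centroid_c = runif(n, 10, 70), mean_value = 10)
    mk <- function(cmp) structure(
      list(label_image = matrix(0L, 80, 80), components = cmp,
           hot_threshold = 5, total_hot_area = sum(cmp$area), empty = FALSE),
      class = "hot_region_set")
    g_before <- classify_discreteness(mk(comps), mask)$grade
    # merge the two largest components
    ord <- order(areas, decreasing = TRUE)
    merged <- comps[-ord[2], ]
    merged$area[merged$id == comps$id[ord[1]]] <-
      areas[ord[1]] + areas[ord[2]]
    g_after <- classify_discreteness(mk(merged), mask)$grade
    expect_lte(g_after, g_before)
  }
})

test_that("trend tables reproduce their own margins and feed the trend test", {
  grades <- c(rep(1, 38), rep(2, 12), rep(3, 6), rep(4, 6))
  truth <- c(rep(0, 36), rep(1, 2), rep(0, 10), rep(1, 2),
             rep(0, 3), rep(1, 3), rep(0, 2), rep(1, 4))
  tt <- trend_against_truth(grades, truth)
  expect_equal(colSums(unclass(tt)), c(grade_1 = 38, grade_2 = 12,
                                       grade_3 = 6, grade_4 = 6))
  expect_equal(rowSums(unclass(tt)), c(benign = 51, malignant = 11))
  fit <- cochran_armitage(tt)
  expect_gt(fit$z, 0)  # malignancy rises with grade in this table
  expect_error(trend_against_truth(c(1, 5), c(0, 1)), "1..4")
})

test_that("grades are recovered from noisy phantoms across archetypes", {
  # spot check here (the full 50-seed ensemble runs in the acceptance suite)
  for (lt in c("1", "2", "3", "4")) {
    ph <- make_phantom(shape = c(64, 64), n_frames = 120, frame_interval = 1,
                       lesion_type = lt, noise_sigma = 0.1, seed = 20)
    map <- compute_map(ph$loop, ph$mask)
    res <- classify_map(map, ph$mask)
    expect_equal(res$grade, as.integer(lt),
                 label = paste("recovered grade for type", lt))
  }
})
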