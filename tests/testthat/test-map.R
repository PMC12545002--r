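test_that("homogeneous noiseless phantom yields a spatially constant map", {
  ph <- tiny_phantom(lesion_type = "none", texture_amp = 0)
  map <- compute_map(ph$loop, ph$mask)
  v <- map$values[map$quality == "ok"]
  expect_equal(length(v), attr(ph$mask, "n_pixels"))
  expect_lt(stats::sd(v) / mean(v), 1e-6)  # coefficient of variation
})

test_that("values outside the mask are NA, never numeric", {
  ph <- tiny_phantom(lesion_type = "1")
  map <- compute_map(ph$loop, ph$mask)
  expect_true(all(is.na(map$values[!ph$mask])))
  expect_true(all(map$quality[!ph$mask] == "outside"))
  expect_true(all(is.finite(map$values[map$quality == "ok"])))
  expect_true(all(map$values[map$quality == "ok"] >= 0))
})

test_that("lesion/background map contrast matches the simulated kinetic ratio", {
  ph <- tiny_phantom(lesion_type = "1", seed = 5)
  map <- compute_map(ph$loop, ph$mask)
  les <- ph$truth$labels > 0
  bg <- ph$mask & !les
  ratio <- mean(map$values[les], na.rm = TRUE) /
    mean(map$values[bg], na.rm = TRUE)
  truth_ratio <- bolus_mgp(ph$truth$lesion) / bolus_mgp(ph$truth$background)
  expect_lt(abs(ratio / truth_ratio - 1), 0.10)
})

test_that("map values scale exactly with intensity and ignore time origin", {
  ph <- tiny_phantom(lesion_type = "1", noise_sigma = 0.05, seed = 3)
  map1 <- compute_map(ph$loop, ph$mask)

  scaled <- ph$loop
  scaled$frames <- scaled$frames * 3.7
  map2 <- compute_map(scaled, ph$mask)
  expect_equal(map2$values, map1$values * 3.7)

  shifted <- ph$loop
  shifted$times <- shifted$times + 11.25
  map3 <- compute_map(shifted, ph$mask)
  expect_equal(map3$values, map1$values)
})

test_that("identical inputs give bit-identical maps", {
  ph <- tiny_phantom(lesion_type = "2", noise_sigma = 0.1, seed = 4)
  m1 <- compute_map(ph$loop, ph$mask)
  m2 <- compute_map(ph$loop, ph$mask)
  expect_identical(m1$values, m2$values)
  expect_identical(m1$quality, m2$quality)
})

test_that("alternative parameters return their own quantities", {
  ph <- tiny_phantom(lesion_type = "none",
                     background = bolus_model(5, 15, 20, 2, 1))
  pe <- compute_map(ph$loop, ph$mask, parameter = "peak_enhancement")
  ttp <- compute_map(ph$loop, ph$mask, parameter = "time_to_peak")
  expect_equal(mean(pe$values[pe$quality == "ok"]), 20, tolerance = 0.05)
  expect_equal(mean(ttp$values[ttp$quality == "ok"]), 10, tolerance = 0.1)
})

test_that("tidy() returns one row per in-ROI pixel", {
  ph <- tiny_phantom(lesion_type = "1")
  map <- compute_map(ph$loop, ph$mask)
  df <- tidy(map)
  expect_s3_class(df, "tbl_df")
  expect_equal(nrow(df), attr(ph$mask, "n_pixels"))
  expect_true(all(c("row", "col", "value", "quality") %in% names(df)))
})

test_that("rendering encodes values faithfully and embeds a colour bar", {
  ph <- tiny_phantom(lesion_type = "none")
  map <- compute_map(ph$loop, ph$mask)
  map$values[ph$mask] <- 5  # exactly constant map: single colour + warning
  p <- withr::local_tempfile(fileext = ".png")
  expect_warning(render_map(map, p), "constant")
  img <- png::readPNG(p)
  C <- ncol(map$values)
  inroi <- which(matrix(ph$mask, nrow(ph$mask), ncol(ph$mask)))
  cols <- unique(round(cbind(img[, 1:C, 1][inroi], img[, 1:C, 2][inroi],
                             img[, 1:C, 3][inroi]), 6))
  expect_equal(nrow(cols), 1)

  # two-valued map: low value renders the coldest colour, high the hottest
  map$values[ph$mask] <- 1
  hotpx <- which(matrix(ph$mask, nrow(ph$mask), ncol(ph$mask)))[1:20]
  map$values[hotpx] <- 2
  p2 <- withr::local_tempfile(fileext = ".png")
  render_map(map, p2)
  img2 <- png::readPNG(p2)
  rgb_at <- function(px) c(img2[, 1:C, 1][px[1]], img2[, 1:C, 2][px[1]],
                           img2[, 1:C, 3][px[1]])
  coldest <- grDevices::col2rgb("#00004B")[, 1] / 255
  hottest <- grDevices::col2rgb("#FF0000")[, 1] / 255
  others <- setdiff(inroi, hotpx)
  expect_equal(rgb_at(others), coldest, tolerance = 0.01, ignore_attr = TRUE)
  expect_equal(rgb_at(hotpx), hottest, tolerance = 0.01, ignore_attr = TRUE)
  # image is wider than the map: colour bar and label strip are embedded
  expect_gt(dim(img2)[2], C)
})

test_that("re-segmenting a rendered multi-focal map recovers the components", {
  # no echotexture so all foci render at the hot end of the scale
  ph <- tiny_phantom(lesion_type = "4", seed = 9, texture_amp = 0)
  map <- compute_map(ph$loop, ph$mask)
  p <- withr::local_tempfile(fileext = ".png")
  render_map(map, p)
  img <- png::readPNG(p)
  C <- ncol(map$values)
  # hot-coloured = red channel dominant and high
  hot <- img[, 1:C, 1] > 0.75 & img[, 1:C, 2] < 0.6
  hot <- hot & matrix(ph$mask, nrow(ph$mask), ncol(ph$mask))
  lab <- ticmapr:::label_components_8(hot)
  areas <- tabulate(lab[lab > 0])
  expect_equal(sum(areas >= 5), nrow(ph$truth$components))
})
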