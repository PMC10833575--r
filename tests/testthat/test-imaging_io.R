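test_that("fluor_image validates intensities and pixel size", {
  img <- fluor_image(matrix(0.2, 40, 60))
  expect_equal(img$width, 60)
  expect_equal(img$height, 40)
  expect_equal(img$pixel_size_mm, 0.085)
  expect_error(fluor_image(matrix(-1, 4, 4)), "non-negative")
  expect_error(fluor_image(matrix(Inf, 4, 4)), "finite")
  expect_error(fluor_image(matrix(0, 4, 4), pixel_size_mm = 0), "positive")
})

test_that("image pairs round-trip through TIFF and reject shape mismatches", {
  set.seed(11)
  px <- matrix(runif(100 * 80), 100, 80)
  wp <- tempfile(fileext = ".tif"); fp <- tempfile(fileext = ".tif")
  write_image(px, wp)
  write_image(px / 2, fp)
  pair <- read_image_pair(wp, fp, pixel_size_mm = 0.085)
  expect_s3_class(pair$fluor, "fluor_image")
  expect_equal(dim(pair$fluor$pixels), c(100, 80))
  # 32-bit integer storage quantizes below 2^-31 absolute
  expect_lt(max(abs(pair$white$pixels - px)), 2^-31)
  # identical file passed twice is a valid (degenerate) pair
  same <- read_image_pair(wp, wp, pixel_size_mm = 0.085)
  expect_identical(same$white$pixels, same$fluor$pixels)
  # shape mismatch is an unpaired acquisition
  op <- tempfile(fileext = ".tif")
  write_image(matrix(0.1, 50, 80), op)
  expect_error(read_image_pair(wp, op, pixel_size_mm = 0.085), "unpaired")
})

test_that("pixel size falls back to 0.085 mm with a warning, OME metadata wins", {
  p <- tempfile(fileext = ".tif")
  write_image(matrix(0.5, 10, 10), p)
  expect_warning(pair <- read_image_pair(p, p), "0.085")
  expect_equal(pair$fluor$pixel_size_mm, 0.085)
  # explicit override silences the warning
  expect_silent(pair2 <- read_image_pair(p, p, pixel_size_mm = 0.1))
  expect_equal(pair2$fluor$pixel_size_mm, 0.1)
  # OME-XML parsing (unit-aware)
  ome <- paste0('<OME><Image><Pixels PhysicalSizeX="85.0" ',
                'PhysicalSizeXUnit="µm"/></Image></OME>')
  expect_equal(fluorquant:::ome_pixel_size_mm(ome), 0.085)
  ome_mm <- '<Pixels PhysicalSizeX="0.2" PhysicalSizeXUnit="mm"/>'
  expect_equal(fluorquant:::ome_pixel_size_mm(ome_mm), 0.2)
  expect_true(is.na(fluorquant:::ome_pixel_size_mm("no metadata here")))
})

test_that("rasterization uses the pixel-center even-odd rule", {
  # axis-aligned rectangle covering centers (10..19, 10..19)
  rect <- cbind(c(9.5, 19.5, 19.5, 9.5), c(9.5, 9.5, 19.5, 19.5))
  m <- rasterize_roi(rect, c(40, 40))
  expect_equal(sum(m), 100)
  expect_true(all(m[11:20, 11:20]))
  # circle: area equals brute-force count of centers strictly inside
  poly <- circle_polygon(30.3, 30.7, 20)
  mc <- rasterize_roi(poly, c(64, 64))
  expect_equal(sum(mc), sum(disk_mask(64, 64, 30.3, 30.7, 20)))
  # ring with a hole under even-odd
  outer_r <- cbind(c(4.5, 25.5, 25.5, 4.5), c(4.5, 4.5, 25.5, 25.5))
  inner_r <- cbind(c(9.5, 20.5, 20.5, 9.5), c(9.5, 9.5, 20.5, 20.5))
  mh <- rasterize_roi(list(outer_r, inner_r), c(40, 40))
  expect_equal(sum(mh), 21 * 21 - 11 * 11)
})

test_that("degenerate and out-of-bounds polygons are rejected or clipped", {
  degen <- cbind(c(1, 5, 9), c(1, 5, 9))  # collinear, zero area
  expect_error(rasterize_roi(degen, c(20, 20)), "empty ROI")
  outside <- cbind(c(100, 110, 110, 100), c(100, 100, 110, 110))
  expect_error(rasterize_roi(outside, c(20, 20)), "empty ROI")
  straddle <- cbind(c(15.5, 30, 30, 15.5), c(15.5, 15.5, 30, 30))
  m <- rasterize_roi(straddle, c(20, 20))  # clipped to the grid
  expect_equal(sum(m), 4 * 4)
})

test_that("rectangle mask -> polygon -> mask round trip is exact", {
  m <- rect_mask(32, 48, 5, 17, 9, 30)
  expect_identical(rasterize_roi(mask_bbox_polygon(m), m), m)
})

test_that("GeoJSON ROIs round-trip with names and coordinates", {
  rois <- list(tumor = circle_polygon(20, 22, 8, n = 32),
               loaf = cbind(c(1.5, 38.5, 38.5, 1.5), c(1.5, 1.5, 38.5, 38.5)))
  p <- tempfile(fileext = ".geojson")
  write_geojson_roi(rois, p)
  back <- read_geojson_roi(p)
  expect_named(back, c("tumor", "loaf"))
  # closing vertex is added on write and dropped on rasterization
  expect_equal(unname(back$tumor[[1]][1:32, ]), unname(rois$tumor),
               tolerance = 1e-12)
  m1 <- rasterize_roi(rois$tumor, c(44, 44))
  m2 <- rasterize_roi(back$tumor, c(44, 44))
  expect_identical(m1, m2)
})

test_that("delineation sets clip the tumor to the loaf and reject empties", {
  loaf <- rect_mask(40, 40, 5, 35, 5, 35)
  tumor <- rect_mask(40, 40, 30, 39, 30, 39)  # spills outside the loaf
  expect_message(ds <- delineation_set(tumor, loaf), "clipped")
  expect_true(all(ds$tumor[!loaf] == FALSE))
  expect_equal(sum(ds$tumor), sum(tumor & loaf))
  expect_error(delineation_set(tumor & !loaf, loaf), "empty tumor|clipped")
})

test_that("quantification CSV writes one row per record and round-trips", {
  recs <- do.call(rbind, lapply(1:60, function(i) data.frame(
    loaf_id = sprintf("loaf_%02d", (i - 1) %/% 6 + 1), lesion_id = "L1",
    observer = sprintf("obs%d", (i - 1) %% 3 + 1),
    session = sprintf("s%d", (i - 1) %% 2 + 1),
    method = "automatic", pipeline = "nontargeted_sbr",
    signal_mfi = 0.5 + i / 1000, background_mfi = 0.1, ratio = 5 + i / 100,
    signal_area_px = 100L + i, background_area_px = 5000L,
    signal_halo_mm = 3, background_margin_mm = 5,
    stringsAsFactors = FALSE)))
  p <- tempfile(fileext = ".csv")
  write_quantification_csv(recs, p)
  expect_length(readLines(p), 61)  # header + 10 loaves x 3 obs x 2 sessions
  back <- read_quantification_csv(p)
  expect_equal(back, recs, tolerance = 1e-12)
  # single record -> two-line file; empty -> header only, with a warning
  write_quantification_csv(recs[1, ], p)
  expect_length(readLines(p), 2)
  expect_warning(write_quantification_csv(NULL, p), "header-only")
  expect_length(readLines(p), 1)
})
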