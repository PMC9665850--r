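test_that("TIFF pairs round-trip bit-exactly at both bit depths", {
  dir <- withr::local_tempdir()
  set.seed(3)
  d8 <- random_intensity_matrix(64, 64)
  m8 <- random_intensity_matrix(64, 64)
  write_gray_tiff(d8, file.path(dir, "a_dna.tif"), 8)
  write_gray_tiff(m8, file.path(dir, "a_marker.tif"), 8)
  f <- read_field(file.path(dir, "a_dna.tif"), file.path(dir, "a_marker.tif"),
                  list(field_id = "a", time_point_min = 30,
                       stimulus = "PMA", objective = "10x"))
  expect_identical(f$dna, d8)
  expect_identical(f$marker, m8)
  expect_equal(f$bit_depth, 8L)
  expect_equal(f$objective, "10x")
  expect_equal(f$time_point_min, 30)
  # 16-bit with max value 4095: intensities unchanged
  d16 <- matrix(as.integer(sample(0:4095, 64 * 64, TRUE)), 64, 64)
  write_gray_tiff(d16, file.path(dir, "b_dna.tif"), 16)
  write_gray_tiff(d16, file.path(dir, "b_marker.tif"), 16)
  f16 <- read_field(file.path(dir, "b_dna.tif"),
                    file.path(dir, "b_marker.tif"))
  expect_identical(f16$dna, d16)
  expect_equal(f16$bit_depth, 16L)
})

test_that("mismatched or non-grayscale inputs are rejected", {
  dir <- withr::local_tempdir()
  write_gray_tiff(matrix(1L, 64, 64), file.path(dir, "a_dna.tif"), 8)
  write_gray_tiff(matrix(1L, 64, 32), file.path(dir, "a_marker.tif"), 8)
  expect_error(read_field(file.path(dir, "a_dna.tif"),
                          file.path(dir, "a_marker.tif")),
               class = "netquant_dimension_error")
  # RGB TIFF
  rgb <- array(0.5, c(8, 8, 3))
  tiff::writeTIFF(rgb, file.path(dir, "rgb.tif"))
  expect_error(read_field(file.path(dir, "rgb.tif"),
                          file.path(dir, "rgb.tif")),
               class = "netquant_format_error")
  # float TIFF
  tiff::writeTIFF(matrix(runif(64), 8, 8), file.path(dir, "f.tif"),
                  bits.per.sample = 32L)
  expect_error(read_field(file.path(dir, "f.tif"), file.path(dir, "f.tif")),
               class = "netquant_format_error")
})

test_that("multi-page stacks split into per-plane fields in page order", {
  dir <- withr::local_tempdir()
  p1 <- matrix(10L, 16, 16); p2 <- matrix(200L, 16, 16)
  tiff::writeTIFF(list(p1 / 255, p2 / 255), file.path(dir, "s_dna.tif"),
                  bits.per.sample = 8L)
  tiff::writeTIFF(list(p2 / 255, p1 / 255), file.path(dir, "s_marker.tif"),
                  bits.per.sample = 8L)
  fields <- read_field_stack(file.path(dir, "s_dna.tif"),
                             file.path(dir, "s_marker.tif"),
                             list(field_id = "s"))
  expect_length(fields, 2)
  expect_equal(fields[[1]]$field_id, "s_p1")
  expect_equal(fields[[2]]$field_id, "s_p2")
  expect_identical(fields[[1]]$dna, p1)
  expect_identical(fields[[2]]$dna, p2)
  expect_error(read_field(file.path(dir, "s_dna.tif"),
                          file.path(dir, "s_marker.tif")),
               class = "netquant_format_error")
})

test_that("size gates resolve per objective and reject unknown ones", {
  g10 <- resolve_size_gates("10x")
  expect_equal(g10$min_area_total, 25L)
  expect_equal(g10$min_area_net, 75L)
  g20 <- resolve_size_gates("20x")
  expect_equal(g20$min_area_total, 100L)
  expect_equal(g20$min_area_net, 250L)
  expect_identical(resolve_size_gates("10x"), resolve_size_gates("10x"))
  expect_error(resolve_size_gates("40x"), class = "netquant_config_error")
})

test_that("object and field tables round-trip through CSV", {
  dir <- withr::local_tempdir()
  m <- matrix(FALSE, 8, 8); m[3:5, 3:5] <- TRUE
  f <- make_field(matrix(10L, 8, 8), field_id = "fx")
  rec <- measure_objects(label_components(m, 8), f)
  path <- file.path(dir, "objects.csv")
  write_object_table(rec, path)
  back <- utils::read.csv(path)
  expect_equal(back$area_px, 9)
  expect_equal(back$sum_dna, 90)
  expect_equal(back$centroid_x, 3)   # x = column
  expect_equal(back$centroid_y, 3)
  sidecar <- jsonlite::read_json(paste0(path, "_boundaries.json"),
                                 simplifyVector = TRUE)
  expect_named(sidecar, "fx/1")
  expect_equal(dim(sidecar[["fx/1"]]), c(8, 2))  # 8 ordered (row, col) pairs
  # empty record list -> header-only CSV
  write_object_table(rec[0, ], file.path(dir, "empty.csv"))
  empty <- utils::read.csv(file.path(dir, "empty.csv"))
  expect_equal(nrow(empty), 0)
  expect_true(all(c("label", "area_px", "class") %in% names(empty)))
})

test_that("field tables carry the full per-field summary", {
  dir <- withr::local_tempdir()
  res <- data.frame(field_id = "f1", time_point_min = 180, stimulus = "PMA",
                    method = "auto", n_total = 20L, n_net = 8L,
                    percent_net = 40, quality_score = 0.97,
                    excluded = FALSE)
  write_field_table(res, file.path(dir, "fields.csv"))
  back <- utils::read.csv(file.path(dir, "fields.csv"))
  expect_equal(back$percent_net, 40)
  expect_equal(back$n_total, 20)
  expect_false(back$excluded)
})

test_that("run configuration enforces its invariants", {
  cfg <- run_config("auto", "20x")
  expect_equal(cfg$bernsen_radius, 15L)
  expect_equal(cfg$bernsen_contrast, 35)
  expect_equal(cfg$min_area_total, 100L)
  expect_equal(cfg$min_area_net, 250L)
  expect_error(run_config("manual", "20x"),
               class = "netquant_config_error")
  expect_error(run_config("auto", "20x", min_area_net = 50),
               class = "netquant_config_error")
  # JSON file + override precedence
  dir <- withr::local_tempdir()
  jsonlite::write_json(list(mode = "manual", objective = "10x",
                            manual_threshold_marker = 80),
                       file.path(dir, "c.json"), auto_unbox = TRUE)
  cfg2 <- read_run_config(file.path(dir, "c.json"),
                          list(manual_threshold_marker = 120))
  expect_equal(cfg2$mode, "manual")
  expect_equal(cfg2$manual_threshold_marker, 120)
  expect_equal(cfg2$min_area_total, 25L)
})
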