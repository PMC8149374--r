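test_that("wavenumber axis validation rejects malformed axes", {
  expect_silent(wavenumber_axis(c(400, 402, 404)))
  expect_error(wavenumber_axis(500), class = "ramanmark_error_axis_too_short")
  expect_error(wavenumber_axis(c(500, 500, 600)),
               class = "ramanmark_error_axis_not_increasing")
  expect_error(wavenumber_axis(c(600, 500)),
               class = "ramanmark_error_axis_not_increasing")
  expect_error(wavenumber_axis(c(400, NA, 500)),
               class = "ramanmark_error_nonfinite")
})

test_that("constructors reject NaN/Inf and shape mismatches", {
  ax <- tiny_axis(4)
  expect_error(raman_spectrum(ax, c(1, 2, 3)),
               class = "ramanmark_error_channel_mismatch")
  expect_error(raman_spectrum(ax, c(1, 2, Inf, 4)),
               class = "ramanmark_error_nonfinite")
  expect_error(raman_map(ax, matrix(1, 4, 5), 2, 3),
               class = "ramanmark_error_grid_mismatch")
  expect_error(raman_map(ax, matrix(1, 3, 6), 2, 3),
               class = "ramanmark_error_channel_mismatch")
  expect_error(raman_map(ax, matrix(NaN, 4, 6), 2, 3),
               class = "ramanmark_error_nonfinite")
  expect_error(component_set(ax, matrix(-1, 4, 1), "a"),
               class = "ramanmark_error_negative_values")
  expect_error(component_set(ax, matrix(1, 4, 2), c("a", "a")),
               class = "ramanmark_error_bad_names")
  expect_error(abundance_stack("a", array(-1, c(2, 2, 1))),
               class = "ramanmark_error_negative_values")

  # property: random malformed inputs always rejected
  set.seed(42)
  for (i in 1:20) {
    m <- sample(3:8, 1)
    bad <- sample(c("shape", "nan"), 1)
    dat <- matrix(runif(m * 6), m, 6)
    if (bad == "shape") {
      expect_error(raman_map(tiny_axis(m + 1), dat, 2, 3),
                   class = "ramanmark_error_channel_mismatch")
    } else {
      dat[sample(length(dat), 1)] <- sample(c(NA, NaN, Inf), 1)
      expect_error(raman_map(tiny_axis(m), dat, 2, 3),
                   class = "ramanmark_error_nonfinite")
    }
  }
})

test_that("component spectra are rescaled to the max-1 convention", {
  ax <- tiny_axis(4)
  cs <- component_set(ax, matrix(c(1, 2, 4, 2), 4, 1), "a")
  expect_equal(max(cs$spectra), 1)
  expect_equal(cs$spectra[, 1], c(0.25, 0.5, 1, 0.5), ignore_attr = TRUE)
})

test_that("pixel linearization is row-major from the top-left", {
  map <- tiny_map(2, 3)
  expect_equal(pixel_index(map, 1, 1), 1L)
  expect_equal(pixel_index(map, 1, 3), 3L)
  expect_equal(pixel_index(map, 2, 1), 4L)
  # H matrix <-> stack round trip follows the same order
  H <- matrix(seq_len(12), 2, 6)
  st <- stack_from_h(H, 2, 3, c("a", "b"))
  expect_equal(st$maps[1, , "a"], H[1, 1:3])
  expect_equal(st$maps[2, , "b"], H[2, 4:6])
  expect_equal(stack_to_h(st), H, ignore_attr = TRUE)
})

test_that("container round trip is lossless, including metadata", {
  map <- tiny_map(2, 2, m = 3,
                  meta = list(group = "WT", region = "ascending",
                              species = "mouse", animal_id = "a7",
                              scan_kind = "high_res"))
  map$data <- matrix(rnorm(12)^3 * 1e-7 + 1, 3, 4)  # awkward doubles
  path <- tempfile(fileext = ".txt")
  write_map(map, path, "container")
  back <- read_map(path, "container")
  expect_identical(back$data, map$data)
  expect_identical(back$wavenumber, map$wavenumber)
  expect_identical(back$meta, map$meta)
  expect_identical(back$pixel_size_um, map$pixel_size_um)

  # degenerate 1x1 grid still valid
  one <- raman_map(tiny_axis(3), matrix(1:3, 3, 1), 1, 1)
  p1 <- tempfile()
  write_map(one, p1, "container")
  expect_equal(read_map(p1, "container")$data, one$data)
})

test_that("csv round trip preserves data; formats are never sniffed", {
  map <- tiny_map(2, 3, m = 4)
  path <- tempfile(fileext = ".csv")
  write_map(map, path, "csv")
  back <- read_map(path, "csv")
  expect_identical(back$data, map$data)
  expect_equal(back$meta$group, "n/a")  # csv carries no metadata

  pc <- tempfile()
  write_map(map, pc, "container")
  expect_error(read_map(pc, "csv"), class = "ramanmark_error")
})

test_that("map readers raise distinct, named validation errors", {
  expect_error(read_map(tempfile(), "container"),
               class = "ramanmark_error_missing_file")
  # csv whose header has 5 wavenumbers but rows carry 4 values
  p <- tempfile()
  writeLines(c("row,col,400,410,420,430,440",
               "1,1,1,2,3,4"), p)
  expect_error(read_map(p, "csv"),
               class = "ramanmark_error_channel_mismatch")
  # header without wavenumbers
  p2 <- tempfile()
  writeLines(c("row,col", "1,1"), p2)
  expect_error(read_map(p2, "csv"), class = "ramanmark_error_missing_axis")
  # container missing the axis record
  p3 <- tempfile()
  writeLines(c("ramanmark-map 1", "meta\t{}", "grid\t1\t1", "data", "1", "2"),
             p3)
  expect_error(read_map(p3, "container"),
               class = "ramanmark_error_missing_axis")
  # non-increasing axis caught on read
  map <- tiny_map()
  p4 <- tempfile()
  write_map(map, p4, "container")
  txt <- readLines(p4)
  txt[5] <- "wavenumber\t500 500 600 610 620"
  writeLines(txt, p4)
  expect_error(read_map(p4, "container"),
               class = "ramanmark_error_axis_not_increasing")
})

test_that("spectrum tables round trip and reject malformed rows", {
  s <- raman_spectrum(default_axis(), runif(701))
  p <- tempfile()
  write_spectrum_table(s, p)
  back <- read_spectrum_table(p)
  expect_equal(back$intensity, s$intensity, tolerance = 1e-12)
  expect_identical(back$wavenumber, s$wavenumber)

  p2 <- tempfile()
  writeLines(c("#hdr", "400 1.0", "402 2.0"), p2)
  sp <- read_spectrum_table(p2)
  expect_equal(length(sp$intensity), 2L)
  expect_equal(sp$intensity, c(1, 2))

  writeLines(c("400 1.0"), p2)
  expect_error(read_spectrum_table(p2),
               class = "ramanmark_error_axis_too_short")
  writeLines(c("400 1.0", "402 x"), p2)
  expect_error(read_spectrum_table(p2),
               class = "ramanmark_error_bad_table_row")
  # comma-delimited accepted too
  writeLines(c("400,1.5", "402,2.5"), p2)
  expect_equal(read_spectrum_table(p2)$intensity, c(1.5, 2.5))
})
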