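test_that("CSV read/write round-trips temperatures exactly", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("25.0,25.0,25.0", "25.0,25.0,25.0", "25.0,25.0,25.0"), path)
  t <- read_temperature_matrix(path, subject_id = "a", side = "right",
                               group = "control")
  expect_s3_class(t, "thermogram")
  expect_identical(dim(t$temperatures), c(3L, 3L))
  expect_true(all(t$temperatures == 25.0))

  set.seed(4)
  m <- matrix(rnorm(20 * 10, 26, 3), 20, 10)
  t2 <- thermogram(m, side = "left", group = "diabetic")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_temperature_matrix(t2, p2)
  expect_identical(length(readLines(p2)), 20L)
  expect_identical(length(strsplit(readLines(p2)[1], ",")[[1]]), 10L)
  back <- read_temperature_matrix(p2, side = "left", group = "diabetic")
  expect_identical(back$temperatures, unname(m))
})

test_that("malformed CSV inputs produce located errors", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("1,2,3", "1,2,3,4"), p)
  expect_error(read_temperature_matrix(p), "row 2")
  p2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("25,25,25", "25,25,25", "25,xx,25", "25,25,25"), p2)
  expect_error(read_temperature_matrix(p2), "row 3, column 2")
  expect_error(read_temperature_matrix(tempfile()), "not found")
})

test_that("thermogram constructor enforces invariants", {
  expect_error(thermogram(matrix(c(1, NA, 3, 4, 5, 6), 3, 2)), "finite")
  expect_error(thermogram(matrix("a", 5, 5)), "numeric")
  # small matrices are storable (2x2 write example); partitioning guards later
  t22 <- thermogram(matrix(25, 2, 2))
  p <- withr::local_tempfile(fileext = ".csv")
  write_temperature_matrix(t22, p)
  expect_identical(length(readLines(p)), 2L)
})

test_that("gray mapping and PNG export follow the configured window", {
  # round(255 * (26 - 18) / 22) = 93
  expect_identical(temperature_to_gray(26, c(18, 40)), 93L)
  expect_identical(temperature_to_gray(10, c(18, 40)), 0L)
  expect_identical(temperature_to_gray(99, c(18, 40)), 255L)

  t <- make_uniform_thermo(26, 12, 7)
  p <- withr::local_tempfile(fileext = ".png")
  export_thermogram_png(t, p, window = c(18, 40))
  bytes <- readBin(p, "raw", 8)
  expect_identical(bytes, as.raw(c(0x89, 0x50, 0x4E, 0x47, 0x0D, 0x0A, 0x1A, 0x0A)))
  # independent decoder oracle (Pillow) recovers the exact gray matrix
  dec <- system2("python", c("-c", shQuote(paste0(
    "from PIL import Image; import sys;",
    "im = Image.open('", p, "');",
    "print(im.size[0], im.size[1]);",
    "print(' '.join(str(v) for v in im.getdata()))"))),
    stdout = TRUE)
  expect_identical(strsplit(dec[1], " ")[[1]], c("7", "12"))
  vals <- as.integer(strsplit(dec[2], " ")[[1]])
  expect_true(all(vals == 93L))
})

test_that("segmentation recovers the foot and handles degenerate inputs", {
  cold <- make_uniform_thermo(20)
  expect_warning(m <- segment_foot(cold, 22), "empty mask")
  expect_false(any(m))

  hot <- make_uniform_thermo(30)
  expect_true(all(segment_foot(hot, 22)))

  # phantom ground truth, zero noise: footprint reproduced pixel-for-pixel
  ph <- generate_phantom(phantom_config(target_grade = 2, noise_sd = 0,
                                        seed = 11))
  expect_identical(segment_foot(ph$thermogram, 24), ph$truth$footprint)

  # speckle + hole: largest component kept, holes filled
  temps <- matrix(20, 30, 20)
  temps[5:25, 5:15] <- 30
  temps[12:14, 8:10] <- 21      # interior hole -> filled
  temps[1, 20] <- 35            # isolated speck -> dropped
  t <- thermogram(temps, side = "right", group = "control")
  m <- segment_foot(t, 22)
  expect_true(all(m[5:25, 5:15]))
  expect_false(m[1, 20])
})

test_that("encoding maps the window affinely with clipping, in every mode", {
  t <- make_uniform_thermo(26, 40, 20)
  for (mode in c("rectangular", "resized", "padded")) {
    e <- encode_for_network(t, mask = matrix(TRUE, 40, 20), mode = mode)
    expect_s3_class(e, "encoded_input")
    core <- if (mode == "padded") e$values[94:133, 104:123] else e$values
    expect_equal(unique(as.vector(core)), (26 - 18) / 22, tolerance = 1e-12)
    expect_true(all(e$values >= 0 & e$values <= 1))
  }
  expect_identical(dim(encode_for_network(t, mode = "rectangular")$values),
                   c(180L, 80L))
  expect_identical(dim(encode_for_network(t, mode = "resized")$values),
                   c(227L, 227L))
  # clipping
  lo <- encode_for_network(make_uniform_thermo(10), mode = "rectangular")
  hi <- encode_for_network(make_uniform_thermo(50), mode = "rectangular")
  expect_true(all(lo$values == 0))
  expect_true(all(hi$values == 1))
})

test_that("padded mode centers the native-scale foot with zero border", {
  temps <- matrix(30, 180, 80)
  t <- thermogram(temps, side = "right", group = "diabetic")
  e <- encode_for_network(t, mask = matrix(TRUE, 180, 80), mode = "padded")
  expect_identical(dim(e$values), c(227L, 227L))
  inner <- e$values[24:203, 74:153]
  expect_equal(unique(as.vector(inner)), (30 - 18) / 22, tolerance = 1e-12)
  border <- e$values
  border[24:203, 74:153] <- NA
  expect_true(all(border == 0, na.rm = TRUE))
  # oversized input downscales to fit, with a warning
  big <- thermogram(matrix(30, 300, 80), side = "right", group = "diabetic")
  expect_warning(e2 <- encode_for_network(big, mask = matrix(TRUE, 300, 80),
                                          mode = "padded"), "downscal")
  expect_identical(dim(e2$values), c(227L, 227L))
})

test_that("encoding is monotone in temperature and preserves regional ranks", {
  # monotone: warmer pixel -> strictly greater intensity (inside the window)
  set.seed(2)
  temps <- matrix(runif(180 * 80, 20, 38), 180, 80)
  t <- thermogram(temps, side = "right", group = "diabetic")
  e <- encode_for_network(t, mode = "rectangular")  # identity-size resample
  ord <- order(temps)
  expect_true(all(diff(e$values[ord]) >= 0))
  expect_gt(e$values[ord[length(ord)]], e$values[ord[1]])

  # rank order of per-quadrant means survives resized/rectangular resampling
  q <- matrix(0, 100, 40)
  q[1:50, 1:20] <- 27.8; q[1:50, 21:40] <- 27.2
  q[51:100, 1:20] <- 29.4; q[51:100, 21:40] <- 28.6
  tq <- thermogram(q, side = "right", group = "diabetic")
  for (mode in c("resized", "rectangular")) {
    e <- encode_for_network(tq, mode = mode)
    d <- dim(e$values)
    hm <- d[1] %/% 2; wm <- d[2] %/% 2
    means <- c(mean(e$values[1:hm, 1:wm]), mean(e$values[1:hm, (wm + 1):d[2]]),
               mean(e$values[(hm + 1):d[1], 1:wm]),
               mean(e$values[(hm + 1):d[1], (wm + 1):d[2]]))
    expect_identical(order(means), order(c(27.8, 27.2, 29.4, 28.6)))
  }
})
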