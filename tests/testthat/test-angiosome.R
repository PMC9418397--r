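test_that("rectangular mask partitions into the documented geometry", {
  mask <- matrix(TRUE, 100, 40)
  p <- partition_angiosomes(mask, side = "right")
  # posterior 27% of 100 rows form the calcaneal zone
  expect_true(all(p$labels[74:100, ] %in% 3:4))
  expect_true(all(p$labels[1:73, ] %in% 1:2))
  # medial half of a right foot is columns 1..20: MPA anterior-medial
  expect_true(all(p$labels[1:73, 1:20] == 1L))
  expect_true(all(p$labels[1:73, 21:40] == 2L))
  expect_true(all(p$labels[74:100, 1:20] == 3L))
  expect_true(all(p$labels[74:100, 21:40] == 4L))
})

test_that("left/right partitions are exact mirror images", {
  set.seed(7)
  mask <- foot_like_mask <- generate_phantom(
    phantom_config(target_grade = 1, noise_sd = 0, seed = 5,
                   side = "right"))$truth$footprint
  pr <- partition_angiosomes(mask, side = "right")
  pl <- partition_angiosomes(mask[, ncol(mask):1], side = "left")
  expect_identical(pl$labels, pr$labels[, ncol(mask):1])
})

test_that("angiosomes partition the mask exactly", {
  ph <- generate_phantom(phantom_config(target_grade = 3, noise_sd = 0, seed = 3,
                                        side = "right"))
  mask <- ph$truth$footprint
  p <- partition_angiosomes(mask, side = "right")
  expect_true(all((p$labels > 0) == mask))       # union = mask, bg elsewhere
  counts <- table(p$labels[mask])
  expect_identical(sort(as.integer(names(counts))), 1:4)  # all non-empty
  # pairwise disjoint is implied by a single label matrix; empty-region error
  # names the region: heel present only on the lateral side -> MCA empty
  holed <- matrix(FALSE, 20, 10)
  holed[1:15, 1:10] <- TRUE
  holed[16:20, 6:10] <- TRUE
  expect_error(partition_angiosomes(holed, side = "right"), "MCA")
  expect_error(partition_angiosomes(matrix(TRUE, 20, 1)), "too small")
  expect_error(partition_angiosomes(matrix(FALSE, 5, 5)), "empty")
})

test_that("regional means are plain arithmetic means per region", {
  t <- make_uniform_thermo(26, 100, 40)
  p <- partition_angiosomes(matrix(TRUE, 100, 40), side = "right")
  expect_equal(unname(regional_mean_temperatures(t, p)), rep(26, 4))

  m <- matrix(20, 100, 40)
  m[1:73, 1:20] <- 27.8; m[1:73, 21:40] <- 27.7
  m[74:100, 1:20] <- 28.4; m[74:100, 21:40] <- 28.1
  t2 <- thermogram(m, side = "right", group = "diabetic")
  expect_equal(regional_mean_temperatures(t2, p),
               c(MPA = 27.8, LPA = 27.7, MCA = 28.4, LCA = 28.1))
  expect_error(regional_mean_temperatures(make_uniform_thermo(26, 10, 10), p),
               "shape")
})

test_that("TCI is the mean absolute deviation from the references", {
  refs <- reference_temperatures()
  expect_identical(unname(refs), c(25.8, 25.7, 26.4, 26.1))
  expect_equal(compute_tci(refs), 0)
  expect_equal(compute_tci(refs + 1), 1)
  expect_equal(compute_tci(refs - 2.5), 2.5)
  expect_equal(compute_tci(c(MPA = 28.3, LPA = 27.2, MCA = 29.4, LCA = 28.6)),
               2.375)
  # name order must not matter
  expect_equal(compute_tci(c(LCA = 28.6, MPA = 28.3, MCA = 29.4, LPA = 27.2)),
               2.375)
  expect_error(compute_tci(c(1, 2, 3)), "four")
})

test_that("TCI translation covariance and pixel-sum oracle", {
  set.seed(12)
  for (i in 1:20) {
    means <- reference_temperatures() + runif(4, -3, 3)
    delta <- runif(1, -2, 2)
    base <- compute_tci(means)
    shifted <- compute_tci(means + delta)
    expect_lte(abs(shifted - base), abs(delta) + 1e-12)
    all_up <- reference_temperatures() + runif(4, 0.5, 3)  # same-sign diffs
    expect_equal(compute_tci(all_up + abs(delta)),
                 compute_tci(all_up) + abs(delta))
  }
  # mean-then-difference equals pixel-sum arithmetic on a constant-region field
  m <- matrix(20, 100, 40)
  m[1:73, 1:20] <- 28.3; m[1:73, 21:40] <- 27.2
  m[74:100, 1:20] <- 29.4; m[74:100, 21:40] <- 28.6
  p <- partition_angiosomes(matrix(TRUE, 100, 40), side = "right")
  means <- vapply(1:4, function(i) {
    px <- m[p$labels == i]; sum(px) / length(px)  # explicit pixel sums
  }, numeric(1))
  names(means) <- c("MPA", "LPA", "MCA", "LCA")
  t <- thermogram(m, side = "right", group = "diabetic")
  expect_equal(compute_tci(regional_mean_temperatures(t, p)),
               compute_tci(means))
})

test_that("severity bins follow the printed boundaries exactly", {
  expect_identical(assign_severity_class(7.3, "control"), 0L)
  expect_identical(assign_severity_class(2.0, "diabetic"), 1L)
  expect_identical(assign_severity_class(2.375, "diabetic"), 2L)
  expect_identical(assign_severity_class(3.0, "diabetic"), 2L)
  expect_identical(assign_severity_class(3.0001, "diabetic"), 3L)
  expect_identical(assign_severity_class(4.0, "diabetic"), 3L)
  expect_identical(assign_severity_class(5.0, "diabetic"), 4L)
  expect_identical(assign_severity_class(5.0001, "diabetic"), 5L)
  expect_error(assign_severity_class(-0.1, "diabetic"), "non-negative")
  # monotone non-decreasing in TCI for diabetic feet
  grid <- seq(0, 8, by = 0.05)
  cls <- vapply(grid, assign_severity_class, integer(1), group = "diabetic")
  expect_true(all(diff(cls) >= 0))
})
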