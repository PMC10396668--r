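test_that("similarity registration recovers known transforms", {
  set.seed(8)
  local <- cbind(runif(20, 0, 500), runif(20, 0, 500))
  ## pure translation, no noise: exact recovery
  tr <- fitLocalToMapTransform(local, sweep(local, 2, c(-100, 50)))
  expect_equal(tr$t, c(100, -50), tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(tr$scale, 1, tolerance = 1e-9)
  expect_equal(tr$rms, 0, tolerance = 1e-9)

  ## rotation 30 degrees + translation with 1 m noise: close recovery
  th <- 30 * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  set.seed(9)
  local2 <- cbind(runif(50, 0, 1000), runif(50, 0, 1000))
  map2 <- t(R %*% t(local2)) + matrix(rnorm(100, 0, 1), ncol = 2)
  map2 <- sweep(map2, 2, c(-2000, 700))
  tr2 <- fitLocalToMapTransform(local2, map2)
  expect_equal(tr2$rotation, th, tolerance = 0.01)
  expect_equal(tr2$scale, 1, tolerance = 0.01)
  expect_equal(tr2$t, c(-2000, 700), tolerance = 5, ignore_attr = TRUE)
  expect_lt(tr2$rms, 2)

  expect_error(fitLocalToMapTransform(local[1:2, ], local[1:2, ]),
               "at least 3")
  col <- cbind(1:10, 2 * (1:10) + 3)
  expect_error(fitLocalToMapTransform(col, col), "collinear")
})

test_that("high registration residuals raise a warning", {
  set.seed(10)
  local <- cbind(runif(10, 0, 100), runif(10, 0, 100))
  map <- local + matrix(rnorm(20, 0, 40), ncol = 2)
  expect_warning(fitLocalToMapTransform(local, map), "RMS")
})

test_that("cell assignment follows the half-open convention", {
  g <- gridGeometry(10L, 8L, 30, c(0, 0))
  ## grid origin: south-west corner belongs to the bottom-left cell
  expect_equal(assignCell(c(0, 0), g), c(row = 10L, col = 1L))
  ## a shared corner belongs to the cell east/north of it
  expect_equal(assignCell(c(60, 60), g), c(row = 8L, col = 3L))
  ## interior point
  expect_equal(assignCell(c(45, 285), g), c(row = 1L, col = 2L))
  expect_error(assignCell(c(-1, 0), g), "outside")
  expect_error(assignCell(c(0, 300), g), "outside")
})

test_that("cell assignment agrees with brute-force containment", {
  g <- gridGeometry(12L, 9L, 30, c(120, -60))
  set.seed(13)
  pts <- cbind(runif(1000, 120, 120 + 9 * 30 - 1e-9),
               runif(1000, -60, -60 + 12 * 30 - 1e-9))
  got <- assignCell(pts, g)
  for (i in sample(1000, 200)) {
    hit <- NULL
    for (r in 1:12) for (cl in 1:9) {
      x0 <- 120 + (cl - 1) * 30
      y0 <- -60 + (12 - r) * 30
      if (pts[i, 1] >= x0 && pts[i, 1] < x0 + 30 &&
          pts[i, 2] >= y0 && pts[i, 2] < y0 + 30) hit <- c(r, cl)
    }
    expect_equal(unname(got[i, ]), hit)
  }
  ## inverse of cell-center generation
  cells <- cbind(sample(1:12, 50, TRUE), sample(1:9, 50, TRUE))
  expect_equal(unname(assignCell(cellCenters(cells, g), g)), unname(cells))
})

test_that("3x3 neighborhoods truncate at edges and span 63 m", {
  g <- gridGeometry(10L, 10L, 30)
  expect_equal(length(neighborhood3x3(c(5L, 5L), g)), 9L)
  expect_equal(length(neighborhood3x3(c(1L, 1L), g)), 4L)
  expect_equal(length(neighborhood3x3(c(1L, 5L), g)), 6L)
  expect_error(neighborhood3x3(c(0L, 5L), g), "bounds")

  ## center-to-outer-corner distance of the home-range block
  nb <- neighborhood3x3(c(5L, 5L), g)
  ctr <- cellCenters(cbind(5L, 5L), g)
  corners <- cellCenters(cellsMatrix(nb), g)
  dmax <- max(sqrt((corners[, 1] - ctr[1])^2 + (corners[, 2] - ctr[2])^2))
  ## block corner cells sit 45*sqrt(2) m away at the outer corner
  expect_equal(dmax + 15 * sqrt(2), 45 * sqrt(2), tolerance = 1e-9)
})

test_that("active landscape is the deduplicated union of neighborhoods", {
  g <- gridGeometry(10L, 10L, 30)
  expect_equal(length(activeLandscape(cbind(5L, 5L), g)), 9L)
  two <- activeLandscape(rbind(c(5L, 5L), c(5L, 6L)), g)
  expect_equal(length(two), 12L)
  ## brute-force union oracle
  oracle <- unique(rbind(cellsMatrix(neighborhood3x3(c(5L, 5L), g)),
                         cellsMatrix(neighborhood3x3(c(5L, 6L), g))))
  expect_equal(nrow(oracle), 12L)
  ## duplicates are idempotent
  dup <- activeLandscape(rbind(c(5L, 5L), c(5L, 5L)), g)
  expect_equal(cellsMatrix(dup), cellsMatrix(activeLandscape(cbind(5L, 5L), g)))
  ## union distributivity over input sets
  s1 <- rbind(c(3L, 3L), c(8L, 8L))
  s2 <- rbind(c(3L, 4L), c(5L, 5L))
  u <- activeLandscape(rbind(s1, s2), g)
  parts <- unique(rbind(cellsMatrix(activeLandscape(s1, g)),
                        cellsMatrix(activeLandscape(s2, g))))
  expect_setequal(paste(cellsMatrix(u)[, 1], cellsMatrix(u)[, 2]),
                  paste(parts[, 1], parts[, 2]))
  expect_warning(activeLandscape(matrix(integer(), 0, 2), g), "empty")
})

test_that("mound assignment uses GPS, registration, then overrides", {
  g <- gridGeometry(20L, 20L, 30, c(0, 0))
  set.seed(17)
  cells <- cbind(sample(2:19, 12), sample(2:19, 12))
  gps <- cellCenters(cells, g)
  th <- 10 * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  local <- t(solve(R, t(sweep(gps, 2, c(-50, 30)))))
  mounds <- data.frame(mound_id = sprintf("M%02d", 1:12),
                       gps_x = c(gps[1:9, 1], rep(NA, 3)),
                       gps_y = c(gps[1:9, 2], rep(NA, 3)),
                       local_x = local[, 1], local_y = local[, 2])
  asg <- assignMounds(mounds, g)
  expect_equal(asg$source, c(rep("gps", 9), rep("registered", 3)))
  expect_equal(cbind(asg$row, asg$col), unname(cells))
  ## manual override wins
  ov <- data.frame(mound_id = "M12", row = 1L, col = 1L)
  asg2 <- assignMounds(mounds, g, overrides = ov)
  expect_equal(asg2$row[12], 1L)
  expect_equal(asg2$source[12], "manual")
})
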