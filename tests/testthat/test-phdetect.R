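test_that("contour extraction matches the brute-force boundary definition", {
  expect_length(extract_contours(matrix(FALSE, 10, 10)), 0)

  mask <- disk_mask(c(64, 64), 32, 30, 16)
  cs <- extract_contours(mask)
  expect_length(cs, 1)
  d <- sqrt((cs[[1]][, 1] - 32)^2 + (cs[[1]][, 2] - 30)^2)
  expect_true(all(d >= 14.5 & d <= 16.5))
  # traced pixels = boundary pixels by definition (filled disk has no holes)
  brute <- brute_boundary_pixels(mask)
  expect_setequal(paste(cs[[1]][, 1], cs[[1]][, 2]),
                  paste(brute[, 1], brute[, 2]))

  two <- disk_mask(c(64, 128), 30, 32, 12) | disk_mask(c(64, 128), 95, 32, 16)
  expect_length(extract_contours(two), 2)
})

test_that("contours are filtered by boundary length", {
  mask <- disk_mask(c(64, 128), 30, 32, 3) | disk_mask(c(64, 128), 95, 32, 16)
  cs <- extract_contours(mask)
  lens <- sort(vapply(cs, nrow, integer(1)))
  expect_identical(filter_contours(cs, 0), cs)
  kept <- filter_contours(cs, 30)
  expect_length(kept, 1)
  expect_gt(nrow(kept[[1]]), 50) # digitized radius-16 disk boundary
  big <- extract_contours(disk_mask(c(64, 64), 32, 32, 16))
  expect_true(nrow(big[[1]]) >= 50)
})

test_that("circumcenter is exact and falls back to barycenter when degenerate", {
  expect_equal(as.vector(circumcenter(c(0, 0), c(2, 0), c(0, 2))), c(1, 1),
               tolerance = 1e-12)
  eq <- rbind(c(cos(pi / 2), sin(pi / 2)),
              c(cos(pi / 2 + 2 * pi / 3), sin(pi / 2 + 2 * pi / 3)),
              c(cos(pi / 2 + 4 * pi / 3), sin(pi / 2 + 4 * pi / 3)))
  expect_lt(max(abs(circumcenter(eq[1, ], eq[2, ], eq[3, ]))), 1e-9)
  th <- c(0.3, 1.9, 4.1)
  on_circle <- cbind(7 + 16 * cos(th), -3 + 16 * sin(th))
  cc <- circumcenter(on_circle[1, ], on_circle[2, ], on_circle[3, ])
  expect_lt(max(abs(cc - c(7, -3))), 1e-9)
  expect_false(attr(cc, "degenerate"))
  deg <- circumcenter(c(0, 0), c(1, 0), c(2, 0))
  expect_true(attr(deg, "degenerate"))
  expect_equal(as.vector(deg), c(1, 0), tolerance = 1e-12)
})

test_that("alpha H1 on the side-2 square is (1, sqrt(2)) with the square's center", {
  sq <- rbind(c(0, 0), c(2, 0), c(2, 2), c(0, 2))
  b <- compute_ph1(sq)
  expect_equal(nrow(b), 1)
  expect_equal(b$birth, 1, tolerance = 1e-12)
  expect_equal(b$death, sqrt(2), tolerance = 1e-12)
  cc <- circumcenter(c(b$x1, b$y1), c(b$x2, b$y2), c(b$x3, b$y3))
  expect_equal(as.vector(cc), c(1, 1), tolerance = 1e-9)
})

test_that("circle clouds produce bars whose death approximates the radius", {
  b <- compute_ph1(circle_cloud(50, 40, 16))
  expect_gte(nrow(b), 1)
  expect_true(b$death[1] >= 15.5 && b$death[1] <= 16.5)
  expect_equal(sum(b$death >= 2), 1) # a single dominant bar
  # death-simplex circumradius equals the death value
  cc <- circumcenter(c(b$x1[1], b$y1[1]), c(b$x2[1], b$y2[1]),
                     c(b$x3[1], b$y3[1]))
  expect_equal(sqrt(sum((cc - c(b$x1[1], b$y1[1]))^2)), b$death[1],
               tolerance = 1e-6)

  two <- rbind(circle_cloud(40, 40, 10, 80), circle_cloud(90, 40, 16, 100))
  b2 <- compute_ph1(two)
  deep <- b2[b2$death >= 5, ]
  expect_equal(nrow(deep), 2)
  expect_equal(sort(deep$death), c(10, 16), tolerance = 0.1)
})

test_that("alpha persistence agrees with the brute-force Cech oracle on small clouds", {
  for (s in 1:25) {
    set.seed(s)
    n <- sample(5:12, 1)
    pts <- cbind(runif(n, 0, 10), runif(n, 0, 10))
    got <- compute_ph1(pts)
    want <- cech_ph1_oracle(pts)
    expect_equal(nrow(got), nrow(want), info = paste("seed", s))
    if (nrow(want) > 0) {
      got <- got[order(got$birth, got$death), ]
      expect_equal(got$birth, want$birth, tolerance = 1e-7,
                   info = paste("seed", s))
      expect_equal(got$death, want$death, tolerance = 1e-7,
                   info = paste("seed", s))
    }
  }
})

test_that("detected points sit at figure centers and respect ph_thres", {
  b <- compute_ph1(circle_cloud(50, 40, 16))
  d <- detect_points(b, detect_params(5))
  expect_gte(nrow(d), 1)
  expect_lt(sqrt((d$x[1] - 50)^2 + (d$y[1] - 40)^2), 1)
  expect_equal(nrow(detect_points(b, detect_params(20))), 0)

  # overlapping dumbbell: two deepest detections at the two true centers
  ch <- gen_overlap_chain(c(16, 16), 8)
  bars <- compute_ph1(pool_contours(extract_contours(ch$mask)))
  dd <- detect_points(bars, detect_params(10))
  expect_gte(nrow(dd), 2)
  for (k in 1:2) {
    dist_k <- min(sqrt((dd$x[1:2] - ch$centers[k, 1])^2 +
                         (dd$y[1:2] - ch$centers[k, 2])^2))
    expect_lt(dist_k, 2)
  }
  # every detection is equidistant from its death-simplex vertices
  for (i in seq_len(nrow(dd))) {
    if (dd$degenerate[i]) next
    v <- rbind(c(dd$x1[i], dd$y1[i]), c(dd$x2[i], dd$y2[i]),
               c(dd$x3[i], dd$y3[i]))
    r3 <- sqrt((v[, 1] - dd$x[i])^2 + (v[, 2] - dd$y[i])^2)
    expect_lt(max(r3) - min(r3), 1e-6)
  }
  # sorted by death descending
  expect_true(all(diff(dd$death) <= 1e-12))
})

test_that("detections map back through the inverse transformation", {
  mask <- disk_mask(c(128, 128), 70, 50, 16)
  img <- matrix(220, 128, 128); img[mask] <- 30
  p <- pipeline_params(bin_thres = 150, erase_thres = 0, rot = 30, mult = 2,
                       ph_thres = 14, bd_thres = 30)
  res <- detect_frame(img, p)
  expect_gte(nrow(res$detections), 1)
  # deepest detection lands near the ORIGINAL center despite the transform
  expect_lt(sqrt((res$detections$x[1] - 70)^2 +
                   (res$detections$y[1] - 50)^2), 2)
})

test_that("non-overlapping disks are each detected within 1.5 px of their center", {
  ser <- gen_model_series("none", n_frames = 1, seed = 5)
  p <- params_from_tuple(c(150, 5, 0, 0, 1, 14, 50, 3), init = ser$truth[1, , ])
  d <- detect_frame(ser$frames[[1]], p)$detections
  expect_gte(nrow(d), 3)
  used <- integer(0)
  for (k in 1:3) {
    dist_k <- sqrt((d$x[1:3] - ser$truth[1, k, 1])^2 +
                     (d$y[1:3] - ser$truth[1, k, 2])^2)
    j <- which.min(dist_k)
    expect_lt(dist_k[j], 1.5)
    expect_false(j %in% used)
    used <- c(used, j)
  }
})

test_that("sure-foreground counting is a vertical line on the barcode", {
  sq <- compute_ph1(rbind(c(0, 0), c(2, 0), c(2, 2), c(0, 2)))
  expect_equal(sure_foreground_count(sq, 1.2), 1)
  expect_equal(sure_foreground_count(sq, 1.5), 0)
  expect_error(sure_foreground_count(sq, -1), ">= 0")
  # alive bars are a subset of bars with death above the line
  clouds <- list(circle_cloud(30, 30, 16),
                 pool_contours(extract_contours(fig4_chain_model()$mask)),
                 rbind(circle_cloud(40, 40, 10, 60), circle_cloud(80, 40, 16)))
  for (cl in clouds) {
    b <- compute_ph1(cl)
    for (t in seq(0, 20, by = 0.5))
      expect_lte(sure_foreground_count(b, t), sum(b$death >= t))
  }
})
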