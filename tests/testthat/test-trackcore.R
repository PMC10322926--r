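fake_dets <- function(xy, death = NULL) {
  data.frame(x = xy[, 1], y = xy[, 2],
             death = death %||% rep(16, nrow(xy)))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("selection picks the nearest detected point per cell", {
  prev <- rbind(c(0, 0), c(10, 0))
  sel <- select_points(prev, fake_dets(prev))
  expect_equal(sel$positions, cbind(x = c(0, 10), y = c(0, 0)))
  expect_length(sel$collisions, 0)

  sel2 <- select_points(rbind(c(0, 0)), fake_dets(rbind(c(1, 0), c(5, 0))))
  expect_equal(as.vector(sel2$positions), c(1, 0))

  # forced collision is permitted and reported
  sel3 <- select_points(prev, fake_dets(rbind(c(4, 0))))
  expect_equal(sel3$index, c(1L, 1L))
  expect_equal(sel3$collisions, 1L)

  # distance ties break by larger death
  sel4 <- select_points(rbind(c(0, 0)),
                        fake_dets(rbind(c(2, 0), c(-2, 0)), death = c(5, 9)))
  expect_equal(sel4$index, 2L)
  expect_error(select_points(prev, fake_dets(prev)[0, ]), "no detected")
})

test_that("a noiseless model series is tracked completely without collisions", {
  ser <- gen_model_series("none", seed = 3)
  p <- params_from_tuple(c(150, 5, 0, 0, 1, 14, 50, 3),
                         init = ser$truth[1, , ])
  tr <- track_sequence(ser, p)
  expect_equal(dim(tr$positions), c(10, 3, 2))
  expect_false(any(is.na(tr$positions)))
  expect_true(all(lengths(tr$collisions) == 0))
  expect_true(all(tr$provenance == "auto"))
  ev <- evaluate_track(tr, ser)
  expect_lt(ev$mean, 1.5)

  # every auto position is one of its frame's detected candidates
  for (i in 1:10) {
    cand <- tr$candidates[[i]]
    for (k in 1:3) {
      expect_true(any(abs(cand$x - tr$positions[i, k, 1]) < 1e-12 &
                        abs(cand$y - tr$positions[i, k, 2]) < 1e-12))
    }
  }
})

test_that("a single-frame sequence selects nearest detections to init", {
  ser <- gen_model_series("none", n_frames = 1, seed = 4)
  p <- params_from_tuple(c(150, 5, 0, 0, 1, 14, 50, 3),
                         init = ser$truth[1, , ])
  tr <- track_sequence(ser$frames, p)
  expect_equal(dim(tr$positions)[1], 1)
  expect_lt(max(sqrt((tr$positions[1, , 1] - ser$truth[1, , 1])^2 +
                       (tr$positions[1, , 2] - ser$truth[1, , 2])^2)), 1.5)
})

test_that("frame stride subsamples the sequence", {
  ser <- gen_model_series("none", n_frames = 145, step_px = 2, seed = 9)
  p <- params_from_tuple(c(150, 5, 0, 0, 1, 14, 50, 3),
                         init = ser$truth[1, , ], frame_stride = 5)
  tr <- track_sequence(ser$frames, p)
  expect_equal(dim(tr$positions)[1], 29)
  expect_equal(tr$frames_used, seq(1, 145, by = 5))
})

test_that("tracking fails loudly when a frame has no detections", {
  ser <- gen_model_series("none", n_frames = 2, seed = 1)
  p <- params_from_tuple(c(150, 5, 0, 0, 1, 40, 50, 3),
                         init = ser$truth[1, , ]) # ph_thres above any death
  expect_error(track_sequence(ser, p), "frame 1")
})

test_that("tracking is deterministic and frame-local", {
  ser <- gen_model_series("two", seed = 6)
  p <- params_from_tuple(c(150, 5, 0, 0, 1, 14, 50, 3),
                         init = ser$truth[1, , ])
  t1 <- track_sequence(ser, p)
  t2 <- track_sequence(ser, p)
  expect_identical(t1$positions, t2$positions)
  expect_identical(t1$index, t2$index)

  # rows 1..i do not depend on frames > i
  short <- ser$frames[1:6]
  t3 <- track_sequence(short, p)
  expect_equal(t3$positions, t1$positions[1:6, , , drop = FALSE])
})

test_that("modification swaps to an existing candidate and re-selects forward", {
  ser <- gen_model_series("none", seed = 3)
  p <- params_from_tuple(c(150, 5, 0, 0, 1, 14, 50, 3),
                         init = ser$truth[1, , ])
  tr <- track_sequence(ser, p)

  # re-choosing the already-selected candidate changes only provenance
  same <- modify_track(tr, 5, 2, tr$index[5, 2])
  expect_identical(same$positions, tr$positions)
  expect_equal(same$provenance[5, 2], "modified")

  # modifying frame 5 leaves frames 1..4 untouched
  alt <- which(seq_len(nrow(tr$candidates[[5]])) != tr$index[5, 2])[1]
  mod <- modify_track(tr, 5, 2, alt)
  expect_identical(mod$positions[1:4, , ], tr$positions[1:4, , ])
  expect_equal(mod$positions[5, 2, ],
               c(tr$candidates[[5]]$x[alt], tr$candidates[[5]]$y[alt]),
               ignore_attr = TRUE)
  # later frames are re-selected from the stored candidates
  for (i in 6:10) {
    for (k in 1:3) {
      cand <- tr$candidates[[i]]
      expect_true(any(abs(cand$x - mod$positions[i, k, 1]) < 1e-12 &
                        abs(cand$y - mod$positions[i, k, 2]) < 1e-12))
    }
  }
  expect_error(modify_track(tr, 5, 2, 999), "candidate")
})

test_that("motion decomposes into barycenter and exact zero-sum relative parts", {
  # two cells rotating rigidly about a fixed center
  th <- seq(0, 2 * pi, length.out = 8)
  pos <- array(NA_real_, dim = c(8, 2, 2))
  pos[, 1, ] <- cbind(5 + 3 * cos(th), 7 + 3 * sin(th))
  pos[, 2, ] <- cbind(5 - 3 * cos(th), 7 - 3 * sin(th))
  dec <- decompose_motion(pos)
  expect_lt(max(abs(sweep(dec$barycenter, 2, c(5, 7)))), 1e-12)
  expect_equal(sqrt(dec$relative[, 1, 1]^2 + dec$relative[, 1, 2]^2),
               rep(3, 8), tolerance = 1e-12)

  # pure translation: relative trajectories constant
  sh <- cbind(seq(0, 7), 2 * seq(0, 7))
  pos2 <- pos
  for (k in 1:2) pos2[, k, ] <- rep(c(10 * k, 5 * k), each = 8) + sh
  dec2 <- decompose_motion(pos2)
  expect_lt(max(abs(sweep(dec2$relative[, 1, , drop = FALSE], 3,
                          dec2$relative[1, 1, ]))), 1e-12)

  # recomposition is exact, zero-sum per frame
  ser <- gen_model_series("two", seed = 2)
  p <- params_from_tuple(c(150, 5, 0, 0, 1, 14, 50, 3),
                         init = ser$truth[1, , ])
  tr <- track_sequence(ser, p)
  dec3 <- decompose_motion(tr)
  rec <- sweep(dec3$relative, c(1, 3), dec3$barycenter, `+`)
  expect_lt(max(abs(rec - tr$positions)), 1e-12)
  expect_lt(max(abs(apply(dec3$relative, c(1, 3), sum))), 1e-12)
})

test_that("evaluation reports per-cell distances with mean and population std", {
  pos <- array(runif(10 * 3 * 2, 0, 100), dim = c(10, 3, 2))
  ev0 <- evaluate_track(pos, pos)
  expect_equal(ev0$mean, 0)
  expect_equal(ev0$std, 0)
  off <- pos; off[, , 1] <- off[, , 1] + 1
  ev1 <- evaluate_track(off, pos)
  expect_equal(ev1$mean, 1, tolerance = 1e-12)
  expect_equal(ev1$std, 0, tolerance = 1e-12)
  expect_equal(nrow(ev1$distances), 30)
  expect_error(evaluate_track(pos, pos[1:5, , ]), "same frame")
})
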