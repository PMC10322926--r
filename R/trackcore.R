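#' Tracking parameters
#'
#' @param n_cells Number N of cells to be tracked.
#' @param init N x 2 matrix of initial (x, y) points, one per cell; frame 1
#'   selections are the detected points nearest to these.
#' @param frame_stride Frame interval `>= 1`; frames are subsampled as
#'   `1, 1 + stride, 1 + 2 stride, ...` before tracking.
#' @return A `track_params` list.
#' @export
track_params <- function(n_cells, init, frame_stride = 1) {
  init <- as_points(init)
  if (n_cells < 1) stop("n_cells must be >= 1")
  if (nrow(init) != n_cells) stop("init must have one row per tracked cell")
  if (frame_stride < 1) stop("frame_stride must be >= 1")
  structure(list(n_cells = as.integer(n_cells), init = init,
                 frame_stride = as.integer(frame_stride)),
            class = "track_params")
}

#' Select the nearest detected point for each tracked cell
#'
#' For each cell independently, picks the detected point minimizing the
#' Euclidean distance from the cell's previous position. Ties are broken by
#' larger death, then lower candidate index. Two cells may select the same
#' point; such collisions are permitted but reported.
#'
#' @param prev N x 2 matrix of previous positions.
#' @param detected Data frame of detected points (needs columns `x`, `y`,
#'   `death`), e.g. from [detect_points()].
#' @return List with `positions` (N x 2), `index` (row of `detected` chosen
#'   per cell) and `collisions` (indices selected by more than one cell).
#' @export
select_points <- function(prev, detected) {
  prev <- as_points(prev)
  if (is.null(detected) || nrow(detected) == 0)
    stop("no detected points to select from")
  idx <- integer(nrow(prev))
  for (k in seq_len(nrow(prev))) {
    d2 <- (detected$x - prev[k, 1])^2 + (detected$y - prev[k, 2])^2
    m <- min(d2)
    cand <- which(d2 <= m + 1e-9)
    if (length(cand) > 1) cand <- cand[order(-detected$death[cand], cand)]
    idx[k] <- cand[1]
  }
  pos <- cbind(x = detected$x[idx], y = detected$y[idx])
  coll <- sort(unique(idx[duplicated(idx)]))
  list(positions = pos, index = idx, collisions = coll)
}

#' Track N cells through an image sequence
#'
#' Runs [detect_frame()] on every frame (after applying the frame stride)
#' and links detections by nearest-neighbour selection: frame 1 selections
#' are the detected points nearest the initial points; frame i selections
#' use the selections of frame i - 1. All per-frame detected points are
#' retained as candidates so that [modify_track()] can swap a selection for
#' an alternative detected point.
#'
#' @param frames List of grayscale matrices (or a `ph_model_series`).
#' @param params A [pipeline_params()] object including `track`
#'   ([track_params()]).
#' @return A `ph_track` object: list with `positions` (frames x N x 2
#'   array), `provenance` (frames x N, `"auto"`/`"modified"`),
#'   `candidates` (per-frame detection data frames), `index` (frames x N
#'   candidate rows), `collisions` (per-frame integer vectors), `params`,
#'   `frames_used`.
#' @export
track_sequence <- function(frames, params) {
  if (inherits(frames, "ph_model_series")) frames <- frames$frames
  tp <- params$track
  if (!inherits(tp, "track_params")) stop("params$track must be track_params()")
  used <- seq(1, length(frames), by = tp$frame_stride)
  if (length(used) < 1) stop("no frames to track after applying frame_stride")
  nf <- length(used)
  N <- tp$n_cells
  positions <- array(NA_real_, dim = c(nf, N, 2),
                     dimnames = list(NULL, NULL, c("x", "y")))
  provenance <- matrix("auto", nf, N)
  index <- matrix(NA_integer_, nf, N)
  candidates <- vector("list", nf)
  collisions <- vector("list", nf)
  prev <- tp$init
  for (i in seq_len(nf)) {
    det <- detect_frame(frames[[used[i]]], params)$detections
    if (nrow(det) == 0) {
      stop("no points detected in frame ", used[i],
           "; check that binarization (bin_thres) does not erase the cells, ",
           "then lower ph_thres / bd_thres")
    }
    sel <- select_points(prev, det)
    positions[i, , ] <- sel$positions
    index[i, ] <- sel$index
    candidates[[i]] <- det
    collisions[[i]] <- sel$collisions
    prev <- sel$positions
  }
  structure(list(positions = positions, provenance = provenance,
                 candidates = candidates, index = index,
                 collisions = collisions, params = params,
                 frames_used = used),
            class = "ph_track")
}

#' @export
print.ph_track <- function(x, ...) {
  cat("ph_track:", dim(x$positions)[1], "frames x", dim(x$positions)[2],
      "cells\n")
  nc <- sum(lengths(x$collisions) > 0)
  if (nc > 0) cat("  frames with selection collisions:", nc, "\n")
  nm <- sum(x$provenance == "modified")
  if (nm > 0) cat("  modified selections:", nm, "\n")
  invisible(x)
}

#' Replace one selection by an alternative detected point
#'
#' Sets the position of `cell` at `frame` to the `candidate_index`-th
#' detected point of that frame (never a free-hand coordinate), marks it
#' `"modified"`, and re-runs nearest-neighbour selection forward from the
#' modified frame — selection depends only on the previous frame, so all
#' later frames are recomputed from the retained candidates.
#'
#' @param t A `ph_track` from [track_sequence()].
#' @param frame Frame row to modify (after stride).
#' @param cell Cell index.
#' @param candidate_index Row of `t$candidates[[frame]]` to select instead.
#' @return The modified `ph_track`.
#' @export
modify_track <- function(t, frame, cell, candidate_index) {
  nf <- dim(t$positions)[1]
  N <- dim(t$positions)[2]
  if (frame < 1 || frame > nf) stop("frame out of range")
  if (cell < 1 || cell > N) stop("cell out of range")
  det <- t$candidates[[frame]]
  if (candidate_index < 1 || candidate_index > nrow(det))
    stop("candidate_index out of range; frame ", frame, " has ",
         nrow(det), " candidates at (",
         paste(sprintf("%.1f,%.1f", det$x, det$y), collapse = " "), ")")
  t$positions[frame, cell, ] <- c(det$x[candidate_index],
                                  det$y[candidate_index])
  t$index[frame, cell] <- candidate_index
  t$provenance[frame, cell] <- "modified"
  dup <- t$index[frame, ]
  t$collisions[[frame]] <- sort(unique(dup[duplicated(dup)]))
  if (frame < nf) {
    prev <- t$positions[frame, , , drop = TRUE]
    if (N == 1) prev <- matrix(prev, 1, 2)
    for (i in (frame + 1):nf) {
      sel <- select_points(prev, t$candidates[[i]])
      t$positions[i, , ] <- sel$positions
      t$index[i, ] <- sel$index
      t$provenance[i, ] <- "auto"
      t$collisions[[i]] <- sel$collisions
      prev <- sel$positions
    }
  }
  t
}

#' Split cell motion into barycenter motion and motion about the barycenter
#'
#' The barycenter trajectory is the per-frame mean of the N tracked
#' positions; relative trajectories are positions minus the barycenter, so
#' they sum to zero in every frame and recompose the original positions
#' exactly. Rotational motion of cells around each other is much easier to
#' see in the relative trajectories.
#'
#' @param t A `ph_track`, or a frames x N x 2 positions array.
#' @return List with `barycenter` (frames x 2) and `relative`
#'   (frames x N x 2).
#' @export
decompose_motion <- function(t) {
  pos <- if (inherits(t, "ph_track")) t$positions else t
  if (any(is.na(pos))) stop("positions must not contain missing values")
  bary <- apply(pos, c(1, 3), mean)
  rel <- sweep(pos, c(1, 3), bary)
  list(barycenter = bary, relative = rel)
}

#' Distance of tracked points to ground truth
#'
#' Per-cell per-frame Euclidean distances between tracked positions and true
#' centers, with their mean and population (divide-by-n) standard deviation.
#' Cell correspondence is fixed by initializing the track at the true
#' centers of frame 1.
#'
#' @param t A `ph_track` (or frames x N x 2 array).
#' @param truth A `ph_model_series` from [gen_model_series()], or a
#'   frames x N x 2 array of true centers.
#' @return List of class `ph_eval` with `distances` (data frame `frame`,
#'   `cell`, `distance`), `mean` and `std`.
#' @export
evaluate_track <- function(t, truth) {
  pos <- if (inherits(t, "ph_track")) t$positions else t
  tr <- if (inherits(truth, "ph_model_series")) truth$truth else truth
  if (!all(dim(pos) == dim(tr)))
    stop("track and truth must have the same frame and cell counts")
  d <- sqrt((pos[, , 1] - tr[, , 1])^2 + (pos[, , 2] - tr[, , 2])^2)
  d <- matrix(d, dim(pos)[1], dim(pos)[2])
  df <- data.frame(frame = rep(seq_len(nrow(d)), ncol(d)),
                   cell = rep(seq_len(ncol(d)), each = nrow(d)),
                   distance = as.vector(d))
  m <- mean(df$distance)
  s <- sqrt(mean((df$distance - m)^2))
  structure(list(distances = df, mean = m, std = s), class = "ph_eval")
}

#' @export
print.ph_eval <- function(x, ...) {
  cat(sprintf("tracking error: %.3f +/- %.3f px over %d distances\n",
              x$mean, x$std, nrow(x$distances)))
  invisible(x)
}
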