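#' Overcount-reduction parameters
#'
#' @param epsilon Boundary-noise allowance `>= 0`: the erasure disk of a
#'   candidate with death radius d has radius `(1 + epsilon) * d`, so a
#'   noisy boundary still gets fully claimed.
#' @param alpha Minimum novel-coverage fraction in `(0, 1)`: a candidate is
#'   kept only if it erases more than `alpha * pi * d^2` not-yet-claimed
#'   foreground pixels. Larger alpha tolerates less overlap between figures.
#' @return A `reduce_params` list.
#' @export
reduce_params <- function(epsilon = 0.3, alpha = 1 / 3) {
  if (!is.numeric(epsilon) || length(epsilon) != 1 || epsilon < 0)
    stop("epsilon must be a single value >= 0")
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha >= 1)
    stop("alpha must be a single value in (0, 1)")
  structure(list(epsilon = epsilon, alpha = alpha), class = "reduce_params")
}

#' Greedy disk-cover reduction of detected points
#'
#' Single-image counting produces overcounts (several H1 bars can be deep in
#' one distorted figure). Candidates are processed from the largest death
#' radius d downward: draw the disk of radius `(1 + epsilon) d` around the
#' candidate, count the currently white (not yet claimed) foreground pixels
#' it covers, erase them, and keep the candidate iff the erased count
#' exceeds `alpha * pi * d^2`. By default a discarded candidate's erasure is
#' rolled back so a rejected duplicate cannot shadow a later, smaller true
#' figure (`rollback = FALSE` keeps the erasure permanent).
#'
#' @param dets Data frame of detected points (`x`, `y`, `death`), e.g. from
#'   [detect_points()]; sorted internally by death (ties by position).
#' @param bin Logical foreground mask of the same image.
#' @param p A [reduce_params()] object.
#' @param rollback Whether a discarded candidate's erasure is undone.
#' @return The kept rows of `dets`, in processing (death-descending) order,
#'   with an added column `covered` (novel foreground pixels claimed).
#' @export
reduce_points <- function(dets, bin, p = reduce_params(), rollback = TRUE) {
  check_binary(bin)
  if (!inherits(p, "reduce_params")) p <- do.call(reduce_params, p)
  if (is.null(dets) || nrow(dets) == 0) {
    dets$covered <- numeric(0)
    return(dets)
  }
  ord <- order(-dets$death, dets$x, dets$y)
  dets <- dets[ord, , drop = FALSE]
  nr <- nrow(bin); nc <- ncol(bin)
  mask <- bin
  keep <- logical(nrow(dets))
  covered <- numeric(nrow(dets))
  for (i in seq_len(nrow(dets))) {
    d <- dets$death[i]
    rad <- (1 + p$epsilon) * d
    cx <- dets$x[i]; cy <- dets$y[i]
    c1 <- max(1L, floor(cx - rad)); c2 <- min(nc, ceiling(cx + rad))
    r1 <- max(1L, floor(cy - rad)); r2 <- min(nr, ceiling(cy + rad))
    if (c1 > c2 || r1 > r2) next
    rows <- r1:r2; cols <- c1:c2
    sub <- mask[rows, cols, drop = FALSE]
    disk <- outer((rows - cy)^2, (cols - cx)^2, `+`) <= rad^2
    hit <- sub & disk
    cnt <- sum(hit)
    covered[i] <- cnt
    ok <- cnt > p$alpha * pi * d^2
    keep[i] <- ok
    if (ok || !rollback) {
      sub[hit] <- FALSE
      mask[rows, cols] <- sub
    }
  }
  out <- dets[keep, , drop = FALSE]
  out$covered <- covered[keep]
  rownames(out) <- NULL
  out
}
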