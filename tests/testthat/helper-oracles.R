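# Independent brute-force oracles used to check the implementation.

# Cech persistence of the full 2-skeleton: every pair at its diametral
# radius, every triple at its minimum-enclosing-ball radius, reduced with a
# plain R boundary-matrix reduction. H1 of the Cech filtration equals H1 of
# the alpha filtration (both are nerves of the same union of balls), so this
# is a complete independent oracle for compute_ph1 on small clouds.
cech_ph1_oracle <- function(pts) {
  pts <- unique(as.matrix(pts))
  n <- nrow(pts)
  if (n < 3) return(data.frame(birth = numeric(0), death = numeric(0)))
  E <- t(combn(n, 2))
  Tm <- t(combn(n, 3))
  ev <- sqrt((pts[E[, 1], 1] - pts[E[, 2], 1])^2 +
               (pts[E[, 1], 2] - pts[E[, 2], 2])^2) / 2
  menc <- function(a, b, c) { # min enclosing ball radius of a triangle
    d2 <- c(sum((a - b)^2), sum((b - c)^2), sum((a - c)^2))
    mx <- max(d2)
    if (mx >= sum(d2) - mx) return(sqrt(mx) / 2) # obtuse: half longest edge
    dd <- 2 * (a[1] * (b[2] - c[2]) + b[1] * (c[2] - a[2]) +
                 c[1] * (a[2] - b[2]))
    ux <- (sum(a^2) * (b[2] - c[2]) + sum(b^2) * (c[2] - a[2]) +
             sum(c^2) * (a[2] - b[2])) / dd
    uy <- (sum(a^2) * (c[1] - b[1]) + sum(b^2) * (a[1] - c[1]) +
             sum(c^2) * (b[1] - a[1])) / dd
    sqrt((ux - a[1])^2 + (uy - a[2])^2)
  }
  tv <- vapply(seq_len(nrow(Tm)), function(i)
    menc(pts[Tm[i, 1], ], pts[Tm[i, 2], ], pts[Tm[i, 3], ]), numeric(1))
  val <- c(rep(0, n), ev, tv)
  dm <- c(rep(0L, n), rep(1L, nrow(E)), rep(2L, nrow(Tm)))
  ord <- order(val, dm)
  pos <- integer(length(val))
  pos[ord] <- seq_along(ord)
  ekey <- paste(E[, 1], E[, 2])
  bnd <- vector("list", length(val))
  for (i in seq_len(n)) bnd[[pos[i]]] <- integer(0)
  for (j in seq_len(nrow(E))) bnd[[pos[n + j]]] <- sort(pos[E[j, ]])
  for (t in seq_len(nrow(Tm))) {
    e3 <- match(c(paste(Tm[t, 1], Tm[t, 2]), paste(Tm[t, 2], Tm[t, 3]),
                  paste(Tm[t, 1], Tm[t, 3])), ekey)
    bnd[[pos[n + nrow(E) + t]]] <- sort(pos[n + e3])
  }
  # plain R reduction
  m <- length(bnd)
  owner <- rep(NA_integer_, m)
  pairs <- matrix(integer(0), 0, 2)
  for (j in seq_len(m)) {
    col <- bnd[[j]]
    while (length(col) > 0 && !is.na(owner[col[length(col)]])) {
      k <- owner[col[length(col)]]
      col <- sort(union(setdiff(col, bnd[[k]]), setdiff(bnd[[k]], col)))
    }
    bnd[[j]] <- col
    if (length(col) > 0) {
      owner[col[length(col)]] <- j
      pairs <- rbind(pairs, c(col[length(col)], j))
    }
  }
  bdim <- dm[ord[pairs[, 1]]]
  ddim <- dm[ord[pairs[, 2]]]
  keep <- bdim == 1L & ddim == 2L
  out <- data.frame(birth = val[ord[pairs[keep, 1]]],
                    death = val[ord[pairs[keep, 2]]])
  # same zero-length cutoff as the implementation, so both sides discard
  # the numerically-zero bars of near-degenerate configurations
  out <- out[out$death - out$birth > 1e-6 * pmax(1, out$death), , drop = FALSE]
  out[order(out$birth, out$death), , drop = FALSE]
}

# boundary pixels by definition: foreground pixel with a background (or
# out-of-image) 8-neighbour
brute_boundary_pixels <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  out <- NULL
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      if (!mask[i, j]) next
      edge <- FALSE
      for (di in -1:1) for (dj in -1:1) {
        ii <- i + di; jj <- j + dj
        if (ii < 1 || ii > nr || jj < 1 || jj > nc || !mask[ii, jj])
          edge <- TRUE
      }
      if (edge) out <- rbind(out, c(j, i)) # (x, y)
    }
  }
  out
}

# white count in the (2r+1)^2 Chebyshev window, direct loops
brute_window_counts <- function(mask, r) {
  nr <- nrow(mask); nc <- ncol(mask)
  cnt <- matrix(0L, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      rows <- max(1, i - r):min(nr, i + r)
      cols <- max(1, j - r):min(nc, j + r)
      cnt[i, j] <- sum(mask[rows, cols])
    }
  }
  cnt
}

# independent 8-connected component count (BFS in plain R)
count_components8 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  seen <- matrix(FALSE, nr, nc)
  n <- 0
  for (i0 in seq_len(nr)) for (j0 in seq_len(nc)) {
    if (!mask[i0, j0] || seen[i0, j0]) next
    n <- n + 1
    stack <- list(c(i0, j0)); seen[i0, j0] <- TRUE
    while (length(stack) > 0) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      for (di in -1:1) for (dj in -1:1) {
        ii <- p[1] + di; jj <- p[2] + dj
        if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc &&
            mask[ii, jj] && !seen[ii, jj]) {
          seen[ii, jj] <- TRUE
          stack[[length(stack) + 1]] <- c(ii, jj)
        }
      }
    }
  }
  n
}

disk_mask <- function(size, cx, cy, r) {
  outer((seq_len(size[1]) - cy)^2, (seq_len(size[2]) - cx)^2, `+`) <= r^2
}

circle_cloud <- function(cx, cy, r, m = 100) {
  th <- seq(0, 2 * pi, length.out = m + 1)[-(m + 1)]
  cbind(cx + r * cos(th), cy + r * sin(th))
}

make_tempdir <- function() {
  d <- tempfile("phtrack_test_")
  dir.create(d)
  d
}
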