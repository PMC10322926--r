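#' Detection thresholds for persistent-homological figure detection
#'
#' @param ph_thres Minimum internal radius, in pixels, of the figures to
#'   detect: only H1 classes whose death radius is at least `ph_thres`
#'   become detected points.
#' @param bd_thres Minimum contour length (boundary pixel count); shorter
#'   contours are discarded before persistence is computed, so that too
#'   small figures are ignored.
#' @return A `detect_params` list.
#' @export
detect_params <- function(ph_thres, bd_thres = 0) {
  if (!is.numeric(ph_thres) || length(ph_thres) != 1 || ph_thres < 0)
    stop("ph_thres must be a single value >= 0")
  if (!is.numeric(bd_thres) || length(bd_thres) != 1 || bd_thres < 0)
    stop("bd_thres must be a single value >= 0")
  structure(list(ph_thres = ph_thres, bd_thres = bd_thres),
            class = "detect_params")
}

#' Extract outer contours of foreground components
#'
#' One contour per 8-connected foreground component: the component pixels
#' that have an outside-background (or out-of-image) 8-neighbour, where
#' "outside" is the background region connected to the image border.
#' Boundaries of interior holes are therefore ignored. Points are returned
#' in circular order (by angle about the component centroid).
#'
#' @param bin Logical foreground mask.
#' @return List of n x 2 matrices of (x, y) pixel coordinates; the contour
#'   length used by [filter_contours()] is the number of rows.
#' @export
extract_contours <- function(bin) {
  check_binary(bin)
  nr <- nrow(bin); nc <- ncol(bin)
  lab <- cpp_label8(bin)
  if (max(lab) == 0) return(list())
  # out-of-image counts as outside background: pad with TRUE
  P <- matrix(TRUE, nr + 2, nc + 2)
  P[2:(nr + 1), 2:(nc + 1)] <- cpp_outside_background(bin)
  touch <- matrix(FALSE, nr, nc)
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    touch <- touch | P[2:(nr + 1) + di, 2:(nc + 1) + dj]
  }
  boundary <- bin & touch
  idx <- which(boundary)
  comp <- lab[idx]
  ys <- ((idx - 1) %% nr) + 1
  xs <- ((idx - 1) %/% nr) + 1
  lapply(seq_len(max(lab)), function(l) {
    sel <- comp == l
    x <- xs[sel]; y <- ys[sel]
    ang <- atan2(y - mean(y), x - mean(x))
    o <- order(ang, (x - mean(x))^2 + (y - mean(y))^2)
    cbind(x = as.double(x[o]), y = as.double(y[o]))
  })
}

#' Drop contours shorter than a boundary-length threshold
#'
#' @param cs List of contours from [extract_contours()].
#' @param bd_thres Minimum number of boundary points.
#' @return The contours with `length >= bd_thres`, order preserved.
#' @export
filter_contours <- function(cs, bd_thres) {
  cs[vapply(cs, nrow, integer(1)) >= bd_thres]
}

#' Pool contours into one point cloud
#'
#' All retained contours of a frame are pooled into a single cloud (with
#' duplicate pixels removed) before persistence is computed, so overlapping
#' figures sharing one contour and multi-component frames are handled
#' uniformly.
#'
#' @param cs List of contours.
#' @return n x 2 matrix of unique (x, y) points.
#' @export
pool_contours <- function(cs) {
  if (length(cs) == 0) return(matrix(numeric(0), 0, 2,
                                     dimnames = list(NULL, c("x", "y"))))
  unique(do.call(rbind, cs))
}

# vectorized circumcircle of triangles given as three n x 2 matrices;
# returns centers, radii and a degeneracy flag (twice the signed area below
# 1e-9 of the max pairwise squared distance)
tri_circum <- function(a, b, c) {
  d <- 2 * (a[, 1] * (b[, 2] - c[, 2]) + b[, 1] * (c[, 2] - a[, 2]) +
              c[, 1] * (a[, 2] - b[, 2]))
  m2 <- pmax((a[, 1] - b[, 1])^2 + (a[, 2] - b[, 2])^2,
             (b[, 1] - c[, 1])^2 + (b[, 2] - c[, 2])^2,
             (a[, 1] - c[, 1])^2 + (a[, 2] - c[, 2])^2)
  degen <- abs(d) < 1e-9 * m2
  sa <- a[, 1]^2 + a[, 2]^2
  sb <- b[, 1]^2 + b[, 2]^2
  sc <- c[, 1]^2 + c[, 2]^2
  ux <- (sa * (b[, 2] - c[, 2]) + sb * (c[, 2] - a[, 2]) +
           sc * (a[, 2] - b[, 2])) / d
  uy <- (sa * (c[, 1] - b[, 1]) + sb * (a[, 1] - c[, 1]) +
           sc * (b[, 1] - a[, 1])) / d
  bx <- (a[, 1] + b[, 1] + c[, 1]) / 3
  by <- (a[, 2] + b[, 2] + c[, 2]) / 3
  ux[degen] <- bx[degen]
  uy[degen] <- by[degen]
  r <- sqrt((ux - a[, 1])^2 + (uy - a[, 2])^2)
  list(cx = ux, cy = uy, r = r, degenerate = degen)
}

#' Circumcenter of a triangle
#'
#' The point equidistant from `a`, `b` and `c`; for three points sampled on
#' a circle this is the circle's centre, which is why detections are plotted
#' there. A degenerate (near-collinear) triangle falls back to the
#' barycenter; the result then carries the attribute `degenerate = TRUE`.
#'
#' @param a,b,c Length-2 numeric vectors (x, y).
#' @return Length-2 numeric vector, with attribute `degenerate`.
#' @examples
#' circumcenter(c(0, 0), c(2, 0), c(0, 2)) # (1, 1)
#' @export
circumcenter <- function(a, b, c) {
  cc <- tri_circum(matrix(a, 1), matrix(b, 1), matrix(c, 1))
  structure(c(cc$cx, cc$cy), degenerate = cc$degenerate)
}

#' H1 persistence of a planar point cloud under the alpha filtration
#'
#' Builds the alpha complex on the Delaunay triangulation of the cloud
#' (edge value: its diametral radius if the edge is Gabriel, otherwise the
#' smallest circumradius among the incident Delaunay triangles whose
#' opposite vertex lies inside the diametral circle; triangle value: its
#' circumradius) and reduces the boundary matrix. Births and deaths are in
#' pixel-radius units. Each bar carries the death simplex: the triangle
#' whose insertion fills the cycle, so its circumradius equals the death
#' value.
#'
#' @param cloud n x 2 matrix of (x, y) points; duplicates are removed.
#' @return Data frame with one row per finite H1 bar, sorted by death
#'   descending (ties: birth ascending, then death-simplex coordinates):
#'   columns `birth`, `death`, vertex indices `i1, i2, i3` into the
#'   deduplicated cloud, coordinates `x1, y1, ..., y3` of the death
#'   triangle, and `degenerate` (circumcenter fallback flag). The
#'   deduplicated cloud is attached as attribute `"cloud"`.
#' @export
compute_ph1 <- function(cloud) {
  empty <- data.frame(birth = numeric(0), death = numeric(0),
                      i1 = integer(0), i2 = integer(0), i3 = integer(0),
                      x1 = numeric(0), y1 = numeric(0), x2 = numeric(0),
                      y2 = numeric(0), x3 = numeric(0), y3 = numeric(0),
                      degenerate = logical(0))
  cloud <- unique(as_points(cloud))
  attr(empty, "cloud") <- cloud
  n <- nrow(cloud)
  if (n < 3) return(empty)
  # the Delaunay triangulation does not depend on the bounding window, but
  # deldir's Voronoi construction can fail numerically on degenerate
  # integer-grid clouds with the default window; retry with wider ones
  try_deldir <- function(margin) {
    rw <- if (is.null(margin)) NULL else
      c(min(cloud[, 1]) - margin, max(cloud[, 1]) + margin,
        min(cloud[, 2]) - margin, max(cloud[, 2]) + margin)
    tryCatch(
      suppressMessages(
        if (is.null(rw)) deldir::deldir(cloud[, 1], cloud[, 2])
        else deldir::deldir(cloud[, 1], cloud[, 2], rw = rw)),
      error = function(e) NULL)
  }
  extent <- max(diff(range(cloud[, 1])), diff(range(cloud[, 2])), 1)
  dd <- try_deldir(NULL)
  if (is.null(dd)) dd <- try_deldir(extent)
  if (is.null(dd)) dd <- try_deldir(10 * extent)
  if (is.null(dd)) {
    # last resort: a deterministic sub-numerical jitter to break the
    # degeneracy (displaces every value by far less than any tolerance)
    cloud <- cloud + with_seed(0, matrix(runif(2 * n, -1e-4, 1e-4), n, 2))
    dd <- try_deldir(extent)
  }
  if (is.null(dd)) return(empty)
  tm <- tryCatch(deldir::triMat(dd), error = function(e) NULL)
  if (is.null(tm) || nrow(tm) == 0) return(empty)
  attr(empty, "cloud") <- cloud

  A <- cloud[tm[, 1], , drop = FALSE]
  B <- cloud[tm[, 2], , drop = FALSE]
  C <- cloud[tm[, 3], , drop = FALSE]
  tc <- tri_circum(A, B, C)
  r_tri <- tc$r
  nt <- nrow(tm)

  # unique edges of the triangulation and the triangle -> edge incidence
  ep <- rbind(cbind(tm[, 1], tm[, 2], tm[, 3]),
              cbind(tm[, 2], tm[, 3], tm[, 1]),
              cbind(tm[, 1], tm[, 3], tm[, 2]))
  e1 <- pmin(ep[, 1], ep[, 2])
  e2 <- pmax(ep[, 1], ep[, 2])
  opp <- ep[, 3]
  key <- paste(e1, e2)
  uk <- !duplicated(key)
  eid <- match(key, key[uk])
  ev1 <- e1[uk]; ev2 <- e2[uk]
  ne <- sum(uk)

  mx <- (cloud[ev1, 1] + cloud[ev2, 1]) / 2
  my <- (cloud[ev1, 2] + cloud[ev2, 2]) / 2
  r_e <- sqrt((cloud[ev1, 1] - cloud[ev2, 1])^2 +
                (cloud[ev1, 2] - cloud[ev2, 2])^2) / 2

  # Gabriel test per incidence: opposite vertex strictly inside the
  # diametral circle of the edge
  d_opp2 <- (cloud[opp, 1] - mx[eid])^2 + (cloud[opp, 2] - my[eid])^2
  viol <- d_opp2 < r_e[eid]^2 * (1 - 1e-12)
  v_tri <- rep(r_tri, 3)
  e_val <- r_e
  if (any(viol)) {
    # a non-Gabriel edge does not enter at its diametral radius: it is
    # delayed to the smallest circumradius among the incident triangles
    # whose opposite vertex witnesses the violation
    adj <- tapply(v_tri[viol], eid[viol], min)
    idx <- as.integer(names(adj))
    e_val[idx] <- as.numeric(adj)
  }

  # filtration order: value, then dimension, then construction index
  val <- c(rep(0, n), e_val, r_tri)
  dm <- c(rep(0L, n), rep(1L, ne), rep(2L, nt))
  ord <- order(val, dm)
  pos <- integer(n + ne + nt)
  pos[ord] <- seq_along(ord)

  bnd <- vector("list", length(ord))
  for (i in seq_len(n)) bnd[[pos[i]]] <- integer(0)
  for (j in seq_len(ne)) {
    bnd[[pos[n + j]]] <- sort(c(pos[ev1[j]], pos[ev2[j]]))
  }
  te <- matrix(eid, nrow = nt) # columns: edges (1,2), (2,3), (1,3)
  for (t in seq_len(nt)) {
    bnd[[pos[n + ne + t]]] <- sort(pos[n + te[t, ]])
  }

  pr <- cpp_reduce_boundary(bnd)
  if (nrow(pr) == 0) return(empty)
  bdim <- dm[ord[pr[, 1]]]
  ddim <- dm[ord[pr[, 2]]]
  keep <- bdim == 1L & ddim == 2L
  if (!any(keep)) return(empty)
  birth <- val[ord[pr[keep, 1]]]
  death <- val[ord[pr[keep, 2]]]
  tri_id <- ord[pr[keep, 2]] - (n + ne)
  # drop zero-length bars, at a relative tolerance: near-cocircular point
  # sets (digitized circles) produce edge/triangle value ties that differ
  # only by floating-point round-off
  pos_len <- death - birth > 1e-6 * pmax(1, death)
  birth <- birth[pos_len]; death <- death[pos_len]
  tri_id <- tri_id[pos_len]
  if (length(birth) == 0) return(empty)

  vs <- tm[tri_id, , drop = FALSE]
  bars <- data.frame(
    birth = birth, death = death,
    i1 = vs[, 1], i2 = vs[, 2], i3 = vs[, 3],
    x1 = cloud[vs[, 1], 1], y1 = cloud[vs[, 1], 2],
    x2 = cloud[vs[, 2], 1], y2 = cloud[vs[, 2], 2],
    x3 = cloud[vs[, 3], 1], y3 = cloud[vs[, 3], 2],
    degenerate = tc$degenerate[tri_id])
  o <- order(-bars$death, bars$birth,
             bars$x1, bars$y1, bars$x2, bars$y2, bars$x3, bars$y3)
  bars <- bars[o, , drop = FALSE]
  rownames(bars) <- NULL
  attr(bars, "cloud") <- cloud
  bars
}

#' Turn persistence bars into detected points
#'
#' Keeps the bars whose death radius is at least `p$ph_thres` (the minimum
#' internal radius of the figures to detect) and places one detected point
#' per bar at the circumcenter of its death triangle, mapped back to
#' original-image coordinates through [inverse_transform_points()].
#'
#' @param bars Output of [compute_ph1()] on the (transformed) contour cloud.
#' @param p A [detect_params()] object.
#' @param t The [transform_params()] the cloud was transformed with
#'   (identity by default).
#' @param center Transformation centre used, typically [image_center()].
#' @param center_method `"circumcenter"` (default) or `"barycenter"` (the
#'   legacy plotting rule, kept for comparison; it can land far from the
#'   centre of a circular figure).
#' @return Data frame sorted by death descending (ties: birth ascending,
#'   then death-simplex coordinates) with columns `x`, `y`, `death`,
#'   `birth`, the death-triangle coordinates, and `degenerate`.
#' @export
detect_points <- function(bars, p, t = transform_params(),
                          center = c(0, 0),
                          center_method = c("circumcenter", "barycenter")) {
  center_method <- match.arg(center_method)
  if (!inherits(p, "detect_params")) p <- do.call(detect_params, p)
  keep <- bars[bars$death >= p$ph_thres, , drop = FALSE]
  if (nrow(keep) == 0) {
    out <- data.frame(x = numeric(0), y = numeric(0), death = numeric(0),
                      birth = numeric(0), x1 = numeric(0), y1 = numeric(0),
                      x2 = numeric(0), y2 = numeric(0), x3 = numeric(0),
                      y3 = numeric(0), degenerate = logical(0))
    return(out)
  }
  if (center_method == "circumcenter") {
    cc <- tri_circum(cbind(keep$x1, keep$y1), cbind(keep$x2, keep$y2),
                     cbind(keep$x3, keep$y3))
    pos <- cbind(cc$cx, cc$cy)
    degen <- cc$degenerate
  } else {
    pos <- cbind((keep$x1 + keep$x2 + keep$x3) / 3,
                 (keep$y1 + keep$y2 + keep$y3) / 3)
    degen <- rep(FALSE, nrow(keep))
  }
  pos <- inverse_transform_points(pos, t, center)
  out <- data.frame(x = pos[, 1], y = pos[, 2],
                    death = keep$death, birth = keep$birth,
                    x1 = keep$x1, y1 = keep$y1, x2 = keep$x2, y2 = keep$y2,
                    x3 = keep$x3, y3 = keep$y3, degenerate = degen)
  rownames(out) <- NULL
  out
}

#' Detect figures in one grayscale frame
#'
#' The full single-frame pipeline: binarize, erase sparse white pixels,
#' extract and filter contours, pool them into one point cloud, transform,
#' compute H1 persistence, and plot detections at death-triangle
#' circumcenters in original-image coordinates.
#'
#' Because all retained contours are pooled into one cloud, frames with
#' several well-separated components also produce H1 classes that encircle
#' the *background* between components; their death triangles span different
#' contours and their circumcenters land on background. With
#' `require_foreground = TRUE` (the default) detections whose position has
#' no foreground pixel in its 3x3 neighbourhood of the cleaned mask are
#' dropped — a figure's centre always lies inside the figure.
#'
#' @param img Grayscale matrix with values in `[0, 255]`.
#' @param params A [pipeline_params()] object (or compatible list).
#' @param require_foreground Drop detections positioned on background.
#' @return List with elements `detections` (see [detect_points()]), `bars`,
#'   `contours` (after length filtering), and `bin` (the cleaned mask).
#' @export
detect_frame <- function(img, params, require_foreground = TRUE) {
  check_gray(img)
  bin <- binarize(img, params$bin)
  bin <- erase_sparse_white(bin, params$cleanup)
  cs <- extract_contours(bin)
  cs <- filter_contours(cs, params$detect$bd_thres)
  cloud <- pool_contours(cs)
  ctr <- image_center(img)
  tcloud <- transform_points(cloud, params$transform, ctr)
  bars <- compute_ph1(tcloud)
  dets <- detect_points(bars, params$detect, params$transform, ctr,
                        center_method = params$center_method %||% "circumcenter")
  if (require_foreground && nrow(dets) > 0) {
    keep <- vapply(seq_len(nrow(dets)), function(i) {
      r <- round(dets$y[i]); c <- round(dets$x[i])
      if (r < 1 || r > nrow(bin) || c < 1 || c > ncol(bin)) return(FALSE)
      any(bin[max(1, r - 1):min(nrow(bin), r + 1),
              max(1, c - 1):min(ncol(bin), c + 1)])
    }, logical(1))
    dets <- dets[keep, , drop = FALSE]
    rownames(dets) <- NULL
  }
  list(detections = dets, bars = bars, contours = cs, bin = bin)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Count bars alive at a filtration value
#'
#' The number of H1 bars with `birth <= t < death`. Counting sure-foreground
#' components after eroding the mask to distance `t` from the background is
#' equivalent to drawing a vertical line at `t` on the barcode and counting
#' intersections; figure detection instead counts all bars with
#' `death >= ph_thres`, so it retains strictly more information.
#'
#' @param bars Output of [compute_ph1()].
#' @param t Filtration value (pixel radius), `>= 0`.
#' @return Integer count.
#' @export
sure_foreground_count <- function(bars, t) {
  if (t < 0) stop("t must be >= 0")
  sum(bars$birth <= t & t < bars$death)
}

#' Sure-foreground component counts over an erosion sweep
#'
#' Erodes the mask by thresholding its Euclidean distance transform at every
#' distance in a grid and counts the remaining 8-connected components: the
#' brute-force image-side counterpart of [sure_foreground_count()]. Used to
#' exhibit configurations of overlapping figures where no single erosion
#' distance recovers all figures while persistence detection does.
#'
#' @param bin Logical foreground mask.
#' @param step Sweep step in pixels.
#' @return Data frame with columns `t` and `components`.
#' @export
erosion_sweep_components <- function(bin, step = 0.5) {
  check_binary(bin)
  dm <- EBImage::distmap(matrix(as.numeric(bin), nrow(bin), ncol(bin)))
  dm <- matrix(as.numeric(dm), nrow(bin), ncol(bin))
  ts <- seq(0, max(dm), by = step)
  comps <- vapply(ts, function(t) {
    lab <- cpp_label8(dm > t)
    max(lab)
  }, numeric(1))
  data.frame(t = ts, components = as.integer(comps))
}
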