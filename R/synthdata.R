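# Seeded generators for ground-truth model series, overlapping-figure
# chains, and scattered-nuclei count images.

render_disks <- function(centers, radius, size, fg, bg) {
  img <- matrix(bg, size[1], size[2])
  for (k in seq_len(nrow(centers))) {
    cx <- centers[k, 1]; cy <- centers[k, 2]
    c1 <- max(1L, floor(cx - radius)); c2 <- min(size[2], ceiling(cx + radius))
    r1 <- max(1L, floor(cy - radius)); r2 <- min(size[1], ceiling(cy + radius))
    rows <- r1:r2; cols <- c1:c2
    inside <- outer((rows - cy)^2, (cols - cx)^2, `+`) <= radius^2
    sub <- img[rows, cols, drop = FALSE]
    sub[inside] <- fg
    img[rows, cols] <- sub
  }
  img
}

pairwise_dists <- function(centers) {
  as.vector(stats::dist(centers))
}

#' Generate a ground-truth model time series of moving disk cells
#'
#' Renders dark disk-shaped cells of a fixed radius on a light background
#' and records their true (sub-pixel) centers, the ground truth for
#' tracking. The three regimes reproduce the study conditions: `"none"` —
#' no two cells ever overlap; `"two"` — two cells overlap in some frames
#' while the third stays clear; `"three"` — all three cells mutually overlap
#' in the middle of the series. Per-frame displacements never exceed
#' `step_px`.
#'
#' @param regime `"none"`, `"two"` or `"three"` (maximum number of cells
#'   overlapping each other).
#' @param n_frames Number of frames.
#' @param n_cells Number of cells (the overlap regimes are defined for 3).
#' @param radius Disk radius in pixels.
#' @param step_px Maximum per-frame displacement of a cell centre.
#' @param seed RNG seed; the generator is a pure function of its arguments.
#' @param size Image size `c(rows, cols)`.
#' @param fg,bg Disk and background intensities (contrast >= 100).
#' @return A `ph_model_series`: list with `frames` (list of matrices),
#'   `truth` (frames x cells x 2 array of (x, y) centers), `radius`,
#'   `regime`, `seed`, `size`.
#' @export
gen_model_series <- function(regime = c("none", "two", "three"),
                             n_frames = 10, n_cells = 3, radius = 16,
                             step_px = 6, seed = 1, size = c(256, 256),
                             fg = 30, bg = 220) {
  regime <- match.arg(regime)
  stopifnot(radius >= 4, step_px < radius, n_frames >= 1)
  if (regime != "none" && n_cells != 3)
    stop("overlap regimes are defined for 3 cells")
  if (abs(fg - bg) < 100) stop("fg/bg contrast must be at least 100")
  margin <- radius + 3
  lo <- margin; hix <- size[2] - margin; hiy <- size[1] - margin
  truth <- with_seed(seed, {
    tr <- array(NA_real_, dim = c(n_frames, n_cells, 2))
    if (regime == "none") {
      base <- rbind(c(0.25, 0.3), c(0.75, 0.3), c(0.5, 0.75))
      if (n_cells > 3) {
        gx <- ceiling(sqrt(n_cells))
        base <- as.matrix(expand.grid(
          x = seq(0.2, 0.8, length.out = gx),
          y = seq(0.2, 0.8, length.out = gx)))[seq_len(n_cells), ]
      }
      cur <- cbind(lo + base[, 1] * (hix - lo), lo + base[, 2] * (hiy - lo))
      cur <- cur + matrix(runif(2 * n_cells, -4, 4), n_cells, 2)
      theta <- runif(n_cells, 0, 2 * pi)
      tr[1, , ] <- cur
      for (i in seq_len(n_frames - 1)) {
        for (k in seq_len(n_cells)) {
          ok <- FALSE
          for (try in 1:80) {
            th <- theta[k] + runif(1, -0.7, 0.7)
            if (try > 30) th <- runif(1, 0, 2 * pi)
            st <- step_px * runif(1, 0.5, 0.98)
            cand <- cur[k, ] + st * c(cos(th), sin(th))
            others <- cur[-k, , drop = FALSE]
            if (cand[1] >= lo && cand[1] <= hix &&
                cand[2] >= lo && cand[2] <= hiy &&
                (nrow(others) == 0 ||
                 min(sqrt(rowSums(sweep(others, 2, cand)^2))) >
                   2 * radius + 2)) {
              cur[k, ] <- cand; theta[k] <- th; ok <- TRUE; break
            }
          }
          if (!ok) theta[k] <- runif(1, 0, 2 * pi) # stay put this frame
        }
        tr[i + 1, , ] <- cur
      }
    } else if (regime == "two") {
      # cells 1 and 2 approach along a slowly turning axis, overlap mid
      # series, and separate again; cell 3 wanders far away
      half_amp <- min(11, 0.9 * step_px * max(n_frames - 1, 1) / 4)
      u <- if (n_frames == 1) 0 else 2 * (seq_len(n_frames) - 1) / (n_frames - 1) - 1
      d <- (2 * radius - 10) + 2 * half_amp * u^2
      phi0 <- runif(1, 0, 2 * pi)
      phi <- phi0 + cumsum(c(0, runif(n_frames - 1, -0.12, 0.12)))
      m0 <- c(size[2] / 2, size[1] * 0.38)
      mj <- rbind(c(0, 0), matrix(runif(2 * (n_frames - 1), -0.6, 0.6),
                                  ncol = 2))
      m <- sweep(apply(mj, 2, cumsum), 2, m0, `+`)
      if (n_frames == 1) m <- matrix(m0, 1, 2)
      tr[, 1, ] <- m - d / 2 * cbind(cos(phi), sin(phi))
      tr[, 2, ] <- m + d / 2 * cbind(cos(phi), sin(phi))
      c3 <- c(size[2] / 2, size[1] - margin - 10)
      th3 <- runif(1, 0, 2 * pi)
      tr[1, 3, ] <- c3
      for (i in seq_len(n_frames - 1)) {
        for (try in 1:80) {
          th <- th3 + runif(1, -0.7, 0.7)
          st <- step_px * runif(1, 0.3, 0.8)
          cand <- c3 + st * c(cos(th), sin(th))
          if (cand[1] >= lo && cand[1] <= hix &&
              cand[2] >= lo && cand[2] <= hiy &&
              min(sqrt((tr[i + 1, 1:2, 1] - cand[1])^2 +
                       (tr[i + 1, 1:2, 2] - cand[2])^2)) > 2 * radius + 4) {
            c3 <- cand; th3 <- th; break
          }
        }
        tr[i + 1, 3, ] <- c3
      }
    } else {
      # three cells around a drifting centroid contract until all pairwise
      # distances drop below 2 * radius, then expand back
      rho_min <- 13.5 * radius / 16
      rho_max <- rho_min + min(11.5, 0.85 * step_px * max(n_frames - 1, 1) / 4)
      u <- if (n_frames == 1) 0 else 2 * (seq_len(n_frames) - 1) / (n_frames - 1) - 1
      rho <- rho_min + (rho_max - rho_min) * u^2
      psi0 <- runif(1, 0, 2 * pi)
      psi <- psi0 + cumsum(c(0, runif(n_frames - 1, -0.05, 0.05)))
      g0 <- c(size[2] / 2, size[1] / 2)
      gj <- rbind(c(0, 0), matrix(runif(2 * (n_frames - 1), -0.5, 0.5),
                                  ncol = 2))
      g <- sweep(apply(gj, 2, cumsum), 2, g0, `+`)
      if (n_frames == 1) g <- matrix(g0, 1, 2)
      for (k in 1:3) {
        ang <- psi + (k - 1) * 2 * pi / 3
        tr[, k, ] <- g + rho * cbind(cos(ang), sin(ang))
      }
    }
    tr
  })
  # programme checks of the regime invariants and the step bound
  for (i in seq_len(n_frames)) {
    pd <- pairwise_dists(truth[i, , ])
    if (regime == "none" && any(pd <= 2 * radius))
      stop("regime 'none' violated at frame ", i)
    if (regime == "two" && all(pd < 2 * radius))
      stop("regime 'two' produced a triple overlap at frame ", i)
  }
  if (n_frames > 1) {
    disp <- sqrt((truth[-1, , 1] - truth[-n_frames, , 1])^2 +
                   (truth[-1, , 2] - truth[-n_frames, , 2])^2)
    if (any(disp > step_px + 1e-9))
      stop("per-frame displacement exceeded step_px")
  }
  if (regime == "two") {
    ov <- vapply(seq_len(n_frames), function(i)
      sum(pairwise_dists(truth[i, , ]) < 2 * radius), numeric(1))
    if (!any(ov >= 1)) stop("regime 'two' produced no overlapping frame")
  }
  if (regime == "three") {
    all3 <- vapply(seq_len(n_frames), function(i)
      all(pairwise_dists(truth[i, , ]) < 2 * radius), logical(1))
    if (!any(all3)) stop("regime 'three' produced no triple-overlap frame")
  }
  frames <- lapply(seq_len(n_frames), function(i)
    render_disks(truth[i, , , drop = TRUE], radius, size, fg, bg))
  structure(list(frames = frames, truth = truth, radius = radius,
                 regime = regime, seed = seed, size = size),
            class = "ph_model_series")
}

#' @export
print.ph_model_series <- function(x, ...) {
  cat("ph_model_series:", length(x$frames), "frames,", dim(x$truth)[2],
      "disk cells of radius", x$radius, "- regime", x$regime, "\n")
  invisible(x)
}

#' Noise specification for model series
#'
#' @param kind One of `"blur_small"` (Gaussian blur, sigma ~ 1 px),
#'   `"blur_large"` (sigma ~ 3 px), `"pick"` (sparse isolated pixels flipped
#'   toward the opposite intensity), `"blur_pick_lch"` (small blur, then
#'   pick noise, then a bounded random perturbation applied in a
#'   lightness/chroma/hue colour representation and converted back to
#'   grayscale).
#' @param blur_sigma Gaussian sigma in pixels (defaults: 1 for small, 3 for
#'   large).
#' @param pick_density Fraction of pixels hit by pick noise.
#' @param lch_amplitude Amplitude of the LCh perturbation (lightness units).
#' @param seed RNG seed for the random noise components.
#' @return A `noise_spec` list.
#' @export
noise_spec <- function(kind = c("blur_small", "blur_large", "pick",
                                "blur_pick_lch"),
                       blur_sigma = NULL, pick_density = 0.02,
                       lch_amplitude = 10, seed = 1) {
  kind <- match.arg(kind)
  if (is.null(blur_sigma))
    blur_sigma <- switch(kind, blur_small = 1, blur_large = 3,
                         pick = 0, blur_pick_lch = 1)
  stopifnot(blur_sigma >= 0, pick_density >= 0, pick_density <= 1,
            lch_amplitude >= 0)
  structure(list(kind = kind, blur_sigma = blur_sigma,
                 pick_density = pick_density,
                 lch_amplitude = lch_amplitude, seed = seed),
            class = "noise_spec")
}

# separable Gaussian blur with replicated edges; sigma -> 0 is the identity
gauss_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  k <- ceiling(3 * sigma)
  if (k < 1) return(img)
  w <- dnorm(-k:k, sd = sigma)
  w <- w / sum(w)
  blur1 <- function(m, along_rows) {
    n <- if (along_rows) nrow(m) else ncol(m)
    acc <- 0
    for (o in -k:k) {
      idx <- pmin(pmax(seq_len(n) + o, 1L), n)
      acc <- acc + w[o + k + 1] *
        (if (along_rows) m[idx, , drop = FALSE] else m[, idx, drop = FALSE])
    }
    acc
  }
  blur1(blur1(img, TRUE), FALSE)
}

apply_pick <- function(img, density) {
  if (density <= 0) return(img)
  n <- length(img)
  hit <- which(runif(n) < density)
  img[hit] <- 255 - img[hit]
  img
}

apply_lch_noise <- function(img, amp) {
  if (amp <= 0) return(img)
  g <- as.vector(img) / 255
  lab <- grDevices::convertColor(cbind(g, g, g), from = "sRGB", to = "Lab")
  L <- lab[, 1]; a <- lab[, 2]; b <- lab[, 3]
  C <- sqrt(a^2 + b^2)
  h <- atan2(b, a)
  n <- length(L)
  L <- pmin(pmax(L + runif(n, -amp, amp), 0), 100)
  C <- pmax(C + runif(n, 0, amp / 2), 0)
  h <- h + runif(n, -pi / 5, pi / 5)
  lab2 <- cbind(L, C * cos(h), C * sin(h))
  rgb <- grDevices::convertColor(lab2, from = "Lab", to = "sRGB", clip = TRUE)
  gray <- 0.299 * rgb[, 1] + 0.587 * rgb[, 2] + 0.114 * rgb[, 3]
  matrix(pmin(pmax(gray * 255, 0), 255), nrow(img), ncol(img))
}

#' Add noise to a model series
#'
#' Applies the noise condition to every frame; the ground-truth centers are
#' unchanged (the same truth remains valid for evaluation).
#'
#' @param series A `ph_model_series`.
#' @param spec A [noise_spec()].
#' @return A `ph_model_series` with noisy frames and identical `truth`.
#' @export
add_noise <- function(series, spec) {
  if (!inherits(spec, "noise_spec")) spec <- do.call(noise_spec, spec)
  frames <- with_seed(spec$seed, {
    lapply(series$frames, function(f) {
      g <- f
      if (spec$kind %in% c("blur_small", "blur_large", "blur_pick_lch"))
        g <- gauss_blur(g, spec$blur_sigma)
      if (spec$kind %in% c("pick", "blur_pick_lch"))
        g <- apply_pick(g, spec$pick_density)
      if (spec$kind == "blur_pick_lch")
        g <- apply_lch_noise(g, spec$lch_amplitude)
      pmin(pmax(g, 0), 255)
    })
  })
  out <- series
  out$frames <- frames
  out$noise <- spec
  out
}

#' Horizontally chained overlapping disks
#'
#' Renders filled disks along a horizontal line with prescribed pairwise
#' overlap depths (consecutive centre distance `r_i + r_{i+1} - depth_i`).
#' Used to construct configurations where an erosion sweep (sure
#' foreground) cannot recover every figure at any single distance while
#' persistence detection can.
#'
#' @param radii Disk radii, at least two.
#' @param overlap_depths Overlap depth per consecutive pair (0 = tangent,
#'   negative = gap); must be smaller than either radius of its pair.
#' @param pad Background margin around the chain.
#' @return List with `mask` (logical matrix), `gray` (dark disks, value 30,
#'   on light background, value 220), and `centers` (n x 2 truth matrix).
#' @export
gen_overlap_chain <- function(radii, overlap_depths, pad = 6) {
  n <- length(radii)
  if (n < 2) stop("need at least two disks")
  if (length(overlap_depths) != n - 1)
    stop("need one overlap depth per consecutive pair")
  for (i in seq_len(n - 1)) {
    if (overlap_depths[i] >= min(radii[i], radii[i + 1]))
      stop("overlap depth must be smaller than either radius of its pair")
  }
  xs <- numeric(n)
  xs[1] <- pad + radii[1]
  for (i in seq_len(n - 1))
    xs[i + 1] <- xs[i] + radii[i] + radii[i + 1] - overlap_depths[i]
  h <- 2 * max(radii) + 2 * pad
  w <- ceiling(xs[n] + radii[n] + pad)
  y0 <- h / 2
  mask <- matrix(FALSE, h, w)
  for (i in seq_len(n)) {
    rows <- seq_len(h); cols <- seq_len(w)
    mask <- mask | (outer((rows - y0)^2, (cols - xs[i])^2, `+`) <= radii[i]^2)
  }
  gray <- matrix(220, h, w)
  gray[mask] <- 30
  list(mask = mask, gray = gray, centers = cbind(x = xs, y = rep(y0, n)))
}

#' The packaged four-figure chain model
#'
#' Four overlapping disks (radii 26, 26, 20, 12; overlap depths 10, 4, 4)
#' chosen so that the deepest pair separates under erosion only after the
#' smallest disk has vanished — no erosion distance yields four components —
#' while every disk's internal radius is at least the recommended detection
#' threshold (attribute `ph_thres`, 10 px), so persistence detection finds
#' all four.
#'
#' @return As [gen_overlap_chain()], with attribute `ph_thres`.
#' @export
fig4_chain_model <- function() {
  out <- gen_overlap_chain(c(26, 26, 20, 12), c(10, 4, 4))
  attr(out, "ph_thres") <- 10
  out
}

#' Scattered elliptical nuclei for counting tests
#'
#' Bright, mildly elliptical nuclei on a dark background with recorded true
#' centers: a synthetic stand-in for fluorescent nucleus-count benchmark
#' images. Centres are placed by seeded rejection sampling with a minimum
#' spacing, so nuclei are mostly disjoint with occasional close pairs.
#'
#' @param n Number of nuclei.
#' @param radius_range Range the mean radius of each nucleus is drawn from;
#'   axes are `rho * sqrt(k)` and `rho / sqrt(k)` with `k` up to
#'   `max_eccentricity`.
#' @param min_spacing Minimum distance between centres.
#' @param size Image size `c(rows, cols)`.
#' @param seed RNG seed.
#' @param fg,bg Nucleus and background intensities.
#' @param max_eccentricity Maximum axis-ratio factor.
#' @return List with `image` (grayscale matrix) and `centers` (n x 2).
#' @export
gen_scatter_nuclei <- function(n, radius_range = c(10, 13), min_spacing = 26,
                               size = c(520, 696), seed = 1,
                               fg = 200, bg = 20, max_eccentricity = 1.15) {
  stopifnot(n >= 1, min_spacing > 0, radius_range[1] > 2)
  with_seed(seed, {
    margin <- radius_range[2] * max_eccentricity + 4
    centers <- matrix(NA_real_, n, 2)
    placed <- 0
    tries <- 0
    while (placed < n) {
      tries <- tries + 1
      if (tries > 4000 * n)
        stop("packing failure: could not place ", n, " nuclei with spacing ",
             min_spacing, " in a ", size[1], " x ", size[2], " image")
      cand <- c(runif(1, margin, size[2] - margin),
                runif(1, margin, size[1] - margin))
      if (placed == 0 ||
          min(sqrt((centers[seq_len(placed), 1] - cand[1])^2 +
                   (centers[seq_len(placed), 2] - cand[2])^2)) >=
            min_spacing) {
        placed <- placed + 1
        centers[placed, ] <- cand
      }
    }
    img <- matrix(bg, size[1], size[2])
    for (k in seq_len(n)) {
      rho <- runif(1, radius_range[1], radius_range[2])
      ecc <- runif(1, 1, max_eccentricity)
      a <- rho * sqrt(ecc); b <- rho / sqrt(ecc)
      phi <- runif(1, 0, pi)
      cx <- centers[k, 1]; cy <- centers[k, 2]
      ext <- ceiling(a) + 1
      cols <- max(1, floor(cx - ext)):min(size[2], ceiling(cx + ext))
      rows <- max(1, floor(cy - ext)):min(size[1], ceiling(cy + ext))
      dx <- outer(rep(1, length(rows)), cols - cx)
      dy <- outer(rows - cy, rep(1, length(cols)))
      u <- (dx * cos(phi) + dy * sin(phi)) / a
      v <- (-dx * sin(phi) + dy * cos(phi)) / b
      inside <- u^2 + v^2 <= 1
      sub <- img[rows, cols, drop = FALSE]
      sub[inside] <- fg
      img[rows, cols] <- sub
    }
    colnames(centers) <- c("x", "y")
    list(image = img, centers = centers)
  })
}
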