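#' Binarization parameters
#'
#' @param bin_thres Intensity threshold in `[0, 255]`. Choose it so that no
#'   nucleus to be detected disappears from the mask.
#' @param polarity `"dark_foreground"` marks pixels strictly below the
#'   threshold as foreground (phase-contrast cells on a bright background);
#'   `"bright_foreground"` marks pixels at or above it (fluorescent nuclei on
#'   a dark background).
#' @return A `binarize_params` list.
#' @export
binarize_params <- function(bin_thres,
                            polarity = c("dark_foreground", "bright_foreground")) {
  polarity <- match.arg(polarity)
  if (!is.numeric(bin_thres) || length(bin_thres) != 1 ||
      bin_thres < 0 || bin_thres > 255)
    stop("bin_thres must be a single value in [0, 255]")
  structure(list(bin_thres = bin_thres, polarity = polarity),
            class = "binarize_params")
}

#' Threshold a grayscale image into a foreground mask
#'
#' @param img Numeric matrix with intensities in `[0, 255]` (rows are image
#'   rows, columns are image columns).
#' @param p A [binarize_params()] object.
#' @return Logical matrix of the same shape; `TRUE` is foreground ("white").
#' @examples
#' img <- matrix(100, 4, 4)
#' binarize(img, binarize_params(50, "bright_foreground"))
#' @export
binarize <- function(img, p) {
  check_gray(img)
  if (!inherits(p, "binarize_params")) p <- do.call(binarize_params, p)
  if (p$polarity == "dark_foreground") img < p$bin_thres else img >= p$bin_thres
}

#' Sparse-white cleanup parameters
#'
#' @param nbd Neighbourhood radius in pixels; the window is the Chebyshev
#'   square of side `2 * nbd + 1` centred on the pixel (the pixel itself is
#'   counted).
#' @param erase_thres Minimum number of white pixels the window must contain
#'   for the centre pixel to survive.
#' @return A `cleanup_params` list.
#' @export
cleanup_params <- function(nbd, erase_thres) {
  if (!is.numeric(nbd) || length(nbd) != 1 || nbd < 0)
    stop("nbd must be a single value >= 0")
  if (!is.numeric(erase_thres) || length(erase_thres) != 1 || erase_thres < 0)
    stop("erase_thres must be a single value >= 0")
  structure(list(nbd = as.integer(nbd), erase_thres = erase_thres),
            class = "cleanup_params")
}

# white-pixel counts in the (2r+1)^2 Chebyshev window of every pixel,
# windows clipped at the image border (integral-image box filter)
window_white_counts <- function(mask, r) {
  nr <- nrow(mask); nc <- ncol(mask)
  P <- matrix(0, nr + 1, nc + 1)
  P[-1, -1] <- mask
  P <- apply(P, 2, cumsum)
  P <- t(apply(P, 1, cumsum))
  top <- pmax(seq_len(nr) - r, 1L)
  bot <- pmin(seq_len(nr) + r, nr)
  lft <- pmax(seq_len(nc) - r, 1L)
  rgt <- pmin(seq_len(nc) + r, nc)
  P[bot + 1L, rgt + 1L, drop = FALSE] - P[top, rgt + 1L, drop = FALSE] -
    P[bot + 1L, lft, drop = FALSE] + P[top, lft, drop = FALSE]
}

#' Erase sparse white pixels
#'
#' Single simultaneous pass over the input mask: a white pixel survives iff
#' the number of white pixels in its Chebyshev window (computed on the input
#' mask, including the pixel itself) is at least `erase_thres`. Black pixels
#' never become white, so the result's white set is a subset of the input's.
#'
#' @param bin Logical foreground mask.
#' @param p A [cleanup_params()] object.
#' @return Logical matrix of the same shape.
#' @export
erase_sparse_white <- function(bin, p) {
  check_binary(bin)
  if (!inherits(p, "cleanup_params")) p <- do.call(cleanup_params, p)
  if (p$erase_thres <= 0) return(bin)
  cnt <- window_white_counts(bin, p$nbd)
  bin & (cnt >= p$erase_thres)
}

#' Rotation/stretch transformation parameters
#'
#' Rotation is about the image centre; positive angles are counter-clockwise
#' in raster coordinates (x right, y down). The stretch multiplies the
#' coordinate along `axis` (relative to the centre) by `mult`.
#'
#' @param rot Rotation angle in degrees (signed).
#' @param mult Stretch factor, must be `> 0`.
#' @param axis Axis to stretch, `"x"` or `"y"`.
#' @return A `transform_params` list.
#' @export
transform_params <- function(rot = 0, mult = 1, axis = c("x", "y")) {
  axis <- match.arg(axis)
  if (!is.numeric(mult) || length(mult) != 1 || mult <= 0)
    stop("mult must be a single value > 0")
  structure(list(rot = rot, mult = mult, axis = axis),
            class = "transform_params")
}

#' Rotate and stretch a point set
#'
#' Applies, to every point, a rotation by `p$rot` degrees about `center`
#' followed by multiplication of the `p$axis` coordinate (relative to
#' `center`) by `p$mult`. Non-disk-like nuclei can be made disk-like this
#' way before persistence is computed; [inverse_transform_points()] maps
#' detections back.
#'
#' @param pts n x 2 matrix of (x, y) points.
#' @param p A [transform_params()] object.
#' @param center Length-2 rotation/stretch centre, typically
#'   [image_center()] of the frame.
#' @return n x 2 matrix, order preserved.
#' @export
transform_points <- function(pts, p, center = c(0, 0)) {
  if (!inherits(p, "transform_params")) p <- do.call(transform_params, p)
  pts <- as_points(pts)
  if (nrow(pts) == 0) return(pts)
  th <- p$rot * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  q <- sweep(pts, 2, center) %*% t(R)
  if (p$axis == "x") q[, 1] <- q[, 1] * p$mult else q[, 2] <- q[, 2] * p$mult
  sweep(q, 2, center, `+`)
}

#' Exact inverse of [transform_points()]
#'
#' @inheritParams transform_points
#' @return n x 2 matrix with
#'   `inverse_transform_points(transform_points(q, p), p) == q` to within
#'   floating-point round-off.
#' @export
inverse_transform_points <- function(pts, p, center = c(0, 0)) {
  if (!inherits(p, "transform_params")) p <- do.call(transform_params, p)
  pts <- as_points(pts)
  if (nrow(pts) == 0) return(pts)
  q <- sweep(pts, 2, center)
  if (p$axis == "x") q[, 1] <- q[, 1] / p$mult else q[, 2] <- q[, 2] / p$mult
  th <- -p$rot * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  sweep(q %*% t(R), 2, center, `+`)
}

#' Read an image file as an 8-bit grayscale matrix
#'
#' Reads PNG or TIFF. RGB images are converted with ITU-R BT.601 luma
#' (0.299 R + 0.587 G + 0.114 B); an alpha channel is ignored. Images with
#' sample values above 255 (16-bit) are rescaled to `[0, 255]` by their
#' maximum.
#'
#' @param path File path (`.png`, `.tif` or `.tiff`).
#' @return Numeric matrix with values in `[0, 255]`.
#' @export
read_image_gray <- function(path) {
  ext <- tolower(tools::file_ext(path))
  a <- switch(ext,
    png = png::readPNG(path) * 255,
    tif = ,
    tiff = {
      x <- tiff::readTIFF(path, as.is = TRUE)
      if (max(x) > 255) x <- x / max(x) * 255
      x
    },
    stop("unsupported image format: ", ext)
  )
  if (length(dim(a)) == 3) {
    a <- 0.299 * a[, , 1] + 0.587 * a[, , 2] + 0.114 * a[, , 3]
  }
  a <- pmin(pmax(a, 0), 255)
  check_gray(a)
}

#' Write an 8-bit grayscale matrix (or RGB array) as PNG
#'
#' @param img Numeric matrix (or rows x cols x 3 array) with values in
#'   `[0, 255]`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_image_png <- function(img, path) {
  png::writePNG(pmin(pmax(img / 255, 0), 1), path)
  invisible(path)
}

#' Centre of an image in pixel coordinates
#'
#' Pixel centres sit at integer (x = column, y = row) coordinates starting at
#' (1, 1) in the top-left corner; the image centre is
#' `((width + 1) / 2, (height + 1) / 2)`. This is the rotation/stretch centre
#' used by the detection pipeline.
#'
#' @param img Image matrix.
#' @return Length-2 numeric vector (x, y).
#' @export
image_center <- function(img) {
  c((ncol(img) + 1) / 2, (nrow(img) + 1) / 2)
}
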