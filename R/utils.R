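# internal helpers shared across modules

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

as_points <- function(pts) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 2, byrow = FALSE)
  pts <- as.matrix(pts)
  if (ncol(pts) != 2) stop("points must be an n x 2 matrix of (x, y)")
  storage.mode(pts) <- "double"
  pts
}

check_gray <- function(img) {
  if (!is.matrix(img) || !is.numeric(img))
    stop("a grayscale image must be a numeric matrix")
  if (nrow(img) < 1 || ncol(img) < 1) stop("image must be at least 1 x 1")
  if (min(img) < 0 || max(img) > 255)
    stop("grayscale intensities must lie in [0, 255]")
  invisible(img)
}

check_binary <- function(bin) {
  if (!is.matrix(bin) || !is.logical(bin))
    stop("a binary image must be a logical matrix")
  invisible(bin)
}
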