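#' Evaluate code with a temporary RNG seed
#'
#' Saves and restores \code{.Random.seed} so generators are deterministic
#' without clobbering the caller's RNG stream.
#' @noRd
local_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Derive a child seed from a parent seed and an index
#'
#' Keeps derived seeds inside the 32-bit integer range so that nested
#' generators (cohort -> slide -> field) are reproducible from one seed.
#' @noRd
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(index) * 16807) %%
               2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Linear pixel indices of a filled disc
#'
#' Pixel-centred, 0-based coordinates (x right, y down): pixel (i, j) of the
#' matrix (row i, column j) has centre (x = j - 1, y = i - 1). A pixel
#' belongs to the disc if its centre lies within \code{radius} of the
#' centroid. Matrices are stored row = y, column = x.
#' @noRd
disc_pixels <- function(cx, cy, radius, width, height) {
  x0 <- max(0L, floor(cx - radius)); x1 <- min(width - 1L, ceiling(cx + radius))
  y0 <- max(0L, floor(cy - radius)); y1 <- min(height - 1L, ceiling(cy + radius))
  if (x0 > x1 || y0 > y1) return(integer(0))
  xs <- x0:x1; ys <- y0:y1
  dx <- matrix(xs - cx, nrow = length(ys), ncol = length(xs), byrow = TRUE)
  dy <- matrix(ys - cy, nrow = length(ys), ncol = length(xs))
  keep <- which(dx * dx + dy * dy <= radius * radius, arr.ind = TRUE)
  # linear index into a height x width matrix (column-major)
  (xs[keep[, 2]]) * height + (ys[keep[, 1]]) + 1L
}

#' Containing pixel of a 0-based centroid, as (row, col) of the image matrix
#' @noRd
centroid_pixel <- function(x, y) {
  cbind(row = floor(y) + 1L, col = floor(x) + 1L)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)
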