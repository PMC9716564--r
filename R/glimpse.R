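# Foveated glimpse extraction: three concentric windows cropped at the view
# centre, the larger ones downscaled to the smallest, stacked along depth.
# The smallest window plays the role of the high-resolution fovea, the
# largest of the low-resolution periphery.

#' Glimpse configuration
#'
#' @param window_sizes strictly increasing crop sizes in pixels; the default
#'   `c(16, 32, 50)` gives fovea, mid and periphery windows.
#' @param out_size common output size; must equal the smallest window.
#' @param center optional `(row, col)` crop centre in 0-based pixel indices;
#'   default is the view centre `(floor(h/2), floor(w/2))`, resolved at
#'   extraction time.
#' @return object of class `glimpse_config`.
#' @export
glimpse_config <- function(window_sizes = c(16L, 32L, 50L), out_size = 16L,
                           center = NULL) {
  window_sizes <- as.integer(window_sizes)
  if (any(diff(window_sizes) <= 0))
    stopf("glimpse_config: window_sizes must be strictly increasing")
  if (as.integer(out_size) != window_sizes[1])
    stopf("glimpse_config: out_size must equal the smallest window")
  structure(list(window_sizes = window_sizes, out_size = as.integer(out_size),
                 center = center), class = "glimpse_config")
}

#' Crop interval of an attention window
#'
#' Half-open pixel interval `[lo, hi)` of a window of the given size centred
#' at a 0-based pixel index: `lo = center - floor(size/2)`, `hi = lo + size`.
#'
#' @param center 0-based centre pixel index along one axis.
#' @param size window size in pixels.
#' @return integer vector `c(lo, hi)`; the interval is half-open.
#' @export
crop_bounds <- function(center, size) {
  center <- as.integer(center); size <- as.integer(size)
  if (size < 1) stopf("crop_bounds: size must be positive")
  lo <- center - size %/% 2L
  c(lo = lo, hi = lo + size)
}

# Sparse-free separable bilinear interpolation matrix (n_out x n_in),
# sampling at output pixel centres; rows sum to 1 (constant-preserving).
bilinear_mat <- function(n_in, n_out) {
  s <- n_in / n_out
  src <- (seq_len(n_out) - 0.5) * s - 0.5
  lo <- floor(src)
  fr <- src - lo
  lo0 <- pmin(pmax(lo, 0), n_in - 1)
  hi0 <- pmin(pmax(lo + 1, 0), n_in - 1)
  A <- matrix(0, n_out, n_in)
  for (i in seq_len(n_out)) {
    A[i, lo0[i] + 1] <- A[i, lo0[i] + 1] + (1 - fr[i])
    A[i, hi0[i] + 1] <- A[i, hi0[i] + 1] + fr[i]
  }
  A
}

# Bilinear resize of an (n x n x C) array to (m x m x C).
bilinear_resize <- function(x, m) {
  d <- dim(x)
  if (d[1] == m && d[2] == m) return(x)
  Ar <- bilinear_mat(d[1], m)
  Ac <- bilinear_mat(d[2], m)
  out <- array(0, c(m, m, d[3]))
  for (ch in seq_len(d[3])) out[, , ch] <- Ar %*% x[, , ch] %*% t(Ac)
  out
}

#' Extract the foveated attentional glimpse from a view
#'
#' Crops the configured concentric windows at the view centre, resizes every
#' window except the smallest down to the common output size by bilinear
#' interpolation, and stacks them along depth, smallest (fovea) first. The
#' channel order within each window is preserved, so a view with `C`
#' channels and `a` windows yields a glimpse of depth `a * C`.
#'
#' @param view image array `h x w x C` (a matrix is treated as `C = 1`),
#'   values in `[0, 1]`.
#' @param cfg a [glimpse_config()].
#' @return array `out_size x out_size x (a*C)`.
#' @export
extract_glimpse <- function(view, cfg = glimpse_config()) {
  d <- dim(view)
  if (length(d) == 2L) { view <- array(view, c(d, 1L)); d <- dim(view) }
  ctr <- cfg$center %||% c(d[1] %/% 2L, d[2] %/% 2L)
  C <- d[3]
  a <- length(cfg$window_sizes)
  out <- array(0, c(cfg$out_size, cfg$out_size, a * C))
  for (k in seq_len(a)) {
    sz <- cfg$window_sizes[k]
    rb <- crop_bounds(ctr[1], sz)
    cb <- crop_bounds(ctr[2], sz)
    if (rb["lo"] < 0 || cb["lo"] < 0 || rb["hi"] > d[1] || cb["hi"] > d[2])
      stopf("extract_glimpse: window %d (%d px) exceeds the %d x %d view",
            k, sz, d[1], d[2])
    crop <- view[(rb["lo"] + 1L):rb["hi"], (cb["lo"] + 1L):cb["hi"], , drop = FALSE]
    out[, , (k - 1L) * C + seq_len(C)] <- bilinear_resize(crop, cfg$out_size)
  }
  out
}
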