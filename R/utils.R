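# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG seed, restoring global RNG state.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a child seed from a base seed and a stream index; stays < 2^31.
child_seed <- function(seed, stream) {
  (as.double(seed) * 48271 + as.double(stream) * 1299721) %% 2147483587L
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

stop_config <- function(...) stop(sprintf(...), call. = FALSE)

is_image <- function(x) is.matrix(x) && is.numeric(x)

check_image <- function(x, name = "image") {
  if (!is_image(x)) stop_config("%s must be a numeric matrix", name)
  if (!all(is.finite(x))) stop_config("%s contains non-finite pixels", name)
  invisible(x)
}

# Separable convolution with replicate (edge-extension) boundary handling.
# kx filters along columns (x direction), ky along rows (y direction).
sep_conv <- function(img, kx, ky = kx) {
  conv_rows <- function(m, k) {
    # convolve each row with kernel k (odd length), replicate padding
    r <- (length(k) - 1L) %/% 2L
    n <- ncol(m)
    idx <- clamp(seq_len(n + 2L * r) - r, 1L, n)
    p <- m[, idx, drop = FALSE]
    out <- matrix(0, nrow(m), n)
    for (j in seq_along(k)) {
      out <- out + k[j] * p[, j:(j + n - 1L), drop = FALSE]
    }
    out
  }
  t(conv_rows(t(conv_rows(img, kx)), ky))
}

gauss_kernel <- function(sigma, order = 0L) {
  r <- max(1L, ceiling(4 * sigma))
  x <- seq(-r, r)
  g <- exp(-x^2 / (2 * sigma^2))
  g <- g / sum(g)
  switch(as.character(order),
    "0" = g,
    "1" = -x / sigma^2 * g,                       # odd: sums to 0 exactly
    "2" = {                                       # enforce zero DC response
      k <- (x^2 - sigma^2) / sigma^4 * g
      k - mean(k)
    },
    stop("unsupported derivative order")
  )
}

# Nearest-neighbour resize of a matrix to (h, w).
resize_nn <- function(img, h, w) {
  ri <- clamp(round(seq(1, nrow(img), length.out = h)), 1, nrow(img))
  ci <- clamp(round(seq(1, ncol(img), length.out = w)), 1, ncol(img))
  img[ri, ci, drop = FALSE]
}

# Orientation (degrees in [0, 180)) of the principal axis of a pixel set.
# Coordinates: x = column, y = -row, so angles follow the usual maths
# convention with respect to the image x axis.
principal_axis_angle <- function(rows, cols) {
  x <- cols - mean(cols)
  y <- -(rows - mean(rows))
  sxx <- mean(x * x); syy <- mean(y * y); sxy <- mean(x * y)
  ang <- 0.5 * atan2(2 * sxy, sxx - syy) * 180 / pi
  ang %% 180
}

# Circular mean of axial angles (period 180 degrees).
axial_mean <- function(deg) {
  a <- deg * pi / 90  # double angles
  (atan2(mean(sin(a)), mean(cos(a))) * 90 / pi) %% 180
}

axial_diff <- function(a, b) {
  d <- abs(a - b) %% 180
  pmin(d, 180 - d)
}
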