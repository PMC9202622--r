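#' Configuration for the synthetic angiogram phantom generator
#'
#' The phantom emulates X-ray coronary angiograms: branching tubular
#' vessel trees of varying diameter, length and orientation rendered dark
#' on a brighter background (contrast agent attenuates X-rays), optional
#' stenotic narrowings, low-frequency background structures with faint
#' rib-like bands, and additive Gaussian noise. Every sample carries the
#' exact binary vessel mask, a normal/abnormal label, and a per-branch
#' geometry table, so downstream stages can be tested without clinical
#' data.
#'
#' @param size Image side in pixels (square raster); the reference
#'   clinical angiograms are 300 x 300, desk-scale tests use 32-96.
#' @param n_branches Integer range `c(min, max)` for the number of vessel
#'   branches (roots plus children).
#' @param diameter_range Branch diameter range in pixels.
#' @param length_range Branch chord length as a fraction of `size`.
#' @param tortuosity Relative amplitude of the Bezier control-point
#'   offset; 0 gives perfectly straight branches.
#' @param branch_child_prob Probability that a new branch sprouts from an
#'   existing one (tree topology) rather than starting a new root.
#' @param stenosis_prob Probability that a sample is abnormal, i.e. that
#'   one branch receives a stenotic narrowing.
#' @param stenosis_range Severity range (fractional lumen narrowing) for
#'   stenosed branches. The default starts at the conventional clinically
#'   significant 50% narrowing.
#' @param abnormal_threshold A sample is labelled `abnormal` iff any
#'   branch has `stenosis_fraction >=` this value.
#' @param vessel_intensity,background_intensity Mean gray levels (0-255)
#'   of vessel lumen and background; vessels darker by X-ray convention.
#' @param background_amplitude Amplitude of smooth background blobs and
#'   rib-like bands ("structural interference").
#' @param noise_sigma Standard deviation of additive Gaussian noise.
#' @param edge_softness Gaussian blur (pixels) applied to the rendered
#'   intensity image (partial-volume softening); the mask is untouched.
#' @param invert If `TRUE`, render bright vessels on dark background.
#' @return An object of class `phantom_config` (a validated list).
#' @seealso [generate_tree()], [generate_phantom_set()]
#' @export
phantom_config <- function(size = 300,
                           n_branches = c(3L, 6L),
                           diameter_range = c(3, 12),
                           length_range = c(0.4, 0.9),
                           tortuosity = 0.15,
                           branch_child_prob = 0.5,
                           stenosis_prob = 0.5,
                           stenosis_range = c(0.5, 0.8),
                           abnormal_threshold = 0.5,
                           vessel_intensity = 70,
                           background_intensity = 190,
                           background_amplitude = 20,
                           noise_sigma = 10,
                           edge_softness = 0.7,
                           invert = FALSE) {
  cfg <- list(size = as.integer(size), n_branches = as.integer(n_branches),
              diameter_range = diameter_range, length_range = length_range,
              tortuosity = tortuosity, branch_child_prob = branch_child_prob,
              stenosis_prob = stenosis_prob, stenosis_range = stenosis_range,
              abnormal_threshold = abnormal_threshold,
              vessel_intensity = vessel_intensity,
              background_intensity = background_intensity,
              background_amplitude = background_amplitude,
              noise_sigma = noise_sigma, edge_softness = edge_softness,
              invert = isTRUE(invert))
  if (cfg$size < 8) stop_config("size must be >= 8")
  if (length(cfg$n_branches) != 2 || any(cfg$n_branches < 0) ||
      cfg$n_branches[1] > cfg$n_branches[2])
    stop_config("n_branches must be a nondecreasing pair of nonnegative integers")
  if (any(cfg$diameter_range <= 0)) stop_config("diameters must be positive")
  if (any(cfg$stenosis_range < 0) || any(cfg$stenosis_range >= 1))
    stop_config("stenosis fractions must lie in [0, 1)")
  if (cfg$noise_sigma < 0) stop_config("noise_sigma must be nonnegative")
  if (cfg$tortuosity < 0) stop_config("tortuosity must be nonnegative")
  class(cfg) <- "phantom_config"
  cfg
}

# Sample a quadratic Bezier centerline; returns dense point list plus the
# chord angle in [0, 180).
sample_centerline <- function(p0, p1, tortuosity, size) {
  chord <- sqrt(sum((p1 - p0)^2))
  mid <- (p0 + p1) / 2
  d <- (p1 - p0) / chord
  n <- c(-d[2], d[1])  # perpendicular
  off <- tortuosity * chord * stats::runif(1, -1, 1)
  ctrl <- mid + off * n
  t <- seq(0, 1, length.out = max(2L, ceiling(chord * 4)))
  pts <- cbind((1 - t)^2 * p0[1] + 2 * t * (1 - t) * ctrl[1] + t^2 * p1[1],
               (1 - t)^2 * p0[2] + 2 * t * (1 - t) * ctrl[2] + t^2 * p1[2])
  pts[, 1] <- clamp(pts[, 1], 1.5, size - 0.5)
  pts[, 2] <- clamp(pts[, 2], 1.5, size - 0.5)
  ang <- (atan2(-(p1[1] - p0[1]), p1[2] - p0[2]) * 180 / pi) %% 180
  list(pts = pts, angle = ang)   # pts columns: (row, col)
}

# Paint the tube around a sampled centerline into a logical mask.
# radius_at: function(arc) -> local radius. A pixel is vessel when its
# center lies strictly within the local radius of some centerline sample.
paint_branch <- function(mask, pts, radius_at) {
  size_r <- nrow(mask); size_c <- ncol(mask)
  seg <- sqrt(rowSums((pts[-1, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE])^2))
  arc <- c(0, cumsum(seg))
  total <- arc[length(arc)]
  # resample to ~0.25 px spacing
  s <- seq(0, total, by = 0.25)
  ri <- stats::approx(arc, pts[, 1], xout = s)$y
  ci <- stats::approx(arc, pts[, 2], xout = s)$y
  rad <- radius_at(s)
  for (k in seq_along(s)) {
    r <- rad[k]
    if (r <= 0) next
    r0 <- max(1L, floor(ri[k] - r)); r1 <- min(size_r, ceiling(ri[k] + r))
    c0 <- max(1L, floor(ci[k] - r)); c1 <- min(size_c, ceiling(ci[k] + r))
    if (r0 > r1 || c0 > c1) next
    rr <- r0:r1; cc <- c0:c1
    d2 <- outer((rr - ri[k])^2, (cc - ci[k])^2, "+")
    hit <- d2 < r^2
    mask[rr, cc] <- mask[rr, cc] | hit
  }
  mask
}

# Smooth background: base level + Gaussian blobs + faint rib-like bands.
render_background <- function(size, level, amplitude) {
  bg <- matrix(level, size, size)
  if (amplitude <= 0) return(bg)
  rr <- matrix(seq_len(size), size, size)
  cc <- matrix(seq_len(size), size, size, byrow = TRUE)
  n_blob <- sample(2:4, 1)
  for (i in seq_len(n_blob)) {
    cy <- stats::runif(1, 1, size); cx <- stats::runif(1, 1, size)
    s <- stats::runif(1, 0.1, 0.3) * size
    a <- stats::runif(1, -1, 1) * amplitude
    bg <- bg + a * exp(-((rr - cy)^2 + (cc - cx)^2) / (2 * s^2))
  }
  # rib-like bands: broad periodic dips along a random orientation
  th <- stats::runif(1, 0, pi)
  u <- cos(th) * cc - sin(th) * rr
  period <- stats::runif(1, 0.25, 0.5) * size
  bg <- bg - 0.4 * amplitude * (0.5 + 0.5 * cos(2 * pi * u / period))
  bg
}

#' Generate a synthetic angiogram phantom
#'
#' Draws a seeded random vessel tree, renders it dark on a structured
#' bright background, adds Gaussian noise, and returns the image together
#' with its exact ground truth. The same `(config, seed)` pair always
#' regenerates a bit-identical sample.
#'
#' @param config A [phantom_config()].
#' @param seed Integer seed; the sample is a pure function of
#'   `(config, seed)`.
#' @param force_label Optional `"normal"` or `"abnormal"` to force the
#'   class (used to emit balanced sets); `NULL` draws the class from
#'   `config$stenosis_prob`.
#' @return An object of class `phantom_sample`: a list with `image`
#'   (noisy, `[0, 255]`), `clean` (pre-noise image), `mask` (0/1 integer
#'   matrix, exactly the union of rendered branch supports), `label`
#'   (`"normal"`/`"abnormal"`), `branches` (data frame with `branch_id`,
#'   `diameter_px`, `angle_deg`, `length_px`, `stenosis_fraction`),
#'   `noise_sigma`, and `seed`.
#' @examples
#' s <- generate_tree(phantom_config(size = 64, noise_sigma = 5), seed = 1)
#' table(s$mask)
#' s$branches
#' @export
generate_tree <- function(config = phantom_config(), seed = 1L,
                          force_label = NULL) {
  if (!inherits(config, "phantom_config")) config <- do.call(phantom_config, config)
  if (!is.null(force_label)) force_label <- match.arg(force_label, c("normal", "abnormal"))
  with_seed(seed, {
    size <- config$size
    nb <- if (config$n_branches[1] == config$n_branches[2]) config$n_branches[1]
          else sample(config$n_branches[1]:config$n_branches[2], 1)
    mask <- matrix(FALSE, size, size)
    branches <- list()
    centerlines <- list()
    margin <- max(config$diameter_range) / 2 + 1
    abnormal <- if (is.null(force_label)) stats::runif(1) < config$stenosis_prob
                else force_label == "abnormal"
    sten_branch <- if (abnormal && nb > 0) sample.int(nb, 1) else 0L
    for (b in seq_len(nb)) {
      d <- stats::runif(1, config$diameter_range[1], config$diameter_range[2])
      len <- stats::runif(1, config$length_range[1], config$length_range[2]) * size
      is_child <- b > 1 && stats::runif(1) < config$branch_child_prob
      if (is_child) {
        pidx <- sample.int(b - 1L, 1)
        parent <- centerlines[[pidx]]
        d <- min(d, branches[[pidx]]$diameter_px)
      }
      # draw a placement whose in-bounds chord keeps most of the target
      # length, so border clamping cannot degenerate the branch
      for (try in 1:10) {
        if (is_child) {
          i0 <- sample.int(nrow(parent$pts), 1)
          p0 <- parent$pts[i0, ]
          ang0 <- parent$angle + sample(c(-1, 1), 1) * stats::runif(1, 20, 70)
        } else {
          p0 <- c(stats::runif(1, margin, size - margin),
                  stats::runif(1, margin, size - margin))
          ang0 <- stats::runif(1, 0, 180)
        }
        th <- ang0 * pi / 180
        dirv <- c(-sin(th), cos(th)) * sample(c(-1, 1), 1)  # (row, col)
        p1 <- clamp(p0 + len * dirv, margin, size - margin)
        if (sqrt(sum((p1 - p0)^2)) >= 0.7 * len) break
      }
      if (sqrt(sum((p1 - p0)^2)) < 4) p1 <- p0 + dirv * 4
      p1 <- clamp(p1, 1.5, size - 0.5)
      cl <- sample_centerline(p0, p1, config$tortuosity, size)
      sten <- if (b == sten_branch)
        stats::runif(1, config$stenosis_range[1], config$stenosis_range[2]) else 0
      seg <- sqrt(rowSums((cl$pts[-1, , drop = FALSE] -
                           cl$pts[-nrow(cl$pts), , drop = FALSE])^2))
      total <- sum(seg)
      site <- stats::runif(1, 0.35, 0.65) * total
      sten_sigma <- clamp(total / 10, 2.5, 5)  # focal: narrow relative to length
      radius_at <- local({
        d0 <- d; s0 <- sten; st <- site; sg <- sten_sigma
        function(arc) (d0 / 2) * (1 - s0 * exp(-(arc - st)^2 / (2 * sg^2)))
      })
      mask <- paint_branch(mask, cl$pts, radius_at)
      centerlines[[b]] <- cl
      branches[[b]] <- data.frame(branch_id = b, diameter_px = d,
                                  angle_deg = cl$angle, length_px = total,
                                  stenosis_fraction = sten)
    }
    branch_df <- if (length(branches)) do.call(rbind, branches)
                 else data.frame(branch_id = integer(), diameter_px = numeric(),
                                 angle_deg = numeric(), length_px = numeric(),
                                 stenosis_fraction = numeric())
    label <- if (any(branch_df$stenosis_fraction >= config$abnormal_threshold))
      "abnormal" else "normal"
    bg <- render_background(size, config$background_intensity,
                            config$background_amplitude)
    img <- bg
    img[mask] <- config$vessel_intensity
    if (config$edge_softness > 0)
      img <- sep_conv(img, gauss_kernel(config$edge_softness))
    img <- clamp(img, 0, 255)
    if (config$invert) img <- 255 - img
    clean <- img
    noisy <- if (config$noise_sigma > 0)
      add_noise(clean, config$noise_sigma, seed = child_seed(seed, 7L)) else clean
    structure(list(image = noisy, clean = clean,
                   mask = matrix(as.integer(mask), size, size),
                   label = label, branches = branch_df,
                   noise_sigma = config$noise_sigma, seed = seed,
                   config = config),
              class = "phantom_sample")
  })
}

#' @export
print.phantom_sample <- function(x, ...) {
  cat(sprintf("<phantom_sample> %dx%d, %d branch(es), label = %s, sigma = %g, seed = %s\n",
              nrow(x$image), ncol(x$image), nrow(x$branches), x$label,
              x$noise_sigma, format(x$seed)))
  invisible(x)
}

#' Generate a set of phantoms with balanced class labels
#'
#' Convenience wrapper around [generate_tree()] that alternates forced
#' normal/abnormal labels so train/test sets are class balanced.
#'
#' @param n Number of samples.
#' @param config A [phantom_config()].
#' @param seed Base seed; sample `i` uses a seed derived from `(seed, i)`.
#' @param balance If `TRUE`, force alternating labels; otherwise labels
#'   are drawn from `config$stenosis_prob`.
#' @return List of `phantom_sample` objects.
#' @export
generate_phantom_set <- function(n, config = phantom_config(), seed = 1L,
                                 balance = TRUE) {
  lapply(seq_len(n), function(i) {
    fl <- if (balance) c("normal", "abnormal")[1L + (i %% 2L)] else NULL
    generate_tree(config, seed = child_seed(seed, i), force_label = fl)
  })
}

#' Add Gaussian noise to an image
#'
#' Additive zero-mean Gaussian noise (the noise model the Wiener stage
#' assumes: noisy = original + noise), clipped to `[0, 255]`.
#'
#' @param image Numeric matrix in `[0, 255]`.
#' @param sigma Noise standard deviation; 0 returns the input unchanged.
#' @param seed Integer seed for the noise field.
#' @return Noisy image, same shape, clipped to `[0, 255]`.
#' @export
add_noise <- function(image, sigma, seed = 1L) {
  check_image(image)
  if (!is.numeric(sigma) || length(sigma) != 1 || !is.finite(sigma) || sigma < 0)
    stop_config("sigma must be a nonnegative number")
  if (sigma == 0) return(image)
  with_seed(seed, {
    noise <- matrix(stats::rnorm(length(image), 0, sigma), nrow(image))
    clamp(image + noise, 0, 255)
  })
}

#' Write a phantom sample to disk
#'
#' Writes the image (binary PGM and PNG), the mask (PGM with values 0/255),
#' the per-branch geometry table (headered CSV) and the label plus
#' generation metadata (JSON sidecar).
#'
#' @param sample A `phantom_sample`.
#' @param dir Output directory (created if missing).
#' @param stem File-name stem, default `"phantom_<seed>"`.
#' @return Invisibly, the named vector of written paths.
#' @export
write_phantom <- function(sample, dir, stem = NULL) {
  stopifnot(inherits(sample, "phantom_sample"))
  if (is.null(stem)) stem <- sprintf("phantom_%s", format(sample$seed))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(image_pgm = file.path(dir, paste0(stem, ".pgm")),
             image_png = file.path(dir, paste0(stem, ".png")),
             mask = file.path(dir, paste0(stem, "_mask.pgm")),
             branches = file.path(dir, paste0(stem, "_branches.csv")),
             label = file.path(dir, paste0(stem, ".json")))
  write_pgm(sample$image, paths["image_pgm"])
  write_angio_image(sample$image, paths["image_png"])
  write_pgm(sample$mask * 255, paths["mask"])
  utils::write.csv(sample$branches, paths["branches"], row.names = FALSE)
  jsonlite::write_json(list(label = sample$label, seed = sample$seed,
                            noise_sigma = sample$noise_sigma),
                       paths["label"], auto_unbox = TRUE)
  invisible(paths)
}
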