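# Threefold feature catalogue: color (intensity moments), texture (GLCM
# statistics) and shape (geometry of the segmented artery region).
# Definitions adopted here are normative for this package:
#  - skewness/kurtosis are standardized moments (kurtosis non-excess);
#  - local_intensity is the contrast between the region mean and the mean
#    of a 5-px dilated background ring;
#  - GLCM is symmetric, offset 1 px, averaged over 0/45/90/135 degrees,
#    on intensities quantized to `levels` gray levels within the region
#    range (so features are invariant to adding a constant);
#  - roundness = 4*pi*area/perimeter^2 with a chain-code perimeter;
#  - solidity = area / convex hull area; convexity = hull perimeter /
#    perimeter; dispersion = max/mean radial distance from the centroid.

# Perimeter of a region from its 8-connected boundary chain: axial steps
# count 1, diagonal steps sqrt(2), with the Vossepoel-Smeulders style
# correction factor 0.95 for raster overestimation.
region_perimeter <- function(sub) {
  ct <- EBImage::ocontour(matrix(as.numeric(sub), nrow(sub)))
  if (!length(ct)) return(4)
  per <- 0
  for (p in ct) {
    q <- rbind(p, p[1, ])
    st <- abs(diff(q))
    per <- per + sum(ifelse(rowSums(st) == 2, sqrt(2), 1))
  }
  0.95 * per
}

# March from a point along +/- the unit normal until leaving the mask;
# returns the two boundary points and the chord length.
cast_normal_ray <- function(mask, r0, c0, angle_deg, step = 0.25) {
  th <- (angle_deg + 90) * pi / 180   # normal to the local orientation
  dr <- -sin(th); dc <- cos(th)
  inside <- function(r, c) {
    ri <- round(r); ci <- round(c)
    ri >= 1 && ri <= nrow(mask) && ci >= 1 && ci <= ncol(mask) &&
      mask[ri, ci] > 0
  }
  march <- function(sgn) {
    t <- 0
    while (inside(r0 + sgn * (t + step) * dr, c0 + sgn * (t + step) * dc))
      t <- t + step
    t
  }
  tp <- march(1); tm <- march(-1)
  p <- c(r0 - tm * dr, c0 - tm * dc)
  q <- c(r0 + tp * dr, c0 + tp * dc)
  list(p = p, q = q, d = euclid_d(p[2], q[2], p[1], q[1]))
}

# Euclidean distance between two points: d = sqrt((x1-x2)^2 + (y1-y2)^2).
euclid_d <- function(x1, x2, y1, y2) sqrt((x1 - x2)^2 + (y1 - y2)^2)

#' Measure the artery diameter of a region
#'
#' At each interior skeleton point a ray is cast along the local normal
#' to the two opposite boundary crossings P and Q, and the width is the
#' Euclidean distance between them. The region's diameter is summarized
#' by the median width over skeleton points (robust to branch ends); the
#' minimum width is also reported because stenosis grading depends on the
#' narrowest site.
#'
#' @param mask Binary matrix.
#' @param region Optional coordinate matrix (row, col) restricting the
#'   measurement to one region; default uses the whole mask.
#' @return Object of class `diameter_measurement`: list with `d` (median
#'   width, px), `d_min` (minimum width), `p`, `q` (boundary points, as
#'   `(x, y)` pairs, of the median-width ray), `widths` (per-skeleton-point
#'   widths) and `degenerate` (`TRUE` when the region is thinner than
#'   1 px and width 1 is returned by convention).
#' @export
measure_diameter <- function(mask, region = NULL) {
  sub <- matrix(FALSE, nrow(mask), ncol(mask))
  if (is.null(region)) sub[mask > 0] <- TRUE else sub[region] <- TRUE
  if (!any(sub)) stop_config("empty region")
  skel <- which(skeletonize(sub), arr.ind = TRUE)
  comp <- which(sub, arr.ind = TRUE)
  if (nrow(skel) < 1)
    return(structure(list(d = 1, d_min = 1, p = NULL, q = NULL,
                          widths = numeric(), degenerate = TRUE),
                     class = "diameter_measurement"))
  # drop skeleton points near the path ends where rays leave the cap
  keep <- rep(TRUE, nrow(skel))
  if (nrow(skel) >= 7) {
    ends <- skel_endpoints(sub, skel)
    if (nrow(ends)) {
      for (e in seq_len(nrow(ends)))
        keep <- keep & (abs(skel[, 1] - ends[e, 1]) > 2 |
                        abs(skel[, 2] - ends[e, 2]) > 2)
      if (sum(keep) < 3) keep <- rep(TRUE, nrow(skel))
    }
  }
  pts <- skel[keep, , drop = FALSE]
  angs <- vapply(seq_len(nrow(pts)), function(i)
    local_orientation(comp, pts[i, ], radius = 5), 0)
  ok <- is.finite(angs)
  pts <- pts[ok, , drop = FALSE]; angs <- angs[ok]
  if (!nrow(pts))
    return(structure(list(d = 1, d_min = 1, p = NULL, q = NULL,
                          widths = numeric(), degenerate = TRUE),
                     class = "diameter_measurement"))
  rays <- lapply(seq_len(nrow(pts)), function(i)
    cast_normal_ray(sub, pts[i, 1], pts[i, 2], angs[i]))
  widths <- vapply(rays, function(r) r$d, 0)
  # order along the principal axis and smooth with a 3-point running
  # median so isolated spurious rays (skeleton spurs, junctions) do not
  # contaminate the minimum
  if (length(widths) >= 3) {
    axis_ang <- principal_axis_angle(comp[, 1], comp[, 2]) * pi / 180
    proj <- pts[, 2] * cos(axis_ang) - pts[, 1] * sin(axis_ang)
    o <- order(proj)
    widths[o] <- stats::runmed(widths[o], 3)
  }
  med <- stats::median(widths)
  ray <- rays[[which.min(abs(widths - med))]]
  med <- ray$d   # report the realized ray so d equals the P-Q distance
  structure(list(d = max(med, 1), d_min = max(min(widths), 1),
                 p = c(x = unname(ray$p[2]), y = unname(ray$p[1])),
                 q = c(x = unname(ray$q[2]), y = unname(ray$q[1])),
                 widths = widths, degenerate = med < 1),
            class = "diameter_measurement")
}

# Skeleton endpoints: skeleton pixels with exactly one skeleton neighbour.
skel_endpoints <- function(sub, skel_pts) {
  skel <- matrix(FALSE, nrow(sub), ncol(sub))
  skel[skel_pts] <- TRUE
  nb <- Reduce(`+`, lapply(list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1),
                                c(0, 1), c(1, -1), c(1, 0), c(1, 1)),
                           function(s) shift_mat(skel, s[1], s[2])))
  which(skel & nb == 1, arr.ind = TRUE)
}

#' Color (intensity) features of a region
#'
#' First four standardized moments of the pixel intensities inside the
#' region (mean, standard deviation, skewness, non-excess kurtosis) plus
#' `local_intensity`, the contrast between the region mean and the mean
#' intensity of a 5-px dilated background ring around it. For a
#' constant-intensity region skewness and kurtosis are undefined (0/0)
#' and returned as 0 and 3 by convention, with attribute
#' `"constant" = TRUE`.
#'
#' @param image Intensity image.
#' @param region Coordinate matrix (row, col) of region pixels.
#' @param ring_px Dilation radius of the background ring.
#' @return Named numeric vector: `mean`, `standard_deviation`,
#'   `skewness`, `kurtosis`, `local_intensity`.
#' @export
color_features <- function(image, region, ring_px = 5L) {
  if (is.null(region) || nrow(region) == 0) stop_config("empty region")
  v <- image[region]
  m <- mean(v); s <- stats::sd(v)
  if (length(v) == 1) s <- 0
  constant <- !is.finite(s) || s == 0
  skw <- if (constant) 0 else mean((v - m)^3) / (sqrt(mean((v - m)^2)))^3
  krt <- if (constant) 3 else mean((v - m)^4) / (mean((v - m)^2))^2
  sub <- matrix(0, nrow(image), ncol(image))
  sub[region] <- 1
  ker <- EBImage::makeBrush(2L * ring_px + 1L, shape = "disc")
  ring <- EBImage::dilate(sub, ker) > 0 & sub == 0
  li <- if (any(ring)) m - mean(image[ring]) else 0
  out <- c(mean = m, standard_deviation = if (constant) 0 else s,
           skewness = skw, kurtosis = krt, local_intensity = li)
  attr(out, "constant") <- constant
  out
}

# Symmetric normalized GLCM averaged over the four unit offsets, counting
# only pixel pairs that both lie inside the region.
glcm_matrix <- function(image, region, levels = 32L) {
  v <- image[region]
  lo <- min(v); hi <- max(v)
  qimg <- matrix(NA_integer_, nrow(image), ncol(image))
  qimg[region] <- if (hi > lo)
    pmin(as.integer(floor((image[region] - lo) / (hi - lo) * levels)), levels - 1L)
  else 0L
  offsets <- list(c(0, 1), c(-1, 1), c(-1, 0), c(-1, -1))  # 0,45,90,135 deg
  P <- matrix(0, levels, levels)
  h <- nrow(image); w <- ncol(image)
  for (off in offsets) {
    r2 <- region[, 1] + off[1]; c2 <- region[, 2] + off[2]
    ok <- r2 >= 1 & r2 <= h & c2 >= 1 & c2 <= w
    a <- qimg[region[ok, , drop = FALSE]]
    b <- qimg[cbind(r2[ok], c2[ok])]
    good <- !is.na(b)
    if (!any(good)) next
    tab <- table(factor(a[good], levels = 0:(levels - 1L)),
                 factor(b[good], levels = 0:(levels - 1L)))
    P <- P + tab + t(tab)   # symmetric
  }
  if (sum(P) == 0) stop_config("degenerate region: no co-occurring pixel pairs")
  P / sum(P)
}

#' Texture features of a region (GLCM statistics)
#'
#' Builds a symmetric normalized gray-level co-occurrence matrix over
#' in-region pixel pairs (offset 1 px, orientations 0/45/90/135 degrees
#' averaged) and evaluates: angular second moment `ASM = sum(p^2)`,
#' `homogeneity = sum(p / (1 + |i - j|))`, GLCM `correlation`, and GLCM
#' `entropy = -sum(p log2 p)`. Intensities are quantized to `levels`
#' levels within the region's own intensity range, so all features are
#' invariant to adding a constant to the image.
#'
#' @param image Intensity image.
#' @param region Coordinate matrix (row, col); must contain more than one
#'   pixel.
#' @param levels Number of quantization gray levels.
#' @return Named numeric vector: `entropy`, `correlation`, `homogeneity`,
#'   `asm`.
#' @export
texture_features <- function(image, region, levels = 32L) {
  if (is.null(region) || nrow(region) < 2)
    stop_config("degenerate region: need at least 2 pixels for texture")
  P <- glcm_matrix(image, region, levels)
  i <- row(P) - 1; j <- col(P) - 1
  asm <- sum(P^2)
  hom <- sum(P / (1 + abs(i - j)))
  ent <- -sum(P[P > 0] * log2(P[P > 0]))
  mu_i <- sum(i * P); mu_j <- sum(j * P)
  sd_i <- sqrt(sum((i - mu_i)^2 * P)); sd_j <- sqrt(sum((j - mu_j)^2 * P))
  corr <- if (sd_i > 0 && sd_j > 0)
    sum((i - mu_i) * (j - mu_j) * P) / (sd_i * sd_j) else 0
  c(entropy = ent, correlation = corr, homogeneity = hom, asm = asm)
}

#' Shape features of a region
#'
#' Geometry of a segmented artery region: `artery_diameter` (median
#' normal-ray width, [measure_diameter()]), `artery_area` (pixel count),
#' `artery_angle` and `artery_length` (principal-axis orientation and
#' skeleton length, as in [estimate_artery_angles()]), `eccentricity`
#' (of the second-moment ellipse, in `[0, 1)`), `roundness`
#' (`4 pi area / perimeter^2`), `dispersion` (max/mean radial distance
#' from the centroid), `convexity` (convex-hull perimeter / perimeter)
#' and `solidity` (area / convex-hull area). `diameter_min` (narrowest
#' normal-ray width) is reported alongside because stenosis detection
#' depends on it.
#'
#' @param mask Binary matrix.
#' @param region Coordinate matrix (row, col); default: all foreground
#'   pixels.
#' @return Named numeric vector of the nine shape features plus
#'   `diameter_min`.
#' @export
shape_features <- function(mask, region = NULL) {
  if (is.null(region)) region <- which(mask > 0, arr.ind = TRUE)
  if (nrow(region) == 0) stop_config("empty region")
  area <- nrow(region)
  sub <- matrix(FALSE, nrow(mask), ncol(mask))
  sub[region] <- TRUE
  dm <- measure_diameter(sub)
  skl <- which(skeletonize(sub), arr.ind = TRUE)
  len <- max(skeleton_length(skl), 1)
  ang <- principal_axis_angle(region[, 1], region[, 2])
  # second-moment ellipse eccentricity
  x <- region[, 2] - mean(region[, 2]); y <- region[, 1] - mean(region[, 1])
  cxx <- mean(x^2) + 1 / 12; cyy <- mean(y^2) + 1 / 12; cxy <- mean(x * y)
  tr <- cxx + cyy; dt <- cxx * cyy - cxy^2
  l1 <- tr / 2 + sqrt(max(tr^2 / 4 - dt, 0))
  l2 <- tr / 2 - sqrt(max(tr^2 / 4 - dt, 0))
  ecc <- if (l1 > 0) sqrt(pmax(1 - l2 / l1, 0)) else 0
  ecc <- min(ecc, 1 - 1e-12)
  per <- region_perimeter(sub)
  roundness <- min(4 * pi * area / per^2, 1)
  rad <- sqrt(x^2 + y^2)
  dispersion <- if (mean(rad) > 0) max(rad) / mean(rad) else 1
  hull <- grDevices::chull(region[, 2], region[, 1])
  hx <- region[hull, 2]; hy <- region[hull, 1]
  n <- length(hull)
  hull_per <- if (n >= 2)
    sum(sqrt(diff(c(hx, hx[1]))^2 + diff(c(hy, hy[1]))^2)) else per
  # pixel-count hull area: lattice shoelace + boundary/2 + 1 (Pick)
  hull_area <- if (n >= 3)
    abs(sum(hx * hy[c(2:n, 1)] - hx[c(2:n, 1)] * hy)) / 2 + hull_per / 2 + 1
  else area
  solidity <- min(area / max(hull_area, 1), 1)
  convexity <- min(hull_per / per, 1)
  c(artery_diameter = dm$d, artery_area = area, artery_angle = ang,
    artery_length = len, eccentricity = ecc, roundness = roundness,
    dispersion = dispersion, convexity = convexity, solidity = solidity,
    diameter_min = dm$d_min)
}

#' Extract the full feature table of a segmentation
#'
#' One row per artery region with the threefold feature catalogue:
#' 5 color, 4 texture and 9 shape descriptors (plus `diameter_min`).
#'
#' @param image Original intensity image.
#' @param regions An `angio_regions` (from [estimate_artery_angles()]) or
#'   a binary mask, in which case regions are derived first.
#' @param sample_id Identifier copied into the table.
#' @param glcm_levels Quantization levels for texture features.
#' @return Data frame, one row per region; empty (0 rows) for an empty
#'   segmentation.
#' @export
extract_features <- function(image, regions, sample_id = NA,
                             glcm_levels = 32L) {
  if (is.matrix(regions)) regions <- estimate_artery_angles(regions)
  stopifnot(inherits(regions, "angio_regions"))
  n <- nrow(regions$regions)
  rows <- vector("list", n)
  mask0 <- matrix(0L, nrow(image), ncol(image))
  for (i in seq_len(n)) {
    pix <- regions$pixels[[i]]
    if (nrow(pix) < 2) next
    col <- color_features(image, pix)
    tex <- texture_features(image, pix, glcm_levels)
    shp <- shape_features(mask0, pix)
    shp["artery_angle"] <- regions$regions$angle_deg[i]
    shp["artery_length"] <- regions$regions$length_px[i]
    rows[[i]] <- data.frame(sample_id = sample_id, region_id = i,
                            t(col), t(tex), t(shp))
  }
  rows <- Filter(Negate(is.null), rows)
  if (!length(rows)) {
    out <- data.frame(sample_id = character(), region_id = integer())
    return(out)
  }
  do.call(rbind, rows)
}
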