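# Region-level geometry: skeletonization, connected components, per-artery
# angle/length/width estimation, and crossing splitting.

shift_mat <- function(m, dr, dc) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(FALSE, h, w)
  rs <- seq_len(h) + dr; cs <- seq_len(w) + dc
  ok_r <- rs >= 1 & rs <= h; ok_c <- cs >= 1 & cs <= w
  out[ok_r, ok_c] <- m[rs[ok_r], cs[ok_c]]
  out
}

#' Morphological skeleton (Zhang-Suen thinning)
#'
#' Iteratively thins a binary mask to a one-pixel-wide skeleton,
#' preserving connectivity. Used for artery length and diameter
#' measurements.
#'
#' @param mask Binary matrix (0/1 or logical).
#' @return Logical matrix of skeleton pixels.
#' @export
skeletonize <- function(mask) {
  m <- mask > 0
  if (!any(m)) return(m)
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      # neighbours clockwise from north: P2..P9
      p2 <- shift_mat(m, -1, 0);  p3 <- shift_mat(m, -1, 1)
      p4 <- shift_mat(m, 0, 1);   p5 <- shift_mat(m, 1, 1)
      p6 <- shift_mat(m, 1, 0);   p7 <- shift_mat(m, 1, -1)
      p8 <- shift_mat(m, 0, -1);  p9 <- shift_mat(m, -1, -1)
      bn <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      a <- (!p2 & p3) + (!p3 & p4) + (!p4 & p5) + (!p5 & p6) +
           (!p6 & p7) + (!p7 & p8) + (!p8 & p9) + (!p9 & p2)
      if (step == 1) {
        cond <- m & bn >= 2 & bn <= 6 & a == 1 &
          !(p2 & p4 & p6) & !(p4 & p6 & p8)
      } else {
        cond <- m & bn >= 2 & bn <= 6 & a == 1 &
          !(p2 & p4 & p8) & !(p2 & p6 & p8)
      }
      if (any(cond)) {
        m[cond] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m
}

# Connected components of a binary mask; returns list of coordinate
# matrices (row, col). Uses EBImage labelling.
mask_components <- function(mask) {
  lab <- EBImage::bwlabel(matrix(as.numeric(mask > 0), nrow(mask)))
  lab <- matrix(as.integer(lab), nrow(mask))
  k <- max(lab)
  if (k == 0) return(list())
  idx <- which(lab > 0)
  ord <- split(idx, lab[idx])
  lapply(ord, function(ii)
    cbind(row = (ii - 1L) %% nrow(mask) + 1L,
          col = (ii - 1L) %/% nrow(mask) + 1L))
}

# Total length of a skeleton point set: weight of the Euclidean minimum
# spanning tree (Prim), a robust geodesic-extent proxy for thin sets.
skeleton_length <- function(pts) {
  n <- nrow(pts)
  if (n <= 1) return(as.numeric(n))
  if (n > 1500) pts <- pts[sort(sample.int(n, 1500)), , drop = FALSE]
  n <- nrow(pts)
  intree <- logical(n)
  mind <- rep(Inf, n)
  intree[1] <- TRUE
  mind <- sqrt((pts[, 1] - pts[1, 1])^2 + (pts[, 2] - pts[1, 2])^2)
  mind[1] <- 0
  total <- 0
  for (i in seq_len(n - 1)) {
    j <- which.min(ifelse(intree, Inf, mind))
    total <- total + mind[j]
    intree[j] <- TRUE
    d <- sqrt((pts[, 1] - pts[j, 1])^2 + (pts[, 2] - pts[j, 2])^2)
    upd <- !intree & d < mind
    mind[upd] <- d[upd]
  }
  total
}

# Local orientation (deg in [0,180)) of the mask around a point, from the
# second moments of component pixels within a square window.
local_orientation <- function(comp, center, radius) {
  sel <- abs(comp[, 1] - center[1]) <= radius & abs(comp[, 2] - center[2]) <= radius
  if (sum(sel) < 3) return(NA_real_)
  principal_axis_angle(comp[sel, 1], comp[sel, 2])
}

# Cluster axial angles (period 180): sort, cut at circular gaps larger
# than `gap`; returns integer cluster assignment.
cluster_axial <- function(deg, gap) {
  n <- length(deg)
  o <- order(deg)
  d <- deg[o]
  gaps <- c(diff(d), d[1] + 180 - d[n])
  cuts <- which(gaps > gap)
  if (length(cuts) <= 1) return(rep(1L, n))
  cl <- integer(n)
  start <- if (n %in% cuts) 1L else {
    # rotate so the sequence starts after the last wrap-around cut
    max(cuts) + 1L
  }
  ord <- c(seq(start, n), if (start > 1) seq(1, start - 1))
  g <- 1L
  prev <- d[ord[1]]
  for (i in seq_along(ord)) {
    cur <- d[ord[i]]
    if (i > 1 && axial_diff(cur, prev) > gap) g <- g + 1L
    cl[o[ord[i]]] <- g
    prev <- cur
  }
  cl
}

#' Estimate per-artery regions from a binary mask
#'
#' Extracts connected components and describes each artery region: the
#' orientation of its principal axis (`angle_deg`, degrees in `[0, 180)`
#' with respect to the image x-axis), its geodesic skeleton length
#' (`length_px`) and its mean width (`mean_width_px = area / length`).
#' Components whose skeleton branches and whose local orientations split
#' into groups further apart than `split_angle` (vessel crossings) are
#' divided into one region per orientation group.
#'
#' @param mask Binary matrix; an empty mask yields an empty region table.
#' @param split_angle Angular threshold (degrees) above which orientation
#'   groups at a skeleton branching are treated as distinct crossing
#'   vessels.
#' @return Object of class `angio_regions`: list with `regions` (data
#'   frame: `region_id`, `angle_deg`, `length_px`, `mean_width_px`,
#'   `area_px`) and `pixels` (list of coordinate matrices, one per
#'   region).
#' @export
estimate_artery_angles <- function(mask, split_angle = 30) {
  stopifnot(is.matrix(mask))
  comps <- mask_components(mask)
  empty <- list(regions = data.frame(region_id = integer(), angle_deg = numeric(),
                                     length_px = numeric(), mean_width_px = numeric(),
                                     area_px = numeric()),
                pixels = list())
  if (!length(comps)) return(structure(empty, class = "angio_regions"))
  regions <- list(); pixels <- list()
  rid <- 0L
  for (comp in comps) {
    sub <- matrix(FALSE, nrow(mask), ncol(mask))
    sub[comp] <- TRUE
    skel <- skeletonize(sub)
    sk <- which(skel, arr.ind = TRUE)
    area <- nrow(comp)
    add_region <- function(angle, len, area_px, pix) {
      rid <<- rid + 1L
      regions[[rid]] <<- data.frame(region_id = rid, angle_deg = angle,
                                    length_px = len,
                                    mean_width_px = area_px / max(len, 1),
                                    area_px = area_px)
      pixels[[rid]] <<- pix
    }
    if (nrow(sk) < 2) {
      add_region(principal_axis_angle(comp[, 1], comp[, 2]), max(1, nrow(sk)),
                 area, comp)
      next
    }
    # branch points: skeleton pixels with >= 3 skeleton neighbours
    nb <- Reduce(`+`, lapply(list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1),
                                  c(0, 1), c(1, -1), c(1, 0), c(1, 1)),
                             function(s) shift_mat(skel, s[1], s[2])))
    bp <- which(skel & nb >= 3, arr.ind = TRUE)
    split_done <- FALSE
    if (nrow(bp) > 0 && nrow(sk) >= 8) {
      width_guess <- max(2, area / max(skeleton_length(sk), 1))
      rw <- max(4, ceiling(width_guess))
      far <- rep(TRUE, nrow(sk))
      for (b in seq_len(nrow(bp)))
        far <- far & (abs(sk[, 1] - bp[b, 1]) > 3 | abs(sk[, 2] - bp[b, 2]) > 3)
      cand <- sk[far, , drop = FALSE]
      if (nrow(cand) >= 4) {
        ori <- vapply(seq_len(nrow(cand)), function(i)
          local_orientation(comp, cand[i, ], rw), 0)
        ok <- is.finite(ori)
        cand <- cand[ok, , drop = FALSE]; ori <- ori[ok]
        if (length(ori) >= 4) {
          cl <- cluster_axial(ori, split_angle)
          if (max(cl) >= 2) {
            # assign every component pixel to its nearest oriented skeleton pixel
            assign_cl <- integer(nrow(comp))
            for (i in seq_len(nrow(comp))) {
              d2 <- (cand[, 1] - comp[i, 1])^2 + (cand[, 2] - comp[i, 2])^2
              assign_cl[i] <- cl[which.min(d2)]
            }
            for (g in sort(unique(cl))) {
              gsk <- cand[cl == g, , drop = FALSE]
              gpx <- comp[assign_cl == g, , drop = FALSE]
              if (!nrow(gpx)) next
              ang <- axial_mean(ori[cl == g])
              th <- ang * pi / 180
              proj <- gsk[, 2] * cos(th) - gsk[, 1] * sin(th)
              len <- max(diff(range(proj)), 1)
              add_region(ang, len, nrow(gpx), gpx)
            }
            split_done <- TRUE
          }
        }
      }
    }
    if (!split_done) {
      add_region(principal_axis_angle(comp[, 1], comp[, 2]),
                 max(skeleton_length(sk), 1), area, comp)
    }
  }
  structure(list(regions = do.call(rbind, regions), pixels = pixels),
            class = "angio_regions")
}

#' @export
print.angio_regions <- function(x, ...) {
  cat(sprintf("<angio_regions> %d region(s)\n", nrow(x$regions)))
  if (nrow(x$regions)) print(x$regions, row.names = FALSE)
  invisible(x)
}
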