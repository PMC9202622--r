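test_that("the diameter formula is the Euclidean distance", {
  expect_equal(angioseg:::euclid_d(0, 3, 0, 4), 5)
})

test_that("diameters are recovered from straight branches within 1 px", {
  errs <- vapply(1:20, function(seed) {
    d_true <- 3 + (seed %% 10)
    s <- generate_tree(straight_branch_config(size = 64, diameter = d_true),
                       seed = 100 + seed)
    dm <- measure_diameter(s$mask)
    abs(dm$d - d_true)
  }, 0)
  expect_lt(mean(errs), 1)
  expect_lt(max(errs), 1.5)
})

test_that("the stenotic minimum width matches the nominal narrowing", {
  s <- generate_tree(straight_branch_config(size = 64, diameter = 8,
                                            stenosis = 0.5), seed = 7)
  dm <- measure_diameter(s$mask)
  expect_lt(abs(dm$d_min - 8 * 0.5), 1)
  # boundary points of the reported ray straddle the vessel
  expect_equal(dm$d,
               angioseg:::euclid_d(dm$p["x"], dm$q["x"], dm$p["y"], dm$q["y"]),
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("color features are exact moments of the region intensities", {
  img <- matrix(100, 16, 16)
  region <- which(disk_mask(16, 5) == 1, arr.ind = TRUE)
  f <- color_features(img, region)
  expect_equal(unname(f["mean"]), 100)
  expect_equal(unname(f["standard_deviation"]), 0)
  expect_equal(unname(f["skewness"]), 0)      # constant-region convention
  expect_equal(unname(f["kurtosis"]), 3)
  set.seed(31)
  img2 <- matrix(rnorm(128 * 128, 120, 25), 128, 128)
  big <- which(matrix(TRUE, 128, 128), arr.ind = TRUE)
  f2 <- color_features(img2, big)
  v <- img2[big]
  # naive-loop oracle for the standardized moments
  n <- length(v); m <- sum(v) / n
  m2 <- sum((v - m)^2) / n; m3 <- sum((v - m)^3) / n; m4 <- sum((v - m)^4) / n
  expect_equal(unname(f2["mean"]), m, tolerance = 1e-9)
  expect_equal(unname(f2["skewness"]), m3 / m2^1.5, tolerance = 1e-9)
  expect_equal(unname(f2["kurtosis"]), m4 / m2^2, tolerance = 1e-9)
  expect_lt(abs(f2[["skewness"]]), 0.05)  # symmetric sample
})

test_that("local intensity measures region/ring contrast", {
  img <- matrix(50, 32, 32)
  d <- disk_mask(32, 6)
  img[d == 1] <- 90
  f <- color_features(img, which(d == 1, arr.ind = TRUE))
  expect_equal(unname(f["local_intensity"]), 40, tolerance = 1e-9)
})

test_that("glcm features are exact on degenerate and checkerboard regions", {
  img <- matrix(77, 12, 12)
  region <- which(matrix(TRUE, 12, 12), arr.ind = TRUE)
  f <- texture_features(img, region)
  expect_equal(unname(f["asm"]), 1)
  expect_equal(unname(f["homogeneity"]), 1)
  expect_equal(unname(f["entropy"]), 0)
  # checkerboard, horizontal offset only: hand-enumerated 2x2 co-occurrence
  cb <- outer(1:8, 1:8, function(i, j) (i + j) %% 2) * 100
  P <- angioseg:::glcm_matrix(cb, which(matrix(TRUE, 8, 8), arr.ind = TRUE),
                              levels = 2L)
  # oracle: enumerate all in-bounds pairs at the four offsets by loop
  cnt <- matrix(0, 2, 2)
  q <- cb / 100
  offs <- list(c(0, 1), c(-1, 1), c(-1, 0), c(-1, -1))
  for (off in offs) for (i in 1:8) for (j in 1:8) {
    i2 <- i + off[1]; j2 <- j + off[2]
    if (i2 < 1 || i2 > 8 || j2 < 1 || j2 > 8) next
    a <- q[i, j] + 1; b <- q[i2, j2] + 1
    cnt[a, b] <- cnt[a, b] + 1
    cnt[b, a] <- cnt[b, a] + 1
  }
  expect_equal(P, cnt / sum(cnt), tolerance = 1e-12, ignore_attr = TRUE)
  f2 <- texture_features(cb, which(matrix(TRUE, 8, 8), arr.ind = TRUE),
                         levels = 2L)
  expect_equal(unname(f2["asm"]), sum((cnt / sum(cnt))^2), tolerance = 1e-12)
})

test_that("texture features are shift invariant", {
  set.seed(32)
  img <- matrix(sample(0:60, 400, TRUE), 20, 20)
  region <- which(matrix(TRUE, 20, 20), arr.ind = TRUE)
  expect_equal(texture_features(img, region),
               texture_features(img + 57, region), tolerance = 1e-12)
})

test_that("single-pixel regions are rejected for texture", {
  expect_error(texture_features(matrix(1, 5, 5), cbind(2, 2)), "degenerate")
})

test_that("shape features describe a disk and a bar correctly", {
  size <- 48
  d <- disk_mask(size, 10)
  f <- shape_features(d)
  expect_gte(unname(f["roundness"]), 0.85)
  expect_lte(unname(f["roundness"]), 1)
  expect_lt(unname(f["eccentricity"]), 0.1)
  expect_gt(unname(f["solidity"]), 0.95)
  expect_equal(unname(f["artery_area"]), sum(d))
  bar <- bar_mask(120, 30, 6, length = 100)
  fb <- shape_features(bar)
  expect_gt(unname(fb["eccentricity"]), 0.95)
  d_ang <- abs(fb[["artery_angle"]] - 30) %% 180
  expect_lt(min(d_ang, 180 - d_ang), 2)
})

test_that("solidity is 1 for convex regions and below for concave ones", {
  rect <- matrix(0L, 30, 30); rect[5:24, 8:17] <- 1L
  expect_equal(unname(shape_features(rect)["solidity"]), 1)
  lshape <- rect; lshape[15:24, 13:17] <- 0L
  expect_lt(unname(shape_features(lshape)["solidity"]), 0.95)
})

test_that("artery angle rotates with the phantom", {
  for (ang in c(0, 30, 60, 90, 120, 150)) {
    m <- bar_mask(80, ang, 6, length = 60)
    f <- shape_features(m)
    d <- abs(f[["artery_angle"]] - ang) %% 180
    expect_lt(min(d, 180 - d), 2)
  }
})

test_that("every feature is finite on random phantom regions", {
  bad <- 0L
  for (seed in 1:40) {
    s <- generate_tree(phantom_config(size = 48, noise_sigma = 10),
                       seed = 600 + seed)
    tab <- extract_features(s$image, s$mask, sample_id = seed)
    if (!nrow(tab)) next
    num <- tab[, !(names(tab) %in% c("sample_id"))]
    bad <- bad + sum(!is.finite(as.matrix(num)))
  }
  expect_equal(bad, 0L)
})

test_that("feature invariants hold on phantom regions", {
  for (seed in 1:10) {
    s <- generate_tree(phantom_config(size = 48, noise_sigma = 8),
                       seed = 700 + seed)
    tab <- extract_features(s$image, s$mask)
    if (!nrow(tab)) next
    expect_true(all(tab$homogeneity >= 0 & tab$homogeneity <= 1))
    expect_true(all(tab$asm >= 0 & tab$asm <= 1))
    expect_true(all(tab$correlation >= -1 & tab$correlation <= 1))
    expect_true(all(tab$entropy >= 0))
    expect_true(all(tab$eccentricity >= 0 & tab$eccentricity < 1))
    expect_true(all(tab$solidity > 0 & tab$solidity <= 1))
    expect_true(all(tab$artery_area > 0))
  }
})
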