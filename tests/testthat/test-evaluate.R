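test_that("confusion metrics follow their defining ratios", {
  cc <- confusion_counts(tr_p = 9, tr_n = 8, fl_p = 2, fl_n = 1)
  m <- confusion_metrics(cc)
  expect_equal(unname(m["accuracy"]), 17 / 20)
  perfect <- confusion_metrics(confusion_counts(10, 10, 0, 0))
  expect_equal(unname(perfect), c(1, 1, 1))
  expect_error(confusion_counts(-1, 0, 0, 0), "nonnegative")
})

test_that("confusion metrics match a label-vector oracle", {
  set.seed(10)
  for (i in 1:200) {
    n <- sample(5:60, 1)
    truth <- sample(c(TRUE, FALSE), n, TRUE)
    pred <- sample(c(TRUE, FALSE), n, TRUE)
    cc <- confusion_counts(tr_p = sum(pred & truth),
                           tr_n = sum(!pred & !truth),
                           fl_p = sum(pred & !truth),
                           fl_n = sum(!pred & truth))
    m <- confusion_metrics(cc)
    expect_equal(unname(m["accuracy"]), mean(pred == truth), tolerance = 1e-12)
    if (any(truth))
      expect_equal(unname(m["sensitivity"]), mean(pred[truth]),
                   tolerance = 1e-12)
    if (any(!truth))
      expect_equal(unname(m["specificity"]), mean(!pred[!truth]),
                   tolerance = 1e-12)
  }
})

test_that("rcnr evaluates |In_A - In_B| / sigma_n", {
  img <- matrix(50, 20, 20)
  v <- matrix(0L, 20, 20); v[5:10, 5:10] <- 1L
  img[v == 1] <- 100
  b <- 1L - v
  expect_equal(rcnr(img, v, b, sigma_n = 25), 2)
  expect_equal(rcnr(img * 0 + 7, v, b, sigma_n = 3), 0)
  expect_error(rcnr(img, v, b, sigma_n = 0), "degenerate")
  expect_error(rcnr(img, v * 0L, b), "nonempty")
})

test_that("contrast enhancement raises the phantom rCNR", {
  wins <- 0L
  for (seed in 1:10) {
    s <- generate_tree(phantom_config(size = 64, noise_sigma = 10),
                       seed = seed)
    if (!any(s$mask > 0)) next
    ring <- !(EBImage::dilate(s$mask, EBImage::makeBrush(11, "disc")) > 0)
    raw <- rcnr(s$image, s$mask, ring)
    # the bare curvature response (no salience floor): noise stays
    # finite so the ratio comparison is meaningful
    enh0 <- principal_curvature_enhance(wiener_denoise(s$image), 2,
                                        noise_floor = 0)$enhanced
    wins <- wins + (rcnr(enh0, s$mask, ring) >= raw)
    # the full stage also floors background noise; on its own noise
    # level its rCNR is at least as large (infinite when sigma -> 0)
    enh <- principal_curvature_enhance(wiener_denoise(s$image), 2)$enhanced
    sigma_enh <- estimate_noise_power(enh)
    full <- if (sigma_enh > 0) rcnr(enh, s$mask, ring, sigma_n = sigma_enh)
            else Inf
    expect_gte(full, raw)
  }
  expect_gte(wins, 8)
})

test_that("mse is the mean of squared differences", {
  expect_equal(mse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(mse(c(0, 0, 0), c(1, 1, 1)), 1)
  set.seed(4)
  a <- rnorm(101); b <- rnorm(101)
  loop <- 0
  for (i in seq_along(a)) loop <- loop + (a[i] - b[i])^2
  expect_equal(mse(a, b), loop / length(a), tolerance = 1e-12)
  expect_error(mse(1:3, 1:4), "length")
})

test_that("dice and jaccard match a set-enumeration oracle", {
  m <- matrix(1L, 8, 8)
  expect_equal(unname(dice_jaccard(m, m)), c(1, 1))
  a <- matrix(0L, 8, 8); a[1:4, ] <- 1L
  b <- matrix(0L, 8, 8); b[5:8, ] <- 1L
  expect_equal(unname(dice_jaccard(a, b)), c(0, 0))
  both <- dice_jaccard(a * 0L, b * 0L)
  expect_equal(unname(both), c(1, 1), ignore_attr = TRUE)
  expect_true(attr(both, "both_empty"))
  set.seed(5)
  for (i in 1:100) {
    r <- random_mask(12, runif(1, 0.1, 0.9))
    p <- random_mask(12, runif(1, 0.1, 0.9))
    ref_set <- which(r == 1); prd_set <- which(p == 1)
    inter <- length(intersect(ref_set, prd_set))
    uni <- length(union(ref_set, prd_set))
    dj <- dice_jaccard(r, p)
    if (uni == 0) next
    expect_equal(unname(dj["dice"]),
                 2 * inter / (length(ref_set) + length(prd_set)),
                 tolerance = 1e-12)
    expect_equal(unname(dj["jaccard"]), inter / uni, tolerance = 1e-12)
    expect_equal(unname(dj["dice"]),
                 2 * dj[["jaccard"]] / (1 + dj[["jaccard"]]),
                 tolerance = 1e-12)
  }
})

test_that("hausdorff equals the quadratic max-min oracle", {
  expect_equal(hausdorff(cbind(1:5, 1:5), cbind(1:5, 1:5)), 0)
  expect_equal(hausdorff(cbind(0, 0), cbind(3, 4)), 5)
  brute <- function(p, q) {
    dpq <- 0
    for (i in seq_len(nrow(p))) {
      best <- Inf
      for (j in seq_len(nrow(q)))
        best <- min(best, sqrt(sum((p[i, ] - q[j, ])^2)))
      dpq <- max(dpq, best)
    }
    dpq
  }
  set.seed(6)
  for (i in 1:50) {
    np_ <- sample(3:40, 1); nq_ <- sample(3:40, 1)
    p <- cbind(runif(np_, 0, 50), runif(np_, 0, 50))
    q <- cbind(runif(nq_, 0, 50), runif(nq_, 0, 50))
    expect_equal(hausdorff(p, q), max(brute(p, q), brute(q, p)),
                 tolerance = 1e-12)
    expect_equal(hausdorff(p, q), hausdorff(q, p))
  }
  expect_error(hausdorff(matrix(0L, 5, 5), cbind(1, 1)), "nonempty")
})

test_that("hausdorff satisfies the triangle inequality on random triples", {
  set.seed(7)
  for (i in 1:10) {
    p <- cbind(runif(10, 0, 20), runif(10, 0, 20))
    q <- cbind(runif(10, 0, 20), runif(10, 0, 20))
    r <- cbind(runif(10, 0, 20), runif(10, 0, 20))
    expect_lte(hausdorff(p, r), hausdorff(p, q) + hausdorff(q, r) + 1e-9)
  }
})

test_that("psnr follows its closed form", {
  a <- matrix(0, 10, 10)
  b <- a; b[] <- 255
  expect_equal(psnr(a, b, peak = 255), 0)  # mse = peak^2
  set.seed(8)
  ref <- matrix(runif(400, 0, 255), 20, 20)
  test_img <- ref + matrix(rep(c(1, -1), 200), 20, 20)  # mse exactly 1
  expect_equal(psnr(ref, test_img, peak = 255), 10 * log10(65025),
               tolerance = 1e-9)
  expect_equal(10 * log10(65025), 48.13, tolerance = 1e-3)
  id <- psnr(ref, ref)
  expect_true(is.infinite(id) && attr(id, "identical"))
})

test_that("denoising improves phantom PSNR", {
  wins <- 0L
  for (seed in 1:10) {
    s <- generate_tree(phantom_config(size = 64, noise_sigma = 15),
                       seed = seed)
    den <- wiener_denoise(s$image)
    wins <- wins + (psnr(s$clean, den) > psnr(s$clean, s$image))
  }
  expect_gte(wins, 9)
})

test_that("roc auc equals the pair-counting statistic", {
  r <- roc_curve(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(r$auc, 1)
  set.seed(9)
  null_auc <- roc_curve(rnorm(2000), rbinom(2000, 1, 0.5))$auc
  expect_lt(abs(null_auc - 0.5), 0.03)
  pair_count <- function(s, y) {
    pos <- s[y == 1]; neg <- s[y == 0]
    tot <- 0
    for (a in pos) for (b in neg)
      tot <- tot + (a > b) + 0.5 * (a == b)
    tot / (length(pos) * length(neg))
  }
  for (i in 1:100) {
    n <- sample(8:40, 1)
    s <- round(rnorm(n), 1)  # ties included
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) next
    expect_equal(roc_curve(s, y)$auc, pair_count(s, y), tolerance = 1e-12)
  }
  expect_error(roc_curve(1:5, rep(1, 5)), "both classes")
})

test_that("roc points form a monotone staircase", {
  set.seed(11)
  r <- roc_curve(rnorm(50), rbinom(50, 1, 0.5))
  expect_true(all(diff(r$points$fpr) >= 0))
  expect_true(all(diff(r$points$tpr) >= 0))
  expect_equal(r$points$fpr[1], 0)
  expect_equal(utils::tail(r$points$tpr, 1), 1)
})

test_that("segmentation accuracy equals a counting oracle", {
  m <- random_mask(10)
  expect_equal(segmentation_accuracy(m, m), 1)
  expect_equal(segmentation_accuracy(m, 1L - m), 0)
  set.seed(12)
  for (i in 1:20) {
    a <- random_mask(9); b <- random_mask(9)
    agree <- 0L
    for (j in seq_along(a)) agree <- agree + ((a[j] > 0) == (b[j] > 0))
    expect_equal(segmentation_accuracy(a, b), agree / length(a),
                 tolerance = 1e-12)
  }
})
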