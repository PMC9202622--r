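test_that("noise estimation recovers the generating sigma", {
  img <- matrix(128, 64, 64)
  expect_lt(estimate_noise_power(img), 1e-9)
  # piecewise-constant image: still zero
  pc <- img; pc[20:40, ] <- 60
  expect_lt(estimate_noise_power(pc), 1e-9)
  base <- matrix(128, 300, 300)
  est <- mean(vapply(1:10, function(i)
    estimate_noise_power(add_noise(base, 10, seed = i)), 0))
  expect_lt(abs(est - 10) / 10, 0.2)
  # doubling sigma roughly doubles the estimate
  e1 <- estimate_noise_power(add_noise(base, 5, seed = 1))
  e2 <- estimate_noise_power(add_noise(base, 10, seed = 2))
  expect_gt(e2 / e1, 1.6)
  expect_lt(e2 / e1, 2.4)
  expect_error(estimate_noise_power(matrix(0, 8, 8)), "16 x 16")
})

test_that("wiener filtering is the identity at zero noise power", {
  s <- generate_tree(phantom_config(size = 48, noise_sigma = 0), seed = 1)
  out <- wiener_denoise(s$clean, wiener_spec(noise_power = 0))
  expect_lt(max(abs(out - s$clean)) / max(abs(s$clean)), 1e-6)
})

test_that("wiener filtering annihilates pure noise given zero signal power", {
  noise <- add_noise(matrix(0, 32, 32) + 100, 10, seed = 3) - 100
  out <- wiener_denoise(noise, wiener_spec(noise_power = 10, signal_power = 0))
  expect_lt(stats::sd(out), stats::sd(noise) * 0.05)
})

test_that("wiener filtering reduces MSE on noisy phantoms", {
  wins <- 0L; n <- 0L
  for (sigma in c(5, 10, 20)) for (i in 1:5) {
    s <- generate_tree(phantom_config(size = 64, noise_sigma = 0),
                       seed = 10 * sigma + i)
    noisy <- add_noise(s$clean, sigma, seed = i)
    den <- wiener_denoise(noisy)
    n <- n + 1L
    wins <- wins + (mse(den, s$clean) < mse(noisy, s$clean))
  }
  expect_gte(wins / n, 0.95)
})

test_that("wiener rejects non-finite input", {
  bad <- matrix(1, 20, 20); bad[3, 3] <- NA
  expect_error(wiener_denoise(bad), "non-finite")
})

test_that("curvature of a constant image is identically zero", {
  out <- principal_curvature_enhance(matrix(7, 32, 32), scale_sigma = 2)
  cv <- out$curv
  for (f in c("k11", "k22", "k12", "G", "M", "gamma_minus", "gamma_plus"))
    expect_equal(max(abs(cv[[f]])), 0)
  expect_equal(max(abs(out$enhanced)), 0)
})

test_that("curvature fields satisfy the eigen identities", {
  s <- generate_tree(phantom_config(size = 64, noise_sigma = 10), seed = 5)
  cv <- principal_curvature_enhance(s$image, 2)$curv
  expect_lt(max(abs(cv$G - (cv$k11 * cv$k22 - cv$k12^2))), 1e-8)
  expect_lt(max(abs(cv$M - (cv$k11 + cv$k22) / 2)), 1e-8)
  expect_lt(max(abs(cv$gamma_minus * cv$gamma_plus - cv$G)), 1e-8)
  expect_lt(max(abs(cv$gamma_minus + cv$gamma_plus - 2 * cv$M)), 1e-8)
  expect_true(all(cv$gamma_minus <= cv$gamma_plus + 1e-12))
  # brute-force 2x2 eigendecomposition oracle at random pixels
  set.seed(1)
  for (k in 1:50) {
    i <- sample(nrow(cv$G), 1); j <- sample(ncol(cv$G), 1)
    ev <- sort(eigen(matrix(c(cv$k11[i, j], cv$k12[i, j],
                              cv$k12[i, j], cv$k22[i, j]), 2),
                     symmetric = TRUE)$values)
    expect_lt(abs(ev[1] - cv$gamma_minus[i, j]), 1e-8)
    expect_lt(abs(ev[2] - cv$gamma_plus[i, j]), 1e-8)
  }
})

test_that("a dark ridge is enhanced with its maximum on the centerline", {
  size <- 64
  img <- matrix(200, size, size)
  img[, 30:33] <- 80   # vertical dark ridge of width ~2*scale_sigma
  out <- principal_curvature_enhance(img, scale_sigma = 2)
  on_ridge <- mean(out$enhanced[10:54, 31:32])
  off_ridge <- mean(out$enhanced[10:54, c(5:20, 45:60)])
  expect_gt(on_ridge, 10 * max(off_ridge, 1e-9))
  raw_contrast <- mean(img[, 31:32]) / mean(img[, c(5:20, 45:60)])
  enh_contrast <- on_ridge / max(off_ridge, 1e-9)
  expect_gt(enh_contrast, 1 / raw_contrast)  # ridge/background ratio improved
})

test_that("otsu matches an exhaustive between-class-variance scan", {
  otsu_oracle <- function(img, levels = 256L) {
    q <- round(pmin(pmax(img, 0), levels - 1))
    s <- tabulate(as.integer(q) + 1L, nbins = levels) / length(q)
    lv <- 0:(levels - 1)
    best <- -Inf; bt <- NA
    for (t in 1:(levels - 1)) {
      w1 <- sum(s[1:t]); w2 <- 1 - w1
      if (w1 <= 0 || w2 <= 0) next
      mu1 <- sum(lv[1:t] * s[1:t]) / w1
      mu2 <- sum(lv[(t + 1):levels] * s[(t + 1):levels]) / w2
      bv <- w1 * w2 * (mu1 - mu2)^2
      if (bv > best + 1e-15) { best <- bv; bt <- t }
    }
    bt
  }
  for (seed in 1:10) {
    s <- generate_tree(phantom_config(size = 48, noise_sigma = 12), seed = seed)
    expect_identical(otsu_threshold(s$image)$threshold,
                     as.integer(otsu_oracle(s$image)))
  }
})

test_that("otsu separates a perfectly bimodal histogram exactly", {
  set.seed(2)
  img <- matrix(sample(c(10, 200), 400, TRUE, prob = c(0.3, 0.7)), 20, 20)
  ot <- otsu_threshold(img)
  expect_gt(ot$threshold, 10)
  expect_lte(ot$threshold, 200)
  expect_identical(ot$binary, matrix(as.integer(img == 200), 20, 20))
})

test_that("otsu threshold is shift-equivariant", {
  set.seed(3)
  img <- matrix(sample(40:120, 900, TRUE), 30, 30)
  t0 <- otsu_threshold(img)$threshold
  t1 <- otsu_threshold(img + 50)$threshold
  expect_identical(t1, t0 + 50L)
})

test_that("otsu state satisfies its conservation invariants", {
  s <- generate_tree(phantom_config(size = 48, noise_sigma = 10), seed = 9)
  st <- otsu_threshold(s$image)$state
  valid <- st$w1 > 0 & st$w2 > 0
  expect_lt(max(abs(st$w1 + st$w2 - 1)), 1e-12)
  expect_lt(max(abs((st$w1 * st$mu1 + st$w2 * st$mu2 - st$mun)[valid])), 1e-9)
  expect_lt(max(abs((st$between_var + st$within_var - st$total_var)[valid])),
            1e-9)
})

test_that("otsu flags a degenerate constant histogram", {
  expect_warning(out <- otsu_threshold(matrix(50, 16, 16)), "degenerate")
  expect_equal(sum(out$binary), 0)
})

test_that("the pipeline segments a clean single-vessel phantom well", {
  s <- generate_tree(straight_branch_config(size = 64, diameter = 8), seed = 6)
  out <- preprocess_pipeline(s$image)
  dj <- dice_jaccard(s$mask, out$binary)
  expect_gte(dj["dice"], 0.8)
})

test_that("an all-background phantom yields almost no foreground", {
  s <- generate_tree(phantom_config(size = 64, n_branches = c(0L, 0L),
                                    noise_sigma = 5), seed = 2)
  out <- preprocess_pipeline(s$image)
  expect_lt(mean(out$binary), 0.01)
})

test_that("the preprocessing pipeline is deterministic and range-safe", {
  s <- generate_tree(phantom_config(size = 48, noise_sigma = 10), seed = 11)
  a <- preprocess_pipeline(s$image)
  b <- preprocess_pipeline(s$image)
  expect_identical(a, b)
  expect_true(all(a$enhanced >= 0 & a$enhanced <= 255))
  expect_true(all(a$binary %in% c(0L, 1L)))
})

test_that("stage failures carry the stage identity", {
  expect_error(preprocess_pipeline(matrix(1, 4, 4)), "noise-estimate")
})
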