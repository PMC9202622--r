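gate_params_fixture <- function(cf, cg, ci, seed = 1) {
  set.seed(seed)
  list(W_F = matrix(rnorm(cf * ci), cf, ci), b_F = rnorm(ci),
       W_G = matrix(rnorm(cg * ci), cg, ci), b_G = rnorm(ci),
       W_theta = matrix(rnorm(ci), ci, 1), b_theta = rnorm(1))
}

# Scalar-loop recomputation of the gate equations, pixel by pixel.
gate_oracle <- function(f, g, p) {
  h <- dim(f)[1]; w <- dim(f)[2]
  out <- array(0, dim(f))
  alpha_map <- matrix(0, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    fv <- f[i, j, ]; gv <- g[i, j, ]
    comb <- pmax(drop(t(p$W_F) %*% fv) + p$b_F, 0) +
            (drop(t(p$W_G) %*% gv) + p$b_G)
    alpha <- 1 / (1 + exp(-(drop(t(p$W_theta) %*% comb) + p$b_theta)))
    out[i, j, ] <- fv * alpha
    alpha_map[i, j] <- alpha
  }
  list(out = out, alpha = alpha_map)
}

test_that("attention gate matches a scalar-loop oracle", {
  set.seed(21)
  f <- array(rnorm(4 * 4 * 3), c(4, 4, 3))
  g <- array(rnorm(4 * 4 * 2), c(4, 4, 2))
  p <- gate_params_fixture(3, 2, 5)
  got <- attention_gate(f, g, p)
  want <- gate_oracle(f, g, p)
  expect_lt(max(abs(got - want$out)), 1e-6)
  expect_lt(max(abs(attr(got, "alpha") - want$alpha)), 1e-6)
  expect_true(all(attr(got, "alpha") > 0 & attr(got, "alpha") < 1))
})

test_that("gate limits: zero coefficient head halves F, saturated head passes F", {
  set.seed(22)
  f <- array(rnorm(6 * 6 * 2), c(6, 6, 2))
  g <- array(rnorm(6 * 6 * 2), c(6, 6, 2))
  p <- gate_params_fixture(2, 2, 3)
  p$W_theta[] <- 0; p$b_theta <- 0
  expect_lt(max(abs(attention_gate(f, g, p) - f / 2)), 1e-12)
  p$b_theta <- 50
  expect_lt(max(abs(attention_gate(f, g, p) - f)), 1e-6)
})

test_that("spatially misaligned gate inputs are rejected", {
  f <- array(0, c(4, 4, 2)); g <- array(0, c(8, 8, 2))
  expect_error(attention_gate(f, g, gate_params_fixture(2, 2, 2)),
               "aligned")
})

test_that("network construction is seeded and shape-safe", {
  net1 <- build_network(segnet_config(seed = 5))
  net2 <- build_network(segnet_config(seed = 5))
  expect_identical(net1$params, net2$params)
  x <- array(runif(64 * 64 * 2), c(64, 64, 2))
  pm <- predict(net1, x)
  expect_equal(dim(pm), c(64, 64))
  expect_true(all(pm > 0 & pm < 1))
  expect_error(predict(net1, array(0, c(30, 30, 2))), "divisible")
})

test_that("attention gates add parameters", {
  with_g <- build_network(segnet_config(attention_on_skips = TRUE))
  without_g <- build_network(segnet_config(attention_on_skips = FALSE))
  expect_gt(sum(vapply(with_g$params, length, 0L)),
            sum(vapply(without_g$params, length, 0L)))
})

test_that("plain U-Net fallback builds and runs", {
  net <- build_network(segnet_config(nested_skips = FALSE, base_channels = 2))
  pm <- predict(net, array(runif(32 * 32 * 2), c(32, 32, 2)))
  expect_equal(dim(pm), c(32, 32))
})

test_that("a one-sample overfit run reaches near-perfect training dice", {
  s <- generate_tree(seg_phantom_config(), seed = 31)
  pre <- preprocess_pipeline(s$image)
  sample1 <- list(x = segnet_input(pre$binary, s$image), y = s$mask)
  net <- build_network(segnet_config(depth = 2, base_channels = 4, seed = 2))
  net <- train_segmenter(net, rep(list(sample1), 8),
                         train_config(lr = 3e-3, epochs = 25, seed = 3))
  expect_gte(utils::tail(net$dice_curve, 1), 0.95)
})

test_that("training is deterministic and its smoothed loss decreases early", {
  ph <- generate_phantom_set(8, seg_phantom_config(), seed = 41)
  samples <- lapply(ph, function(s) {
    pre <- preprocess_pipeline(s$image)
    list(x = segnet_input(pre$binary, s$image), y = s$mask)
  })
  hy <- train_config(lr = 3e-3, epochs = 6, seed = 9)
  n1 <- train_segmenter(build_network(tiny_seg_config()), samples, hy)
  n2 <- train_segmenter(build_network(tiny_seg_config()), samples, hy)
  expect_identical(n1$loss_curve, n2$loss_curve)
  expect_identical(n1$params, n2$params)
  smoothed <- stats::filter(n1$loss_curve, rep(1 / 2, 2), sides = 1)
  expect_true(all(diff(stats::na.omit(smoothed)[1:5]) < 0))
})

test_that("angle estimation recovers single-branch orientations within 2 degrees", {
  errs <- vapply(1:25, function(seed) {
    s <- generate_tree(straight_branch_config(size = 64, diameter = 6),
                       seed = seed)
    reg <- estimate_artery_angles(s$mask)
    expect_gte(nrow(reg$regions), 1)
    main <- which.max(reg$regions$area_px)
    d <- abs(reg$regions$angle_deg[main] - s$branches$angle_deg[1]) %% 180
    min(d, 180 - d)
  }, 0)
  expect_lt(max(errs), 2)
})

test_that("crossing branches are split into their two orientations", {
  m <- bar_mask(64, 0, 5) | bar_mask(64, 90, 5)
  reg <- estimate_artery_angles(matrix(as.integer(m), 64, 64))
  expect_gte(nrow(reg$regions), 2)
  angs <- reg$regions$angle_deg
  expect_true(any(pmin(angs %% 180, 180 - angs %% 180) < 5))
  expect_true(any(abs(angs - 90) < 5))
})

test_that("an empty mask yields an empty region table", {
  reg <- estimate_artery_angles(matrix(0L, 32, 32))
  expect_equal(nrow(reg$regions), 0)
  expect_length(reg$pixels, 0)
})

test_that("segment() honours its mask/AND contracts", {
  ph <- generate_phantom_set(8, seg_phantom_config(), seed = 51)
  samples <- lapply(ph, function(s) {
    pre <- preprocess_pipeline(s$image)
    list(x = segnet_input(pre$binary, s$image), y = s$mask)
  })
  net <- train_segmenter(build_network(tiny_seg_config()), samples,
                         train_config(lr = 3e-3, epochs = 10, seed = 1))
  s <- ph[[1]]
  pre <- preprocess_pipeline(s$image)
  out <- segment(s$image, pre$binary, net)
  expect_identical(out$masked_original, s$image * out$mask)
  expect_true(all(out$probability_map >= 0 & out$probability_map <= 1))
  # all-zero binarized input -> empty segmentation
  empty <- segment(s$image, matrix(0L, 32, 32), net)
  expect_equal(sum(empty$mask), 0)
  expect_equal(nrow(empty$regions$regions), 0)
  expect_true(all(empty$masked_original == 0))
  # untrained network refuses to run
  expect_error(segment(s$image, pre$binary, build_network(tiny_seg_config())),
               "not trained")
  expect_error(segment(s$image, matrix(1L, 8, 8), net), "shapes differ")
})
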