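# Shared fixtures, all generated in code at test time.

# Straight single-branch phantom with controllable geometry.
straight_branch_config <- function(size = 64, diameter = 6, noise = 0,
                                   stenosis = 0) {
  phantom_config(size = size, n_branches = c(1L, 1L),
                 diameter_range = c(diameter, diameter),
                 tortuosity = 0, branch_child_prob = 0,
                 stenosis_prob = if (stenosis > 0) 1 else 0,
                 stenosis_range = c(stenosis, stenosis + 1e-9),
                 background_amplitude = 0, noise_sigma = noise,
                 edge_softness = 0)
}

# Deterministic straight-bar mask at a given angle through the image
# centre (used when the exact orientation must be controlled).
bar_mask <- function(size, angle_deg, width, length = 0.8 * size) {
  th <- angle_deg * pi / 180
  c0 <- (size + 1) / 2
  rr <- matrix(seq_len(size), size, size)
  cc <- matrix(seq_len(size), size, size, byrow = TRUE)
  # signed distances along/across the bar axis (y up convention)
  u <- (cc - c0) * cos(th) + (-(rr - c0)) * sin(th)
  v <- -(cc - c0) * sin(th) + (-(rr - c0)) * cos(th)
  m <- abs(v) < width / 2 & abs(u) < length / 2
  matrix(as.integer(m), size, size)
}

# Filled disk mask.
disk_mask <- function(size, radius, c0 = (size + 1) / 2) {
  rr <- matrix(seq_len(size), size, size)
  cc <- matrix(seq_len(size), size, size, byrow = TRUE)
  matrix(as.integer((rr - c0)^2 + (cc - c0)^2 <= radius^2), size, size)
}

# Random binary mask with given foreground probability.
random_mask <- function(size, p = 0.3) {
  matrix(as.integer(stats::runif(size * size) < p), size, size)
}

# Desk-scale phantom set for segmentation work (32 px).
seg_phantom_config <- function(noise_sigma = 8) {
  phantom_config(size = 32, n_branches = c(1L, 3L),
                 diameter_range = c(3, 6), noise_sigma = noise_sigma)
}

# Classification study conditions: 64 px, 1-2 independent branches of
# 6-10 px calibre, stenoses of 50-70% when abnormal.
clf_phantom_config <- function() {
  phantom_config(size = 64, n_branches = c(1L, 2L),
                 diameter_range = c(6, 10), branch_child_prob = 0,
                 stenosis_range = c(0.5, 0.7), noise_sigma = 8)
}

tiny_seg_config <- function(seed = 4L)
  segnet_config(depth = 2L, base_channels = 4L, seed = seed)

tiny_run_config <- function(seed, preprocess_enabled = TRUE,
                            low_contrast = FALSE, epochs = 20L) {
  ph <- if (low_contrast) {
    # the regime multi-constraint preprocessing targets: weak vessel
    # contrast, strong structured background, heavy noise
    phantom_config(size = 32, n_branches = c(1L, 3L),
                   diameter_range = c(3, 6), vessel_intensity = 120,
                   background_intensity = 180, background_amplitude = 35,
                   noise_sigma = 20)
  } else {
    phantom_config(size = 32, n_branches = c(1L, 3L),
                   diameter_range = c(3, 6), noise_sigma = 8)
  }
  run_config(seed = seed, n_train = 16L, n_test = 6L, phantom = ph,
             preprocess_enabled = preprocess_enabled,
             segnet = segnet_config(depth = 2L, base_channels = 4L),
             seg_hyper = train_config(lr = 3e-3, epochs = epochs),
             classifier = vgg_config("tiny", input_size = c(16L, 16L, 1L),
                                     conv_blocks = list(4L), fc_sizes = 8L),
             clf_hyper = train_config(loss = "cross_entropy", lr = 1e-2,
                                      epochs = 10L, weight_decay = 10))
}
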