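#' Attention gate
#'
#' Learned sigmoid-bounded gating of encoder features on a skip
#' connection. With encoder feature stack `F` and (already upsampled)
#' gating signal `G`, the gate computes the combined map
#' `f = relu(W_F^T F + b_F) + (W_G^T G + b_G)`, the pixelwise attention
#' coefficient `alpha = sigmoid(W_theta^T f + b_theta)` (strictly inside
#' `(0, 1)`), and returns `F * alpha`. All projections are 1x1
#' convolutions, expressed as channel-mixing matrices.
#'
#' @param f Feature array `h x w x cF` (encoder skip features).
#' @param g Gating array `h x w x cG`, spatially aligned with `f`.
#' @param params List with `W_F` (`cF x ci`), `b_F` (`ci`), `W_G`
#'   (`cG x ci`), `b_G` (`ci`), `W_theta` (`ci x 1`), `b_theta` (scalar).
#' @return Gated feature array, same shape as `f`, with the coefficient
#'   map attached as attribute `"alpha"` (an `h x w` matrix).
#' @export
attention_gate <- function(f, g, params) {
  if (length(dim(f)) != 3 || length(dim(g)) != 3)
    stop_config("f and g must be h x w x c arrays")
  if (!all(dim(f)[1:2] == dim(g)[1:2]))
    stop_config("f and g are not spatially aligned: %dx%d vs %dx%d",
                dim(f)[1], dim(f)[2], dim(g)[1], dim(g)[2])
  h <- dim(f)[1]; w <- dim(f)[2]
  fm <- matrix(f, h * w, dim(f)[3])
  gm <- matrix(g, h * w, dim(g)[3])
  ff <- pmax(sweep(fm %*% params$W_F, 2, params$b_F, "+"), 0)
  fg <- sweep(gm %*% params$W_G, 2, params$b_G, "+")
  comb <- ff + fg
  alpha <- 1 / (1 + exp(-(comb %*% params$W_theta + params$b_theta)))
  out <- f * as.vector(alpha)
  attr(out, "alpha") <- matrix(alpha, h, w)
  out
}

# Seeded random initialization of attention-gate parameters.
init_gate_params <- function(cf, cg, ci) {
  list(W_F = matrix(stats::rnorm(cf * ci, 0, sqrt(2 / cf)), cf, ci),
       b_F = numeric(ci),
       W_G = matrix(stats::rnorm(cg * ci, 0, sqrt(2 / cg)), cg, ci),
       b_G = numeric(ci),
       W_theta = matrix(stats::rnorm(ci, 0, sqrt(1 / ci)), ci, 1),
       b_theta = 0)
}

# Tape version of the attention gate; parameters are 1x1 convs named
# <prefix>_{WF,bF,WG,bG,Wt,bt} in the tape's parameter list.
t_attention_gate <- function(tp, f, g, prefix) {
  ff <- t_relu(tp, t_conv(tp, f, paste0(prefix, "_WF"), paste0(prefix, "_bF")))
  fg <- t_conv(tp, g, paste0(prefix, "_WG"), paste0(prefix, "_bG"))
  comb <- t_add(tp, ff, fg)
  alpha <- t_sigmoid(tp, t_conv(tp, comb, paste0(prefix, "_Wt"), paste0(prefix, "_bt")))
  t_gate_mul(tp, f, alpha)
}

#' Nested U-Net configuration
#'
#' @param depth Number of pooling levels (>= 2); input sides must be
#'   divisible by `2^depth`.
#' @param base_channels Channels of the top encoder level; level `i`
#'   uses `base_channels * 2^i`.
#' @param nested_skips Use dense UNet++-style intermediate skip nodes;
#'   `FALSE` gives a plain U-Net decoder.
#' @param attention_on_skips Put an attention gate on every skip
#'   connection.
#' @param input_channels Input channels (2 when the binarized and
#'   original images are stacked).
#' @param seed Seed for parameter initialization.
#' @return Object of class `segnet_config`.
#' @export
segnet_config <- function(depth = 2L, base_channels = 8L, nested_skips = TRUE,
                          attention_on_skips = TRUE, input_channels = 2L,
                          seed = 1L) {
  if (depth < 2) stop_config("depth must be >= 2")
  if (base_channels < 1) stop_config("base_channels must be >= 1")
  structure(list(depth = as.integer(depth),
                 base_channels = as.integer(base_channels),
                 nested_skips = isTRUE(nested_skips),
                 attention_on_skips = isTRUE(attention_on_skips),
                 input_channels = as.integer(input_channels),
                 seed = as.integer(seed)),
            class = "segnet_config")
}

# Enumerate the UNet++ node grid: levels i = 1..D+1 (top to bottom),
# skip index j = 1..D+2-i; node (i, j > 1) consumes skips X[i, 1..j-1]
# plus the upsampled X[i+1, j-1]. Plain U-Net keeps only j == 1 encoders
# and the single decoder chain.
segnet_nodes <- function(config) {
  D <- config$depth
  ch <- function(i) config$base_channels * 2L^(i - 1L)
  nodes <- list()
  for (i in seq_len(D + 1L)) {
    jmax <- if (config$nested_skips) D + 2L - i else if (i <= D) 2L else 1L
    for (j in seq_len(jmax)) {
      if (j == 1L) {
        cin <- if (i == 1L) config$input_channels else ch(i - 1L)
      } else {
        nskip <- if (config$nested_skips) j - 1L else 1L
        cin <- nskip * ch(i) + ch(i + 1L)
      }
      nodes[[paste0("x", i, "_", j)]] <- list(i = i, j = j, cin = cin, cout = ch(i))
    }
  }
  nodes
}

#' Build an attention-gated nested U-Net
#'
#' Constructs the segmentation network with seeded parameter
#' initialization: an encoder-decoder with dense (UNet++-style) skip
#' pathways, an attention gate on every skip connection, and a sigmoid
#' 1x1 output head producing a probability map of the input's spatial
#' shape.
#'
#' @param config A [segnet_config()].
#' @return Object of class `angio_segmenter` (untrained).
#' @export
build_network <- function(config = segnet_config()) {
  stopifnot(inherits(config, "segnet_config"))
  nodes <- segnet_nodes(config)
  with_seed(config$seed, {
    params <- list()
    for (nm in names(nodes)) {
      nd <- nodes[[nm]]
      params[[paste0(nm, "_W")]] <- init_conv(3L, nd$cin, nd$cout)
      params[[paste0(nm, "_b")]] <- numeric(nd$cout)
      if (nd$j > 1L && config$attention_on_skips) {
        cf <- nd$cin - config$base_channels * 2L^nd$i  # skip channels
        cg <- config$base_channels * 2L^nd$i           # gating channels
        ci <- max(2L, cf %/% 2L)
        gp <- init_gate_params(cf, cg, ci)
        pre <- paste0("ag", nd$i, "_", nd$j)
        params[[paste0(pre, "_WF")]] <- array(gp$W_F, c(1L, 1L, cf, ci))
        params[[paste0(pre, "_bF")]] <- gp$b_F
        params[[paste0(pre, "_WG")]] <- array(gp$W_G, c(1L, 1L, cg, ci))
        params[[paste0(pre, "_bG")]] <- gp$b_G
        params[[paste0(pre, "_Wt")]] <- array(gp$W_theta, c(1L, 1L, ci, 1L))
        params[[paste0(pre, "_bt")]] <- 0
      }
    }
    head_cin <- config$base_channels
    params[["head_W"]] <- init_conv(1L, head_cin, 1L)
    params[["head_b"]] <- 0
    structure(list(config = config, params = params, trained = FALSE,
                   loss_curve = NULL, dice_curve = NULL),
              class = "angio_segmenter")
  })
}

#' @export
print.angio_segmenter <- function(x, ...) {
  np <- sum(vapply(x$params, length, 0L))
  cat(sprintf("<angio_segmenter> depth %d, base channels %d, %s skips, %s, %d parameters, %s\n",
              x$config$depth, x$config$base_channels,
              if (x$config$nested_skips) "nested" else "plain",
              if (x$config$attention_on_skips) "attention-gated" else "ungated",
              np, if (x$trained) "trained" else "untrained"))
  invisible(x)
}

# Forward graph on a tape; x is an input node, returns the sigmoid output.
segnet_forward <- function(tp, x, config) {
  D <- config$depth
  X <- list()
  key <- function(i, j) paste0("x", i, "_", j)
  conv_block <- function(inp, nm)
    t_relu(tp, t_conv(tp, inp, paste0(nm, "_W"), paste0(nm, "_b")))
  X[[key(1, 1)]] <- conv_block(x, key(1, 1))
  for (i in 2:(D + 1L))
    X[[key(i, 1)]] <- conv_block(t_pool2(tp, X[[key(i - 1L, 1)]]), key(i, 1))
  jtop <- if (config$nested_skips) D + 1L else 2L
  for (j in 2:jtop) {
    imax <- if (config$nested_skips) D + 2L - j else D
    ivals <- if (config$nested_skips) seq_len(imax) else rev(seq_len(imax))
    for (i in ivals) {
      below_j <- if (config$nested_skips) j - 1L else
        if (i == D) 1L else 2L
      up <- t_up2(tp, X[[key(i + 1L, below_j)]])
      skips <- if (config$nested_skips)
        lapply(seq_len(j - 1L), function(jj) X[[key(i, jj)]])
      else list(X[[key(i, 1L)]])
      fskip <- if (length(skips) > 1L) t_concat(tp, skips) else skips[[1]]
      if (config$attention_on_skips)
        fskip <- t_attention_gate(tp, fskip, up, paste0("ag", i, "_", j))
      X[[key(i, j)]] <- conv_block(t_concat(tp, list(fskip, up)), key(i, j))
    }
  }
  t_sigmoid(tp, t_conv(tp, X[[key(1L, jtop)]], "head_W", "head_b"))
}

#' Stack the segmentation network input
#'
#' Builds the 2-channel network input from a binarized image and the
#' original intensity image (scaled to `[0, 1]`).
#'
#' @param binary 0/1 matrix from the preprocessing stage.
#' @param original Intensity image in `[0, 255]`, same shape.
#' @return Array `h x w x 2`.
#' @export
segnet_input <- function(binary, original) {
  stopifnot(all(dim(binary) == dim(original)))
  array(c(binary, original / 255), c(dim(binary), 2L))
}

#' Predict a vessel probability map
#'
#' @param object A (trained) `angio_segmenter`.
#' @param x Input array `h x w x input_channels` (see `segnet_input`), or
#'   a list with `binary` and `image` matrices.
#' @param ... Unused.
#' @return Matrix of vessel probabilities in `[0, 1]`.
#' @export
predict.angio_segmenter <- function(object, x, ...) {
  if (is.list(x) && !is.array(x)) x <- segnet_input(x$binary, x$image)
  d <- dim(x)
  if (length(d) == 2L) x <- array(x, c(d, 1L))
  if (dim(x)[3] != object$config$input_channels)
    stop_config("expected %d input channels, got %d",
                object$config$input_channels, dim(x)[3])
  if (any(dim(x)[1:2] %% 2L^object$config$depth != 0L))
    stop_config("input %dx%d not divisible by 2^depth = %d (spatial collapse)",
                dim(x)[1], dim(x)[2], 2L^object$config$depth)
  tp <- new_tape(object$params)
  out <- segnet_forward(tp, t_input(tp, x), object$config)
  matrix(out$val, dim(x)[1], dim(x)[2])
}

#' Training hyperparameters
#'
#' @param loss Loss name (`"bce_dice"`: compound binary cross-entropy plus
#'   soft-Dice).
#' @param lr Adam learning rate.
#' @param epochs Training epochs.
#' @param batch_size Minibatch size.
#' @param weight_decay Decoupled (AdamW-style) weight decay applied to
#'   convolution and dense weights (not biases or the feature-attention
#'   head); regularizes the image path when training sets are small.
#' @param seed Seed covering shuffling and dropout.
#' @return Object of class `train_config`.
#' @export
train_config <- function(loss = "bce_dice", lr = 1e-3, epochs = 30L,
                         batch_size = 8L, weight_decay = 0, seed = 1L) {
  structure(list(loss = loss, lr = lr, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 weight_decay = weight_decay, seed = as.integer(seed)),
            class = "train_config")
}

#' Train the segmentation network
#'
#' Minibatch Adam training of the attention-gated nested U-Net on
#' phantom samples with exact ground-truth masks, using a compound
#' binary cross-entropy + soft-Dice loss. Fully seeded: the same
#' `(network, samples, hyper)` triple reproduces the same loss curve.
#'
#' @param network An `angio_segmenter` from [build_network()].
#' @param samples List of >= 8 training samples, each a list with `x`
#'   (input array, see `segnet_input`) and `y` (0/1 mask matrix); or
#'   `phantom_sample` objects, which are preprocessed automatically.
#' @param hyper A [train_config()].
#' @return The trained `angio_segmenter`, with `loss_curve` and
#'   `dice_curve` (per-epoch means) attached.
#' @export
train_segmenter <- function(network, samples, hyper = train_config()) {
  stopifnot(inherits(network, "angio_segmenter"))
  if (length(samples) < 8) stop_config("need at least 8 training samples")
  samples <- lapply(samples, function(s) {
    if (inherits(s, "phantom_sample")) {
      pre <- preprocess_pipeline(s$image)
      list(x = segnet_input(pre$binary, s$image), y = s$mask)
    } else s
  })
  params <- network$params
  opt <- adam_init(params)
  loss_curve <- numeric(hyper$epochs)
  dice_curve <- numeric(hyper$epochs)
  with_seed(hyper$seed, {
    for (ep in seq_len(hyper$epochs)) {
      ord <- sample(length(samples))
      ep_loss <- 0; ep_dice <- 0
      for (start in seq(1, length(ord), hyper$batch_size)) {
        batch <- ord[start:min(start + hyper$batch_size - 1L, length(ord))]
        grads <- NULL
        for (k in batch) {
          s <- samples[[k]]
          tp <- new_tape(params)
          out <- segnet_forward(tp, t_input(tp, s$x), network$config)
          l <- bce_dice_loss(as.vector(out$val), as.vector(s$y))
          if (!is.finite(l$loss))
            stop_config("NaN/Inf loss at epoch %d (sample %d); lower the learning rate",
                        ep, k)
          tape_backward(tp, out, array(l$grad, dim(out$val)))
          grads <- if (is.null(grads)) tp$pgrad
                   else Map(`+`, grads, tp$pgrad)
          ep_loss <- ep_loss + l$loss
          pm <- as.vector(out$val) >= 0.5
          yv <- as.vector(s$y) == 1
          ep_dice <- ep_dice + 2 * sum(pm & yv) / max(sum(pm) + sum(yv), 1)
        }
        grads <- lapply(grads, function(g) g / length(batch))
        st <- adam_step(params, grads, opt, lr = hyper$lr)
        params <- st$params; opt <- st$state
      }
      loss_curve[ep] <- ep_loss / length(samples)
      dice_curve[ep] <- ep_dice / length(samples)
    }
  })
  network$params <- params
  network$trained <- TRUE
  network$loss_curve <- loss_curve
  network$dice_curve <- dice_curve
  network
}

#' Segment an angiogram
#'
#' Runs the trained network on the stacked (binarized, original) input,
#' thresholds the probability map, estimates per-artery regions and
#' angles, and masks the original image (bitwise-AND of the binary mask
#' with the original intensities). An all-zero binarized input yields an
#' empty segmentation without invoking the network.
#'
#' @param original Original grayscale image in `[0, 255]`.
#' @param binary Binarized image (0/1) from the preprocessing stage.
#' @param network Trained `angio_segmenter`.
#' @param threshold Probability threshold for the binary mask.
#' @param split_angle Crossing-split angle for
#'   [estimate_artery_angles()].
#' @return Object of class `angio_segmentation`: list with
#'   `probability_map`, `mask` (0/1), `regions` (an `angio_regions`),
#'   and `masked_original`.
#' @export
segment <- function(original, binary, network, threshold = 0.5,
                    split_angle = 30) {
  check_image(original, "original")
  if (!all(dim(original) == dim(binary)))
    stop_config("original and binary shapes differ")
  if (!isTRUE(network$trained))
    stop_config("network is not trained; train or load one first")
  if (!any(binary > 0)) {
    prob <- matrix(0, nrow(original), ncol(original))
    mask <- matrix(0L, nrow(original), ncol(original))
    regions <- estimate_artery_angles(mask, split_angle)
    return(structure(list(probability_map = prob, mask = mask,
                          regions = regions,
                          masked_original = original * 0),
                     class = "angio_segmentation"))
  }
  prob <- predict(network, list(binary = binary, image = original))
  mask <- matrix(as.integer(prob >= threshold), nrow(prob), ncol(prob))
  regions <- estimate_artery_angles(mask, split_angle)
  structure(list(probability_map = prob, mask = mask, regions = regions,
                 masked_original = original * mask),
            class = "angio_segmentation")
}

#' @export
print.angio_segmentation <- function(x, ...) {
  cat(sprintf("<angio_segmentation> %dx%d, %d vessel pixel(s), %d region(s)\n",
              nrow(x$mask), ncol(x$mask), sum(x$mask), nrow(x$regions$regions)))
  invisible(x)
}
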