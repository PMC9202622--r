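#' Spatial attention map
#'
#' Channel-wise average pooling and max pooling of a feature stack give
#' two `h x w` maps; their 2-channel concatenation is passed through a
#' 7x7 convolution and a sigmoid, yielding a pixelwise attention map in
#' `(0, 1)` that is applied multiplicatively to the stack.
#'
#' @param feature_stack Array `h x w x c` (c >= 1).
#' @param kernel 7x7 convolution weights, array `7 x 7 x 2 x 1`.
#' @param bias Scalar bias.
#' @return Matrix `h x w` of attention coefficients, with the pooled maps
#'   attached as attributes `"F_A"` and `"F_M"`.
#' @export
spatial_attention <- function(feature_stack,
                              kernel = array(0, c(7, 7, 2, 1)),
                              bias = 0) {
  if (length(dim(feature_stack)) != 3 || dim(feature_stack)[3] < 1)
    stop_config("feature_stack must be an h x w x c array with c >= 1")
  if (!all(dim(kernel) == c(7, 7, 2, 1)))
    stop_config("kernel must be 7 x 7 x 2 x 1")
  fa <- apply(feature_stack, c(1, 2), mean)
  fm <- apply(feature_stack, c(1, 2), max)
  stack2 <- array(c(fa, fm), c(dim(fa), 2L))
  conv <- conv_fwd(stack2, kernel, bias)
  out <- 1 / (1 + exp(-conv[, , 1]))
  attr(out, "F_A") <- fa
  attr(out, "F_M") <- fm
  out
}

#' Softmax classification of a logit vector
#'
#' Numerically stable softmax (max subtraction). Probabilities are
#' strictly positive and sum to 1; the label is the argmax class with
#' ties broken toward the lower class index.
#'
#' @param logits Finite numeric vector, optionally named with class
#'   labels (default `c("normal", "abnormal")` when of length 2).
#' @return Object of class `class_probabilities`: list with
#'   `probabilities`, `label`, `logits`.
#' @export
softmax_classify <- function(logits) {
  if (!is.numeric(logits) || !all(is.finite(logits)))
    stop_config("logits must be finite numbers")
  nm <- names(logits)
  if (is.null(nm)) nm <- if (length(logits) == 2) c("normal", "abnormal")
                         else paste0("class", seq_along(logits))
  p <- exp(logits - max(logits))
  p <- pmax(p / sum(p), 1e-300)   # strictly positive even under underflow
  p <- p / sum(p)
  names(p) <- nm
  structure(list(probabilities = p, label = nm[which.max(p)], logits = logits),
            class = "class_probabilities")
}

#' @export
print.class_probabilities <- function(x, ...) {
  cat(sprintf("<class_probabilities> label = %s (%s)\n", x$label,
              paste(sprintf("%s = %.4f", names(x$probabilities),
                            x$probabilities), collapse = ", ")))
  invisible(x)
}

#' VGG-style classifier configuration
#'
#' The `"full"` preset is the canonical 16-layer stack: five 3x3
#' convolution blocks of 64/128/256/512/512 channels (2, 2, 3, 3, 3
#' convs), each followed by a 2x2 stride-2 max pool (224 -> 112 -> 56 ->
#' 28 -> 14 -> 7 spatial), then dense layers 25088 -> 4096 -> 4096 ->
#' `n_classes`. The `"tiny"` preset (32x32x1 input, blocks 8 and 16, one
#' 32-unit dense layer) trains in seconds on a CPU and is used
#' throughout the desk-scale tests. A spatial-attention block
#' (see [spatial_attention()]) acts on the output of `attention_block`
#' (the fourth block in the full preset), before its pool.
#'
#' @param preset `"tiny"` or `"full"`.
#' @param input_size Integer triple (h, w, channels).
#' @param conv_blocks List of per-block channel vectors.
#' @param fc_sizes Hidden dense-layer widths.
#' @param n_classes Output classes (2: normal/abnormal).
#' @param dropout_rate Dropout on dense layers during training.
#' @param attention_block Index of the conv block whose output receives
#'   spatial attention (pre-pool).
#' @param use_cnn,use_features Enable the CNN path on the masked image
#'   and/or the attention-weighted handcrafted-feature path; the final
#'   logits are the sum of the enabled paths.
#' @param seed Parameter-initialization seed.
#' @return Object of class `vgg_config`.
#' @export
vgg_config <- function(preset = c("tiny", "full"), input_size = NULL,
                       conv_blocks = NULL, fc_sizes = NULL, n_classes = 2L,
                       dropout_rate = NULL, attention_block = NULL,
                       use_cnn = TRUE, use_features = TRUE, seed = 1L) {
  preset <- match.arg(preset)
  if (preset == "full") {
    input_size <- input_size %||% c(224L, 224L, 3L)
    conv_blocks <- conv_blocks %||% list(c(64L, 64L), c(128L, 128L),
                                         c(256L, 256L, 256L),
                                         c(512L, 512L, 512L),
                                         c(512L, 512L, 512L))
    fc_sizes <- fc_sizes %||% c(4096L, 4096L)
    dropout_rate <- dropout_rate %||% 0.5
    attention_block <- attention_block %||% 4L
  } else {
    input_size <- input_size %||% c(32L, 32L, 1L)
    conv_blocks <- conv_blocks %||% list(4L, 8L)
    fc_sizes <- fc_sizes %||% 16L
    dropout_rate <- dropout_rate %||% 0.3
    attention_block <- attention_block %||% length(conv_blocks)
  }
  nb <- length(conv_blocks)
  if (input_size[1] %% 2L^nb != 0L || input_size[2] %% 2L^nb != 0L)
    stop_config("input %dx%d not divisible through %d pooling stages",
                input_size[1], input_size[2], nb)
  if (dropout_rate < 0 || dropout_rate >= 1)
    stop_config("dropout_rate must lie in [0, 1)")
  structure(list(preset = preset, input_size = as.integer(input_size),
                 conv_blocks = lapply(conv_blocks, as.integer),
                 fc_sizes = as.integer(fc_sizes),
                 n_classes = as.integer(n_classes),
                 dropout_rate = dropout_rate,
                 attention_block = as.integer(attention_block),
                 use_cnn = isTRUE(use_cnn), use_features = isTRUE(use_features),
                 seed = as.integer(seed)),
            class = "vgg_config")
}

#' Per-layer shape trace of a VGG configuration
#'
#' Computes, without instantiating any weights, the input and output
#' shape of every layer: each 3x3 stride-1 convolution preserves the
#' spatial size and sets the channel count, each 2x2 stride-2 max pool
#' halves the spatial size, and the dense layers map the flattened
#' feature vector through `fc_sizes` to `n_classes`.
#'
#' @param config A [vgg_config()].
#' @return Data frame with columns `layer`, `kernel`, `stride`, `in_h`,
#'   `in_w`, `in_c`, `out_h`, `out_w`, `out_c`.
#' @export
vgg_shape_trace <- function(config) {
  stopifnot(inherits(config, "vgg_config"))
  h <- config$input_size[1]; w <- config$input_size[2]; ch <- config$input_size[3]
  rows <- list()
  add <- function(layer, kernel, stride, oh, ow, oc) {
    rows[[length(rows) + 1L]] <<- data.frame(
      layer = layer, kernel = kernel, stride = stride,
      in_h = h, in_w = w, in_c = ch, out_h = oh, out_w = ow, out_c = oc)
    h <<- oh; w <<- ow; ch <<- oc
  }
  for (b in seq_along(config$conv_blocks)) {
    for (cout in config$conv_blocks[[b]])
      add(sprintf("Conv%d-%d", b, cout), "3 x 3", 1L, h, w, cout)
    add("maxpool", "2 x 2", 2L, h %/% 2L, w %/% 2L, ch)
  }
  flat <- h * w * ch
  h <- 1L; w <- 1L; ch <- flat
  for (f in c(config$fc_sizes, config$n_classes))
    add("fc", "1 x 1", NA_integer_, 1L, 1L, f)
  do.call(rbind, rows)
}

#' Build a VGG-style classifier
#'
#' Seeded construction of the convolutional classifier described by a
#' [vgg_config()], including the spatial-attention block and the
#' attention-estimator weights over the handcrafted feature columns.
#' The full preset holds ~138M parameters; pass `instantiate = FALSE`
#' (its default) to work with the architecture and
#' [vgg_shape_trace()] without allocating them.
#'
#' @param config A [vgg_config()].
#' @param n_features Number of handcrafted feature columns (for the
#'   feature path), default 20.
#' @param instantiate Allocate parameter arrays; defaults to `TRUE` for
#'   the tiny preset and `FALSE` for the full preset.
#' @return Object of class `angio_classifier` (untrained).
#' @export
build_vgg <- function(config = vgg_config("tiny"), n_features = 20L,
                      instantiate = config$preset != "full") {
  stopifnot(inherits(config, "vgg_config"))
  net <- structure(list(config = config, params = NULL, trained = FALSE,
                        n_features = as.integer(n_features),
                        feature_names = NULL, feature_center = NULL,
                        feature_scale = NULL, loss_curve = NULL),
                   class = "angio_classifier")
  if (!instantiate) return(net)
  with_seed(config$seed, {
    params <- list()
    cin <- config$input_size[3]
    for (b in seq_along(config$conv_blocks)) {
      for (k in seq_along(config$conv_blocks[[b]])) {
        cout <- config$conv_blocks[[b]][k]
        params[[sprintf("c%d_%d_W", b, k)]] <- init_conv(3L, cin, cout)
        params[[sprintf("c%d_%d_b", b, k)]] <- numeric(cout)
        cin <- cout
      }
    }
    params[["sa_W"]] <- init_conv(7L, 2L, 1L)
    params[["sa_b"]] <- 0
    nb <- length(config$conv_blocks)
    flat <- (config$input_size[1] %/% 2L^nb) *
            (config$input_size[2] %/% 2L^nb) * cin
    prev <- flat
    for (i in seq_along(config$fc_sizes)) {
      params[[sprintf("fc%d_W", i)]] <- init_dense(prev, config$fc_sizes[i])
      params[[sprintf("fc%d_b", i)]] <- numeric(config$fc_sizes[i])
      prev <- config$fc_sizes[i]
    }
    params[["out_W"]] <- init_dense(prev, config$n_classes)
    params[["out_b"]] <- numeric(config$n_classes)
    # handcrafted-feature path: softmax attention weights + linear head
    params[["attn_theta"]] <- numeric(n_features)
    params[["featB_W"]] <- matrix(0, config$n_classes, n_features)
    params[["featB_b"]] <- numeric(config$n_classes)
    net$params <- params
    net
  })
}

#' @export
print.angio_classifier <- function(x, ...) {
  np <- if (is.null(x$params)) 0 else sum(vapply(x$params, length, 0L))
  cat(sprintf("<angio_classifier> %s preset, %s, %s parameters, %s\n",
              x$config$preset,
              paste(c(if (x$config$use_cnn) "CNN path",
                      if (x$config$use_features) "feature path"),
                    collapse = " + "),
              format(np, big.mark = ","),
              if (x$trained) "trained" else "untrained"))
  invisible(x)
}

# CNN forward graph on a tape; returns the logit node.
vgg_forward <- function(tp, x, config, training = FALSE) {
  cur <- x
  for (b in seq_along(config$conv_blocks)) {
    for (k in seq_along(config$conv_blocks[[b]]))
      cur <- t_relu(tp, t_conv(tp, cur, sprintf("c%d_%d_W", b, k),
                               sprintf("c%d_%d_b", b, k)))
    if (b == config$attention_block) {
      amap <- t_sigmoid(tp, t_conv(tp, t_chanpool(tp, cur), "sa_W", "sa_b"))
      cur <- t_gate_mul(tp, cur, amap)
    }
    cur <- t_pool2(tp, cur)
  }
  cur <- t_flatten(tp, cur)
  for (i in seq_along(config$fc_sizes)) {
    cur <- t_relu(tp, t_dense(tp, cur, sprintf("fc%d_W", i), sprintf("fc%d_b", i)))
    cur <- t_dropout(tp, cur, config$dropout_rate, training)
  }
  t_dense(tp, cur, "out_W", "out_b")
}

#' Attention estimator over feature columns
#'
#' Standardizes a handcrafted feature matrix and scales its columns by a
#' softmax-normalized weight vector (the learnable feature-importance
#' weights; uniform `1/k` at initialization). Zero-variance columns are
#' dropped with a warning. During classifier training the weight logits
#' are learned jointly with the linear feature head; the learned weights
#' are exposed via [attention_weights()].
#'
#' @param features Numeric matrix (rows = samples) or list of named
#'   feature vectors.
#' @param theta Weight logits (default all zero: uniform weights).
#' @param center,scale Optional standardization statistics (training-set
#'   statistics at prediction time); computed from `features` if `NULL`.
#' @return List with `weighted` (weighted standardized matrix), `weights`
#'   (softmax weights, summing to 1), `center`, `scale`, `kept`
#'   (retained column names).
#' @export
attention_estimator <- function(features, theta = NULL, center = NULL,
                                scale = NULL) {
  if (is.list(features) && !is.data.frame(features))
    features <- do.call(rbind, features)
  features <- as.matrix(features)
  if (nrow(features) < 1) stop_config("need at least one feature vector")
  center <- center %||% colMeans(features)
  scale <- scale %||% apply(features, 2, stats::sd)
  if (nrow(features) == 1 && is.null(scale)) scale <- rep(1, ncol(features))
  scale[!is.finite(scale)] <- 0
  drop <- scale == 0
  if (any(drop)) {
    warning(sprintf("dropping %d zero-variance feature column(s): %s",
                    sum(drop), paste(colnames(features)[drop], collapse = ", ")))
  }
  kept <- which(!drop)
  z <- sweep(sweep(features[, kept, drop = FALSE], 2, center[kept]), 2,
             scale[kept], "/")
  theta <- theta %||% numeric(length(kept))
  w <- exp(theta - max(theta)); w <- w / sum(w)
  list(weighted = sweep(z, 2, w, "*"), weights = w,
       center = center[kept], scale = scale[kept],
       kept = colnames(features)[kept])
}

#' Learned feature-importance weights of a trained classifier
#'
#' @param object A trained `angio_classifier`.
#' @return Named numeric vector of softmax attention weights (sums to 1).
#' @export
attention_weights <- function(object) {
  stopifnot(inherits(object, "angio_classifier"))
  th <- object$params$attn_theta
  w <- exp(th - max(th)); w <- w / sum(w)
  names(w) <- object$feature_names
  w
}

#' Image-level feature vector for classification
#'
#' Aggregates the per-region threefold feature table of a segmented
#' angiogram into one vector: area-weighted means of the catalogue
#' features, total vessel area and length, the narrowest diameter, and
#' `stenosis_ratio`, the minimum over regions of
#' `diameter_min / artery_diameter` (1 = uniform calibre, small values =
#' focal narrowing).
#'
#' @param image Original intensity image.
#' @param mask Binary vessel mask.
#' @param glcm_levels Texture quantization levels.
#' @return Named numeric vector (all zeros, ratio 1, for an empty mask).
#' @export
classifier_features <- function(image, mask, glcm_levels = 16L) {
  feat_cols <- c("mean", "standard_deviation", "skewness", "kurtosis",
                 "local_intensity", "entropy", "correlation", "homogeneity",
                 "asm", "artery_diameter", "artery_angle", "eccentricity",
                 "roundness", "dispersion", "convexity", "solidity")
  empty <- c(stats::setNames(numeric(length(feat_cols)), feat_cols),
             total_area = 0, total_length = 0, diameter_min = 0,
             stenosis_ratio = 1, calibre_drop = 0, width_cv = 0)
  tab <- extract_features(image, mask, glcm_levels = glcm_levels)
  if (!nrow(tab)) return(empty)
  wts <- tab$artery_area / sum(tab$artery_area)
  agg <- vapply(feat_cols, function(cn) sum(tab[[cn]] * wts), 0)
  # calibre profile per connected component (not per crossing-split
  # region): the narrowest-to-median width ratio flags focal narrowing
  comps <- mask_components(mask)
  ratio <- 1; drop <- 0; wcv <- 0
  for (cc in comps) {
    if (nrow(cc) < 20) next
    dm <- measure_diameter(mask, cc)
    dmed <- max(dm$d, 1e-9)
    ratio <- min(ratio, dm$d_min / dmed)
    drop <- max(drop, dm$d - dm$d_min)
    if (length(dm$widths) > 1)
      wcv <- max(wcv, stats::sd(dm$widths) / dmed)
  }
  c(agg, total_area = sum(tab$artery_area),
    total_length = sum(tab$artery_length),
    diameter_min = min(tab$diameter_min),
    stenosis_ratio = ratio, calibre_drop = drop, width_cv = wcv)
}

# Internal: forward both paths for one prepared sample; returns logits,
# tape/out node (or NULL) and cached pieces needed for the backward pass.
clf_forward <- function(params, config, s, training = FALSE) {
  logits <- numeric(config$n_classes)
  tp <- NULL; out <- NULL
  if (config$use_cnn) {
    tp <- new_tape(params)
    out <- vgg_forward(tp, t_input(tp, s$x), config, training)
    logits <- logits + out$val
  }
  wx <- NULL; w <- NULL
  if (config$use_features) {
    th <- params$attn_theta
    w <- exp(th - max(th)); w <- w / sum(w)
    wx <- w * s$z
    logits <- logits + as.vector(params$featB_W %*% wx) + params$featB_b
  }
  list(logits = logits, tp = tp, out = out, w = w, wx = wx)
}

# Internal: accumulate feature-path gradients for one sample.
clf_feature_grads <- function(grads, params, s, w, gvec) {
  grads$featB_W <- grads$featB_W + outer(gvec, w * s$z)
  grads$featB_b <- grads$featB_b + gvec
  dwx <- as.vector(crossprod(params$featB_W, gvec))
  dw <- dwx * s$z
  grads$attn_theta <- grads$attn_theta + w * (dw - sum(dw * w))
  grads
}

#' Train the normal/abnormal classifier
#'
#' Joint Adam training of the two classification paths on labeled
#' samples: the VGG-style CNN on the masked (segmented) image, and the
#' linear head on attention-weighted standardized handcrafted features.
#' Cross-entropy loss; all randomness (shuffling, dropout) is seeded.
#'
#' @param network An `angio_classifier` from [build_vgg()].
#' @param samples List of labeled samples: each a list with `label`
#'   (`"normal"`/`"abnormal"`) plus either `image` and `mask` matrices
#'   (features and the CNN input are derived) or a precomputed named
#'   `features` vector (feature path only).
#' @param hyper A [train_config()] (default: cross-entropy, Adam,
#'   `lr = 1e-4`, 30 epochs).
#' @return The trained `angio_classifier` with `loss_curve` and the
#'   feature standardization statistics attached.
#' @export
train_classifier <- function(network, samples,
                             hyper = train_config(loss = "cross_entropy",
                                                  lr = 1e-4)) {
  stopifnot(inherits(network, "angio_classifier"))
  config <- network$config
  labels <- vapply(samples, function(s) s$label, "")
  if (length(unique(labels)) < 2)
    stop_config("training set contains a single class")
  y <- ifelse(labels == "abnormal", 2L, 1L)
  fmat <- NULL
  if (config$use_features) {
    fl <- lapply(samples, function(s) {
      if (!is.null(s$features)) s$features
      else classifier_features(s$image, s$mask)
    })
    fmat <- do.call(rbind, fl)
    ae <- attention_estimator(fmat)
    network$feature_names <- ae$kept
    network$feature_center <- ae$center
    network$feature_scale <- ae$scale
    fz <- sweep(sweep(fmat[, ae$kept, drop = FALSE], 2, ae$center), 2,
                ae$scale, "/")
  }
  if (is.null(network$params) || length(network$params$attn_theta) !=
      (if (config$use_features) length(network$feature_names) else network$n_features)) {
    k <- if (config$use_features) length(network$feature_names) else network$n_features
    network <- build_vgg(config, n_features = k, instantiate = TRUE)
    if (config$use_features) {
      ae <- attention_estimator(fmat)
      network$feature_names <- ae$kept
      network$feature_center <- ae$center
      network$feature_scale <- ae$scale
    }
  }
  prep <- lapply(seq_along(samples), function(i) {
    s <- samples[[i]]
    x <- NULL
    if (config$use_cnn) {
      img <- if (!is.null(s$image)) {
        m <- if (!is.null(s$mask)) s$image * (s$mask > 0) else s$image
        resize_nn(m, config$input_size[1], config$input_size[2]) / 255
      } else matrix(0, config$input_size[1], config$input_size[2])
      x <- array(img, c(config$input_size[1], config$input_size[2], 1L))
      if (config$input_size[3] > 1)
        x <- array(rep(x, config$input_size[3]),
                   c(dim(img), config$input_size[3]))
    }
    list(x = x, z = if (config$use_features) fz[i, ] else NULL, y = y[i])
  })
  params <- network$params
  opt <- adam_init(params)
  loss_curve <- numeric(hyper$epochs)
  with_seed(hyper$seed, {
    for (ep in seq_len(hyper$epochs)) {
      ord <- sample(length(prep))
      ep_loss <- 0
      for (start in seq(1, length(ord), hyper$batch_size)) {
        batch <- ord[start:min(start + hyper$batch_size - 1L, length(ord))]
        grads <- lapply(params, zeros_like)
        for (kk in batch) {
          s <- prep[[kk]]
          fw <- clf_forward(params, config, s, training = TRUE)
          l <- softmax_ce_loss(fw$logits, s$y)
          if (!is.finite(l$loss))
            stop_config("NaN/Inf loss at epoch %d; lower the learning rate", ep)
          ep_loss <- ep_loss + l$loss
          if (config$use_cnn) {
            tape_backward(fw$tp, fw$out, l$grad)
            grads <- Map(`+`, grads, fw$tp$pgrad)
          }
          if (config$use_features)
            grads <- clf_feature_grads(grads, params, s, fw$w, l$grad)
        }
        grads <- lapply(grads, function(g) g / length(batch))
        st <- adam_step(params, grads, opt, lr = hyper$lr)
        params <- st$params; opt <- st$state
        wd <- hyper$weight_decay %||% 0
        if (wd > 0) {
          decay_nms <- grep("^(c\\d+_\\d+|fc\\d+|out|sa)_W$", names(params),
                            value = TRUE)
          for (nm in decay_nms)
            params[[nm]] <- params[[nm]] * (1 - hyper$lr * wd)
        }
      }
      loss_curve[ep] <- ep_loss / length(prep)
    }
  })
  network$params <- params
  network$trained <- TRUE
  network$loss_curve <- loss_curve
  network
}

#' Classify angiogram samples
#'
#' @param object A trained `angio_classifier`.
#' @param samples List of samples as in [train_classifier()] (labels not
#'   required).
#' @param ... Unused.
#' @return Data frame with `p_normal`, `p_abnormal`, `label`.
#' @export
predict.angio_classifier <- function(object, samples, ...) {
  if (!isTRUE(object$trained)) stop_config("classifier is not trained")
  config <- object$config
  rows <- lapply(samples, function(s) {
    z <- NULL
    if (config$use_features) {
      f <- if (!is.null(s$features)) s$features
           else classifier_features(s$image, s$mask)
      f <- f[object$feature_names]
      z <- (f - object$feature_center) / object$feature_scale
    }
    x <- NULL
    if (config$use_cnn) {
      img <- if (!is.null(s$image)) {
        m <- if (!is.null(s$mask)) s$image * (s$mask > 0) else s$image
        resize_nn(m, config$input_size[1], config$input_size[2]) / 255
      } else matrix(0, config$input_size[1], config$input_size[2])
      x <- array(img, c(config$input_size[1], config$input_size[2], 1L))
      if (config$input_size[3] > 1)
        x <- array(rep(x, config$input_size[3]), c(dim(img), config$input_size[3]))
    }
    fw <- clf_forward(object$params, config, list(x = x, z = z), training = FALSE)
    sc <- softmax_classify(fw$logits)
    data.frame(p_normal = sc$probabilities[1], p_abnormal = sc$probabilities[2],
               label = sc$label)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
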