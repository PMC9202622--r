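#' End-to-end run configuration
#'
#' Bundles every stage configuration for a reproducible pipeline run:
#' phantom generation, preprocessing, segmentation training, feature
#' extraction, classification, and evaluation. The split default mirrors
#' a 100:30 train/test division.
#'
#' @param seed Master seed; every stage derives its own stream from it.
#' @param n_train,n_test Phantom counts for the two splits.
#' @param phantom A [phantom_config()].
#' @param preprocess_enabled Toggle the multi-constraint preprocessing
#'   stage; when off, the segmenter consumes a raw Otsu binarization of
#'   the noisy image (the ablation arm).
#' @param preprocess A [preprocess_config()].
#' @param segnet A [segnet_config()].
#' @param seg_hyper,clf_hyper [train_config()]s for the two networks.
#' @param classifier A [vgg_config()].
#' @param mask_threshold Probability threshold for the segmentation mask.
#' @param out_dir Optional run directory; when given, the config
#'   snapshot, per-stage outputs, metrics report and a log are written
#'   there.
#' @param verbose Print stage progress.
#' @return Object of class `run_config`.
#' @export
run_config <- function(seed = 1L, n_train = 100L, n_test = 30L,
                       phantom = phantom_config(),
                       preprocess_enabled = TRUE,
                       preprocess = preprocess_config(),
                       segnet = segnet_config(),
                       seg_hyper = train_config(),
                       classifier = vgg_config("tiny"),
                       clf_hyper = train_config(loss = "cross_entropy",
                                                lr = 1e-3, epochs = 20L),
                       mask_threshold = 0.5,
                       out_dir = NULL, verbose = FALSE) {
  structure(list(seed = as.integer(seed), n_train = as.integer(n_train),
                 n_test = as.integer(n_test), phantom = phantom,
                 preprocess_enabled = isTRUE(preprocess_enabled),
                 preprocess = preprocess, segnet = segnet,
                 seg_hyper = seg_hyper, classifier = classifier,
                 clf_hyper = clf_hyper, mask_threshold = mask_threshold,
                 out_dir = out_dir, verbose = isTRUE(verbose)),
            class = "run_config")
}

# Strip classes recursively so a config can round-trip through JSON.
config_snapshot <- function(x) {
  if (is.list(x)) return(lapply(unclass(x), config_snapshot))
  x
}

#' Run the full pipeline
#'
#' Executes, in order: phantom generation (balanced train/test splits),
#' preprocessing, segmenter training, segmentation of both splits,
#' feature extraction, classifier training on the training split,
#' classification of the test split, and the full metric suite on the
#' test split. Deterministic under a fixed `config$seed`. Any stage
#' failure is re-signalled with the stage name attached.
#'
#' @param config A [run_config()].
#' @return Object of class `metrics_report` (see Details) with
#'   classification metrics (accuracy, sensitivity, specificity, AUC),
#'   segmentation metrics (mean Dice, Jaccard, Hausdorff, pixel
#'   accuracy), image-quality metrics (PSNR, rCNR, MSE), per-sample
#'   tables, and the trained networks.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (config$verbose) message(sprintf(...))
  stage <- function(what, expr) {
    tryCatch(expr, error = function(e)
      stop_config("pipeline stage '%s' failed: %s", what, conditionMessage(e)))
  }
  log_lines <- character()
  note <- function(...) {
    log_lines <<- c(log_lines, sprintf(...))
    say(...)
  }

  note("generating %d train + %d test phantoms (size %d, sigma %g)",
       config$n_train, config$n_test, config$phantom$size,
       config$phantom$noise_sigma)
  train <- stage("phantom", generate_phantom_set(
    config$n_train, config$phantom, seed = child_seed(config$seed, 1L)))
  test <- stage("phantom", generate_phantom_set(
    config$n_test, config$phantom, seed = child_seed(config$seed, 2L)))

  note("preprocessing (%s)",
       if (config$preprocess_enabled) "wiener + curvature + otsu" else "raw otsu only")
  prep_one <- function(s) {
    if (config$preprocess_enabled) {
      pre <- preprocess_pipeline(s$image, config$preprocess)
      list(binary = pre$binary, denoised = pre$denoised,
           enhanced = pre$enhanced, noise_sigma = pre$noise_sigma)
    } else {
      ots <- otsu_threshold(s$image, foreground = "dark")
      list(binary = ots$binary, denoised = s$image, enhanced = s$image,
           noise_sigma = estimate_noise_power(s$image))
    }
  }
  pre_train <- stage("preprocess", lapply(train, prep_one))
  pre_test <- stage("preprocess", lapply(test, prep_one))

  note("training segmenter (%d epochs)", config$seg_hyper$epochs)
  seg_cfg <- config$segnet
  seg_cfg$seed <- as.integer(child_seed(config$seed, 3L) %% 2^31)
  seg_hyper <- config$seg_hyper
  seg_hyper$seed <- as.integer(child_seed(config$seed, 4L) %% 2^31)
  seg_samples <- Map(function(s, p)
    list(x = segnet_input(p$binary, s$image), y = s$mask), train, pre_train)
  segnet <- stage("train-segmenter",
                  train_segmenter(build_network(seg_cfg), seg_samples, seg_hyper))

  note("segmenting both splits")
  seg_train <- stage("segment", Map(function(s, p)
    segment(s$image, p$binary, segnet, config$mask_threshold), train, pre_train))
  seg_test <- stage("segment", Map(function(s, p)
    segment(s$image, p$binary, segnet, config$mask_threshold), test, pre_test))

  note("training classifier (%d epochs)", config$clf_hyper$epochs)
  clf_cfg <- config$classifier
  clf_cfg$seed <- as.integer(child_seed(config$seed, 5L) %% 2^31)
  clf_hyper <- config$clf_hyper
  clf_hyper$seed <- as.integer(child_seed(config$seed, 6L) %% 2^31)
  clf_samples <- Map(function(s, g)
    list(image = s$image, mask = g$mask, label = s$label), train, seg_train)
  classifier <- stage("train-classifier",
                      train_classifier(build_vgg(clf_cfg), clf_samples, clf_hyper))

  note("classifying the test split")
  test_samples <- Map(function(s, g)
    list(image = s$image, mask = g$mask, label = s$label), test, seg_test)
  pred <- stage("classify", predict(classifier, test_samples))

  note("computing the metric suite")
  report <- stage("evaluate", metrics_report(test, pre_test, seg_test, pred))
  report$segmenter <- segnet
  report$classifier <- classifier
  report$train_dice <- utils::tail(segnet$dice_curve, 1)
  report$config <- config

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(config_snapshot(config),
                         file.path(config$out_dir, "config.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    jsonlite::write_json(report$summary,
                         file.path(config$out_dir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA)
    utils::write.csv(report$per_sample,
                     file.path(config$out_dir, "per_sample.csv"),
                     row.names = FALSE)
    for (i in seq_along(test)) {
      write_pgm(seg_test[[i]]$mask * 255,
                file.path(config$out_dir, sprintf("test_%02d_mask.pgm", i)))
    }
    writeLines(log_lines, file.path(config$out_dir, "run.log"))
  }
  report
}

#' Assemble the metric suite of a finished run
#'
#' @param samples List of ground-truth `phantom_sample`s (test split).
#' @param pre List of preprocessing results (with `denoised`, `enhanced`,
#'   `binary`).
#' @param seg List of `angio_segmentation`s for the same samples.
#' @param pred Prediction data frame from [predict.angio_classifier()].
#' @return Object of class `metrics_report`: list with `summary` (named
#'   list of scalar metrics), `per_sample` (data frame), `confusion`
#'   (a `confusion_counts`), `roc` (ROC points + AUC).
#' @export
metrics_report <- function(samples, pre, seg, pred) {
  n <- length(samples)
  per <- lapply(seq_len(n), function(i) {
    s <- samples[[i]]; p <- pre[[i]]; g <- seg[[i]]
    dj <- dice_jaccard(s$mask, g$mask)
    hd <- if (any(s$mask > 0) && any(g$mask > 0)) hausdorff(s$mask, g$mask)
          else NA_real_
    ps <- psnr(s$clean, p$denoised)
    ring <- !(EBImage::dilate(s$mask, EBImage::makeBrush(11, "disc")) > 0)
    rc_raw <- tryCatch(rcnr(s$image, s$mask, ring), error = function(e) NA_real_)
    # the enhanced field can be piecewise constant (noise floored to 0);
    # fall back to the raw image's noise level as sigma_n
    rc_enh <- tryCatch(rcnr(p$enhanced, s$mask, ring), error = function(e)
      tryCatch(rcnr(p$enhanced, s$mask, ring, sigma_n = p$noise_sigma),
               error = function(e2) NA_real_))
    data.frame(sample = i, label = s$label,
               dice = dj["dice"], jaccard = dj["jaccard"], hausdorff = hd,
               sa = segmentation_accuracy(s$mask, g$mask),
               psnr = if (is.infinite(ps)) NA_real_ else ps,
               mse = mse(s$clean, p$denoised),
               rcnr_raw = rc_raw, rcnr = rc_enh)
  })
  per <- do.call(rbind, per)
  rownames(per) <- NULL
  truth <- vapply(samples, function(s) s$label, "")
  cc <- confusion_counts(
    tr_p = sum(pred$label == "abnormal" & truth == "abnormal"),
    tr_n = sum(pred$label == "normal" & truth == "normal"),
    fl_p = sum(pred$label == "abnormal" & truth == "normal"),
    fl_n = sum(pred$label == "normal" & truth == "abnormal"))
  cm <- confusion_metrics(cc)
  roc <- if (length(unique(truth)) == 2)
    roc_curve(pred$p_abnormal, truth == "abnormal") else NULL
  summary <- list(accuracy = unname(cm["accuracy"]),
                  sensitivity = unname(cm["sensitivity"]),
                  specificity = unname(cm["specificity"]),
                  auc = if (!is.null(roc)) roc$auc else NA_real_,
                  dice = mean(per$dice), jaccard = mean(per$jaccard),
                  hausdorff = mean(per$hausdorff, na.rm = TRUE),
                  sa = mean(per$sa),
                  psnr = mean(per$psnr, na.rm = TRUE),
                  mse = mean(per$mse),
                  rcnr = mean(per$rcnr, na.rm = TRUE))
  structure(list(summary = summary, per_sample = per, confusion = cc,
                 roc = roc),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  s <- x$summary
  cat("<metrics_report>\n")
  cat(sprintf("  classification: accuracy %.3f, sensitivity %.3f, specificity %.3f, AUC %.3f\n",
              s$accuracy, s$sensitivity, s$specificity, s$auc))
  cat(sprintf("  segmentation:   dice %.3f, jaccard %.3f, hausdorff %.2f px, pixel accuracy %.3f\n",
              s$dice, s$jaccard, s$hausdorff, s$sa))
  cat(sprintf("  image quality:  PSNR %.2f dB, rCNR %.2f, MSE %.2f\n",
              s$psnr, s$rcnr, s$mse))
  invisible(x)
}
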