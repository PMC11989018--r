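# End-to-end pipeline: synthetic images -> (optional) superpixel ROI
# segmentation -> multi-scale texture features standing in for three
# backbone outputs -> DWAFF fusion -> (optional) PSO/RDO wrapper feature
# selection -> classifier -> stratified K-fold evaluation.
#
# Four experimental scenarios are supported: "none" (no segmentation),
# "seg" (ROI segmentation), "seg_pso" and "seg_rdo" (segmentation plus
# wrapper feature selection). All fold-internal steps (class-mean offsets
# in faithful fusion, feature selection, classifier training) are fitted
# on training folds only.

#' Multi-scale texture feature extractor
#'
#' A lightweight stand-in for a deep-feature backbone: the image is
#' denoised with the adaptive fuzzy filter at the requested window scale,
#' then summarized by a 16-bin global intensity histogram plus first-order
#' statistics (mean, SD, skewness, histogram entropy, gradient energy,
#' dark-pixel fraction) and — when a segmentation ROI is available — an
#' additional ROI block: area fraction, within-ROI mean/SD, and
#' object-level morphology (component count, mean and SD of component
#' sizes, boundary-to-area ratio). The ROI block is precisely the
#' information a segmentation stage adds over raw intensity statistics;
#' without segmentation it is zero. Larger windows play the role of deeper
#' backbones (coarser, more abstract summaries).
#'
#' @param window fuzzy-filter window (odd; 3, 5, 7 for the three scales).
#' @return function(list(image, roi)) -> numeric feature vector (31 values).
#' @export
texture_extractor <- function(window = 3L) {
  function(item) {
    img <- adaptive_fuzzy_filter(item$image, window = window)
    roi <- item$roi
    px <- as.vector(img)
    hist16 <- tabulate(pmin(16L, 1L + floor(px / 16)), nbins = 16L) / length(px)
    g <- .gradient_magnitude(img)
    s <- stats::sd(px)
    roi_block <- rep(0, 8)
    if (!is.null(roi) && any(roi)) {
      rpx <- img[roi]
      comp <- .connected_components(roi * 1L)
      sizes <- tabulate(comp[roi])
      sizes <- sizes[sizes > 0]
      per <- sum(label_boundaries(roi * 1L))
      roi_block <- c(mean(roi),
                     mean(rpx) / 255,
                     stats::sd(rpx) / 255,
                     mean(sqrt(g)[roi]) / 255,
                     length(sizes) / 20,
                     mean(sizes) / 500,
                     if (length(sizes) > 1) stats::sd(sizes) / 500 else 0,
                     per / max(1, sum(roi)))
    }
    c(hist16,
      mean(px) / 255,
      s / 255,
      if (is.finite(s) && s > 0) e1071::skewness(px, type = 1) else 0,
      shannon_entropy(hist16 + 1e-12 * (1 - sum(hist16)) / 16, input = "prob"),
      mean(sqrt(g)) / 255,
      mean(item$image < 128),
      roi_block)
  }
}

#' Run configuration for the experiment pipeline
#'
#' @param scenario `"none"`, `"seg"`, `"seg_pso"` or `"seg_rdo"`.
#' @param n_per_class synthetic images per class.
#' @param K fold counts to evaluate (subset of 2, 4, 5, 8, 10).
#' @param classifier classifier name for [make_classifier()].
#' @param weights a [fusion_weights()] (default the published operating
#'   point 0.45 / 0.35 / 0.20).
#' @param fusion_mode `"leak_free"` (default) or `"faithful"` (train-fold
#'   class-mean offsets applied inside each fold).
#' @param selector_cfg optimizer configuration for the seg_pso / seg_rdo
#'   scenarios (defaults sized for the wrapper search).
#' @param slic_cfg a [slic_config()] for the segmentation scenarios.
#' @param image_spec_args list of overrides for [synth_image_spec()].
#' @param seed master seed; all stage seeds derive from it.
#' @return a `run_config` list.
#' @export
run_config <- function(scenario = c("none", "seg", "seg_pso", "seg_rdo"),
                       n_per_class = 20L, K = c(5L),
                       classifier = "knn",
                       weights = fusion_weights(0.45, 0.35, 0.20),
                       fusion_mode = c("leak_free", "faithful"),
                       selector_cfg = NULL, slic_cfg = NULL,
                       image_spec_args = list(), seed = 1L) {
  scenario <- match.arg(scenario)
  fusion_mode <- match.arg(fusion_mode)
  if (!all(K %in% c(2L, 4L, 5L, 8L, 10L))) {
    stop("K must be a subset of {2, 4, 5, 8, 10}")
  }
  if (is.null(slic_cfg)) slic_cfg <- slic_config(M = 48L, k_thresholds = 1L)
  structure(list(scenario = scenario, n_per_class = as.integer(n_per_class),
                 K = as.integer(K), classifier = classifier, weights = weights,
                 fusion_mode = fusion_mode, selector_cfg = selector_cfg,
                 slic_cfg = slic_cfg, image_spec_args = image_spec_args,
                 seed = as.integer(seed)),
            class = "run_config")
}

# Generate the image set for a run: n_per_class per class, seeds derived
# from the master seed.
.generate_images <- function(cfg) {
  specs <- c(
    lapply(seq_len(cfg$n_per_class), function(i) {
      do.call(synth_image_spec,
              c(list(class = "benign", seed = cfg$seed * 10000L + i),
                cfg$image_spec_args))
    }),
    lapply(seq_len(cfg$n_per_class), function(i) {
      do.call(synth_image_spec,
              c(list(class = "aca", seed = cfg$seed * 10000L + 5000L + i),
                cfg$image_spec_args))
    })
  )
  list(items = lapply(specs, make_image),
       labels = rep(c(0L, 1L), each = cfg$n_per_class))
}

# Compute the three backbone feature matrices for a list of images. With
# segmentation, the extractors see the ROI-extracted image (background
# whitened to 255, as removed tissue) plus the ROI mask for morphology —
# the analogue of feeding the segmentation result image to a backbone.
.pipeline_features <- function(items, segment, slic_cfg) {
  inputs <- lapply(items, function(it) {
    img <- it$image
    roi <- NULL
    if (segment) {
      seg <- slic_segment(it$image, slic_cfg)
      roi <- roi_mask(seg)
      img[!roi] <- 255
    }
    list(image = img, roi = roi)
  })
  list(f50 = extract_features(inputs, texture_extractor(3L)),
       f101 = extract_features(inputs, texture_extractor(5L)),
       f152 = extract_features(inputs, texture_extractor(7L)))
}

# Fold-internal pipeline factory: fuses the triplet (with train-fold
# offsets in faithful mode), optionally selects features on the training
# folds, and fits the classifier.
.pipeline_factory <- function(cfg) {
  clf <- make_classifier(cfg$classifier)
  sel_method <- switch(cfg$scenario, seg_pso = "pso", seg_rdo = "rdo", NULL)
  function(features, labels) {
    means <- NULL
    if (cfg$fusion_mode == "faithful") {
      means <- class_mean_offsets(features$f50, features$f101, features$f152, labels)
    }
    fuse <- function(fs, lab) {
      if (cfg$fusion_mode == "faithful" && !is.null(lab)) {
        dwaff_fuse(fs$f50, fs$f101, fs$f152, cfg$weights, labels = lab,
                   means = means, mode = "faithful")
      } else {
        dwaff_fuse(fs$f50, fs$f101, fs$f152, cfg$weights)
      }
    }
    train_fused <- fuse(features, labels)
    mask <- rep(TRUE, ncol(train_fused))
    if (!is.null(sel_method)) {
      sel_cfg <- cfg$selector_cfg
      if (is.null(sel_cfg)) {
        sel_cfg <- if (sel_method == "pso") {
          pso_config(n_particles = 30L, k_max = 40L, r_mode = "random",
                     v_max = 0.2, seed = cfg$seed)
        } else {
          rdo_config(n_pop = 30L, n_males = 6L, max_iter = 25L, seed = cfg$seed)
        }
      }
      sel <- select_features(train_fused, labels, method = sel_method,
                             cfg = sel_cfg, eval_seed = cfg$seed)
      mask <- sel$mask
    }
    model <- clf$fit(train_fused[, mask, drop = FALSE], labels)
    function(test_features) {
      test_fused <- fuse(test_features, NULL)
      clf$predict(model, test_fused[, mask, drop = FALSE])
    }
  }
}

#' Run a full experiment scenario
#'
#' Generates the synthetic image set, computes (optionally ROI-masked)
#' backbone features, and evaluates the configured pipeline with
#' stratified K-fold cross-validation for every requested K. When
#' `out_dir` is given, metrics (CSV and JSON) and a manifest capturing the
#' configuration and seeds are written beneath it.
#'
#' @param cfg a [run_config()].
#' @param out_dir optional output directory.
#' @return a `run_result` list: `scenario`, `by_K` (named list of
#'   [cross_validate()] results), `mean_accuracy` (across all K), `config`.
#' @export
run_experiment <- function(cfg = run_config(), out_dir = NULL) {
  data <- .generate_images(cfg)
  segment <- cfg$scenario != "none"
  feats <- .pipeline_features(data$items, segment, cfg$slic_cfg)
  factory <- .pipeline_factory(cfg)
  by_K <- lapply(cfg$K, function(K) {
    plan <- kfold_plan(data$labels, K = K, seed = cfg$seed + K)
    cross_validate(factory, feats, data$labels, plan)
  })
  names(by_K) <- paste0("K", cfg$K)
  res <- structure(list(
    scenario = cfg$scenario,
    by_K = by_K,
    mean_accuracy = mean(vapply(by_K, function(r) r$mean[["accuracy"]], numeric(1))),
    config = cfg
  ), class = "run_result")
  if (!is.null(out_dir)) .write_run_outputs(res, out_dir)
  res
}

.write_run_outputs <- function(res, out_dir) {
  dir.create(file.path(out_dir, "metrics"), recursive = TRUE, showWarnings = FALSE)
  tab <- do.call(rbind, lapply(names(res$by_K), function(k) {
    df <- res$by_K[[k]]$per_fold
    df$K <- k
    df
  }))
  utils::write.csv(tab, file.path(out_dir, "metrics", "per_fold.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(scenario = res$scenario,
         mean_accuracy = res$mean_accuracy,
         by_K = lapply(res$by_K, function(r) as.list(r$mean))),
    file.path(out_dir, "metrics", "summary.json"),
    auto_unbox = TRUE, digits = NA)
  cfg <- res$config
  jsonlite::write_json(
    list(scenario = cfg$scenario, n_per_class = cfg$n_per_class, K = cfg$K,
         classifier = cfg$classifier,
         weights = unclass(cfg$weights), fusion_mode = cfg$fusion_mode,
         seed = cfg$seed, package_version = as.character(utils::packageVersion("slicfuse"))),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE)
  invisible(out_dir)
}

#' @export
print.run_result <- function(x, ...) {
  cat("Scenario:", x$scenario, "\n")
  for (k in names(x$by_K)) {
    cat(sprintf("  %s: accuracy %.2f%% (sd %.2f)\n", k,
                x$by_K[[k]]$mean[["accuracy"]], x$by_K[[k]]$sd[["accuracy"]]))
  }
  cat(sprintf("  mean accuracy across K: %.2f%%\n", x$mean_accuracy))
  invisible(x)
}
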