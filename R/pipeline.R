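# End-to-end orchestration. Two modes:
#   automatic: factorize (Bregman-RNMF) -> segment (PDHG) -> refine
#   windowed:  exclusion-RNMF -> window scan -> factorize -> segment inside
#              the window -> refine
# plus pixelwise evaluation against ground truth.

#' Pipeline configuration
#'
#' Bundles the per-stage configurations with their published defaults:
#' muscle detection `lam = 0.1`, rank 2; segmentation `theta = 0.01`,
#' `lam1 = 0.04`, `lam3 = 1`, with `lam2 = 0.075` in automatic mode and
#' `0.05` in windowed mode (the window already limits the spatial extent, so
#' the area penalty is relaxed); windowing factorization `mu1 = 1`,
#' `mu2 = 0.4`, rank 5; 11 refinement iterations.
#'
#' @param mode `"automatic"` or `"windowed"`.
#' @param factorization a [factorization_config()] for muscle detection.
#' @param segmentation a [segmentation_config()].
#' @param windowing_factorization a [factorization_config()] for the
#'   exclusion-regularized windowing factorization.
#' @param refinement list with `n_iters` and optional `sigma_schedule`,
#'   passed to [iterative_centroid()].
#' @param window_size `(height, width)` of the search window; required in
#'   windowed mode.
#' @param seed master seed; seeds the stage configurations unless they are
#'   supplied explicitly.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(mode = c("automatic", "windowed"),
                            factorization = NULL, segmentation = NULL,
                            windowing_factorization = NULL,
                            refinement = list(n_iters = 11L,
                                              sigma_schedule = NULL),
                            window_size = NULL, seed = 1L) {
  mode <- match.arg(mode)
  seed <- assert_count(seed, "seed")
  if (is.null(factorization)) {
    factorization <- factorization_config(seed = seed)
  }
  if (is.null(segmentation)) {
    segmentation <- segmentation_config(
      lam2 = if (mode == "windowed") 0.05 else 0.075
    )
  }
  if (is.null(windowing_factorization)) {
    windowing_factorization <- factorization_config(rank = 5L,
                                                    seed = seed + 1L)
  }
  if (mode == "windowed") {
    if (is.null(window_size) || length(window_size) != 2L ||
        any(window_size < 1)) {
      vs_validation_error("windowed mode requires `window_size = c(height, width)`")
    }
    window_size <- as.integer(window_size)
  }
  structure(
    list(mode = mode, factorization = factorization,
         segmentation = segmentation,
         windowing_factorization = windowing_factorization,
         refinement = refinement, window_size = window_size, seed = seed),
    class = "pipeline_config"
  )
}

pipeline_video_matrix <- function(video) {
  if (inherits(video, "phantom_output")) video <- video$video
  v3 <- as_video3d(video)
  assert_nonneg_array(v3, "video")
  list(X = video_to_matrix(v3), sx = dim(v3)[1L], sy = dim(v3)[2L])
}

refine_mask <- function(bin_mask, S3, refinement) {
  S_map <- temporal_projection(S3)
  centroid <- iterative_centroid(S_map,
                                 n_iters = refinement$n_iters %||% 11L,
                                 sigma_schedule = refinement$sigma_schedule)
  if (sum(bin_mask) == 0) {
    vs_refinement_error("segmentation produced an empty mask",
                        stage = "clustering")
  }
  clusters <- connected_components_3d(bin_mask)
  mask <- select_cluster(clusters, centroid)
  attr(mask, "centroid") <- centroid
  mask
}

#' Fully automatic valve segmentation
#'
#' Bregman-RNMF on the pixels x frames matrix, PDHG segmentation of the
#' sparse component against the low-rank muscle estimate, binarization at
#' 0.5, then refinement (iterative centroid + spatiotemporal connected
#' components + nearest-cluster selection). Deterministic given the seed in
#' `cfg`.
#'
#' @param video `sx x sy x t` array in `[0, 1]` (or a [generate_phantom()]
#'   result, whose `$video` is used).
#' @param cfg a [pipeline_config()] with `mode = "automatic"`.
#' @return binary `sx x sy x t` array of class `binary_mask` (a single
#'   6-connected component), with attributes `centroid`, `cluster_id` and
#'   `factorization`.
#' @export
run_automatic <- function(video, cfg = pipeline_config("automatic")) {
  if (cfg$mode != "automatic") {
    vs_validation_error("`cfg$mode` must be 'automatic'")
  }
  vm <- pipeline_video_matrix(video)
  fr <- bregman_rnmf(vm$X, cfg$factorization, keep_diagnostics = FALSE)
  WH <- fr$W %*% fr$H
  soft <- pdhg_segment(fr$S, WH, cfg$segmentation, sx = vm$sx, sy = vm$sy)
  bin <- matrix_to_video(binarize(soft), vm$sx, vm$sy)
  S3 <- matrix_to_video(fr$S, vm$sx, vm$sy)
  mask <- refine_mask(bin, S3, cfg$refinement)
  attr(mask, "factorization") <- fr
  mask
}

#' Valve segmentation with window-based localization
#'
#' Runs the exclusion-regularized factorization once on the whole video and
#' scans the window over its sparse component; the muscle-detection
#' factorization's S and WH are then restricted to the winning window before
#' segmentation and refinement. The returned mask is zero outside the
#' window.
#'
#' @param video as in [run_automatic()].
#' @param cfg a [pipeline_config()] with `mode = "windowed"` and
#'   `window_size` set.
#' @return list with `mask` (binary `sx x sy x t` array) and `window` (a
#'   [window_spec()]).
#' @export
run_windowed <- function(video, cfg) {
  if (cfg$mode != "windowed") {
    vs_validation_error("`cfg$mode` must be 'windowed'")
  }
  vm <- pipeline_video_matrix(video)
  if (cfg$window_size[1L] > vm$sx || cfg$window_size[2L] > vm$sy) {
    vs_validation_error("window larger than the frame")
  }
  excl <- exclusion_rnmf(vm$X, cfg$windowing_factorization,
                         keep_diagnostics = FALSE)
  w <- detect_window(matrix_to_video(excl$S, vm$sx, vm$sy),
                     cfg$window_size[1L], cfg$window_size[2L])
  fr <- bregman_rnmf(vm$X, cfg$factorization, keep_diagnostics = FALSE)
  WH3 <- restrict_to_window(matrix_to_video(fr$W %*% fr$H, vm$sx, vm$sy), w)
  S3 <- restrict_to_window(matrix_to_video(fr$S, vm$sx, vm$sy), w)
  soft <- pdhg_segment(S3, WH3, cfg$segmentation)
  bin <- matrix_to_video(binarize(soft), vm$sx, vm$sy)
  mask <- refine_mask(bin, S3, cfg$refinement)
  mask <- restrict_to_window(unclass(mask), w)
  class(mask) <- "binary_mask"
  attr(mask, "factorization") <- fr
  list(mask = mask, window = w)
}

#' Pixelwise segmentation metrics
#'
#' Precision, recall and f1 over all voxels of the video; any metric whose
#' denominator is 0 is reported as 0.
#'
#' @param pred predicted binary mask (array or pixels x frames matrix).
#' @param truth ground-truth binary mask, same shape.
#' @return named numeric vector `(recall, precision, f1)`.
#' @export
evaluate <- function(pred, truth) {
  p3 <- as_video3d(pred)
  t3 <- as_video3d(truth)
  if (!identical(dim(p3), dim(t3))) {
    vs_validation_error("`pred` and `truth` shapes differ")
  }
  p <- p3 > 0.5; tr <- t3 > 0.5
  tp <- sum(p & tr); fp <- sum(p & !tr); fn <- sum(!p & tr)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  c(recall = recall, precision = precision, f1 = f1)
}

#' Evaluate several videos and average
#'
#' Per-video pixelwise metrics plus their unweighted means (macro average
#' across videos).
#'
#' @param preds,truths lists of masks of equal length.
#' @param names optional video names.
#' @return list of class `eval_report`: `per_video` data.frame and
#'   `averages` named vector.
#' @export
evaluate_set <- function(preds, truths, names = NULL) {
  if (length(preds) != length(truths)) {
    vs_validation_error("`preds` and `truths` lengths differ")
  }
  rows <- mapply(function(p, tr) evaluate(p, tr), preds, truths)
  per <- data.frame(
    name = names %||% sprintf("video_%02d", seq_along(preds)),
    recall = rows["recall", ], precision = rows["precision", ],
    f1 = rows["f1", ]
  )
  structure(
    list(per_video = per,
         averages = c(recall = mean(per$recall),
                      precision = mean(per$precision),
                      f1 = mean(per$f1))),
    class = "eval_report"
  )
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report>\n")
  print(x$per_video, row.names = FALSE)
  cat(sprintf("averages: recall %.3f  precision %.3f  f1 %.3f\n",
              x$averages["recall"], x$averages["precision"],
              x$averages["f1"]))
  invisible(x)
}
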