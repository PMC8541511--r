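# Window-based valve localization: scan a fixed-size spatial rectangle over
# the sparse component of the exclusion-regularized factorization and keep
# the position with maximal windowed energy sum(S^2) (squared Frobenius norm
# of the covered voxels, all frames). The scan uses a summed-area table over
# the per-pixel temporal sum of S^2, so it is linear in image size.

#' Window specification
#'
#' @param row0,col0 0-based top-left corner (inclusive).
#' @param height_w,width_w spatial window size.
#' @param score windowed energy at this position.
#' @return object of class `window_spec`.
#' @export
window_spec <- function(row0, col0, height_w, width_w, score = NA_real_) {
  structure(
    list(row0 = as.integer(row0), col0 = as.integer(col0),
         height_w = as.integer(height_w), width_w = as.integer(width_w),
         score = as.numeric(score)),
    class = "window_spec"
  )
}

#' @export
print.window_spec <- function(x, ...) {
  cat(sprintf("<window_spec> corner (%d, %d), size %dx%d, score %.4g\n",
              x$row0, x$col0, x$height_w, x$width_w, x$score))
  invisible(x)
}

#' Locate the valve window by maximal sparse energy
#'
#' Evaluates `c = sum(S^2)` over every stride-spaced window position and
#' returns the maximizer; ties break lexicographically by `(row0, col0)`.
#' `S_hat3D` should come from a single exclusion-regularized factorization of
#' the whole video (never from per-window factorizations).
#'
#' @param S_hat3D nonnegative `sx x sy x t` array (or pixels x frames matrix
#'   with `sx`/`sy` attributes).
#' @param height_w,width_w window size in pixels; must fit in the frame.
#' @param stride scan stride (default 1: exhaustive).
#' @return a [window_spec()] with the winning corner and score.
#' @export
detect_window <- function(S_hat3D, height_w, width_w, stride = 1L) {
  S3 <- as_video3d(S_hat3D)
  assert_nonneg_array(S3, "S_hat3D")
  d <- dim(S3)
  height_w <- assert_count(height_w, "height_w", 1L)
  width_w <- assert_count(width_w, "width_w", 1L)
  stride <- assert_count(stride, "stride", 1L)
  if (height_w > d[1L] || width_w > d[2L]) {
    vs_validation_error("window larger than the frame")
  }
  e <- rowSums(S3^2, dims = 2L)              # per-pixel temporal sum of S^2
  # summed-area table, zero-padded: sat[i+1, j+1] = sum(e[1:i, 1:j])
  cs <- apply(e, 2L, cumsum)                 # cumulative down rows
  if (is.null(dim(cs))) cs <- matrix(cs, nrow = 1L)
  ii <- t(apply(cs, 1L, cumsum))             # then across columns
  if (d[2L] == 1L) ii <- matrix(ii, ncol = 1L)
  sat <- rbind(0, cbind(0, ii))
  r0 <- seq(0L, d[1L] - height_w, by = stride)
  c0 <- seq(0L, d[2L] - width_w, by = stride)
  scores <- matrix(0, length(r0), length(c0))
  for (j in seq_along(c0)) {
    cc <- c0[j]
    scores[, j] <- sat[r0 + height_w + 1L, cc + width_w + 1L] -
      sat[r0 + 1L, cc + width_w + 1L] -
      sat[r0 + height_w + 1L, cc + 1L] +
      sat[r0 + 1L, cc + 1L]
  }
  if (max(scores) <= 0) {
    warning("sparse component has zero energy; window defaults to (0, 0)",
            call. = FALSE)
  }
  best <- which(scores == max(scores), arr.ind = TRUE)
  # lexicographic (row0, col0) tie-break
  best <- best[order(r0[best[, 1L]], c0[best[, 2L]]), , drop = FALSE][1L, ]
  window_spec(r0[best[1L]], c0[best[2L]], height_w, width_w,
              scores[best[1L], best[2L]])
}

#' Zero out everything outside a spatial window
#'
#' Entries outside the window's rectangle are set to 0 in every frame;
#' entries inside are unchanged.
#'
#' @param x `sx x sy x t` array, `sx x sy` matrix, or pixels x frames matrix
#'   with `sx`/`sy` attributes.
#' @param w a [window_spec()].
#' @return object of the same shape and representation as `x`.
#' @export
restrict_to_window <- function(x, w) {
  was_matrix <- is.matrix(x) && !is.null(attr(x, "sx"))
  x3 <- if (was_matrix) as_video3d(x) else x
  if (is.matrix(x3)) dim(x3) <- c(dim(x3), 1L)
  d <- dim(x3)
  if (w$row0 < 0 || w$col0 < 0 || w$row0 + w$height_w > d[1L] ||
      w$col0 + w$width_w > d[2L]) {
    vs_validation_error("window does not fit inside the spatial extent")
  }
  keep <- array(FALSE, d)
  keep[w$row0 + seq_len(w$height_w), w$col0 + seq_len(w$width_w), ] <- TRUE
  x3[!keep] <- 0
  if (was_matrix) {
    out <- video_to_matrix(x3)
    class(out) <- class(x)
    return(out)
  }
  if (is.matrix(x)) dim(x3) <- d[1:2]
  x3
}

#' Fraction of ground-truth voxels covered by a window
#'
#' @param w a [window_spec()].
#' @param truth_mask binary `sx x sy x t` array with at least one foreground
#'   voxel.
#' @return recall in `[0, 1]`.
#' @export
window_recall <- function(w, truth_mask) {
  m3 <- as_video3d(truth_mask)
  fg <- which(m3 > 0)
  if (length(fg) == 0L) {
    vs_validation_error("`truth_mask` has no foreground voxels")
  }
  d <- dim(m3)
  fg0 <- fg - 1L
  row <- fg0 %% d[1L]
  col <- (fg0 %/% d[1L]) %% d[2L]
  inside <- row >= w$row0 & row < w$row0 + w$height_w &
    col >= w$col0 & col < w$col0 + w$width_w
  mean(inside)
}
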