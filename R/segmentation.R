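# Convex-relaxed Chan-Vese segmentation of the sparse component.
#
# The relaxed mask B in [0,1]^{s x t} minimizes
#   1/2 <Theta - S, B> + lam1 * TV(B) + lam2 * <1, B> + lam3 * <WH, B>,
# equivalently 1/2 <Theta2 - S, B> + lam1 * TV(B) + lam2 * <1, B> with the
# spatially varying threshold Theta2 = Theta + 2 * lam3 * WH: a pixel is
# pushed toward 1 only where S exceeds the local threshold, and the presence
# of muscle (large WH) raises that threshold. TV is isotropic, per frame
# (spatial forward differences only), and the saddle-point problem is solved
# by the primal-dual hybrid gradient (Chambolle-Pock) iteration; the final
# relaxed mask is binarized at 0.5.

#' Segmentation hyperparameters
#'
#' Defaults are the published ones: base threshold `theta = 0.01`, TV weight
#' `lam1 = 0.04`, area weight `lam2 = 0.075` (automatic mode; the windowed
#' mode lowers it to 0.05), muscle-exclusion weight `lam3 = 1`. Step sizes
#' default to `tau = sigma_dual = 1/sqrt(8)` so that
#' `tau * sigma_dual * ||D||^2 <= 1` for the forward-difference operator.
#'
#' @param theta base threshold, > 0.
#' @param lam1,lam2,lam3 nonnegative weights of the TV, area and
#'   muscle-exclusion terms.
#' @param n_iters PDHG iterations.
#' @param tau,sigma_dual primal and dual step sizes.
#' @param tv `"isotropic"` (the published choice) or `"anisotropic"`.
#'   Anisotropic TV satisfies the exact coarea formula, so thresholding a
#'   relaxed minimizer is guaranteed to yield a binary minimizer; with
#'   isotropic TV that holds only approximately (genuinely fractional
#'   minimizers exist). The anisotropic option exists to validate the solver
#'   against exhaustive enumeration.
#' @return object of class `segmentation_config`.
#' @export
segmentation_config <- function(theta = 0.01, lam1 = 0.04, lam2 = 0.075,
                                lam3 = 1.0, n_iters = 500L,
                                tau = 1 / sqrt(8), sigma_dual = 1 / sqrt(8),
                                tv = c("isotropic", "anisotropic")) {
  tv <- match.arg(tv)
  assert_scalar_number(theta, "theta")
  if (theta <= 0) vs_validation_error("`theta` must be > 0")
  assert_scalar_number(lam1, "lam1", 0)
  assert_scalar_number(lam2, "lam2", 0)
  assert_scalar_number(lam3, "lam3", 0)
  n_iters <- assert_count(n_iters, "n_iters", 1L)
  assert_scalar_number(tau, "tau", 0)
  assert_scalar_number(sigma_dual, "sigma_dual", 0)
  if (tau * sigma_dual * 8 > 1 + 1e-12) {
    vs_validation_error("step sizes violate tau * sigma_dual * ||D||^2 <= 1")
  }
  structure(
    list(theta = theta, lam1 = lam1, lam2 = lam2, lam3 = lam3,
         n_iters = n_iters, tau = tau, sigma_dual = sigma_dual, tv = tv),
    class = "segmentation_config"
  )
}

#' Spatially varying segmentation threshold
#'
#' `Theta2 = theta + 2 * lam3 * WH`: the muscle-exclusion term of the energy
#' re-expressed as a per-pixel threshold that S must exceed before the mask
#' is pushed toward 1.
#'
#' @param theta base threshold, > 0.
#' @param lam3 muscle-exclusion weight, >= 0.
#' @param WH nonnegative low-rank (muscle) component.
#' @return numeric object shaped like `WH`, everywhere `>= theta`.
#' @export
build_threshold_map <- function(theta, lam3, WH) {
  assert_scalar_number(theta, "theta")
  if (theta <= 0) vs_validation_error("`theta` must be > 0")
  assert_scalar_number(lam3, "lam3", 0)
  assert_nonneg_array(WH, "WH")
  theta + 2 * lam3 * WH
}

# Spatial forward-difference gradient of a frame stack (sx x sy x t), with
# replicate (Neumann) boundary: the last difference in each direction is 0.
grad_spatial <- function(b) {
  d <- dim(b)
  gx <- b[c(seq_len(d[1L])[-1L], d[1L]), , , drop = FALSE] - b
  gy <- b[, c(seq_len(d[2L])[-1L], d[2L]), , drop = FALSE] - b
  list(gx = gx, gy = gy)
}

# Adjoint D^T p of the forward-difference operator (negative divergence with
# backward differences); relies on the last-slice components of p being 0,
# which the PDHG iteration preserves.
div_adjoint <- function(px, py) {
  d <- dim(px)
  sx <- d[1L]; sy <- d[2L]
  pxs <- array(0, d); pys <- array(0, d)
  if (sx > 1L) pxs[seq(2L, sx), , ] <- px[seq_len(sx - 1L), , ]
  if (sy > 1L) pys[, seq(2L, sy), ] <- py[, seq_len(sy - 1L), ]
  (pxs - px) + (pys - py)
}

#' Isotropic total variation of an image or frame stack
#'
#' Sum over pixels of `sqrt(gx^2 + gy^2)` with spatial forward differences
#' and replicate boundary. A 3-D input is treated as a stack of frames (no
#' temporal differences) and the per-frame values are summed.
#'
#' @param b numeric matrix (single image) or `sx x sy x t` array.
#' @return nonnegative scalar.
#' @export
tv_isotropic <- function(b) {
  if (is.matrix(b)) dim(b) <- c(dim(b), 1L)
  g <- grad_spatial(b)
  sum(sqrt(g$gx^2 + g$gy^2))
}

# Coerce segmentation inputs (s x t matrix with sx/sy attributes, or 3-D
# array) to a frame stack plus bookkeeping.
seg_input_3d <- function(x, sx, sy, name) {
  if (!is.null(dim(x)) && length(dim(x)) == 3L) return(unclass(x))
  if (is.matrix(x)) {
    return(matrix_to_video(x, sx %||% attr(x, "sx"), sy %||% attr(x, "sy")))
  }
  vs_validation_error(sprintf("`%s` must be a matrix or 3-D array", name))
}

#' Relaxed valve segmentation by primal-dual hybrid gradient
#'
#' Minimizes the relaxed energy (see [energy()]) over `B` in `[0,1]`
#' entrywise. Per iteration: dual ascent `p <- proj(p + sigma * D bbar)` onto
#' the per-pixel disc of radius `lam1`; primal descent
#' `b <- clip01(b - tau * (D^T p + (Theta2 - S)/2 + lam2))`; extrapolation
#' `bbar <- 2 b_new - b_old`. TV couples pixels within a frame only.
#'
#' @param S_hat nonnegative sparse component (`s x t` matrix with `sx`/`sy`
#'   attributes, or `sx x sy x t` array).
#' @param WH nonnegative low-rank component, same shape.
#' @param cfg a [segmentation_config()].
#' @param sx,sy spatial dimensions if not recoverable from `S_hat`.
#' @param trace_every record the relaxed energy every this many iterations
#'   (1 = every iteration; the final iterate is always recorded).
#' @return soft mask of class `soft_mask`: `s x t` matrix with entries in
#'   `[0, 1]`, attributes `sx`, `sy`, `energy_trace` and
#'   `energy_trace_iters` (the iteration numbers the trace was sampled at).
#' @export
pdhg_segment <- function(S_hat, WH, cfg = segmentation_config(),
                         sx = NULL, sy = NULL, trace_every = 10L) {
  if (!inherits(cfg, "segmentation_config")) {
    cfg <- do.call(segmentation_config, as.list(cfg))
  }
  S3 <- seg_input_3d(S_hat, sx, sy, "S_hat")
  W3 <- seg_input_3d(WH, sx %||% dim(S3)[1L], sy %||% dim(S3)[2L], "WH")
  if (!identical(dim(S3), dim(W3))) {
    vs_validation_error("`S_hat` and `WH` must have identical shapes")
  }
  assert_nonneg_array(S3, "S_hat")
  theta2 <- build_threshold_map(cfg$theta, cfg$lam3, W3)
  # gradient of the data part G(b) = <Theta2 - S, b>/2 + lam2 <1, b>
  gradG <- 0.5 * (theta2 - S3) + cfg$lam2
  d <- dim(S3)
  trace_every <- assert_count(trace_every, "trace_every", 1L)
  trace_iters <- unique(c(seq(trace_every, cfg$n_iters, by = trace_every),
                          cfg$n_iters))
  iso <- cfg$tv == "isotropic"
  res <- .pdhg_core(as.numeric(gradG), d[1L], d[2L], d[3L],
                    cfg$lam1, cfg$tau, cfg$sigma_dual,
                    cfg$n_iters, iso, as.integer(trace_iters))
  b <- array(res$b, d)
  trace <- res$trace
  out <- video_to_matrix(b)
  attr(out, "energy_trace") <- trace
  attr(out, "energy_trace_iters") <- trace_iters
  class(out) <- c("soft_mask", class(out))
  out
}

#' Binarize a relaxed mask at 0.5
#'
#' Strict threshold: an entry maps to 1 iff it exceeds 0.5 (ties at exactly
#' 0.5 map to 0).
#'
#' @param B soft mask (matrix or array) with entries in `[0, 1]`.
#' @return object shaped like `B` with entries in `{0, 1}`, class
#'   `binary_mask`.
#' @export
binarize <- function(B) {
  out <- (unclass(B) > 0.5) * 1
  attr(out, "sx") <- attr(B, "sx")
  attr(out, "sy") <- attr(B, "sy")
  if (is.matrix(out)) class(out) <- c("binary_mask", class(out))
  out
}

#' Relaxed segmentation energy
#'
#' Evaluates the segmentation objective at a (soft or binary) mask `B`,
#' either in its model form
#' `1/2 <Theta - S, B> + lam1 TV(B) + lam2 <1, B> + lam3 <WH, B>`
#' (`form = "model"`) or in the threshold form
#' `1/2 <Theta2 - S, B> + lam1 TV(B) + lam2 <1, B>` with
#' `Theta2 = Theta + 2 lam3 WH` (`form = "threshold"`). The two are
#' algebraically identical.
#'
#' @param B mask, same shape conventions as [pdhg_segment()] inputs.
#' @param S_hat,WH sparse and low-rank components.
#' @param cfg a [segmentation_config()].
#' @param form which algebraic form to evaluate.
#' @param sx,sy spatial dimensions if not recoverable from the inputs.
#' @return scalar energy.
#' @export
energy <- function(B, S_hat, WH, cfg = segmentation_config(),
                   form = c("model", "threshold"), sx = NULL, sy = NULL) {
  form <- match.arg(form)
  if (!inherits(cfg, "segmentation_config")) {
    cfg <- do.call(segmentation_config, as.list(cfg))
  }
  B3 <- seg_input_3d(B, sx, sy, "B")
  S3 <- seg_input_3d(S_hat, sx, sy, "S_hat")
  W3 <- seg_input_3d(WH, sx, sy, "WH")
  tv <- if ((cfg$tv %||% "isotropic") == "isotropic") {
    tv_isotropic(B3)
  } else {
    g <- grad_spatial(B3)
    sum(abs(g$gx) + abs(g$gy))
  }
  if (form == "model") {
    0.5 * sum((cfg$theta - S3) * B3) + cfg$lam1 * tv +
      cfg$lam2 * sum(B3) + cfg$lam3 * sum(W3 * B3)
  } else {
    theta2 <- build_threshold_map(cfg$theta, cfg$lam3, W3)
    0.5 * sum((theta2 - S3) * B3) + cfg$lam1 * tv + cfg$lam2 * sum(B3)
  }
}
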