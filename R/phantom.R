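# Synthetic echocardiography phantoms.
#
# A phantom emulates the additive structure assumed by the factorization
# model: a low-rank background (bright sector outline plus smooth blobs, each
# modulated by a smooth nonnegative temporal profile, standing in for the
# rigidly/periodically moving myocardium), a thin fast-moving valve (two
# leaflets hinged at a point, swinging open and closed), optional bright
# moving distractors (mimicking a second valve), and clipped Gaussian noise.
# Ground truth is emitted voxelwise so every downstream stage can be scored.

#' Specification of a synthetic echo phantom
#'
#' @param height,width spatial size in pixels.
#' @param n_frames number of frames.
#' @param bg_rank exact rank (across frames) of the background component.
#' @param bg_amplitude peak background gray level, in `[0, 1]`.
#' @param valve_amplitude peak valve gray level (at the hinge; leaflets taper
#'   linearly to 15% of this value at the free edge).
#' @param valve_length leaflet length in pixels; must be `< min(height, width)`.
#' @param valve_thickness leaflet thickness in pixels.
#' @param hinge_position 0-based `(row, col)` of the leaflet hinge.
#' @param swing_period frames per open-close cycle.
#' @param noise_sigma standard deviation of the additive Gaussian noise.
#' @param distractor_count number of extra bright moving blobs placed away
#'   from the hinge (e.g. an aortic valve look-alike).
#' @param seed integer seed; identical specs generate bit-identical phantoms.
#' @return an object of class `phantom_spec`.
#' @seealso [generate_phantom()], [phantom_fixture_suite()]
#' @export
phantom_spec <- function(height = 96L, width = 96L, n_frames = 40L,
                         bg_rank = 2L, bg_amplitude = 0.5,
                         valve_amplitude = 0.9, valve_length = 24L,
                         valve_thickness = 2L,
                         hinge_position = c(28L, 48L),
                         swing_period = 20L, noise_sigma = 0.01,
                         distractor_count = 0L, seed = 1L) {
  height <- assert_count(height, "height", 1L)
  width <- assert_count(width, "width", 1L)
  n_frames <- assert_count(n_frames, "n_frames", 1L)
  bg_rank <- assert_count(bg_rank, "bg_rank", 1L)
  assert_scalar_number(bg_amplitude, "bg_amplitude", 0, 1)
  assert_scalar_number(valve_amplitude, "valve_amplitude", 0)
  valve_length <- assert_count(valve_length, "valve_length", 1L)
  valve_thickness <- assert_count(valve_thickness, "valve_thickness", 1L)
  assert_scalar_number(swing_period, "swing_period", 2)
  assert_scalar_number(noise_sigma, "noise_sigma", 0)
  distractor_count <- assert_count(distractor_count, "distractor_count", 0L)
  seed <- assert_count(seed, "seed")
  if (length(hinge_position) != 2L || any(hinge_position < 0) ||
      hinge_position[1L] > height - 1 || hinge_position[2L] > width - 1) {
    vs_validation_error("`hinge_position` must be a 0-based (row, col) inside the frame")
  }
  if (valve_length >= min(height, width)) {
    vs_validation_error("`valve_length` must be < min(height, width)")
  }
  if (bg_rank > min(height * width, n_frames)) {
    vs_validation_error("`bg_rank` must be <= min(height*width, n_frames)")
  }
  structure(
    list(height = height, width = width, n_frames = n_frames,
         bg_rank = bg_rank, bg_amplitude = bg_amplitude,
         valve_amplitude = valve_amplitude, valve_length = valve_length,
         valve_thickness = valve_thickness,
         hinge_position = as.numeric(hinge_position),
         swing_period = as.numeric(swing_period), noise_sigma = noise_sigma,
         distractor_count = distractor_count, seed = seed),
    class = "phantom_spec"
  )
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf(
    "<phantom_spec> %dx%dx%d  bg rank %d (amp %.2f)  valve amp %.2f len %d  noise sd %.3g  distractors %d  seed %d\n",
    x$height, x$width, x$n_frames, x$bg_rank, x$bg_amplitude,
    x$valve_amplitude, x$valve_length, x$noise_sigma, x$distractor_count,
    x$seed
  ))
  invisible(x)
}

# Raster a set of disc-shaped stamps into a frame, keeping the max value per
# pixel. centers: matrix (n x 2) of 0-based (row, col); values: length n.
stamp_discs <- function(frame, centers, values, radius) {
  if (nrow(centers) == 0L) return(frame)
  sx <- nrow(frame); sy <- ncol(frame)
  r <- max(0L, as.integer(ceiling(radius)))
  offs <- expand.grid(di = -r:r, dj = -r:r)
  offs <- offs[offs$di^2 + offs$dj^2 <= radius^2 + 1e-9, , drop = FALSE]
  n <- nrow(centers)
  rows <- rep(round(centers[, 1L]), times = nrow(offs)) +
    rep(offs$di, each = n)
  cols <- rep(round(centers[, 2L]), times = nrow(offs)) +
    rep(offs$dj, each = n)
  vals <- rep(values, times = nrow(offs))
  keep <- rows >= 0 & rows < sx & cols >= 0 & cols < sy
  if (!any(keep)) return(frame)
  rows <- rows[keep]; cols <- cols[keep]; vals <- vals[keep]
  idx <- rows + 1L + cols * sx
  ord <- order(vals)                      # later (larger) assignments win
  frame[idx[ord]] <- pmax(frame[idx[ord]], vals[ord])
  frame
}

# Background spatial patterns: a bright sector outline (side walls + outer
# arc, the myocardium silhouette of an apical view) and, for higher ranks,
# smooth blobs sitting on the walls.
phantom_bg_patterns <- function(spec) {
  sx <- spec$height; sy <- spec$width
  apex <- c(2, (sy - 1) / 2)
  rows <- matrix(0:(sx - 1), sx, sy)
  cols <- matrix(0:(sy - 1), sx, sy, byrow = TRUE)
  dr <- rows - apex[1L]; dc <- cols - apex[2L]
  rad <- sqrt(dr^2 + dc^2)
  ang <- atan2(dc, pmax(dr, 1e-9))        # angle from straight-down
  half <- pi / 4
  r_out <- 0.88 * (sx - apex[1L])
  wall <- exp(-((abs(ang) - half)^2) / (2 * 0.05^2)) *
    (rad > 0.15 * r_out & rad < 1.02 * r_out)
  arc <- exp(-((rad - r_out)^2) / (2 * (0.03 * sx)^2)) * (abs(ang) <= half)
  p1 <- pmin(wall + arc, 1)
  pats <- list(p1)
  if (spec$bg_rank > 1L) {
    n_blob <- spec$bg_rank - 1L
    blob_ang <- seq(-0.8 * half, 0.8 * half, length.out = max(n_blob, 2L))[seq_len(n_blob)]
    for (k in seq_len(n_blob)) {
      cr <- apex[1L] + r_out * cos(blob_ang[k])
      cc <- apex[2L] + r_out * sin(blob_ang[k])
      pats[[k + 1L]] <- exp(-((rows - cr)^2 + (cols - cc)^2) / (2 * (sx / 10)^2))
    }
  }
  pats
}

#' Generate a synthetic echo phantom with voxel-level ground truth
#'
#' The emitted video is `clip01(background + valve + distractors + noise)`.
#' The background is an exact rank `<= bg_rank` tensor across frames (each
#' spatial pattern times a smooth nonnegative temporal profile). The valve is
#' a pair of thin leaflets hinged at `hinge_position`, whose opening angle
#' oscillates as `theta_max * |sin(2 * pi * t / swing_period)|`; leaflet
#' intensity tapers from `valve_amplitude` at the hinge to 15% of it at the
#' free edge. Noise is zero-mean Gaussian, clipped with the video to `[0, 1]`.
#'
#' @param spec a [phantom_spec()].
#' @return an object of class `phantom_output`: a list with `video`,
#'   `truth_background`, `truth_valve_mask`, `truth_valve_values`,
#'   `truth_distractor_values`, `truth_distractor_mask` (all `sx x sy x t`
#'   arrays) and the originating `spec`.
#' @export
generate_phantom <- function(spec) {
  if (!inherits(spec, "phantom_spec")) {
    spec <- do.call(phantom_spec, as.list(spec))
  }
  sx <- spec$height; sy <- spec$width; tt <- spec$n_frames
  with_seed(spec$seed, {
    pats <- phantom_bg_patterns(spec)
    frames <- 0:(tt - 1)
    phases <- stats::runif(length(pats), 0, 2 * pi)
    bg <- array(0, dim = c(sx, sy, tt))
    for (k in seq_along(pats)) {
      prof <- if (k == 1L) rep(1, tt) else {
        0.7 + 0.3 * sin(2 * pi * frames / tt + phases[k])
      }
      bg <- bg + outer(pats[[k]], prof)
    }
    mx <- max(bg)
    if (mx > 0) bg <- bg * (spec$bg_amplitude / mx)

    valve <- array(0, dim = c(sx, sy, tt))
    theta_max <- 0.9
    L <- spec$valve_length
    samp <- seq(0, L, by = 0.3)
    taper <- 1 - 0.85 * samp / L
    for (f in seq_len(tt)) {
      th <- theta_max * abs(sin(2 * pi * (f - 1) / spec$swing_period))
      centers <- rbind(
        cbind(spec$hinge_position[1L] + samp * cos(th),
              spec$hinge_position[2L] + samp * sin(th)),
        cbind(spec$hinge_position[1L] + samp * cos(th),
              spec$hinge_position[2L] - samp * sin(th))
      )
      vals <- spec$valve_amplitude * c(taper, taper)
      valve[, , f] <- stamp_discs(valve[, , f], centers, vals,
                                  spec$valve_thickness / 2)
    }

    distract <- array(0, dim = c(sx, sy, tt))
    if (spec$distractor_count > 0L) {
      for (d in seq_len(spec$distractor_count)) {
        base <- c(spec$hinge_position[1L] + 0.1 * sx,
                  spec$hinge_position[2L] + (-1)^d * 0.35 * sy)
        period <- 0.7 * spec$swing_period + 2 * (d - 1)
        phase <- stats::runif(1, 0, 2 * pi)
        for (f in seq_len(tt)) {
          ctr <- base + 5 * c(sin(2 * pi * (f - 1) / period + phase),
                              cos(2 * pi * (f - 1) / period + phase))
          distract[, , f] <- stamp_discs(
            distract[, , f], matrix(ctr, 1L), spec$valve_amplitude, 2.5
          )
        }
      }
    }

    noise <- if (spec$noise_sigma > 0) {
      array(stats::rnorm(sx * sy * tt, sd = spec$noise_sigma),
            dim = c(sx, sy, tt))
    } else {
      array(0, dim = c(sx, sy, tt))
    }

    video <- clip01(bg + valve + distract + noise)
    structure(
      list(video = video,
           truth_background = bg,
           truth_valve_mask = (valve > 0) * 1L,
           truth_valve_values = valve,
           truth_distractor_values = distract,
           truth_distractor_mask = (distract > 0) * 1L,
           spec = spec),
      class = "phantom_output"
    )
  })
}

#' @export
print.phantom_output <- function(x, ...) {
  d <- dim(x$video)
  cat(sprintf(
    "<phantom_output> video %dx%dx%d, valve voxels %d (%.2f%%), distractor voxels %d\n",
    d[1L], d[2L], d[3L], sum(x$truth_valve_mask),
    100 * mean(x$truth_valve_mask), sum(x$truth_distractor_mask)
  ))
  invisible(x)
}

#' Named phantom presets covering the scenarios the pipeline must survive
#'
#' * `easy` - high valve contrast, low noise, no distractors.
#' * `noisy` - Gaussian noise with a standard deviation comparable to the
#'   faint (tapered) part of the valve.
#' * `distractor` - an extra bright moving blob away from the hinge,
#'   mimicking a second (aortic) valve in the field of view.
#'
#' @return named list of [phantom_spec()] objects.
#' @export
phantom_fixture_suite <- function() {
  list(
    easy = phantom_spec(noise_sigma = 0.01, seed = 101L),
    noisy = phantom_spec(valve_amplitude = 0.8, noise_sigma = 0.25,
                         seed = 102L),
    distractor = phantom_spec(noise_sigma = 0.01, distractor_count = 1L,
                              seed = 103L)
  )
}
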