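# Internal helpers: error conditions, seeded RNG scoping, tensor <-> matrix
# reshaping. The pixels x frames matrix view uses ROW-MAJOR vectorization of
# the two spatial dimensions: pixel index p = (row - 1) * sy + col, frames as
# columns. All public coordinates are 0-based (row, col, frame).

vs_stop <- function(msg, class, ..., call. = FALSE) {
  cnd <- structure(
    class = c(class, "valveseg_error", "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1) else NULL, ...)
  )
  stop(cnd)
}

vs_validation_error <- function(msg, ...) {
  vs_stop(msg, "valveseg_validation_error", ...)
}

vs_numerical_error <- function(msg, ...) {
  vs_stop(msg, "valveseg_numerical_error", ...)
}

vs_refinement_error <- function(msg, stage = "refinement", ...) {
  vs_stop(msg, "valveseg_refinement_error", stage = stage, ...)
}

vs_io_error <- function(msg, ...) {
  vs_stop(msg, "valveseg_io_error", ...)
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    vs_validation_error(sprintf("`%s` must be a finite numeric scalar", name))
  }
  if (x < lower || x > upper) {
    vs_validation_error(sprintf(
      "`%s` = %g is outside [%g, %g]", name, x, lower, upper
    ))
  }
  invisible(x)
}

assert_count <- function(x, name, lower = 0L) {
  assert_scalar_number(x, name, lower = lower)
  if (x != round(x)) {
    vs_validation_error(sprintf("`%s` must be an integer, got %g", name, x))
  }
  invisible(as.integer(x))
}

assert_nonneg_array <- function(x, name) {
  if (!is.numeric(x)) vs_validation_error(sprintf("`%s` must be numeric", name))
  if (anyNA(x) || min(x) < 0) {
    vs_validation_error(sprintf("`%s` must be entrywise nonnegative", name))
  }
  invisible(x)
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

# Evaluate `expr` under a private RNG stream seeded with `seed`; the caller's
# .Random.seed is untouched.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Convert a video tensor to its pixels-by-frames matrix view
#'
#' The two spatial dimensions of an `sx x sy x t` tensor are vectorized
#' row-major (pixel `p = (row - 1) * sy + col`), so each column of the result
#' is one frame.
#'
#' @param video numeric 3-D array, `sx x sy x t`.
#' @return numeric matrix `s x t` (`s = sx * sy`) with attributes `sx`, `sy`.
#' @export
video_to_matrix <- function(video) {
  d <- dim(video)
  if (is.null(d) || length(d) != 3L) {
    vs_validation_error("`video` must be a 3-D array (sx x sy x t)")
  }
  m <- aperm(video, c(2L, 1L, 3L))
  dim(m) <- c(d[1L] * d[2L], d[3L])
  attr(m, "sx") <- d[1L]
  attr(m, "sy") <- d[2L]
  m
}

#' Convert a pixels-by-frames matrix back to a video tensor
#'
#' Inverse of [video_to_matrix()]. Spatial dimensions are taken from the
#' matrix attributes unless given explicitly.
#'
#' @param m numeric matrix `s x t`.
#' @param sx,sy spatial dimensions with `sx * sy == nrow(m)`.
#' @return numeric 3-D array `sx x sy x t`.
#' @export
matrix_to_video <- function(m, sx = attr(m, "sx"), sy = attr(m, "sy")) {
  if (is.null(sx) || is.null(sy)) {
    vs_validation_error("`sx`/`sy` missing and not stored on `m`")
  }
  if (sx * sy != nrow(m)) {
    vs_validation_error(sprintf(
      "sx * sy = %d does not match nrow(m) = %d", sx * sy, nrow(m)
    ))
  }
  v <- m
  attributes(v) <- NULL
  dim(v) <- c(sy, sx, ncol(m))
  aperm(v, c(2L, 1L, 3L))
}

as_video3d <- function(x, sx = NULL, sy = NULL) {
  if (!is.null(dim(x)) && length(dim(x)) == 3L) return(unclass(x))
  if (is.matrix(x)) return(matrix_to_video(x, sx %||% attr(x, "sx"),
                                           sy %||% attr(x, "sy")))
  vs_validation_error("expected a 3-D array or a pixels x frames matrix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

relative_error <- function(x, ref) {
  n <- sqrt(sum(ref^2))
  if (n == 0) sqrt(sum(x^2)) else sqrt(sum(x^2)) / n
}

frob <- function(x) sqrt(sum(x^2))
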