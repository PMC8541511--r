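# Plain-text I/O. Videos and masks travel either as a directory of ASCII PGM
# (P2) frames (frame order = lexicographic file order) or as a single
# "valveseg-tensor" text file; overlays are written as ASCII PPM (P3).
# Everything round-trips through text so that fixtures stay human-readable
# and portable.

read_pgm <- function(path) {
  toks <- scan(path, what = character(), quiet = TRUE, comment.char = "#")
  if (length(toks) < 4L || toks[1L] != "P2") {
    vs_io_error(sprintf("'%s' is not an ASCII (P2) PGM file", path))
  }
  wdt <- as.integer(toks[2L]); hgt <- as.integer(toks[3L])
  maxval <- as.numeric(toks[4L])
  px <- as.numeric(toks[-(1:4)])
  if (length(px) != wdt * hgt) {
    vs_io_error(sprintf("'%s': expected %d pixels, found %d",
                        path, wdt * hgt, length(px)))
  }
  # PGM stores row-major (row by row)
  m <- matrix(px, nrow = hgt, ncol = wdt, byrow = TRUE)
  attr(m, "maxval") <- maxval
  m
}

write_pgm <- function(m, path, maxval = 255L) {
  vals <- round(clip01(m) * maxval)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(m), nrow(m)), as.character(maxval)), con)
  writeLines(apply(vals, 1L, paste, collapse = " "), con)
  invisible(path)
}

write_ppm <- function(r, g, b, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P3", paste(ncol(r), nrow(r)), "255"), con)
  n <- ncol(r)
  for (i in seq_len(nrow(r))) {
    writeLines(paste(as.vector(rbind(r[i, ], g[i, ], b[i, ])),
                     collapse = " "), con)
  }
  invisible(path)
}

read_tensor_txt <- function(path) {
  lines <- readLines(path, n = 2L)
  if (length(lines) < 2L || !startsWith(lines[1L], "valveseg-tensor")) {
    vs_io_error(sprintf("'%s' is not a valveseg tensor file", path))
  }
  d <- as.integer(strsplit(trimws(lines[2L]), "\\s+")[[1L]])
  vals <- scan(path, skip = 2L, quiet = TRUE)
  if (length(vals) != prod(d)) {
    vs_io_error(sprintf("'%s': expected %d values, found %d",
                        path, prod(d), length(vals)))
  }
  # frames stored sequentially, each frame row-major
  arr <- array(0, d)
  per <- d[1L] * d[2L]
  for (f in seq_len(d[3L])) {
    arr[, , f] <- matrix(vals[(f - 1L) * per + seq_len(per)],
                         d[1L], d[2L], byrow = TRUE)
  }
  arr
}

write_tensor_txt <- function(arr, path) {
  d <- dim(arr)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("valveseg-tensor 1", paste(d, collapse = " ")), con)
  for (f in seq_len(d[3L])) {
    writeLines(paste(format(as.vector(t(arr[, , f])), digits = 17L,
                            trim = TRUE, scientific = TRUE),
                     collapse = " "), con)
  }
  invisible(path)
}

#' Read an echo video
#'
#' Accepts a directory of ASCII PGM (P2) frames (read in lexicographic file
#' order; all frames must share one size) or a single `valveseg-tensor` text
#' file. Integer PGM data are rescaled by the file's `maxval`, so 8-bit input
#' with maximum 255 yields a float video with maximum 1.0.
#'
#' @param path directory of `.pgm` frames or a tensor text file.
#' @return numeric `sx x sy x t` array with values in `[0, 1]`.
#' @export
read_video <- function(path) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.pgm$", full.names = TRUE))
    if (length(files) == 0L) {
      vs_io_error(sprintf("no .pgm frames found in '%s'", path))
    }
    frames <- lapply(files, read_pgm)
    d1 <- dim(frames[[1L]])
    for (k in seq_along(frames)) {
      if (!identical(dim(frames[[k]]), d1)) {
        vs_io_error(sprintf("frame '%s' has size %dx%d, expected %dx%d",
                            basename(files[k]), nrow(frames[[k]]),
                            ncol(frames[[k]]), d1[1L], d1[2L]))
      }
    }
    arr <- array(0, c(d1, length(frames)))
    for (k in seq_along(frames)) {
      arr[, , k] <- frames[[k]] / attr(frames[[k]], "maxval")
    }
    return(arr)
  }
  if (!file.exists(path)) vs_io_error(sprintf("'%s' does not exist", path))
  arr <- read_tensor_txt(path)
  mx <- max(arr)
  if (mx > 1) arr <- arr / mx
  arr
}

#' Write a binary mask as a directory of PGM frames (0/255)
#'
#' @param mask binary `sx x sy x t` array (or pixels x frames matrix with
#'   `sx`/`sy` attributes).
#' @param path output directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  m3 <- as_video3d(mask)
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  for (f in seq_len(dim(m3)[3L])) {
    write_pgm((m3[, , f] > 0.5) * 1,
              file.path(path, sprintf("frame_%04d.pgm", f)))
  }
  invisible(path)
}

#' Read a binary mask written by [write_mask()]
#'
#' @param path directory of PGM frames.
#' @return binary `sx x sy x t` array with entries in `{0, 1}`.
#' @export
read_mask <- function(path) {
  (read_video(path) > 0.5) * 1
}

#' Write a grayscale video as a directory of PGM frames
#'
#' @param video numeric `sx x sy x t` array with values in `[0, 1]`.
#' @param path output directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_video <- function(video, path) {
  v3 <- as_video3d(video)
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  for (f in seq_len(dim(v3)[3L])) {
    write_pgm(v3[, , f], file.path(path, sprintf("frame_%04d.pgm", f)))
  }
  invisible(path)
}

#' Write a phantom plus its ground truth to disk
#'
#' Emits the video and the ground-truth valve mask as PGM frame directories
#' and a sidecar `spec.txt` with the generating parameters.
#'
#' @param phantom a [generate_phantom()] result.
#' @param path output directory.
#' @return `path`, invisibly.
#' @export
write_phantom <- function(phantom, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  write_video(phantom$video, file.path(path, "video"))
  write_mask(phantom$truth_valve_mask, file.path(path, "truth_valve_mask"))
  sp <- phantom$spec
  writeLines(
    vapply(names(sp), function(k) {
      paste0(k, ": ", paste(sp[[k]], collapse = " "))
    }, character(1)),
    file.path(path, "spec.txt")
  )
  invisible(path)
}

# per-frame contour of a binary frame: foreground pixels with at least one
# 4-neighbour outside the mask
frame_contour <- function(m) {
  sx <- nrow(m); sy <- ncol(m)
  pad <- matrix(0, sx + 2L, sy + 2L)
  pad[2:(sx + 1L), 2:(sy + 1L)] <- m
  inner <- pad[1:sx, 2:(sy + 1L)] & pad[3:(sx + 2L), 2:(sy + 1L)] &
    pad[2:(sx + 1L), 1:sy] & pad[2:(sx + 1L), 3:(sy + 2L)]
  (m > 0) & !inner
}

#' Write contour overlays as PPM frames
#'
#' Grayscale video with the predicted mask outlined in red, an optional
#' ground-truth mask outlined in green, and an optional window rectangle in
#' yellow.
#'
#' @param video numeric `sx x sy x t` array in `[0, 1]`.
#' @param mask predicted binary mask, same shape (or `NULL`).
#' @param path output directory.
#' @param truth optional ground-truth binary mask.
#' @param window optional [window_spec()].
#' @return `path`, invisibly.
#' @export
write_overlay <- function(video, mask, path, truth = NULL, window = NULL) {
  v3 <- as_video3d(video)
  m3 <- if (!is.null(mask)) as_video3d(mask)
  t3 <- if (!is.null(truth)) as_video3d(truth)
  d <- dim(v3)
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  for (f in seq_len(d[3L])) {
    gray <- round(clip01(v3[, , f]) * 255)
    r <- gray; g <- gray; b <- gray
    if (!is.null(t3)) {
      ct <- frame_contour(t3[, , f])
      r[ct] <- 0; g[ct] <- 255; b[ct] <- 0
    }
    if (!is.null(m3)) {
      cm <- frame_contour(m3[, , f])
      r[cm] <- 255; g[cm] <- 0; b[cm] <- 0
    }
    if (!is.null(window)) {
      rr <- window$row0 + c(1L, window$height_w)
      cc <- window$col0 + c(1L, window$width_w)
      rows <- window$row0 + seq_len(window$height_w)
      cols <- window$col0 + seq_len(window$width_w)
      r[rr, cols] <- 255; g[rr, cols] <- 255; b[rr, cols] <- 0
      r[rows, cc] <- 255; g[rows, cc] <- 255; b[rows, cc] <- 0
    }
    write_ppm(r, g, b, file.path(path, sprintf("frame_%04d.ppm", f)))
  }
  invisible(path)
}

#' Serialize a window specification as a one-line text record
#'
#' @param w a [window_spec()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_window <- function(w, path) {
  writeLines(paste(w$row0, w$col0, w$height_w, w$width_w,
                   format(w$score, digits = 17L)), path)
  invisible(path)
}

#' Read a window specification written by [write_window()]
#' @param path input file.
#' @return a [window_spec()].
#' @export
read_window <- function(path) {
  v <- strsplit(trimws(readLines(path, n = 1L)), "\\s+")[[1L]]
  window_spec(as.integer(v[1L]), as.integer(v[2L]), as.integer(v[3L]),
              as.integer(v[4L]), as.numeric(v[5L]))
}

#' Read a flat key/value pipeline configuration file
#'
#' One `key: value` pair per line; `#` starts a comment; any omitted key
#' keeps its published default (see [pipeline_config()]). Recognized keys:
#' `mode`, `seed`, `rank`, `lam`, `n_outer_iters`, `n_init_nmf_iters`,
#' `theta`, `lam1`, `lam2`, `lam3`, `seg_iters`, `mu1`, `mu2`, `window_rank`,
#' `refine_iters`, `window_height`, `window_width`.
#'
#' @param path configuration file.
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- list()
  for (ln in lines) {
    parts <- strsplit(ln, ":", fixed = TRUE)[[1L]]
    if (length(parts) < 2L) {
      vs_io_error(sprintf("malformed config line: '%s'", ln))
    }
    key <- trimws(parts[1L])
    val <- trimws(paste(parts[-1L], collapse = ":"))
    kv[[key]] <- val
  }
  num <- function(k, default) if (is.null(kv[[k]])) default else as.numeric(kv[[k]])
  mode <- kv[["mode"]] %||% "automatic"
  seed <- as.integer(num("seed", 1))
  lam2_default <- if (mode == "windowed") 0.05 else 0.075
  window_size <- NULL
  if (!is.null(kv[["window_height"]]) && !is.null(kv[["window_width"]])) {
    window_size <- c(as.integer(kv[["window_height"]]),
                     as.integer(kv[["window_width"]]))
  }
  pipeline_config(
    mode = mode,
    factorization = factorization_config(
      rank = as.integer(num("rank", 2)), lam = num("lam", 0.1),
      n_outer_iters = as.integer(num("n_outer_iters", 100)),
      n_init_nmf_iters = as.integer(num("n_init_nmf_iters", 200)),
      seed = seed
    ),
    segmentation = segmentation_config(
      theta = num("theta", 0.01), lam1 = num("lam1", 0.04),
      lam2 = num("lam2", lam2_default), lam3 = num("lam3", 1.0),
      n_iters = as.integer(num("seg_iters", 500))
    ),
    windowing_factorization = factorization_config(
      rank = as.integer(num("window_rank", 5)), mu1 = num("mu1", 1),
      mu2 = num("mu2", 0.4), seed = seed + 1L
    ),
    refinement = list(n_iters = as.integer(num("refine_iters", 11)),
                      sigma_schedule = NULL),
    window_size = window_size,
    seed = seed
  )
}
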