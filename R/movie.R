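#' Movie stack container
#'
#' Holds a fluorescence time-lapse as a numeric array plus the physical
#' calibration needed to turn pixel displacements into speeds. Frames are
#' indexed `[t, y, x]` (or `[t, z, y, x]` before maximum projection); pixel
#' coordinates are 1-based array indices, so a spot at `(x = 3, y = 5)` sits
#' on `frames[t, 5, 3]`.
#'
#' @param frames numeric array, `t x h x w` or `t x z x h x w`.
#' @param pixel_size pixel size in micrometres per pixel (> 0).
#' @param interval frame interval in seconds (> 0); the acquisition this
#'   emulates imaged every 2 s over 3 min.
#' @return object of class `movie_stack`.
#' @export
movie_stack <- function(frames, pixel_size, interval = 2) {
  if (!is.array(frames) || !(length(dim(frames)) %in% c(3L, 4L)))
    stop("`frames` must be a 3-D [t,y,x] or 4-D [t,z,y,x] array")
  if (!is.numeric(pixel_size) || pixel_size <= 0)
    stop("`pixel_size` must be > 0 (micrometres per pixel)")
  if (!is.numeric(interval) || interval <= 0)
    stop("`interval` must be > 0 (seconds)")
  structure(list(frames = frames, pixel_size = pixel_size,
                 interval = interval),
            class = "movie_stack")
}

#' @export
print.movie_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("movie_stack: %d frames%s, %dx%d px, %.3g um/px, %.3g s/frame\n",
              d[1], if (length(d) == 4L) sprintf(" x %d z", d[2]) else "",
              d[length(d) - 1L], d[length(d)], x$pixel_size, x$interval))
  invisible(x)
}

n_frames <- function(stack) dim(stack$frames)[1]

#' Simulate a comet movie with known emitter tracks
#'
#' Renders point emitters (growing microtubule plus-end comets) as symmetric
#' Gaussian blobs that advance along straight headings at fixed speeds, over
#' a constant background with additive Gaussian noise. Per frame an emitter
#' moves `speed / 60 * interval / pixel_size` pixels. Emitters are placed so
#' the full path, padded by 3 PSF sigmas, stays inside the frame.
#'
#' @param n_frames frames in the movie (default 90: 3 min at 2 s).
#' @param interval frame interval in seconds (default 2).
#' @param pixel_size micrometres per pixel (default 0.1).
#' @param width,height frame size in pixels.
#' @param n_emitters number of emitters.
#' @param speed emitter speed(s) in micrometres per minute, recycled over
#'   emitters; all >= 0.
#' @param heading heading angle(s) in radians, recycled; `NULL` draws
#'   uniform headings.
#' @param psf_sigma Gaussian PSF sigma in pixels.
#' @param amplitude peak intensity of an emitter above background.
#' @param background constant background level.
#' @param noise_sd sd of additive Gaussian pixel noise; `0` is noise-free.
#' @param seed RNG seed.
#' @return list of class `comet_simulation`: `movie` (a [movie_stack()]),
#'   `truth` (data.frame `emitter`, `frame`, `x`, `y` of true sub-pixel
#'   positions) and `speeds` (true speed per emitter, um/min).
#' @export
simulate_comet_movie <- function(n_frames = 90, interval = 2,
                                 pixel_size = 0.1, width = 128, height = 128,
                                 n_emitters = 10, speed = 3, heading = NULL,
                                 psf_sigma = 1.5, amplitude = 100,
                                 background = 10, noise_sd = 2, seed = 1L) {
  stopifnot(n_frames >= 1, interval > 0, pixel_size > 0, n_emitters >= 0,
            all(speed >= 0), psf_sigma > 0, noise_sd >= 0)
  speed <- rep_len(speed, n_emitters)
  step_px <- speed / 60 * interval / pixel_size      # px per frame
  path_px <- step_px * (n_frames - 1)
  margin <- 3 * psf_sigma + 1
  if (any(path_px + 2 * margin > min(width, height)))
    stop("emitter paths do not fit in the frame; enlarge the frame or slow the emitters")

  geom <- with_seed(child_seed(seed, 1L), {
    th <- if (is.null(heading)) stats::runif(n_emitters, 0, 2 * pi)
          else rep_len(heading, n_emitters)
    x0 <- y0 <- numeric(n_emitters)
    for (i in seq_len(n_emitters)) {
      repeat {
        sx <- stats::runif(1, margin, width - margin)
        sy <- stats::runif(1, margin, height - margin)
        ex <- sx + path_px[i] * cos(th[i])
        ey <- sy + path_px[i] * sin(th[i])
        if (ex >= margin && ex <= width - margin &&
            ey >= margin && ey <= height - margin) {
          x0[i] <- sx; y0[i] <- sy; break
        }
      }
    }
    list(th = th, x0 = x0, y0 = y0)
  })

  t_idx <- rep(seq_len(n_frames), each = n_emitters)
  e_idx <- rep(seq_len(n_emitters), times = n_frames)
  truth <- data.frame(
    emitter = e_idx, frame = t_idx,
    x = geom$x0[e_idx] + step_px[e_idx] * (t_idx - 1) * cos(geom$th[e_idx]),
    y = geom$y0[e_idx] + step_px[e_idx] * (t_idx - 1) * sin(geom$th[e_idx]))

  frames <- array(background, dim = c(n_frames, height, width))
  r <- ceiling(4 * psf_sigma)
  for (k in seq_len(nrow(truth))) {
    cx <- truth$x[k]; cy <- truth$y[k]; t <- truth$frame[k]
    xs <- max(1, floor(cx) - r):min(width, ceiling(cx) + r)
    ys <- max(1, floor(cy) - r):min(height, ceiling(cy) + r)
    g <- amplitude * exp(-(outer((ys - cy)^2, (xs - cx)^2, `+`)) /
                           (2 * psf_sigma^2))
    frames[t, ys, xs] <- frames[t, ys, xs] + g
  }
  if (noise_sd > 0) {
    noise <- with_seed(child_seed(seed, 2L),
                       stats::rnorm(length(frames), 0, noise_sd))
    frames <- frames + array(noise, dim = dim(frames))
  }
  structure(list(movie = movie_stack(frames, pixel_size, interval),
                 truth = truth, speeds = speed),
            class = "comet_simulation")
}
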