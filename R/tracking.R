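#' Maximum-intensity z-projection
#'
#' Collapses the z dimension of a `[t, z, y, x]` movie by a per-pixel
#' maximum, the standard first step before comet detection. A movie that is
#' already 2-D per frame is returned unchanged.
#'
#' @param stack a [movie_stack()].
#' @return a `movie_stack` with `[t, y, x]` frames; calibration preserved.
#' @export
max_project <- function(stack) {
  stopifnot(inherits(stack, "movie_stack"))
  d <- dim(stack$frames)
  if (length(d) == 3L) return(stack)
  out <- array(stack$frames[, 1, , ], dim = d[-2])
  if (d[2] > 1) for (z in 2:d[2])
    out <- pmax(out, array(stack$frames[, z, , ], dim = d[-2]))
  movie_stack(out, stack$pixel_size, stack$interval)
}

# reflect (mirror-with-edge) index into 1..n
reflect_idx <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  period <- 2L * n
  j <- ((i - 1L) %% period + period) %% period
  ifelse(j < n, j + 1L, period - j)
}

# n x n matrix applying a 1-D Gaussian (sigma px, radius 4 sigma) with
# reflect padding; blur along rows of an image is K %*% img
gaussian_conv_matrix <- function(n, sigma) {
  r <- max(1L, ceiling(4 * sigma))
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  k <- k / sum(k)
  m <- matrix(0, n, n)
  for (o in (-r):r) {
    src <- reflect_idx(seq_len(n) + o, n)
    m[cbind(seq_len(n), src)] <- m[cbind(seq_len(n), src)] + k[o + r + 1L]
  }
  m
}

gaussian_blur <- function(img, sigma) {
  ky <- gaussian_conv_matrix(nrow(img), sigma)
  kx <- gaussian_conv_matrix(ncol(img), sigma)
  ky %*% img %*% t(kx)
}

#' Difference-of-Gaussians band-pass filter
#'
#' `Gaussian(sigma_small) - Gaussian(sigma_large)` with reflect-padded
#' borders: removes smooth background and enhances blobs at the comet scale.
#'
#' @param frame numeric matrix.
#' @param sigma_small,sigma_large Gaussian sigmas in px,
#'   `0 < sigma_small < sigma_large`.
#' @return filtered matrix of the same size.
#' @export
dog_filter <- function(frame, sigma_small, sigma_large) {
  if (!(sigma_small > 0 && sigma_large > sigma_small))
    stop("need 0 < sigma_small < sigma_large")
  gaussian_blur(frame, sigma_small) - gaussian_blur(frame, sigma_large)
}

#' Detect comet spots in a filtered frame
#'
#' Finds local maxima of the band-passed response with minimum mutual
#' separation `radius` px, keeps those whose response (the quality score)
#' reaches `quality_threshold`, and refines each to sub-pixel position with
#' an independent 1-D quadratic fit per axis over the 3x3 neighbourhood.
#'
#' @param filtered DoG-filtered matrix (see [dog_filter()]).
#' @param radius expected blob radius in px (>= 1); also the minimum
#'   separation between detections.
#' @param quality_threshold minimum response at the maximum.
#' @return data.frame `x`, `y` (sub-pixel, 1-based), `quality`; possibly
#'   empty.
#' @export
detect_spots <- function(filtered, radius = 3, quality_threshold = 0) {
  if (radius < 1) stop("`radius` must be >= 1")
  h <- nrow(filtered); w <- ncol(filtered)
  r <- ceiling(radius)
  # grey dilation over a (2r+1)^2 square via shifted pmax
  dil <- filtered
  for (dy in (-r):r) for (dx in (-r):r) {
    if (dy == 0 && dx == 0) next
    ys <- reflect_idx(seq_len(h) + dy, h)
    xs <- reflect_idx(seq_len(w) + dx, w)
    dil <- pmax(dil, filtered[ys, xs, drop = FALSE])
  }
  cand <- which(filtered >= dil & filtered >= quality_threshold, arr.ind = TRUE)
  if (nrow(cand) == 0)
    return(data.frame(x = numeric(0), y = numeric(0), quality = numeric(0)))
  q <- filtered[cand]
  ord <- order(-q)
  cand <- cand[ord, , drop = FALSE]; q <- q[ord]
  # greedy non-maximum suppression at euclidean distance < radius
  keep <- rep(TRUE, nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!keep[i]) next
    if (i < nrow(cand)) {
      later <- (i + 1):nrow(cand)
      d2 <- (cand[later, 1] - cand[i, 1])^2 + (cand[later, 2] - cand[i, 2])^2
      keep[later][d2 < radius^2] <- FALSE
    }
  }
  cand <- cand[keep, , drop = FALSE]; q <- q[keep]
  # sub-pixel: 1-D parabola through the three samples along each axis
  subpix <- function(cm, c0, cp) {
    den <- cm - 2 * c0 + cp
    if (den >= 0) return(0)   # not a proper maximum; keep integer position
    max(-0.5, min(0.5, 0.5 * (cm - cp) / den))
  }
  x <- y <- numeric(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    yy <- cand[i, 1]; xx <- cand[i, 2]
    dy <- if (yy > 1 && yy < h)
      subpix(filtered[yy - 1, xx], filtered[yy, xx], filtered[yy + 1, xx]) else 0
    dx <- if (xx > 1 && xx < w)
      subpix(filtered[yy, xx - 1], filtered[yy, xx], filtered[yy, xx + 1]) else 0
    x[i] <- xx + dx; y[i] <- yy + dy
  }
  data.frame(x = x, y = y, quality = q)
}

#' Detect spots in every frame of a movie
#'
#' Applies [dog_filter()] and [detect_spots()] per frame of a (projected)
#' movie. Default sigmas follow the blob radius: `sigma_small = radius /
#' sqrt(2)` and `sigma_large = 1.6 * sigma_small`.
#'
#' @param stack a 2-D-per-frame [movie_stack()].
#' @param radius blob radius in px.
#' @param quality_threshold minimum DoG response.
#' @param sigma_small,sigma_large DoG sigmas; defaults derived from
#'   `radius`.
#' @return a `spot_set`: data.frame `frame`, `x`, `y`, `quality`.
#' @export
detect_movie_spots <- function(stack, radius = 3, quality_threshold = 0,
                               sigma_small = radius / sqrt(2),
                               sigma_large = 1.6 * sigma_small) {
  stopifnot(inherits(stack, "movie_stack"))
  d <- dim(stack$frames)
  if (length(d) != 3L) stop("project the movie first (max_project)")
  out <- lapply(seq_len(d[1]), function(t) {
    f <- dog_filter(matrix(stack$frames[t, , ], d[2], d[3]),
                    sigma_small, sigma_large)
    s <- detect_spots(f, radius, quality_threshold)
    if (nrow(s) > 0) cbind(frame = t, s) else NULL
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(frame = integer(0), x = numeric(0), y = numeric(0),
                      quality = numeric(0))
  structure(out, class = c("spot_set", "data.frame"))
}

# Square linear assignment problem, Jonker-Volgenant style shortest
# augmenting paths with potentials. cost: finite n x n matrix (use a large
# finite value for forbidden pairs). Returns col assigned to each row.
solve_lap <- function(cost) {
  n <- nrow(cost)
  stopifnot(n == ncol(cost))
  INF <- Inf
  u <- numeric(n + 1L); v <- numeric(n + 1L)
  p <- integer(n + 1L)          # p[j+1] = row assigned to col j (0 = none)
  way <- integer(n + 1L)
  for (i in seq_len(n)) {
    p[1L] <- i; j0 <- 0L
    minv <- rep(INF, n + 1L)
    used <- rep(FALSE, n + 1L)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]; delta <- INF; j1 <- 0L
      free_j <- which(!used[-1L])
      if (length(free_j) > 0) {
        cur <- cost[i0, free_j] - u[i0 + 1L] - v[free_j + 1L]
        upd <- cur < minv[free_j + 1L]
        minv[free_j[upd] + 1L] <- cur[upd]
        way[free_j[upd] + 1L] <- j0
        jbest <- free_j[which.min(minv[free_j + 1L])]
        delta <- minv[jbest + 1L]; j1 <- jbest
      }
      usedj <- which(used)
      u[p[usedj] + 1L] <- u[p[usedj] + 1L] + delta
      v[usedj] <- v[usedj] - delta
      notj <- which(!used)
      minv[notj] <- minv[notj] - delta
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1L]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  assign_row <- integer(n)
  for (j in seq_len(n)) if (p[j + 1L] > 0) assign_row[p[j + 1L]] <- j
  assign_row
}

#' Link detected spots into tracks (simple LAP)
#'
#' Frame-to-frame linear assignment in the "simple" sense: no gap closing,
#' no splitting or merging. Between consecutive frames the assignment
#' minimising total squared displacement is solved with a per-link cost cap
#' of `max_disp^2`; candidate links longer than `max_disp` are forbidden,
#' and leaving a spot unlinked costs the cap. Unlinked spots start new
#' tracks. Deterministic.
#'
#' @param spots a `spot_set` (see [detect_movie_spots()]), or any data.frame
#'   with `frame`, `x`, `y` columns.
#' @param max_disp maximum linking displacement in px (> 0).
#' @return a `track_set`: data.frame `track`, `frame`, `x`, `y`.
#' @export
link_tracks <- function(spots, max_disp) {
  if (max_disp <= 0) stop("`max_disp` must be > 0")
  need <- c("frame", "x", "y")
  stopifnot(all(need %in% names(spots)))
  spots <- spots[order(spots$frame), , drop = FALSE]
  spots$track <- NA_integer_
  next_track <- 0L
  frames <- sort(unique(spots$frame))
  idx_by_frame <- split(seq_len(nrow(spots)), spots$frame)
  prev <- integer(0)
  prev_frame <- -Inf
  cap2 <- max_disp^2
  big <- 4 * cap2 + 1
  for (f in frames) {
    cur <- idx_by_frame[[as.character(f)]]
    if (length(prev) == 0 || f != prev_frame + 1) {
      # no candidates to link from (simple tracker: consecutive frames only)
      spots$track[cur] <- next_track + seq_along(cur)
      next_track <- next_track + length(cur)
    } else {
      n1 <- length(prev); n2 <- length(cur)
      d2 <- outer(spots$x[prev], spots$x[cur], `-`)^2 +
            outer(spots$y[prev], spots$y[cur], `-`)^2
      N <- n1 + n2
      cm <- matrix(big, N, N)
      cm[seq_len(n1), seq_len(n2)] <- ifelse(d2 <= cap2, d2, big)
      for (i in seq_len(n1)) cm[i, n2 + i] <- cap2
      for (j in seq_len(n2)) cm[n1 + j, j] <- cap2
      cm[n1 + seq_len(n2), n2 + seq_len(n1)] <- 0
      a <- solve_lap(cm)
      linked <- rep(FALSE, n2)
      for (i in seq_len(n1)) {
        j <- a[i]
        if (j <= n2 && d2[i, j] <= cap2) {
          spots$track[cur[j]] <- spots$track[prev[i]]
          linked[j] <- TRUE
        }
      }
      new_idx <- cur[!linked]
      if (length(new_idx) > 0) {
        spots$track[new_idx] <- next_track + seq_along(new_idx)
        next_track <- next_track + length(new_idx)
      }
    }
    prev <- cur
    prev_frame <- f
  }
  out <- spots[order(spots$track, spots$frame),
               c("track", "frame", "x", "y"), drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("track_set", "data.frame"))
}

#' Filter tracks by duration and spot count
#'
#' @param tracks a `track_set`.
#' @param min_duration_frames minimum span in frames (last - first + 1).
#' @param min_spots minimum number of spots on the track.
#' @return filtered `track_set`.
#' @export
filter_tracks <- function(tracks, min_duration_frames = 1L, min_spots = 1L) {
  if (min_duration_frames < 1 || min_spots < 1)
    stop("thresholds must be >= 1")
  if (nrow(tracks) == 0) return(tracks)
  by <- split(seq_len(nrow(tracks)), tracks$track)
  keep <- unlist(lapply(by, function(i) {
    fr <- tracks$frame[i]
    if ((max(fr) - min(fr) + 1) >= min_duration_frames &&
        length(i) >= min_spots) i else NULL
  }), use.names = FALSE)
  out <- tracks[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-track and per-cell mean speeds
#'
#' Track speed is the mean over consecutive spot pairs of euclidean
#' displacement converted to micrometres per minute:
#' `(d_px * pixel_size) / (dframes * interval) * 60`. The per-cell speed is
#' the unweighted mean of the track means (every track counts once,
#' regardless of its length).
#'
#' @param tracks a `track_set`.
#' @param stack the source [movie_stack()] (provides `pixel_size` and
#'   `interval`), or a list with those two fields.
#' @return list with `track_speeds` (data.frame `track`, `speed`,
#'   `n_spots`) and `cell_speed` (um/min; `NA` with no >= 2-spot track).
#' @export
track_speeds <- function(tracks, stack) {
  px <- stack$pixel_size; dt <- stack$interval
  if (is.null(px) || is.null(dt)) stop("stack must carry pixel_size and interval")
  by <- split(seq_len(nrow(tracks)), tracks$track)
  rows <- lapply(names(by), function(tr) {
    i <- by[[tr]]
    i <- i[order(tracks$frame[i])]
    if (length(i) < 2) return(NULL)
    dx <- diff(tracks$x[i]); dy <- diff(tracks$y[i])
    df <- diff(tracks$frame[i])
    v <- sqrt(dx^2 + dy^2) * px / (df * dt) * 60
    data.frame(track = as.integer(tr), speed = mean(v), n_spots = length(i))
  })
  ts <- do.call(rbind, rows)
  if (is.null(ts))
    ts <- data.frame(track = integer(0), speed = numeric(0),
                     n_spots = integer(0))
  list(track_speeds = ts,
       cell_speed = if (nrow(ts) > 0) mean(ts$speed) else NA_real_)
}
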