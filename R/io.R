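#' Read a binned count track
#'
#' Accepts a headered TSV (columns `chrom`, `start`, `end`, `count` and
#' optionally `gc`) or a headerless bedGraph / BED-like file
#' (`chrom start end count [gc]`). Coordinates are 0-based, half-open.
#' Malformed lines are reported with their line numbers; overlapping bins
#' name both offending lines. Chromosomes out of order raise an error unless
#' `sort = TRUE`. A missing `gc` column is filled with the constant 0.45
#' (GC correction then degenerates to the identity, with a notice).
#'
#' @param path input file.
#' @param sort re-sort instead of erroring on unsorted input.
#' @return a `bin_track` data.frame.
#' @export
read_bin_track <- function(path, sort = FALSE) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  lines <- readLines(path)
  lineno <- seq_along(lines)
  skip <- grepl("^\\s*$|^#|^track\\b|^browser\\b", lines)
  lines <- lines[!skip]; lineno <- lineno[!skip]
  if (length(lines) == 0) stop(sprintf("%s: no data lines", path))
  fields <- strsplit(lines, "[\t ]+")
  header <- NULL
  first <- fields[[1]]
  if (length(first) >= 4 && is.na(suppressWarnings(as.numeric(first[2])))) {
    header <- tolower(first)
    fields <- fields[-1]; lineno <- lineno[-1]
  }
  nf <- lengths(fields)
  bad <- which(nf < 4)
  if (length(bad) > 0)
    stop(sprintf("%s: line %d has %d fields, expected >= 4 (chrom start end count)",
                 path, lineno[bad[1]], nf[bad[1]]))
  col <- function(name, pos) {
    if (!is.null(header)) {
      i <- match(name, header)
      if (is.na(i)) return(NULL)
    } else {
      i <- pos
      if (i > min(nf)) return(NULL)
    }
    vapply(fields, `[[`, character(1), i)
  }
  chrom <- col("chrom", 1)
  start <- suppressWarnings(as.numeric(col("start", 2)))
  end <- suppressWarnings(as.numeric(col("end", 3)))
  count_chr <- col("count", 4)
  if (is.null(count_chr)) count_chr <- col("value", 4)
  count <- suppressWarnings(as.numeric(count_chr))
  gc_chr <- col("gc", 5)
  gc <- if (is.null(gc_chr)) rep(0.45, length(chrom))
        else suppressWarnings(as.numeric(gc_chr))
  for (v in list(start = start, end = end, count = count)) {
    bad <- which(is.na(v))
    if (length(bad) > 0)
      stop(sprintf("%s: line %d is malformed (non-numeric field)",
                   path, lineno[bad[1]]))
  }
  if (any(start < 0))
    stop(sprintf("%s: line %d has a negative coordinate",
                 path, lineno[which(start < 0)[1]]))
  if (any(end <= start))
    stop(sprintf("%s: line %d has end <= start", path,
                 lineno[which(end <= start)[1]]))
  if (any(count < 0))
    stop(sprintf("%s: line %d has a negative count", path,
                 lineno[which(count < 0)[1]]))
  df <- data.frame(chrom = chrom, start = start, end = end, gc = gc,
                   count = count, line = lineno, stringsAsFactors = FALSE)
  # chromosome blocks must be contiguous and internally sorted
  ord <- order(match(df$chrom, unique(df$chrom)), df$start)
  if (!identical(ord, seq_len(nrow(df)))) {
    if (!sort)
      stop(sprintf("%s: input is not sorted; pass sort = TRUE to re-sort", path))
    df <- df[ord, , drop = FALSE]
  }
  for (ch in unique(df$chrom)) {
    d <- df[df$chrom == ch, , drop = FALSE]
    if (nrow(d) > 1) {
      ov <- which(d$start[-1] < d$end[-nrow(d)])
      if (length(ov) > 0)
        stop(sprintf("%s: bins overlap on %s (lines %d and %d)",
                     path, ch, d$line[ov[1]], d$line[ov[1] + 1]))
    }
  }
  df$line <- NULL
  rownames(df) <- NULL
  structure(df, class = c("bin_track", "data.frame"))
}

#' Write a binned track as headered TSV
#'
#' @param track a `bin_track`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bin_track <- function(track, path) {
  track <- as_bin_track(track)
  utils::write.table(
    track[, c("chrom", "start", "end", "gc", "count")], path,
    sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an interval track as bedGraph
#'
#' Four columns, no header: `chrom start end value`, 0-based half-open.
#'
#' @param df data.frame with `chrom`, `start`, `end` and the value column.
#' @param path output path.
#' @param value_col which column carries the value (default `count`, or
#'   `log2ratio` for ratio tracks).
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(df, path, value_col = "count") {
  stopifnot(all(c("chrom", "start", "end", value_col) %in% names(df)))
  out <- data.frame(df$chrom, format(df$start, scientific = FALSE, trim = TRUE),
                    format(df$end, scientific = FALSE, trim = TRUE),
                    sprintf("%.17g", df[[value_col]]))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write / read a segment table
#'
#' Headered TSV with `chrom`, `start`, `end`, `n_bins`, `mean_log2` and,
#' after [call_copy_numbers()], `cn`.
#'
#' @param segments a `segment_set`.
#' @param path file path.
#' @return `write_segments`: `path` invisibly; `read_segments`: a
#'   `segment_set`.
#' @export
write_segments <- function(segments, path) {
  stopifnot(inherits(segments, "segment_set"))
  df <- as.data.frame(segments)
  df$mean_log2 <- sprintf("%.17g", df$mean_log2)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_segments
#' @export
read_segments <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "mean_log2")
  if (!all(need %in% names(df)))
    stop(sprintf("%s: expected columns %s", path, paste(need, collapse = ", ")))
  structure(df, class = c("segment_set", "data.frame"))
}

#' Write / read a movie as a plain-text stack
#'
#' A self-describing text format (one whitespace matrix per frame after a
#' small header) used in place of multi-frame TIFF: the toolchain here is
#' text-only and R lacks a TIFF codec in this stack. Values round-trip
#' bit-exactly via 17 significant digits.
#'
#' @param stack a 2-D-per-frame [movie_stack()].
#' @param path file path.
#' @param pixel_size,interval calibration overrides when the file header
#'   lacks them (required then).
#' @return `write_movie`: `path` invisibly; `read_movie`: a `movie_stack`.
#' @export
write_movie <- function(stack, path) {
  stopifnot(inherits(stack, "movie_stack"))
  d <- dim(stack$frames)
  if (length(d) != 3L) stop("write_movie expects 2-D-per-frame movies")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# cinmetrics movie v1",
               sprintf("# frames: %d", d[1]),
               sprintf("# height: %d", d[2]),
               sprintf("# width: %d", d[3]),
               sprintf("# pixel_size_um: %.17g", stack$pixel_size),
               sprintf("# interval_s: %.17g", stack$interval)), con)
  for (t in seq_len(d[1])) {
    writeLines(sprintf("# frame %d", t), con)
    m <- matrix(stack$frames[t, , ], d[2], d[3])
    writeLines(apply(m, 1, function(r) paste(sprintf("%.17g", r),
                                             collapse = " ")), con)
  }
  invisible(path)
}

#' @rdname write_movie
#' @export
read_movie <- function(path, pixel_size = NULL, interval = NULL) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  lines <- readLines(path)
  meta <- function(key) {
    m <- grep(sprintf("^# %s:", key), lines, value = TRUE)
    if (length(m) == 0) return(NULL)
    as.numeric(sub(sprintf("^# %s:\\s*", key), "", m[1]))
  }
  nt <- meta("frames"); h <- meta("height"); w <- meta("width")
  if (is.null(nt) || is.null(h) || is.null(w))
    stop(sprintf("%s: missing frames/height/width header", path))
  pixel_size <- pixel_size %||% meta("pixel_size_um")
  interval <- interval %||% meta("interval_s")
  if (is.null(pixel_size))
    stop("pixel size not in file header; pass `pixel_size` explicitly")
  if (is.null(interval))
    stop("frame interval not in file header; pass `interval` explicitly")
  data_lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(data_lines) != nt * h)
    stop(sprintf("%s: expected %d data rows, found %d", path, nt * h,
                 length(data_lines)))
  vals <- as.numeric(unlist(strsplit(data_lines, "[ \t]+")))
  if (length(vals) != nt * h * w || anyNA(vals))
    stop(sprintf("%s: malformed pixel data", path))
  frames <- array(0, dim = c(nt, h, w))
  rows <- matrix(vals, nrow = nt * h, ncol = w, byrow = TRUE)
  for (t in seq_len(nt))
    frames[t, , ] <- rows[(t - 1) * h + seq_len(h), , drop = FALSE]
  movie_stack(frames, pixel_size, interval)
}

#' Write a track set as CSV
#'
#' Columns `track`, `frame`, `x`, `y`.
#'
#' @param tracks a `track_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(tracks, path) {
  df <- as.data.frame(tracks)[, c("track", "frame", "x", "y")]
  df$x <- sprintf("%.17g", df$x)
  df$y <- sprintf("%.17g", df$y)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
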