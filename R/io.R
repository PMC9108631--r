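#' Write a movie to multi-page TIFF
#'
#' Counts are stored as 16-bit samples scaled by `2^bit_depth - 1`, so the
#' round trip is lossless for integer data up to 16-bit. Multi-channel
#' movies are written either as one file per channel (`"separate"`, file
#' names gain a `_chN` suffix) or as channel-interleaved pages within one
#' file (`"interleaved"`: ch1 frame 0, ch2 frame 0, ch1 frame 1, ...).
#'
#' @param movie a [puncta_movie()].
#' @param path output path (`.tif`).
#' @param layout `"separate"` or `"interleaved"`.
#' @return the written file path(s), invisibly.
#' @export
write_movie <- function(movie, path, layout = c("separate", "interleaved")) {
  stopifnot(inherits(movie, "puncta_movie"))
  layout <- match.arg(layout)
  scale <- 2^movie$bit_depth - 1
  to_pages <- function(arr) lapply(seq_len(dim(arr)[3]),
                                   function(f) arr[, , f] / scale)
  nch <- length(movie$channels)
  if (layout == "separate" && nch > 1L) {
    paths <- vapply(seq_len(nch), function(ch)
      sub("(\\.tiff?)$", sprintf("_ch%d\\1", ch), path, ignore.case = TRUE),
      "")
    for (ch in seq_len(nch))
      tiff::writeTIFF(to_pages(movie$channels[[ch]]), paths[ch],
                      bits.per.sample = 16L)
    return(invisible(paths))
  }
  pages <- list()
  for (f in seq_len(n_frames(movie)))
    for (ch in seq_len(nch))
      pages[[length(pages) + 1L]] <- movie$channels[[ch]][, , f] / scale
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a movie from multi-page TIFF
#'
#' @param path file path, or a vector of per-channel paths for the
#'   `"separate"` layout.
#' @param n_channels number of channels in the file (for the interleaved
#'   layout).
#' @param layout `"separate"` or `"interleaved"`.
#' @param pixel_size,frame_interval,bit_depth acquisition metadata to
#'   attach (TIFF does not carry them).
#' @return a [puncta_movie()].
#' @export
read_movie <- function(path, n_channels = 1L,
                       layout = c("separate", "interleaved"),
                       pixel_size = 0.19, frame_interval = 1,
                       bit_depth = 16) {
  layout <- match.arg(layout)
  scale <- 2^bit_depth - 1
  read_pages <- function(p) {
    if (!file.exists(p)) stop("file not found: ", p)
    pages <- tiff::readTIFF(p, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    dims <- vapply(pages, function(x) dim(x)[1:2], integer(2))
    if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
      stop("inconsistent page shapes in ", p)
    lapply(pages, function(x) {
      if (length(dim(x)) == 3L) x <- x[, , 1]
      round(x * scale)
    })
  }
  if (layout == "separate") {
    if (length(path) == 1L && n_channels > 1L)
      path <- vapply(seq_len(n_channels), function(ch)
        sub("(\\.tiff?)$", sprintf("_ch%d\\1", ch), path,
            ignore.case = TRUE), "")
    channels <- lapply(path, function(p) {
      pages <- read_pages(p)
      array(unlist(pages), dim = c(dim(pages[[1]]), length(pages)))
    })
  } else {
    pages <- read_pages(path)
    if (length(pages) %% n_channels != 0L)
      stop("page count is not a multiple of n_channels")
    nf <- length(pages) %/% n_channels
    channels <- lapply(seq_len(n_channels), function(ch) {
      sel <- pages[seq(ch, length(pages), by = n_channels)]
      array(unlist(sel), dim = c(dim(sel[[1]]), nf))
    })
  }
  puncta_movie(channels, pixel_size, frame_interval, bit_depth)
}

#' Write trajectories to CSV
#'
#' Columns `track_id, frame, t_s, x_um, y_um` (frame indices 0-based);
#' gap frames are absent rows and survive the round trip unchanged.
#'
#' @param tracks trajectory data.frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(tracks, path) {
  need <- c("track_id", "frame", "t_s", "x_um", "y_um")
  stopifnot(all(need %in% names(tracks)))
  utils::write.csv(tracks[, need], path, row.names = FALSE)
  invisible(path)
}

#' Read trajectories from CSV
#'
#' @param path CSV path with columns `track_id, frame, t_s, x_um, y_um`.
#' @return trajectory data.frame, validated (frames strictly increasing
#'   within each track).
#' @export
read_tracks <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path)
  need <- c("track_id", "frame", "t_s", "x_um", "y_um")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing columns: ", paste(miss, collapse = ", "))
  bad <- tapply(df$frame, df$track_id, function(f) any(diff(f) <= 0))
  if (any(unlist(bad)))
    stop("frames are not strictly increasing within every track")
  df
}
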