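#' Global Otsu threshold
#'
#' Exhaustive maximization of between-class intensity variance over 256
#' candidate levels. Integer-valued images in `[0, 255]` use the exact
#' 8-bit levels; other images are binned into 256 equal-width bins over
#' their range. Ties (e.g. a two-level image) resolve to the midpoint of
#' the maximizing range, so a `{0, 255}` image thresholds strictly between
#' the two levels. Foreground is `image > threshold`.
#'
#' @param image numeric matrix; must not be constant.
#' @return threshold value on the intensity scale of `image`.
#' @export
otsu_threshold <- function(image) {
  x <- as.numeric(image)
  if (!length(x)) stop("empty image")
  rng <- range(x)
  if (diff(rng) == 0) stop("no threshold exists for a constant image")
  eight_bit <- all(x == round(x)) && rng[1] >= 0 && rng[2] <= 255
  if (eight_bit) {
    levels <- 0:255
    h <- tabulate(x + 1L, 256L)
  } else {
    levels <- seq(rng[1], rng[2], length.out = 257L)[-257L]
    bin <- pmin(floor((x - rng[1]) / diff(rng) * 256) + 1L, 256L)
    h <- tabulate(bin, 256L)
    levels <- levels + diff(rng) / 512  # bin centres
  }
  w <- cumsum(h)
  mu <- cumsum(h * levels)
  n <- w[256]; mtot <- mu[256]
  w0 <- w[1:255]; w1 <- n - w0
  valid <- w0 > 0 & w1 > 0
  bcv <- rep(-Inf, 255)
  m0 <- mu[1:255] / w0
  m1 <- (mtot - mu[1:255]) / w1
  bcv[valid] <- w0[valid] * w1[valid] * (m0[valid] - m1[valid])^2
  best <- which(bcv == max(bcv))
  t_idx <- mean(range(best))  # midpoint of the maximizing plateau
  if (eight_bit) {
    if (t_idx == round(t_idx)) as.numeric(levels[t_idx]) else
      (levels[floor(t_idx)] + levels[ceiling(t_idx)]) / 2
  } else {
    rng[1] + t_idx / 256 * diff(rng)
  }
}

#' 8-connected component labelling
#'
#' @param mask logical or 0/1 matrix.
#' @return integer matrix of labels (0 = background), labelled in order of
#'   first occurrence (column-major).
#' @export
label_components <- function(mask) {
  stopifnot(is.matrix(mask))
  m <- mask != 0
  out <- matrix(0L, nrow(m), ncol(m))
  idx <- which(m)
  if (!length(idx)) return(out)
  nr <- nrow(m); nc <- ncol(m)
  r <- ((idx - 1L) %% nr) + 1L
  cc <- ((idx - 1L) %/% nr) + 1L
  edge_pairs <- function(dr, dc) {
    r2 <- r + dr; c2 <- cc + dc
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    j <- (c2[ok] - 1L) * nr + r2[ok]
    keep <- m[j]
    cbind(idx[ok][keep], j[keep])
  }
  e <- rbind(edge_pairs(1L, 0L), edge_pairs(0L, 1L),
             edge_pairs(1L, 1L), edge_pairs(-1L, 1L))
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (nrow(e))
    g <- igraph::add_edges(g, t(matrix(match(c(e), idx), ncol = 2)))
  memb <- igraph::components(g)$membership
  relabel <- match(memb, unique(memb))  # stable column-major ordering
  out[idx] <- relabel
  out
}

# Moore-neighbour boundary tracing of a single-object mask, returning the
# chain-code perimeter with Vossepoel-Smeulders weights
# (0.980 per axial step, 1.406 per diagonal step, -0.091 per corner),
# which is near-unbiased for digitized circles and near-exact for
# axis-aligned rectangles. Degenerate objects whose boundary cannot be
# traced get the perimeter of the equal-area circle (circularity 1).
object_perimeter_px <- function(mask) {
  area <- sum(mask != 0)
  if (area == 0L) return(0)
  p <- matrix(0L, nrow(mask) + 2L, ncol(mask) + 2L)
  p[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)] <- (mask != 0) * 1L
  # clockwise Moore neighbourhood starting at West
  dr <- c(0L, -1L, -1L, -1L, 0L, 1L, 1L, 1L)
  dc <- c(-1L, -1L, 0L, 1L, 1L, 1L, 0L, -1L)
  start <- which(p == 1L)[1]
  nr <- nrow(p)
  r0 <- ((start - 1L) %% nr) + 1L
  c0 <- ((start - 1L) %/% nr) + 1L
  chain <- integer(0)
  r <- r0; cc <- c0
  b <- 1L  # scan start: the (background) West neighbour of the start pixel
  max_iter <- 4L * area + 8L
  for (step in seq_len(max_iter)) {
    found <- 0L
    for (k in 0:7) {
      j <- ((b - 1L + k) %% 8L) + 1L
      if (p[r + dr[j], cc + dc[j]] == 1L) { found <- j; break }
    }
    if (found == 0L) break  # isolated pixel
    r <- r + dr[found]; cc <- cc + dc[found]
    # next scan starts one step clockwise past the direction we came from
    b <- ((found + 4L - 1L) %% 8L) + 1L
    b <- (b %% 8L) + 1L
    chain <- c(chain, found)
    if (r == r0 && cc == c0 && length(chain) > 2L) break
  }
  if (!length(chain)) return(2 * sqrt(pi * area))
  diag_steps <- sum(chain %% 2L == 0L)
  axial_steps <- length(chain) - diag_steps
  corners <- sum(diff(c(chain, chain[1])) != 0)
  len <- 0.980 * axial_steps + 1.406 * diag_steps - 0.091 * corners
  if (len <= 0) 2 * sqrt(pi * area) else len
}

#' Segment fluorescent objects by Otsu thresholding
#'
#' Optionally median-filters the image, binarises it at the global Otsu
#' threshold, labels 8-connected components, drops components below
#' `min_area` pixels, and measures each object: area, chain-code
#' perimeter, circularity (`4*pi*area/perimeter^2`, clipped at 1),
#' centroid and mean intensity (taken from the unfiltered image).
#'
#' @param image numeric matrix of intensities; must not be constant.
#' @param smoothing median filter half-width in pixels (0 = none).
#' @param min_area minimum object area in pixels (default 4, suppressing
#'   single-pixel noise).
#' @param pixel_size um per pixel (1 to keep pixel units).
#' @return list with `mask` (labelled integer matrix), `threshold`, and
#'   `objects` (data.frame: `label`, `area_px`, `area_um2`,
#'   `perimeter_um`, `circularity`, `x_um`, `y_um`, `mean_intensity`).
#' @export
segment_objects <- function(image, smoothing = 0, min_area = 4,
                            pixel_size = 1) {
  stopifnot(is.matrix(image), is.numeric(image))
  if (diff(range(image)) == 0) stop("no threshold exists for a constant image")
  work <- image
  if (smoothing > 0) {
    hi <- max(work)
    lo <- min(work)
    scaled <- (work - lo) / (hi - lo)
    work <- EBImage::medianFilter(scaled, as.integer(smoothing)) *
      (hi - lo) + lo
  }
  thr <- otsu_threshold(work)
  labels <- label_components(work > thr)
  objs <- measure_labelled(labels, image, pixel_size, min_area)
  # relabel mask to the retained objects
  keep_map <- integer(max(labels, 1L))
  if (nrow(objs)) keep_map[objs$label] <- seq_len(nrow(objs))
  mask <- matrix(0L, nrow(labels), ncol(labels))
  nz <- labels > 0L
  mask[nz] <- keep_map[labels[nz]]
  objs$label <- seq_len(nrow(objs))
  list(mask = mask, threshold = thr, objects = objs)
}

#' Measure all objects of a labelled mask
#'
#' Computes the morphometric table ([segment_objects()] output) for an
#' existing labelled mask against an intensity image.
#'
#' @param labels integer matrix of object labels (0 = background).
#' @param image numeric intensity matrix, same shape.
#' @param pixel_size um per pixel.
#' @param min_area minimum object area in pixels.
#' @return per-object data.frame (see [segment_objects()]).
#' @export
measure_labelled <- function(labels, image, pixel_size = 1, min_area = 0) {
  n <- max(labels)
  rows <- vector("list", n)
  nr <- nrow(labels)
  for (lab in seq_len(n)) {
    idx <- which(labels == lab)
    area <- length(idx)
    if (area < min_area || area == 0L) next
    r <- ((idx - 1L) %% nr) + 1L
    cc <- ((idx - 1L) %/% nr) + 1L
    sub <- matrix(0L, max(r) - min(r) + 3L, max(cc) - min(cc) + 3L)
    sub[cbind(r - min(r) + 2L, cc - min(cc) + 2L)] <- 1L
    per_px <- object_perimeter_px(sub)
    circ <- if (per_px > 0) min(4 * pi * area / per_px^2, 1) else 1
    rows[[lab]] <- data.frame(
      label = lab, area_px = area, area_um2 = area * pixel_size^2,
      perimeter_um = per_px * pixel_size, circularity = circ,
      x_um = mean(cc - 1L) * pixel_size, y_um = mean(r - 1L) * pixel_size,
      mean_intensity = mean(image[idx]))
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(label = integer(0), area_px = numeric(0),
                      area_um2 = numeric(0), perimeter_um = numeric(0),
                      circularity = numeric(0), x_um = numeric(0),
                      y_um = numeric(0), mean_intensity = numeric(0))
  rownames(out) <- NULL
  out
}

#' Summarize object morphometrics
#'
#' @param objects object table from [segment_objects()].
#' @return list with the per-object `table`, `count`, `mean_area_um2`,
#'   `mean_circularity`.
#' @export
measure_morphometrics <- function(objects) {
  if (is.null(objects) || !nrow(objects)) stop("no objects to measure")
  list(table = objects, count = nrow(objects),
       mean_area_um2 = mean(objects$area_um2),
       mean_circularity = mean(objects$circularity))
}

#' Per-cell mean grey value
#'
#' Arithmetic mean of pixel intensities inside each cell mask, optionally
#' log10-transformed (only defined for positive means; non-positive means
#' yield `NA` rather than `-Inf`).
#'
#' @param image numeric intensity matrix.
#' @param cells integer matrix of cell labels (0 = background), same shape
#'   as `image`; every labelled cell must be non-empty.
#' @param log10 apply a log10 transform to the means.
#' @return data.frame: `cell_id`, `mean_grey`, and `log10_mean_grey` when
#'   requested.
#' @export
measure_cell_intensity <- function(image, cells, log10 = FALSE) {
  stopifnot(is.matrix(image), is.matrix(cells),
            all(dim(image) == dim(cells)))
  ids <- sort(unique(cells[cells > 0]))
  if (!length(ids)) stop("no cells in mask")
  means <- vapply(ids, function(id) mean(image[cells == id]), 0)
  out <- data.frame(cell_id = ids, mean_grey = means)
  if (log10) {
    lg <- rep(NA_real_, length(means))
    pos <- means > 0
    lg[pos] <- log10(means[pos])
    out$log10_mean_grey <- lg
  }
  out
}

#' Percentage of cells containing at least one aggregate
#'
#' A cell is positive when at least one aggregate centroid falls inside
#' its mask.
#'
#' @param objects aggregate object table (columns `x_um`, `y_um`), e.g.
#'   from [segment_objects()].
#' @param cells integer matrix of cell labels (0 = background).
#' @param pixel_size um per pixel used for the centroid coordinates.
#' @return list with `percent` (0..100) and `table` (data.frame `cell_id`,
#'   `n_aggregates`, `positive`).
#' @export
quantify_uptake <- function(objects, cells, pixel_size = 1) {
  stopifnot(is.matrix(cells))
  ids <- sort(unique(cells[cells > 0]))
  if (!length(ids)) stop("no cells in mask")
  counts <- setNames(integer(length(ids)), ids)
  if (!is.null(objects) && nrow(objects)) {
    r <- round(objects$y_um / pixel_size) + 1L
    cc <- round(objects$x_um / pixel_size) + 1L
    ok <- r >= 1L & r <= nrow(cells) & cc >= 1L & cc <= ncol(cells)
    hit <- cells[cbind(r[ok], cc[ok])]
    hit <- hit[hit > 0]
    if (length(hit)) {
      tab <- table(hit)
      counts[names(tab)] <- as.integer(tab)
    }
  }
  tbl <- data.frame(cell_id = ids, n_aggregates = as.integer(counts),
                    positive = counts > 0)
  list(percent = 100 * mean(tbl$positive), table = tbl)
}
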