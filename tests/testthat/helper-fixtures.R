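# Shared fixtures and independent oracles used across the test files.

# Brute-force all-ordered-pairs MSD oracle (independent of compute_msd).
msd_oracle <- function(track) {
  track <- track[order(track$frame), ]
  f <- track$frame
  dt <- stats::median(diff(track$t_s) / diff(f))
  span <- max(f) - min(f)
  out <- lapply(seq_len(span), function(n) {
    sq <- c()
    for (i in seq_len(nrow(track))) {
      j <- which(f == f[i] + n)
      if (length(j) == 1)
        sq <- c(sq, (track$x_um[j] - track$x_um[i])^2 +
                     (track$y_um[j] - track$y_um[i])^2)
    }
    if (length(sq)) data.frame(lag_s = n * dt, msd_um2 = mean(sq),
                               n_pairs = length(sq)) else NULL
  })
  do.call(rbind, out)
}

# Random gapped trajectory for property sweeps.
random_track <- function(max_points = 10) {
  n <- sample(2:max_points, 1)
  frames <- sort(sample(0:(max_points + 4), n))
  data.frame(track_id = 1L, frame = frames, t_s = frames * 1.0,
             x_um = stats::rnorm(n), y_um = stats::rnorm(n))
}

# Exhaustive minimum-cost assignment by permutation enumeration.
enumerate_assignment <- function(cost) {
  n <- nrow(cost)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    out
  }
  best <- Inf
  for (p in perms(seq_len(n)))
    best <- min(best, sum(cost[cbind(seq_len(n), p)]))
  best
}

# Direct (loop-based) exhaustive Otsu oracle for 8-bit images: maximize
# between-class variance over all candidate levels 0..254; exact ties
# (empty-bin plateaus) resolve to the midpoint of the maximizing range,
# the same convention the package documents.
otsu_oracle_8bit <- function(img) {
  x <- as.numeric(img)
  v <- vapply(0:254, function(t) {
    lo <- x[x <= t]; hi <- x[x > t]
    if (!length(lo) || !length(hi)) return(-Inf)
    length(lo) * length(hi) * (mean(lo) - mean(hi))^2
  }, 0)
  best <- which(v == max(v)) - 1L
  mean(range(best))
}

# Rasterized shapes for morphometrics.
raster_disc <- function(radius, size = 2 * radius + 20) {
  ctr <- size / 2
  x <- matrix(rep(seq_len(size), size), size)
  y <- t(x)
  (x - ctr)^2 + (y - ctr)^2 <= radius^2
}
raster_square <- function(side, pad = 10) {
  m <- matrix(FALSE, side + 2 * pad, side + 2 * pad)
  m[pad + seq_len(side), pad + seq_len(side)] <- TRUE
  m
}

# Greedy nearest-neighbour matching of detections to ground truth within
# `tol_px`; returns true/false positives/negatives and match errors (px).
match_detections <- function(det, truth, pixel_size, tol_px = 2) {
  tp <- 0L; fn <- 0L; errs <- c()
  used <- rep(FALSE, nrow(det))
  for (i in seq_len(nrow(truth))) {
    if (!nrow(det)) { fn <- fn + 1L; next }
    d <- sqrt((det$x_px - truth$x_um[i] / pixel_size)^2 +
              (det$y_px - truth$y_um[i] / pixel_size)^2)
    d[used] <- Inf
    j <- which.min(d)
    if (d[j] < tol_px) {
      tp <- tp + 1L; used[j] <- TRUE; errs <- c(errs, d[j])
    } else fn <- fn + 1L
  }
  list(tp = tp, fn = fn, fp = sum(!used), errs = errs)
}

# Delete `gap_len` consecutive frames (1-3, random start) from every
# particle; returns the thinned table plus the flanking frames of each
# injected gap.
inject_gaps <- function(det, seed) {
  set.seed(seed)
  flank <- list(); keep <- rep(TRUE, nrow(det))
  for (p in unique(det$particle_id)) {
    rows <- which(det$particle_id == p)
    g <- sample(1:3, 1); s <- sample(5:20, 1)
    cut <- rows[det$frame[rows] %in% s:(s + g - 1)]
    keep[cut] <- FALSE
    flank[[as.character(p)]] <- c(before = s - 1, after = s + g)
  }
  list(det = det[keep, ], flank = flank)
}

# Fraction of injected gaps whose flanking detections share a track id.
gap_bridge_rate <- function(tracks, det, flank) {
  key <- paste(det$particle_id, det$frame)
  tkey <- paste(det$frame, round(det$x_um, 9), round(det$y_um, 9))
  lkey <- paste(tracks$frame, round(tracks$x_um, 9), round(tracks$y_um, 9))
  tid <- tracks$track_id[match(tkey, lkey)]
  ok <- vapply(names(flank), function(p) {
    a <- tid[key == paste(p, flank[[p]]["before"])]
    b <- tid[key == paste(p, flank[[p]]["after"])]
    length(a) == 1 && length(b) == 1 && !is.na(a) && a == b
  }, TRUE)
  mean(ok)
}

# Fraction of ground-truth consecutive observations joined into the same
# linked track (positions are matched exactly; works on noise-free input).
link_recovery <- function(tracks, det) {
  key <- paste(det$frame, round(det$x_um, 9), round(det$y_um, 9))
  tkey <- paste(tracks$frame, round(tracks$x_um, 9), round(tracks$y_um, 9))
  tid <- tracks$track_id[match(key, tkey)]
  n_true <- 0L; n_rec <- 0L
  for (p in unique(det$particle_id)) {
    rows <- which(det$particle_id == p)
    rows <- rows[order(det$frame[rows])]
    for (i in seq_len(length(rows) - 1L)) {
      n_true <- n_true + 1L
      if (!is.na(tid[rows[i]]) && !is.na(tid[rows[i + 1L]]) &&
          tid[rows[i]] == tid[rows[i + 1L]])
        n_rec <- n_rec + 1L
    }
  }
  c(recovered = n_rec, total = n_true)
}
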