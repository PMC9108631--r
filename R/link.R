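#' Link per-frame detections into trajectories
#'
#' Two-pass LAP (linear assignment problem) tracking. Pass 1 links
#' detections between consecutive frames by minimizing total squared
#' displacement via optimal bipartite assignment, with a non-link
#' alternative costing `linking_max_distance^2` (links longer than
#' `linking_max_distance` are forbidden). Pass 2 joins the resulting track
#' segments end-to-start when the frame difference is at most
#' `max_frame_gap` and the bridged distance at most
#' `gap_closing_max_distance`, again by optimal assignment on squared
#' distance. Each detection belongs to at most one trajectory.
#'
#' @param detections data.frame with columns `frame` (0-based), `x_um`,
#'   `y_um` (other columns are carried through).
#' @param cfg a [linking_config()].
#' @param dt frame interval in seconds (fills the `t_s` column).
#'
#' @return data.frame of trajectories: `track_id`, `frame`, `t_s`, `x_um`,
#'   `y_um` (plus carried columns), ordered by track then frame. Gap
#'   frames are simply absent rows.
#' @export
link_tracks <- function(detections, cfg = linking_config(), dt = 1) {
  stopifnot(inherits(cfg, "linking_config"), is.data.frame(detections))
  need <- c("frame", "x_um", "y_um")
  if (!all(need %in% names(detections)))
    stop("detections must have columns frame, x_um, y_um")
  if (!nrow(detections)) {
    out <- detections
    out$track_id <- integer(0); out$t_s <- numeric(0)
    return(out)
  }
  det <- detections[order(detections$frame), , drop = FALSE]
  det$.row <- seq_len(nrow(det))
  frames <- sort(unique(det$frame))

  # ---- pass 1: frame-to-frame linking ----------------------------------
  seg_of <- rep(NA_integer_, nrow(det))   # segment id per detection row
  n_seg <- 0L
  by_frame <- split(seq_len(nrow(det)), factor(det$frame, levels = frames))
  lmax2 <- cfg$linking_max_distance^2

  prev_rows <- by_frame[[1]]
  seg_of[prev_rows] <- n_seg + seq_along(prev_rows)
  n_seg <- n_seg + length(prev_rows)
  for (k in seq_along(frames)[-1]) {
    cur_rows <- by_frame[[k]]
    linked <- rep(NA_integer_, length(cur_rows))
    if (frames[k] - frames[k - 1] == 1L &&
        length(prev_rows) && length(cur_rows)) {
      d2 <- outer(det$x_um[prev_rows], det$x_um[cur_rows], `-`)^2 +
            outer(det$y_um[prev_rows], det$y_um[cur_rows], `-`)^2
      d2[d2 > lmax2] <- NA
      match_idx <- solve_link_lap(d2, lmax2)
      ok <- !is.na(match_idx)
      seg_of[cur_rows[match_idx[ok]]] <- seg_of[prev_rows[ok]]
      linked[match_idx[ok]] <- 1L
    }
    new <- which(is.na(seg_of[cur_rows]))
    seg_of[cur_rows[new]] <- n_seg + seq_along(new)
    n_seg <- n_seg + length(new)
    prev_rows <- cur_rows
  }

  # ---- pass 2: gap closing between segments ----------------------------
  seg_rows <- split(seq_len(nrow(det)), seg_of)
  ends <- vapply(seg_rows, function(r) r[which.max(det$frame[r])], 0L)
  starts <- vapply(seg_rows, function(r) r[which.min(det$frame[r])], 0L)
  ns <- length(seg_rows)
  succ <- rep(NA_integer_, ns)
  if (ns > 1L && cfg$max_frame_gap > 0L) {
    gap <- outer(det$frame[starts], det$frame[ends], `-`)  # [j, i]
    d2 <- (outer(det$x_um[starts], det$x_um[ends], `-`)^2 +
           outer(det$y_um[starts], det$y_um[ends], `-`)^2)
    feas <- t(gap) >= 1 & t(gap) <= cfg$max_frame_gap &
            t(d2) <= cfg$gap_closing_max_distance^2
    diag(feas) <- FALSE
    cost <- t(d2); cost[!feas] <- NA
    if (any(feas)) {
      match_idx <- solve_link_lap(cost, cfg$gap_closing_max_distance^2)
      succ <- match_idx
    }
  }

  # ---- merge segment chains into final tracks --------------------------
  has_pred <- rep(FALSE, ns)
  has_pred[succ[!is.na(succ)]] <- TRUE
  track_of_seg <- rep(NA_integer_, ns)
  tid <- 0L
  for (s in seq_len(ns)) {
    if (has_pred[s]) next
    tid <- tid + 1L
    cur <- s
    while (!is.na(cur)) {
      track_of_seg[cur] <- tid
      cur <- succ[cur]
    }
  }

  det$track_id <- track_of_seg[seg_of]
  det$t_s <- det$frame * dt
  det <- det[order(det$track_id, det$frame), , drop = FALSE]
  det$.row <- NULL
  rownames(det) <- NULL
  front <- c("track_id", "frame", "t_s", "x_um", "y_um")
  det[, c(front, setdiff(names(det), front)), drop = FALSE]
}

#' Filter trajectories by duration
#'
#' Keeps only trajectories strictly longer than `min_duration` seconds
#' (duration is last minus first timepoint). With the conventional 30 s
#' threshold, a track spanning exactly 30 s is excluded.
#'
#' @param tracks trajectory data.frame (columns `track_id`, `t_s`).
#' @param min_duration minimum duration in seconds (>= 0).
#' @return the qualifying rows of `tracks`, input order preserved.
#' @export
filter_trajectories <- function(tracks, min_duration = 30) {
  stopifnot(min_duration >= 0, is.data.frame(tracks),
            all(c("track_id", "t_s") %in% names(tracks)))
  if (!nrow(tracks)) return(tracks)
  dur <- tapply(tracks$t_s, tracks$track_id, function(t) max(t) - min(t))
  keep_ids <- names(dur)[dur > min_duration]
  out <- tracks[as.character(tracks$track_id) %in% keep_ids, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Split a trajectory table into a list of per-track data.frames.
split_tracks <- function(tracks) {
  split(tracks, tracks$track_id)
}
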