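#' Time-averaged mean squared displacement of one trajectory
#'
#' Overlapping-window estimator: for lag `n` frames,
#' `MSD(n*dt) = mean_i |r(t_i + n*dt) - r(t_i)|^2` over every ordered pair
#' of observations separated by `n` frames. Gap frames are simply skipped
#' (a pair contributes only when both frames are present). All lags up to
#' the track span are reported; lags supported by fewer than 3 pairs are
#' flagged unreliable.
#'
#' @param track data.frame for a single trajectory with columns `frame`,
#'   `t_s`, `x_um`, `y_um`.
#' @return data.frame (class `msd_curve`): `lag_s`, `msd_um2`, `n_pairs`,
#'   `reliable`.
#' @export
compute_msd <- function(track) {
  stopifnot(is.data.frame(track),
            all(c("frame", "t_s", "x_um", "y_um") %in% names(track)))
  if (nrow(track) < 2L) stop("a trajectory needs at least 2 points")
  track <- track[order(track$frame), , drop = FALSE]
  f <- track$frame
  if (anyDuplicated(f)) stop("duplicate frames in trajectory")
  dt <- median(diff(track$t_s) / diff(f))
  span <- max(f) - min(f)
  # positions indexed by frame offset for O(span) pair lookup per lag
  idx <- rep(NA_integer_, span + 1L)
  idx[f - min(f) + 1L] <- seq_along(f)
  lags <- seq_len(span)
  msd <- numeric(span); npairs <- integer(span)
  for (n in lags) {
    a <- idx[seq_len(span + 1L - n)]
    b <- idx[seq_len(span + 1L - n) + n]
    ok <- !is.na(a) & !is.na(b)
    npairs[n] <- sum(ok)
    msd[n] <- if (npairs[n] > 0)
      mean((track$x_um[b[ok]] - track$x_um[a[ok]])^2 +
           (track$y_um[b[ok]] - track$y_um[a[ok]])^2) else NA_real_
  }
  keep <- npairs >= 1L
  out <- data.frame(lag_s = lags[keep] * dt, msd_um2 = msd[keep],
                    n_pairs = npairs[keep], reliable = npairs[keep] >= 3L)
  class(out) <- c("msd_curve", "data.frame")
  out
}

#' Fit the diffusive-ballistic MSD model
#'
#' Least-squares fit of `MSD = 4*D*dt + v^2*dt^2` to the measured curve
#' over lags up to `fit_range`, with both coefficients constrained
#' non-negative (a negative unconstrained coefficient is clipped to zero
#' and the best feasible reduced model re-solved). When the curve carries
#' pair counts from the overlapping-window estimator, the fit is weighted
#' by the inverse of the Brownian-motion variance of the time-averaged MSD
#' (proportional to `n*(2*n^2 + 1) / (N - n + 1)` at lag `n` frames for an
#' `N`-point track), which concentrates information at the short,
#' well-determined lags.
#'
#' Directed transport is flagged by a nested-model comparison (quadratic
#' vs pure diffusion) at `alpha_level`, with `v > 0`. Because
#' overlapping-window MSD points are strongly correlated across lags, the
#' F statistic is calibrated by parametric simulation under the fitted
#' pure-diffusion null (99 replicate Brownian tracks of the same length)
#' rather than referred to the nominal F distribution, so the test holds
#' its size on single trajectories. Curves without pair counts fall back
#' to the classical F reference distribution.
#'
#' @param curve a [compute_msd()] result (or any data.frame with `lag_s`,
#'   `msd_um2`, optionally `n_pairs`).
#' @param fit_range maximum lag fitted, in seconds (default 20 s).
#' @param include_offset also fit a non-negative constant offset
#'   (accounts for localization error, `4*sigma_loc^2`); off by default to
#'   mirror the two-term model.
#' @param alpha_level significance level of the directed-motion test.
#' @param n_null number of null simulations for the calibrated test.
#'
#' @return list of class `motion_fit`: `D` (um^2/s), `v` (um/s), `offset`
#'   (um^2 or NA), `sse`, `p_directed`, `directed_flag`, `fit_range`,
#'   `n_lags`.
#' @export
fit_diffusion_ballistic <- function(curve, fit_range = 20,
                                    include_offset = FALSE,
                                    alpha_level = 0.05, n_null = 99L) {
  stopifnot(all(c("lag_s", "msd_um2") %in% names(curve)))
  sel <- curve$lag_s <= fit_range + 1e-9 & is.finite(curve$msd_um2)
  t <- curve$lag_s[sel]; y <- curve$msd_um2[sel]
  if (length(t) < 3L) stop("need at least 3 lags within fit_range")

  # frame-lag structure (needed for variance weights and the null model)
  dt <- t[1]
  n_fr <- t / dt
  np <- if (!is.null(curve$n_pairs)) curve$n_pairs[sel] else NULL
  regular <- !is.null(np) && all(abs(n_fr - round(n_fr)) < 1e-6)
  if (regular) {
    n_fr <- round(n_fr)
    N <- np[1] + n_fr[1]
    w <- (N - n_fr + 1) / (n_fr * (2 * n_fr^2 + 1))
  } else {
    N <- NA_integer_
    w <- rep(1, length(t))
  }

  design <- function(tt) {
    X <- cbind(tt, tt^2)
    if (include_offset) cbind(1, X) else X
  }
  wfit <- function(X, y) {
    # exhaustive active-set search over the (tiny) coefficient subsets,
    # keeping the best feasible (all-non-negative) weighted fit
    p <- ncol(X); best <- NULL
    for (k in p:0) {
      subsets <- if (k == 0) list(integer(0)) else
        utils::combn(p, k, simplify = FALSE)
      for (s in subsets) {
        if (length(s) == 0L) {
          beta <- numeric(p)
        } else {
          Xs <- X[, s, drop = FALSE] * sqrt(w)
          cf <- tryCatch(solve(crossprod(Xs), crossprod(Xs, y * sqrt(w))),
                         error = function(e) NULL)
          if (is.null(cf) || any(cf < 0)) next
          beta <- numeric(p); beta[s] <- cf
        }
        sse <- sum(w * (y - X %*% beta)^2)
        if (is.null(best) || sse < best$sse - 1e-15)
          best <- list(beta = beta, sse = sse)
      }
      if (!is.null(best)) break  # prefer fuller feasible models
    }
    best
  }
  X_full <- design(t)
  X_diff <- X_full[, -ncol(X_full), drop = FALSE]
  fstat <- function(y) {
    full <- wfit(X_full, y)
    red <- wfit(X_diff, y)
    k <- length(y)
    list(full = full, red = red,
         F = if (full$sse > 0)
           (red$sse - full$sse) / (full$sse / (k - ncol(X_full))) else Inf)
  }

  obs <- fstat(y)
  cf <- obs$full$beta
  # snap numerically negligible terms (fitted contribution below the
  # floating-point resolution of the data) to exactly zero
  contrib <- abs(cf) * apply(abs(X_full), 2, max)
  cf[contrib < 1e-10 * max(abs(y), .Machine$double.eps)] <- 0
  sse <- sum(w * (y - X_full %*% cf)^2)
  off <- if (include_offset) cf[1] else NA_real_
  D <- cf[length(cf) - 1L] / 4
  v <- sqrt(max(cf[length(cf)], 0))

  tol <- 1e-12 * max(sum(y^2), 1)
  if (obs$red$sse - obs$full$sse <= tol) {
    p_directed <- 1  # diffusion explains the curve (or both fits exact)
  } else if (obs$full$sse <= tol) {
    p_directed <- 0  # exact quadratic fit, diffusion alone cannot explain it
  } else if (regular && N >= 4L && is.finite(obs$F)) {
    # parametric null calibration: Brownian tracks at the diffusion-only D
    D0 <- max(obs$red$beta[length(obs$red$beta)] / 4, .Machine$double.eps)
    old_seed <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv()) else NULL
    set.seed(as.integer(abs(sum(y) * 1e6) %% 2147483647))
    nmax <- max(n_fr)
    Fstar <- vapply(seq_len(n_null), function(i) {
      xs <- cumsum(c(0, rnorm(N - 1L, sd = sqrt(2 * D0 * dt))))
      ys <- cumsum(c(0, rnorm(N - 1L, sd = sqrt(2 * D0 * dt))))
      m <- vapply(seq_len(nmax), function(n)
        mean((xs[(1 + n):N] - xs[1:(N - n)])^2 +
             (ys[(1 + n):N] - ys[1:(N - n)])^2), 0)
      fstat(m[n_fr])$F
    }, 0)
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
    p_directed <- (1 + sum(Fstar >= obs$F)) / (n_null + 1)
  } else {
    k <- length(y)
    p_directed <- pf(max(obs$F, 0), 1, k - ncol(X_full), lower.tail = FALSE)
  }
  structure(list(D = D, v = v, offset = off, sse = sse,
                 p_directed = p_directed,
                 directed_flag = (p_directed < alpha_level) && v > 0,
                 fit_range = fit_range, n_lags = length(t)),
            class = "motion_fit")
}

#' Anomalous exponent from a log-log fit of the MSD curve
#'
#' Ordinary least-squares slope of `log(MSD)` versus `log(lag)` over the
#' first `lag_fraction` of available lags (at least 3). Zero or negative
#' MSD values are excluded. If no positive MSD values remain (an immobile
#' particle), the exponent is undefined and `NA` is returned with a
#' warning; downstream classification treats this as constrained.
#'
#' @param curve an [compute_msd()] result.
#' @param lag_fraction fraction (0..1) of the lag range used (default 0.25).
#' @return the fitted exponent `alpha` (numeric scalar, possibly `NA`).
#' @export
fit_alpha_loglog <- function(curve, lag_fraction = 0.25) {
  stopifnot(all(c("lag_s", "msd_um2") %in% names(curve)),
            lag_fraction > 0, lag_fraction <= 1)
  n_use <- max(3L, ceiling(lag_fraction * nrow(curve)))
  sub <- curve[seq_len(min(n_use, nrow(curve))), , drop = FALSE]
  sub <- sub[is.finite(sub$msd_um2) & sub$msd_um2 > 0, , drop = FALSE]
  if (nrow(sub) < 3L) {
    if (all(curve$msd_um2 <= 0, na.rm = TRUE)) {
      warning("all-zero MSD curve: anomalous exponent undefined")
      return(NA_real_)
    }
    stop("need at least 3 positive-MSD lags in the fitted span")
  }
  lx <- log(sub$lag_s); ly <- log(sub$msd_um2)
  sum((lx - mean(lx)) * (ly - mean(ly))) / sum((lx - mean(lx))^2)
}

#' Classify motion from the anomalous exponent
#'
#' Slope near 1 indicates free diffusion, near 2 directed transport, and
#' below 1 constrained motion. The default bin edges (0.8, 1.5) place
#' those anchors in the diffusive, transported and constrained classes
#' respectively.
#'
#' @param alpha anomalous exponent(s); `NA` maps to `"constrained"`
#'   (immobile particles).
#' @param bins two increasing thresholds `c(lower, upper)`.
#' @return character vector: `"constrained"`, `"diffusive"` or
#'   `"transported"`.
#' @export
classify_motion <- function(alpha, bins = c(0.8, 1.5)) {
  stopifnot(length(bins) == 2L, bins[1] < bins[2])
  out <- ifelse(is.na(alpha), "constrained",
         ifelse(alpha < bins[1], "constrained",
         ifelse(alpha < bins[2], "diffusive", "transported")))
  as.character(out)
}

#' Per-trajectory motion analysis
#'
#' Runs [compute_msd()], [fit_diffusion_ballistic()], [fit_alpha_loglog()]
#' and [classify_motion()] on every trajectory of a track table.
#'
#' @param tracks trajectory data.frame (`track_id`, `frame`, `t_s`,
#'   `x_um`, `y_um`).
#' @param fit_range,include_offset passed to [fit_diffusion_ballistic()].
#' @param lag_fraction passed to [fit_alpha_loglog()].
#' @param bins passed to [classify_motion()].
#' @return data.frame with one row per track: `track_id`, `n_points`,
#'   `duration_s`, `D`, `v`, `sse`, `p_directed`, `directed_flag`,
#'   `alpha`, `motion_class`.
#' @export
analyze_motion <- function(tracks, fit_range = 20, include_offset = FALSE,
                           lag_fraction = 0.25, bins = c(0.8, 1.5)) {
  per <- split_tracks(tracks)
  rows <- lapply(per, function(tr) {
    curve <- compute_msd(tr)
    fit <- fit_diffusion_ballistic(curve, fit_range,
                                   include_offset = include_offset)
    alpha <- suppressWarnings(fit_alpha_loglog(curve, lag_fraction))
    data.frame(track_id = tr$track_id[1], n_points = nrow(tr),
               duration_s = max(tr$t_s) - min(tr$t_s),
               D = fit$D, v = fit$v, sse = fit$sse,
               p_directed = fit$p_directed,
               directed_flag = fit$directed_flag,
               alpha = alpha,
               motion_class = classify_motion(alpha, bins),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Ensemble summary of motion fits
#'
#' @param fits data.frame from [analyze_motion()] (needs `motion_class`,
#'   `v`, `directed_flag`).
#' @return list with `fractions` (named numeric over the three classes,
#'   summing to 1), `n`, `n_directed`, and `v_summary` (quantiles of the
#'   fitted velocities).
#' @export
summarize_motion <- function(fits) {
  if (is.null(fits) || !nrow(fits)) stop("no motion fits to summarize")
  classes <- c("constrained", "diffusive", "transported")
  counts <- table(factor(fits$motion_class, levels = classes))
  list(fractions = setNames(as.numeric(counts) / nrow(fits), classes),
       n = nrow(fits),
       n_directed = sum(fits$directed_flag),
       v_summary = stats::quantile(fits$v, c(0, 0.25, 0.5, 0.75, 1)))
}
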