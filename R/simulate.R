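#' @importFrom stats rnorm rpois runif pnorm pf setNames median
NULL

# Derive a per-particle seed from a base seed and a particle counter, so
# trajectories are reproducible regardless of the order in which particles
# are generated. Kept below 2^31 - 1.
particle_seed <- function(seed, i) {
  as.integer((as.double(seed) %% 2147483647 * 7919 + i * 104729) %% 2147483647)
}

#' Simulate a single 2D particle trajectory
#'
#' Generates a discrete-time trajectory under the given motion model.
#' Brownian steps are i.i.d. Gaussian with per-axis variance `2*D*dt`;
#' directed motion adds a constant drift `v*dt` per frame; confined motion
#' reflects Brownian steps specularly at a circular boundary of radius `R`
#' centred on the starting point. Independent Gaussian localization error
#' of s.d. `sigma_loc` is added per coordinate to the *observed* positions;
#' the returned ground truth stores the noise-free path.
#'
#' @param model a [motion_model()].
#' @param n_frames number of frames (>= 2).
#' @param dt frame interval in seconds (> 0).
#' @param seed integer seed; identical seeds give identical output.
#' @param origin starting position `c(x, y)` in um.
#' @param particle_id id recorded in the output tables.
#'
#' @return a list with `track` (data.frame: `track_id`, `frame`, `t_s`,
#'   `x_um`, `y_um` — observed positions) and `truth` (data.frame of true
#'   positions plus the generative parameters).
#' @export
simulate_trajectory <- function(model, n_frames, dt, seed = 1,
                                origin = c(0, 0), particle_id = 1L) {
  stopifnot(inherits(model, "motion_model"))
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    stop("dt must be a positive number")
  if (!is.numeric(n_frames) || n_frames < 2)
    stop("n_frames must be at least 2")
  n_frames <- as.integer(n_frames)
  set.seed(particle_seed(seed, particle_id))

  step_sd <- sqrt(2 * model$D * dt)
  dx <- rnorm(n_frames - 1L, sd = step_sd)
  dy <- rnorm(n_frames - 1L, sd = step_sd)
  if (model$kind == "directed") {
    dx <- dx + model$v[1] * dt
    dy <- dy + model$v[2] * dt
  }
  x <- origin[1] + c(0, cumsum(dx))
  y <- origin[2] + c(0, cumsum(dy))

  if (model$kind == "confined") {
    # specular (radial) reflection at the corral boundary
    x <- numeric(n_frames); y <- numeric(n_frames)
    x[1] <- origin[1]; y[1] <- origin[2]
    for (i in seq_len(n_frames - 1L)) {
      px <- x[i] + dx[i]; py <- y[i] + dy[i]
      repeat {
        d <- sqrt((px - origin[1])^2 + (py - origin[2])^2)
        if (d <= model$R) break
        scale <- (2 * model$R - d) / d
        px <- origin[1] + (px - origin[1]) * scale
        py <- origin[2] + (py - origin[2]) * scale
      }
      x[i + 1L] <- px; y[i + 1L] <- py
    }
  }

  obs_x <- x + rnorm(n_frames, sd = model$sigma_loc)
  obs_y <- y + rnorm(n_frames, sd = model$sigma_loc)
  frames <- 0:(n_frames - 1L)

  track <- data.frame(track_id = particle_id, frame = frames,
                      t_s = frames * dt, x_um = obs_x, y_um = obs_y)
  truth <- data.frame(particle_id = particle_id, frame = frames,
                      t_s = frames * dt, x_um = x, y_um = y,
                      channel = 1L, coloc_label = "none",
                      model_kind = model$kind, D = model$D,
                      vx = if (model$kind == "directed") model$v[1] else 0,
                      vy = if (model$kind == "directed") model$v[2] else 0,
                      R = if (model$kind == "confined") model$R else NA_real_,
                      stringsAsFactors = FALSE)
  list(track = track, truth = truth)
}

#' Simulate an ensemble of trajectories
#'
#' Convenience wrapper generating many particles, optionally scattering
#' their origins uniformly over a field of view (with a margin so rendered
#' spots stay inside the frame).
#'
#' @param models a single [motion_model()] or a list of them (recycled over
#'   particles in order).
#' @param n_particles number of particles.
#' @param n_frames,dt as in [simulate_trajectory()].
#' @param seed base seed; each particle uses a counter-derived substream.
#' @param fov_um field-of-view size `c(width, height)` in um, or `NULL` to
#'   start every particle at the origin.
#' @param margin_um margin kept clear of the field edges (um).
#'
#' @return list with `tracks` and `truth` data.frames (all particles
#'   row-bound).
#' @export
simulate_ensemble <- function(models, n_particles, n_frames, dt, seed = 1,
                              fov_um = NULL, margin_um = 2) {
  if (inherits(models, "motion_model")) models <- list(models)
  stopifnot(length(models) >= 1L, n_particles >= 1L)
  set.seed(particle_seed(seed, 0L))
  if (!is.null(fov_um)) {
    ox <- runif(n_particles, margin_um, fov_um[1] - margin_um)
    oy <- runif(n_particles, margin_um, fov_um[2] - margin_um)
  } else {
    ox <- rep(0, n_particles); oy <- rep(0, n_particles)
  }
  sims <- lapply(seq_len(n_particles), function(i) {
    m <- models[[(i - 1L) %% length(models) + 1L]]
    simulate_trajectory(m, n_frames, dt, seed = seed,
                        origin = c(ox[i], oy[i]), particle_id = i)
  })
  list(tracks = do.call(rbind, lapply(sims, `[[`, "track")),
       truth = do.call(rbind, lapply(sims, `[[`, "truth")))
}
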