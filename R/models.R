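#' Motion model for a simulated particle
#'
#' Describes the generative kinetics of one particle in the plane. Three
#' regimes are supported: free Brownian diffusion, directed (ballistic)
#' transport superimposed on diffusion, and diffusion confined to a circular
#' corral. These correspond to the three canonical MSD signatures: linear
#' (slope `4*D`), quadratic (`4*D*dt + v^2*dt^2`) and plateauing.
#'
#' @param kind one of `"brownian"`, `"directed"`, `"confined"`.
#' @param D translational diffusion coefficient (um^2/s, >= 0).
#' @param v ballistic velocity vector `c(vx, vy)` in um/s; required (and
#'   non-zero) when `kind = "directed"`, ignored otherwise.
#' @param R confinement radius in um; required (> 0) when
#'   `kind = "confined"`, ignored otherwise.
#' @param sigma_loc static localization error s.d. per coordinate (um,
#'   >= 0). Adds an offset of `4*sigma_loc^2` to the observed MSD.
#'
#' @return an object of class `motion_model`.
#' @export
motion_model <- function(kind = c("brownian", "directed", "confined"),
                         D = 0, v = c(0, 0), R = NA_real_,
                         sigma_loc = 0) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(D), length(D) == 1L, !is.na(D), D >= 0,
            is.numeric(sigma_loc), length(sigma_loc) == 1L, sigma_loc >= 0)
  if (kind == "directed") {
    stopifnot(is.numeric(v), length(v) == 2L, all(is.finite(v)))
    if (sqrt(sum(v^2)) <= 0)
      stop("directed motion requires a non-zero velocity vector")
  }
  if (kind == "confined") {
    if (!is.numeric(R) || length(R) != 1L || is.na(R) || R <= 0)
      stop("confined motion requires a confinement radius R > 0")
  }
  structure(list(kind = kind, D = D, v = as.numeric(v), R = R,
                 sigma_loc = sigma_loc),
            class = "motion_model")
}

#' @export
print.motion_model <- function(x, ...) {
  extra <- switch(x$kind,
    brownian = "",
    directed = sprintf(", v = (%.3g, %.3g) um/s", x$v[1], x$v[2]),
    confined = sprintf(", R = %.3g um", x$R))
  cat(sprintf("<motion_model: %s, D = %.3g um^2/s%s, sigma_loc = %.3g um>\n",
              x$kind, x$D, extra, x$sigma_loc))
  invisible(x)
}

#' Optical / acquisition model for movie rendering
#'
#' Bundles the imaging parameters used to render ground-truth particle
#' positions into synthetic camera frames: geometry (pixel size, PSF
#' width), timing, photon budget and noise. Defaults emulate a confocal
#' live-imaging acquisition at ~1 frame/s with ~190 nm pixels.
#'
#' @param pixel_size um per pixel.
#' @param psf_sigma Gaussian PSF standard deviation (um). Must satisfy
#'   `psf_sigma >= pixel_size / 4` (sampling sanity).
#' @param frame_interval seconds between frames.
#' @param photons_per_particle expected photon count per particle per frame.
#' @param background mean background level (counts/pixel).
#' @param read_noise_sd additive Gaussian read noise s.d. (counts).
#' @param bit_depth camera bit depth; output clipped to `[0, 2^bit_depth - 1]`.
#'
#' @return an object of class `optics_model`.
#' @export
optics_model <- function(pixel_size = 0.19, psf_sigma = 0.15,
                         frame_interval = 1, photons_per_particle = 5000,
                         background = 100, read_noise_sd = 2,
                         bit_depth = 16) {
  vals <- c(pixel_size, psf_sigma, frame_interval, photons_per_particle,
            background, bit_depth)
  stopifnot(all(is.finite(vals)), all(vals > 0) || photons_per_particle >= 0,
            is.finite(read_noise_sd), read_noise_sd >= 0)
  if (pixel_size <= 0 || psf_sigma <= 0 || frame_interval <= 0 ||
      background <= 0 || bit_depth <= 0)
    stop("optics parameters must be strictly positive")
  if (photons_per_particle < 0)
    stop("photons_per_particle must be >= 0")
  if (psf_sigma < pixel_size / 4)
    stop("psf_sigma must be at least pixel_size / 4 (undersampled PSF)")
  structure(list(pixel_size = pixel_size, psf_sigma = psf_sigma,
                 frame_interval = frame_interval,
                 photons_per_particle = photons_per_particle,
                 background = background, read_noise_sd = read_noise_sd,
                 bit_depth = as.integer(bit_depth)),
            class = "optics_model")
}

#' Linking configuration for LAP tracking
#'
#' @param linking_max_distance maximum frame-to-frame link distance (um).
#' @param gap_closing_max_distance maximum distance bridged when closing a
#'   gap between track segments (um).
#' @param max_frame_gap maximum frame difference bridged by gap closing.
#'
#' @return an object of class `linking_config`.
#' @export
linking_config <- function(linking_max_distance = 1,
                           gap_closing_max_distance = 1,
                           max_frame_gap = 5) {
  stopifnot(linking_max_distance >= 0, gap_closing_max_distance >= 0,
            max_frame_gap >= 0)
  structure(list(linking_max_distance = linking_max_distance,
                 gap_closing_max_distance = gap_closing_max_distance,
                 max_frame_gap = as.integer(max_frame_gap)),
            class = "linking_config")
}
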